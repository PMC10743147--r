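## ---- residue template ---------------------------------------------------
## One nucleotide-like residue: 12 sugar-phosphate atoms + 20 base atoms,
## in a local (radial, tangential, axial) frame with the phosphorus at the
## origin and the phosphate oxygens pointing radially outward (so a
## nanoparticle substituted onto O1P/O2P extends away from the chain).
.residueTemplate <- function() {
  sugar <- rbind(
    P     = c( 0.00,  0.00,  0.00),
    O1P   = c( 1.245,  0.10,  0.872),
    O2P   = c( 1.245, -0.10, -0.872),
    `O5'` = c(-0.70,  0.90,  0.90),
    `C5'` = c(-2.20,  1.20,  1.00),
    `C4'` = c(-2.90,  0.50,  2.20),
    `O4'` = c(-3.40, -0.70,  1.70),
    `C3'` = c(-3.90,  1.30,  2.90),
    `O3'` = c(-4.30,  2.40,  2.20),
    `C2'` = c(-4.90,  0.40,  3.20),
    `O2'` = c(-5.70,  0.90,  4.10),
    `C1'` = c(-4.50, -0.90,  2.50)
  )
  ## base: two stacked rings of generic C/N/O atoms, inward of the sugar
  baseNames <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9", "O10",
                 "C11", "N12", "C13", "O14", "N15", "C16", "C17", "N18",
                 "C19", "O20")
  ang1 <- 2 * pi * (0:9) / 10
  ring1 <- cbind(-6.5 + 2.2 * cos(ang1), 2.2 * sin(ang1), rep(2.5, 10))
  ang2 <- 2 * pi * (0:9) / 10 + pi / 10
  ring2 <- cbind(-6.5 + 1.2 * cos(ang2), 1.2 * sin(ang2), rep(3.6, 10))
  base <- rbind(ring1, ring2)
  rownames(base) <- baseNames
  rbind(sugar, base)
}

## 15-atom terminal cap appended after the last residue (names start with
## the element letter, as throughout the synthetic generator).
.capTemplate <- function() {
  k <- 0:14
  el <- c("O", "C", "N")[k %% 3 + 1]
  nm <- paste0(el, "T", k + 1)
  xyz <- cbind(-1.0 - 1.1 * (k %% 5), 0.9 * (k %% 3) - 0.9, 1.1 * (k %/% 5))
  rownames(xyz) <- nm
  xyz
}

.elementFromName <- function(name) {
  ## first alphabetic character; adequate for the synthetic naming scheme
  sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", name)
}

#' Generate a synthetic fluctuating ssRNA-like conformer ensemble
#'
#' Emulates molecular-dynamics snapshots of a single-stranded RNA without
#' running MD. Residues (32 atoms each: phosphate, ribose-like sugar, and
#' a 20-atom base cluster) are placed along a compact superhelical
#' backbone (radius 28 A, 22 residues per turn, 16 A pitch), so a
#' 70-residue chain occupies a ~90 A extent comparable to a folded RNA of
#' that size, and the phosphate oxygens point outward, leaving sterically
#' feasible nanoparticle attachment sites. A 15-atom terminal cap brings
#' a 70-residue chain to exactly 2255 atoms.
#'
#' Snapshot-to-snapshot fluctuations are the sum of (a) three
#' low-frequency backbone bending modes (random 3D direction, phase, and
#' amplitude `fluctuationAmplitude / m` for mode `m`), which displace
#' whole residues coherently and give correlated inter-site distance
#' fluctuations of a few Angstrom, and (b) i.i.d. Gaussian jitter with
#' standard deviation `0.3 * fluctuationAmplitude`, drawn per atom except
#' within each phosphate group (P/O1P/O2P/O5'), whose four atoms share one
#' draw: bond and angle stiffness make intra-phosphate relative motion
#' negligible, and a rigid phosphate keeps the nanoparticle anchor
#' geometry chemically sensible.
#'
#' @param nResidues number of residues (>= 2).
#' @param nSnapshots number of snapshots (>= 1).
#' @param fluctuationAmplitude collective fluctuation scale, Angstrom.
#' @param seed integer RNG seed; the ensemble is deterministic given it.
#' @return an [Ensemble-class] with `source = "synthetic"`.
#' @examples
#' ens <- syntheticEnsemble(nResidues = 10, nSnapshots = 3, seed = 1)
#' @export
syntheticEnsemble <- function(nResidues = 70, nSnapshots = 30,
                              fluctuationAmplitude = 2, seed = 1) {
  if (nResidues < 2) stop("invalid argument: nResidues must be >= 2")
  if (nSnapshots < 1) stop("invalid argument: nSnapshots must be >= 1")
  if (fluctuationAmplitude < 0)
    stop("invalid argument: fluctuationAmplitude must be >= 0")
  set.seed(as.integer(seed))

  tmpl <- .residueTemplate()
  cap <- .capTemplate()
  helixRadius <- 28; resPerTurn <- 22; pitch <- 16
  dTheta <- 2 * pi / resPerTurn
  rise <- pitch / resPerTurn

  placeResidue <- function(r, local) {
    th <- r * dTheta
    er <- c(cos(th), sin(th), 0)
    et <- c(-sin(th), cos(th), 0)
    ez <- c(0, 0, 1)
    ctr <- c(helixRadius * cos(th), helixRadius * sin(th), r * rise)
    sweep(local[, 1, drop = FALSE] %*% rbind(er) +
          local[, 2, drop = FALSE] %*% rbind(et) +
          local[, 3, drop = FALSE] %*% rbind(ez), 2, ctr, "+")
  }

  baseXYZ <- do.call(rbind, lapply(seq_len(nResidues), placeResidue, local = tmpl))
  baseXYZ <- rbind(baseXYZ, placeResidue(nResidues + 1, cap))
  atomName <- c(rep(rownames(tmpl), nResidues), rownames(cap))
  residueIndex <- c(rep(seq_len(nResidues), each = nrow(tmpl)),
                    rep(nResidues + 1L, nrow(cap)))
  atomTab <- data.frame(element = .elementFromName(atomName),
                        atomName = atomName, residueIndex = residueIndex,
                        stringsAsFactors = FALSE)
  ## arc-length parameter per atom (whole residues move together in modes)
  s <- residueIndex / (nResidues + 1)

  ## jitter groups: each phosphate moiety is rigid, everything else per-atom
  phosphate <- atomName %in% c("P", "O1P", "O2P", "O5'")
  group <- integer(nrow(atomTab))
  group[phosphate] <- residueIndex[phosphate]
  group[!phosphate] <- max(residueIndex) + seq_len(sum(!phosphate))
  group <- match(group, unique(group))
  nGroup <- max(group)

  jitterSd <- 0.3 * fluctuationAmplitude
  confs <- vector("list", nSnapshots)
  for (snap in seq_len(nSnapshots)) {
    disp <- matrix(0, nrow(baseXYZ), 3)
    for (m in 1:3) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      amp <- fluctuationAmplitude / m
      phase <- runif(1, 0, 2 * pi)
      disp <- disp + outer(amp * sin(pi * m * s + phase), u)
    }
    jit <- matrix(rnorm(3 * nGroup, 0, jitterSd), ncol = 3)
    xyz <- baseXYZ + disp + jit[group, , drop = FALSE]
    dimnames(xyz) <- NULL
    confs[[snap]] <- Conformer(atomTab, xyz, snapshotId = snap)
  }
  Ensemble(confs, source = "synthetic")
}

## ---- PDB input ----------------------------------------------------------

#' Read a conformer from a PDB file
#'
#' Parses a standard PDB file (ATOM/HETATM records) via [bio3d::read.pdb]
#' and returns the first model as a [Conformer-class]. Elements are taken
#' from the element column (77-78) when present, case-normalized (so
#' "AU" becomes "Au"), with a fallback heuristic from the atom name.
#'
#' @param path path to a PDB file.
#' @return a [Conformer-class].
#' @export
readPDB <- function(path) {
  if (!file.exists(path)) stop("PDB format error: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^(ATOM|HETATM)", lines)))
    stop("PDB format error at line ", length(lines) + 1L,
         ": no ATOM/HETATM records in ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("PDB format error: ", conditionMessage(e)))
  at <- pdb$atom
  elem <- at$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  elem[bad] <- substr(trimws(at$elety[bad]), 1L, 1L)
  elem <- trimws(elem)
  ## normalize case: AU -> Au, o -> O
  elem <- paste0(toupper(substr(elem, 1, 1)), tolower(substr(elem, 2, 10)))
  atomTab <- data.frame(element = elem, atomName = trimws(at$elety),
                        residueIndex = as.integer(at$resno),
                        stringsAsFactors = FALSE)
  xyz <- unname(cbind(at$x, at$y, at$z))
  Conformer(atomTab, xyz, snapshotId = 1L)
}

## ---- rotations ----------------------------------------------------------

.eulerMatrix <- function(alpha, beta, gamma) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- function(b) matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

#' Rigidly rotate a conformer
#'
#' Applies the intrinsic z-y'-z'' Euler rotation `Rz(alpha) Ry(beta)
#' Rz(gamma)` to all atoms about the rotation centre (the structure
#' centroid by default). Pairwise distances are preserved to machine
#' precision.
#'
#' @param conformer a [Conformer-class].
#' @param alpha,beta,gamma Euler angles, radian.
#' @param center 3-vector rotation centre; default the coordinate centroid.
#' @return the rotated [Conformer-class].
#' @export
rotateConformer <- function(conformer, alpha, beta, gamma, center = NULL) {
  stopifnot(is(conformer, "Conformer"))
  if (is.null(center)) center <- colMeans(conformer@xyz)
  R <- .eulerMatrix(alpha, beta, gamma)
  xyz <- sweep(sweep(conformer@xyz, 2, center) %*% t(R), 2, center, "+")
  initialize(conformer, xyz = xyz)
}

#' Draw Haar-uniform random Euler angles
#'
#' `alpha, gamma ~ U(0, 2 pi)` and `cos(beta) ~ U(-1, 1)`, giving
#' orientations uniform over the rotation group.
#'
#' @param n number of angle triples.
#' @return an `n x 3` matrix with columns alpha, beta, gamma.
#' @export
randomEulerAngles <- function(n = 1) {
  cbind(alpha = runif(n, 0, 2 * pi),
        beta = acos(runif(n, -1, 1)),
        gamma = runif(n, 0, 2 * pi))
}

#' Build an ensemble of random orientations of one conformer
#'
#' @param conformer a [Conformer-class].
#' @param nOrient number of random orientations (>= 1).
#' @param seed RNG seed.
#' @return an [Ensemble-class] with `source = "pdb_multi_orientation"`.
#' @export
orientationEnsemble <- function(conformer, nOrient = 30, seed = 1) {
  stopifnot(is(conformer, "Conformer"), nOrient >= 1)
  set.seed(as.integer(seed))
  ang <- randomEulerAngles(nOrient)
  confs <- lapply(seq_len(nOrient), function(i) {
    cf <- rotateConformer(conformer, ang[i, 1], ang[i, 2], ang[i, 3])
    initialize(cf, snapshotId = as.integer(i))
  })
  Ensemble(confs, source = "pdb_multi_orientation")
}

## ---- nanoparticle labeling ----------------------------------------------

#' Enumerate candidate nanoparticle labeling sites
#'
#' For RNA, the two free phosphate oxygens (atom names O1P/O2P, with the
#' OP1/OP2 aliases also accepted); for proteins, the backbone carbonyl
#' oxygen of the peptide bond (atom name "O").
#'
#' @param conformer a [Conformer-class].
#' @param moleculeKind `"rna"` or `"protein"`.
#' @return data.frame with columns `residueIndex`, `atomName` (possibly
#'   zero rows).
#' @export
enumerateLabelSites <- function(conformer, moleculeKind = c("rna", "protein")) {
  moleculeKind <- match.arg(moleculeKind)
  at <- conformer@atoms
  keep <- if (moleculeKind == "rna") {
    at$atomName %in% c("O1P", "O2P", "OP1", "OP2")
  } else {
    at$atomName == "O"
  }
  out <- at[keep, c("residueIndex", "atomName")]
  rownames(out) <- NULL
  out
}

## Row index of a site in the atom table (error if absent).
.siteRow <- function(conformer, site) {
  at <- conformer@atoms
  i <- which(at$residueIndex == site$residueIndex & at$atomName == site$atomName)
  if (length(i) != 1L)
    stop("site (", site$residueIndex, ", ", site$atomName,
         ") not found uniquely in conformer")
  i
}

## Atom rows of the site's anchoring moiety, excluded from the clash scan:
## the residue's phosphate group for phosphate-oxygen sites, the carbonyl
## C/O for backbone-oxygen sites.
.anchorMoietyRows <- function(conformer, site) {
  at <- conformer@atoms
  moiety <- if (site$atomName %in% c("O1P", "O2P", "OP1", "OP2"))
    c("P", "O1P", "O2P", "OP1", "OP2", "O5'")
  else c("C", "O")
  which(at$residueIndex == site$residueIndex & at$atomName %in% moiety)
}

## Bonded heavy-atom partner of a labeling site: the phosphate P for
## O1P/O2P-type sites, the carbonyl C for a backbone "O".
.partnerRow <- function(conformer, site) {
  at <- conformer@atoms
  partnerName <- if (site$atomName %in% c("O1P", "O2P", "OP1", "OP2")) "P" else "C"
  i <- which(at$residueIndex == site$residueIndex & at$atomName == partnerName)
  if (length(i) != 1L)
    stop("geometry error: bonded partner '", partnerName,
         "' of site (", site$residueIndex, ", ", site$atomName, ") not found")
  i
}

#' Place a gold nanoparticle on a labeling site
#'
#' The sphere centre is the labeled oxygen displaced outward by `R` along
#' the bond direction from its bonded heavy atom (phosphorus for
#' phosphate oxygens, carbonyl carbon for backbone oxygens), so the
#' sphere surface passes through the original oxygen position. The
#' placement is rejected if any atom outside the site's own anchoring
#' moiety (for phosphate sites the residue's P/O1P/O2P/O5' group, for
#' backbone carbonyl sites its C and O) lies within `R + clashMargin` of
#' the centre; the anchoring moiety is the covalent attachment point of
#' the particle and permanently sits at the margin boundary.
#'
#' @param conformer a [Conformer-class].
#' @param site list with `residueIndex` and `atomName`.
#' @param R nanoparticle radius, Angstrom.
#' @param clashMargin steric margin, Angstrom (default 1.5, roughly a
#'   heavy-atom van der Waals radius).
#' @return list with `accepted` (logical), `center` (3-vector, or NULL if
#'   rejected), `siteRow`, `partnerRow`, and `minClearance` (smallest
#'   centre-to-atom distance among scanned atoms).
#' @export
placeAuNP <- function(conformer, site, R, clashMargin = 1.5) {
  stopifnot(is(conformer, "Conformer"), R > 0)
  iO <- .siteRow(conformer, site)
  iP <- .partnerRow(conformer, site)
  o <- conformer@xyz[iO, ]
  p <- conformer@xyz[iP, ]
  u <- o - p
  u <- u / sqrt(sum(u^2))
  center <- o + R * u
  others <- setdiff(seq_len(nrow(conformer@xyz)),
                    .anchorMoietyRows(conformer, site))
  d2 <- colSums((t(conformer@xyz[others, , drop = FALSE]) - center)^2)
  minClear <- sqrt(min(d2))
  accepted <- minClear >= R + clashMargin
  list(accepted = accepted, center = if (accepted) center else NULL,
       siteRow = iO, partnerRow = iP, minClearance = minClear)
}

## AuNP centres of one site across all conformers; NULL if the placement
## is rejected in any conformer (all-snapshot feasibility).
.siteCenters <- function(ensemble, site, R, clashMargin) {
  centers <- matrix(NA_real_, length(ensemble@conformers), 3)
  for (i in seq_along(ensemble@conformers)) {
    pl <- placeAuNP(ensemble@conformers[[i]], site, R, clashMargin)
    if (!pl$accepted) return(NULL)
    centers[i, ] <- pl$center
  }
  centers
}

#' Select feasible nanoparticle label-site pairs on an ensemble
#'
#' Randomly selects between `nPairsMin` and `nPairsMax` site pairs such
#' that, in every conformer of the ensemble, both placements are sterically
#' accepted by [placeAuNP] and the inter-particle distance exceeds
#' `2.4 R` (so the two spheres never approach each other); across the
#' selected pairs, the ensemble-mean distances differ pairwise by at
#' least `minSpread`, covering a broad range of distances.
#'
#' @param ensemble an [Ensemble-class].
#' @param moleculeKind `"rna"` or `"protein"`.
#' @param R nanoparticle radius, Angstrom.
#' @param nPairsMin,nPairsMax number of pairs to return.
#' @param minSpread minimum pairwise difference of ensemble-mean
#'   distances, Angstrom.
#' @param clashMargin steric margin passed to [placeAuNP].
#' @param maxDistance optional upper bound on the ensemble-mean distance.
#' @param seed RNG seed; the selection is deterministic given it.
#' @return list of [LabelPair-class] objects.
#' @export
selectLabelPairs <- function(ensemble, moleculeKind = "rna", R = 9,
                             nPairsMin = 2, nPairsMax = 6, minSpread = 10,
                             clashMargin = 1.5, maxDistance = Inf, seed = 1) {
  stopifnot(is(ensemble, "Ensemble"), nPairsMin >= 1, nPairsMax >= nPairsMin)
  set.seed(as.integer(seed))
  sites <- enumerateLabelSites(ensemble@conformers[[1L]], moleculeKind)
  if (nrow(sites) < 2L)
    stop("no-feasible-labeling: fewer than two candidate sites of kind '",
         moleculeKind, "'")

  ## per-site feasibility + cached centres across all conformers
  centersList <- vector("list", nrow(sites))
  for (k in seq_len(nrow(sites))) {
    centersList[[k]] <- .siteCenters(
      ensemble, as.list(sites[k, ]), R, clashMargin)
  }
  feasibleSites <- which(!vapply(centersList, is.null, TRUE))
  if (length(feasibleSites) < 2L)
    stop("no-feasible-labeling: fewer than two sites pass the steric scan ",
         "(R + clashMargin = ", R + clashMargin, " A)")

  pairs <- t(utils::combn(feasibleSites, 2L))
  ## two oxygens of one and the same phosphate are never a useful pair
  pairs <- pairs[sites$residueIndex[pairs[, 1L]] !=
                 sites$residueIndex[pairs[, 2L]], , drop = FALSE]

  ## distance constraints per candidate pair
  rList <- vector("list", nrow(pairs))
  meanR <- rep(NA_real_, nrow(pairs))
  for (rix in seq_len(nrow(pairs))) {
    ca <- centersList[[pairs[rix, 1L]]]; cb <- centersList[[pairs[rix, 2L]]]
    r <- sqrt(rowSums((cb - ca)^2))
    if (any(r <= 2.4 * R) || mean(r) > maxDistance) next
    rList[[rix]] <- r
    meanR[rix] <- mean(r)
  }
  eligible <- which(!is.na(meanR))

  ## cover a broad distance range: ascending window greedy, randomized
  ## within each half-spread window, so up to nPairsMax pairs with
  ## pairwise mean separation >= minSpread are packed into the range
  chosen <- list(); lastMean <- -Inf
  while (length(chosen) < nPairsMax && length(eligible)) {
    ok <- eligible[meanR[eligible] >= lastMean + minSpread]
    if (!length(ok)) break
    lo <- min(meanR[ok])
    window <- ok[meanR[ok] <= lo + 3]
    rix <- window[sample.int(length(window), 1L)]
    a <- pairs[rix, 1L]; b <- pairs[rix, 2L]
    chosen[[length(chosen) + 1L]] <- new(
      "LabelPair",
      siteA = as.list(sites[a, ]), siteB = as.list(sites[b, ]),
      radius = R, centersA = centersList[[a]], centersB = centersList[[b]],
      rAuNP = rList[[rix]])
    lastMean <- meanR[rix]
    eligible <- setdiff(eligible, rix)
  }
  if (length(chosen) < nPairsMin)
    stop("no-feasible-labeling: only ", length(chosen), " pair(s) satisfy the ",
         "constraints (r_AuNP > 2.4 R = ", 2.4 * R, " A in every snapshot, ",
         "steric acceptance, mean spread >= ", minSpread, " A)")
  chosen
}

#' Write an ensemble and its labels to a plain-text archive
#'
#' Persists a labeled ensemble as a directory of text files: `atoms.csv`
#' (shared topology), `positions_<snap>.csv` (one coordinate table per
#' snapshot, Angstrom), `labels.csv` (per pair and snapshot: both sphere
#' centres, the ground-truth vector `d_true`, and `r_AuNP`), and
#' `meta.json`.
#'
#' @param ensemble an [Ensemble-class].
#' @param pairs list of [LabelPair-class] (may be empty).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
writeEnsembleArchive <- function(ensemble, pairs = list(), dir) {
  stopifnot(is(ensemble, "Ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfs <- ensemble@conformers
  data.table::fwrite(cfs[[1L]]@atoms, file.path(dir, "atoms.csv"))
  for (i in seq_along(cfs)) {
    data.table::fwrite(data.table::as.data.table(cfs[[i]]@xyz),
                       file.path(dir, sprintf("positions_%03d.csv", i)),
                       col.names = FALSE)
  }
  rows <- list()
  for (p in seq_along(pairs)) {
    pr <- pairs[[p]]
    for (i in seq_along(cfs)) {
      d <- pr@centersB[i, ] - pr@centersA[i, ]
      rows[[length(rows) + 1L]] <- data.table::data.table(
        pair = p, snapshot = i,
        resA = pr@siteA$residueIndex, atomA = pr@siteA$atomName,
        resB = pr@siteB$residueIndex, atomB = pr@siteB$atomName,
        radius = pr@radius,
        cax = pr@centersA[i, 1], cay = pr@centersA[i, 2],
        caz = pr@centersA[i, 3],
        cbx = pr@centersB[i, 1], cby = pr@centersB[i, 2],
        cbz = pr@centersB[i, 3],
        dx = d[1], dy = d[2], dz = d[3], r_AuNP = pr@rAuNP[i])
    }
  }
  if (length(rows))
    data.table::fwrite(data.table::rbindlist(rows),
                       file.path(dir, "labels.csv"))
  jsonlite::write_json(
    list(source = ensemble@source, n_snapshots = length(cfs),
         n_atoms = nrow(cfs[[1L]]@atoms), n_pairs = length(pairs)),
    file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read an ensemble archive written by [writeEnsembleArchive]
#'
#' @param dir archive directory.
#' @return list with `ensemble` (an [Ensemble-class]) and `labels` (a
#'   data.frame, or NULL when the archive carries no labels).
#' @export
readEnsembleArchive <- function(dir) {
  metaPath <- file.path(dir, "meta.json")
  if (!file.exists(metaPath)) stop("format error: no meta.json in ", dir)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  atomTab <- as.data.frame(data.table::fread(file.path(dir, "atoms.csv")))
  cfs <- lapply(seq_len(meta$n_snapshots), function(i) {
    xyz <- as.matrix(data.table::fread(
      file.path(dir, sprintf("positions_%03d.csv", i)), header = FALSE))
    dimnames(xyz) <- NULL
    Conformer(atomTab, xyz, snapshotId = i)
  })
  labelsPath <- file.path(dir, "labels.csv")
  labels <- if (file.exists(labelsPath))
    as.data.frame(data.table::fread(labelsPath)) else NULL
  list(ensemble = Ensemble(cfs, meta$source), labels = labels)
}

#' Attach a label pair to one conformer
#'
#' Builds the [LabeledStructure-class] for conformer `i` of the ensemble
#' the pair was selected on: the two sphere centres, the ground-truth
#' vector `d_true`, and (by default) the indices of the two substituted
#' oxygens, which are removed from the scattering sum.
#'
#' @param conformer the [Conformer-class] (conformer `i` of the ensemble).
#' @param pair a [LabelPair-class].
#' @param i conformer index into the pair's cached centres.
#' @param removeLabeledOxygen drop the substituted oxygens from the
#'   scattering sum? Default TRUE.
#' @return a [LabeledStructure-class].
#' @export
labeledStructure <- function(conformer, pair, i, removeLabeledOxygen = TRUE) {
  ca <- pair@centersA[i, ]; cb <- pair@centersB[i, ]
  removed <- if (removeLabeledOxygen) {
    c(.siteRow(conformer, pair@siteA), .siteRow(conformer, pair@siteB))
  } else integer(0)
  new("LabeledStructure", conformer = conformer, centerA = ca, centerB = cb,
      radius = pair@radius, dTrue = cb - ca, removedAtoms = as.integer(removed))
}
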