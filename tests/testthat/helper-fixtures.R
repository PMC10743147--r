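## Shared fixtures, built once per test run.

baselineBeam <- function() BeamParams(12, 1e14, 100)

tinyDetector <- function(n = 9) DetectorParams(n, 234, 40)

## cache for expensive objects
.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, force(expr), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

## small synthetic ensemble: 16 residues, 5 snapshots
miniEnsemble <- function() {
  cached("miniEnsemble", syntheticEnsemble(16, 5, 2, seed = 42))
}

## toy conformer built from explicit atoms; names must start with the
## element letter
toyConformer <- function(names, xyz, residue = NULL, snapshotId = 1L) {
  if (is.null(residue)) residue <- seq_along(names)
  atoms <- data.frame(element = sub("^([A-Za-z]).*$", "\\1", names),
                      atomName = names, residueIndex = as.integer(residue),
                      stringsAsFactors = FALSE)
  BioSOSS:::Conformer(atoms, xyz, snapshotId)
}

## a well-separated random cloud of light atoms
randomCloud <- function(nAtoms, seed = 1, spread = 20) {
  set.seed(seed)
  els <- sample(c("C", "N", "O", "P"), nAtoms, replace = TRUE)
  names <- paste0(els, seq_len(nAtoms))
  toyConformer(names, matrix(runif(3 * nAtoms, -spread, spread), ncol = 3))
}

## brute-force per-pixel, per-atom image (non-vectorized oracle)
bruteForceImage <- function(conformer, beam, detModel,
                            centers = NULL, R = NULL) {
  n <- nPixels(detModel)
  pref <- detModel@polarization * detModel@solidAngle *
    BioSOSS:::.re_A^2 * fluence(beam)
  out <- matrix(0, n, n)
  xyz <- coords(conformer)
  els <- atoms(conformer)$element
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- 0 + 0i
      q <- c(detModel@qx[i, j], detModel@qy[i, j], detModel@qz[i, j])
      for (k in seq_len(nrow(xyz))) {
        f <- atomicFormFactor(els[k], detModel@qmag[i, j])
        a <- a + f * exp(1i * sum(q * xyz[k, ]))
      }
      if (!is.null(centers)) {
        fN <- aunpFormFactor(detModel@qmag[i, j], R)
        for (k in seq_len(nrow(centers))) {
          a <- a + fN * exp(1i * sum(q * centers[k, ]))
        }
      }
      out[i, j] <- pref[i, j] * Mod(a)^2
    }
  }
  out
}

## write a minimal, column-correct PDB file; returns the path
writeToyPDB <- function(path, names, elements, xyz, resno = NULL) {
  if (is.null(resno)) resno <- seq_along(names)
  lines <- vapply(seq_along(names), function(i) {
    sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, names[i], "UNK", resno[i], xyz[i, 1], xyz[i, 2], xyz[i, 3],
            1, 0, elements[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}
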