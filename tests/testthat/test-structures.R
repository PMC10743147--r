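test_that("synthetic generator hits the reference atom count", {
  ## 70 residues x 32 atoms + 15-atom terminal cap = 2255
  ens <- syntheticEnsemble(70, 1, 0, seed = 1)
  expect_equal(nrow(atoms(conformers(ens)[[1]])), 2255L)
  ## general residue counts
  expect_equal(nrow(atoms(conformers(syntheticEnsemble(10, 1, 0, 1))[[1]])),
               10L * 32L + 15L)
})

test_that("zero fluctuation gives bitwise-identical snapshots", {
  ens <- syntheticEnsemble(8, 5, 0, seed = 3)
  xyz1 <- coords(conformers(ens)[[1]])
  for (cf in conformers(ens)[-1]) expect_identical(coords(cf), xyz1)
})

test_that("the generator is seed-deterministic and seed-sensitive", {
  a <- syntheticEnsemble(8, 3, 1.5, seed = 11)
  b <- syntheticEnsemble(8, 3, 1.5, seed = 11)
  c <- syntheticEnsemble(8, 3, 1.5, seed = 12)
  for (i in 1:3)
    expect_identical(coords(conformers(a)[[i]]), coords(conformers(b)[[i]]))
  expect_gt(max(abs(coords(conformers(a)[[1]]) - coords(conformers(c)[[1]]))), 0)
})

test_that("inter-site distances fluctuate when the amplitude is positive", {
  ens <- miniEnsemble()
  i <- which(atoms(conformers(ens)[[1]])$atomName == "O1P")[c(2, 12)]
  d <- vapply(conformers(ens), function(cf)
    sqrt(sum((coords(cf)[i[1], ] - coords(cf)[i[2], ])^2)), numeric(1))
  expect_gt(var(d), 0)
})

test_that("degenerate generator arguments are rejected", {
  expect_error(syntheticEnsemble(1, 5), "invalid argument")
  expect_error(syntheticEnsemble(8, 0), "invalid argument")
  expect_error(syntheticEnsemble(8, 5, -1), "invalid argument")
})

test_that("Euler rotation matches the quarter-turn and identity cases", {
  cf <- toyConformer(c("C1", "C2"), rbind(c(1, 0, 0), c(-1, 0, 0)))
  ## identity
  expect_equal(coords(rotateConformer(cf, 0, 0, 0)), coords(cf))
  ## quarter turn about z around the origin (the centroid)
  rot <- rotateConformer(cf, pi / 2, 0, 0, center = c(0, 0, 0))
  expect_equal(coords(rot), rbind(c(0, 1, 0), c(0, -1, 0)), tolerance = 1e-12)
})

test_that("rigid rotations preserve the full pairwise distance matrix", {
  cf <- randomCloud(25, seed = 8)
  d0 <- dist(coords(cf))
  set.seed(9)
  for (rep in 1:5) {
    ang <- randomEulerAngles(1)
    rot <- rotateConformer(cf, ang[1], ang[2], ang[3])
    expect_lt(max(abs(dist(coords(rot)) - d0) / d0), 1e-9)
  }
})

test_that("orientation ensembles are rigid, seeded, and sized correctly", {
  cf <- randomCloud(20, seed = 5)
  ens <- orientationEnsemble(cf, 30, seed = 1)
  expect_length(conformers(ens), 30L)
  expect_identical(ens@source, "pdb_multi_orientation")
  for (c2 in conformers(ens)[1:3])
    expect_lt(max(abs(dist(coords(c2)) - dist(coords(cf)))), 1e-8)
  ## different seeds displace at least one atom
  ens2 <- orientationEnsemble(cf, 30, seed = 2)
  expect_gt(max(abs(coords(conformers(ens)[[1]]) -
                    coords(conformers(ens2)[[1]]))), 0)
})

test_that("label-site enumeration follows the molecule kind", {
  ens <- syntheticEnsemble(70, 1, 0, seed = 1)
  cf <- conformers(ens)[[1]]
  sites <- enumerateLabelSites(cf, "rna")
  expect_equal(nrow(sites), 140L)  # two phosphate oxygens per residue
  ## OP1/OP2 aliases are accepted for RNA
  cf2 <- toyConformer(c("P", "OP1", "OP2", "C1'"),
                      rbind(c(0, 0, 0), c(1.5, 0, 0), c(-1.5, 0, 0),
                            c(0, 3, 0)), residue = c(1, 1, 1, 1))
  expect_equal(nrow(enumerateLabelSites(cf2, "rna")), 2L)
  ## protein enumeration on RNA-style names finds nothing
  expect_equal(nrow(enumerateLabelSites(cf, "protein")), 0L)
})

test_that("nanoparticle placement is collinear with the P-O bond", {
  cf <- toyConformer(c("P", "O1P", "C1'"),
                     rbind(c(0, 0, 0), c(1.5, 0, 0), c(50, 0, 0)),
                     residue = c(1, 1, 2))
  pl <- placeAuNP(cf, list(residueIndex = 1L, atomName = "O1P"), R = 9)
  expect_true(pl$accepted)
  expect_equal(pl$center, c(10.5, 0, 0), tolerance = 1e-12)
})

test_that("a nearby atom forces placement rejection", {
  cf <- toyConformer(c("P", "O1P", "C1'"),
                     rbind(c(0, 0, 0), c(1.5, 0, 0), c(10.5, 0, 2)),
                     residue = c(1, 1, 2))
  pl <- placeAuNP(cf, list(residueIndex = 1L, atomName = "O1P"), R = 9,
                  clashMargin = 0.5)
  expect_false(pl$accepted)   # distance 2 < 9.5
  expect_null(pl$center)
  expect_equal(pl$minClearance, 2, tolerance = 1e-12)
})

test_that("placement without a bonded partner is a geometry error", {
  cf <- toyConformer(c("O1P", "C1'"), rbind(c(0, 0, 0), c(5, 0, 0)),
                     residue = c(1, 2))
  expect_error(placeAuNP(cf, list(residueIndex = 1L, atomName = "O1P"), 9),
               "geometry error")
})

test_that("clash decisions agree with an exhaustive distance scan", {
  ens <- miniEnsemble()
  cf <- conformers(ens)[[2]]
  sites <- enumerateLabelSites(cf, "rna")
  xyz <- coords(cf); at <- atoms(cf)
  for (k in seq_len(nrow(sites))) {
    site <- as.list(sites[k, ])
    pl <- placeAuNP(cf, site, R = 9, clashMargin = 1.5)
    ## brute force: center from the bond geometry, scan all atoms
    ## outside the anchoring phosphate moiety
    iO <- which(at$residueIndex == site$residueIndex &
                at$atomName == site$atomName)
    iP <- which(at$residueIndex == site$residueIndex & at$atomName == "P")
    u <- xyz[iO, ] - xyz[iP, ]; u <- u / sqrt(sum(u^2))
    ctr <- xyz[iO, ] + 9 * u
    excl <- which(at$residueIndex == site$residueIndex &
                  at$atomName %in% c("P", "O1P", "O2P", "OP1", "OP2", "O5'"))
    dmin <- Inf
    for (a in setdiff(seq_len(nrow(xyz)), excl))
      dmin <- min(dmin, sqrt(sum((xyz[a, ] - ctr)^2)))
    expect_equal(pl$accepted, dmin >= 9 + 1.5, label = paste("site", k))
    expect_equal(pl$minClearance, dmin, tolerance = 1e-9)
  }
})

test_that("selected label pairs respect every constraint in every snapshot", {
  ens <- miniEnsemble()
  pairs <- selectLabelPairs(ens, "rna", R = 6, nPairsMin = 2, nPairsMax = 4,
                            minSpread = 8, seed = 7)
  expect_gte(length(pairs), 2L)
  expect_lte(length(pairs), 4L)
  means <- vapply(pairs, function(p) mean(rAuNP(p)), numeric(1))
  if (length(means) > 1L)
    expect_gte(min(dist(means)), 8)
  for (p in pairs) {
    expect_true(all(rAuNP(p) > 2.4 * 6))
    ## both placements re-accepted in every conformer
    for (i in seq_along(conformers(ens))) {
      for (site in list(p@siteA, p@siteB)) {
        pl <- placeAuNP(conformers(ens)[[i]], site, R = 6)
        expect_true(pl$accepted)
      }
    }
  }
  ## determinism
  pairs2 <- selectLabelPairs(ens, "rna", R = 6, nPairsMin = 2, nPairsMax = 4,
                             minSpread = 8, seed = 7)
  expect_equal(vapply(pairs2, function(p) mean(rAuNP(p)), numeric(1)), means)
})

test_that("the 2.4 R proximity rule excludes close pairs", {
  ## two isolated phosphates whose sphere centres end up exactly 20 A
  ## apart: excluded at R = 9 because 2.4 * 9 = 21.6 > 20
  cf <- toyConformer(c("P", "O1P", "P", "O1P"),
                     rbind(c(0, 0, 0), c(1.5, 0, 0),
                           c(41, 0, 0), c(39.5, 0, 0)),
                     residue = c(1, 1, 2, 2))
  ens <- BioSOSS:::Ensemble(list(cf), "synthetic")
  expect_error(selectLabelPairs(ens, "rna", R = 9, nPairsMin = 1, seed = 1),
               "no-feasible-labeling")
  ## the same geometry is feasible for a smaller particle (2.4*8 = 19.2)
  pairs <- selectLabelPairs(ens, "rna", R = 8, nPairsMin = 1, seed = 1)
  expect_equal(rAuNP(pairs[[1]]),
               41 - 1.5 - 8 - (1.5 + 8), tolerance = 1e-12)
})

test_that("PDB reading echoes coordinates and normalizes elements", {
  path <- tempfile(fileext = ".pdb")
  xyz <- rbind(c(1.5, 2.25, -3), c(0, 0, 0), c(4, 5, 6))
  writeToyPDB(path, c("O1P", "P", "AU"), c("O", "P", "AU"), xyz)
  cf <- readPDB(path)
  expect_equal(nrow(atoms(cf)), 3L)
  expect_equal(coords(cf), xyz, tolerance = 1e-6)
  expect_equal(atoms(cf)$element, c("O", "P", "Au"))
  expect_equal(atoms(cf)$atomName[1], "O1P")
})

test_that("ensemble archives round-trip through the text format", {
  ens <- miniEnsemble()
  pairs <- selectLabelPairs(ens, "rna", R = 6, nPairsMin = 1, nPairsMax = 2,
                            minSpread = 8, seed = 7)
  dir <- file.path(tempdir(), "ensArch")
  writeEnsembleArchive(ens, pairs, dir)
  back <- readEnsembleArchive(dir)
  expect_length(conformers(back$ensemble), length(conformers(ens)))
  expect_equal(coords(conformers(back$ensemble)[[3]]),
               coords(conformers(ens)[[3]]), tolerance = 1e-12)
  expect_equal(atoms(conformers(back$ensemble)[[1]])$atomName,
               atoms(conformers(ens)[[1]])$atomName)
  expect_equal(nrow(back$labels), length(pairs) * length(conformers(ens)))
  expect_equal(back$labels$r_AuNP[back$labels$pair == 1],
               rAuNP(pairs[[1]]), tolerance = 1e-9)
  expect_error(readEnsembleArchive(tempfile()), "format error")
  unlink(dir, recursive = TRUE)
})

test_that("PDB files without atoms are format errors", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER    NOTHING", "END"), path)
  expect_error(readPDB(path), "format error")
  expect_error(readPDB(tempfile()), "not found")
})
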