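test_that("component deltas follow the length-difference definition", {
  d0 <- componentDelta(c(3, 4, 0), c(3, 4, 0))
  expect_equal(unlist(d0), c(dx = 0, dy = 0, dz = 0, dr = 0))
  ## dr is a difference of lengths, not the length of the difference
  d1 <- componentDelta(c(3, 4, 0), c(0, 0, 5))
  expect_equal(d1$dr, 0)
  expect_equal(c(d1$dx, d1$dy, d1$dz), c(3, 4, -5))
  ## arithmetic oracle via explicit square roots
  set.seed(2)
  for (rep in 1:10) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(componentDelta(a, b)$dr,
                 sqrt(a[1]^2 + a[2]^2 + a[3]^2) -
                 sqrt(b[1]^2 + b[2]^2 + b[3]^2), tolerance = 1e-12)
  }
})

test_that("the Gaussian fit recovers a known normal distribution", {
  set.seed(17)
  x <- rnorm(1800, mean = 0, sd = 0.2)
  g <- gaussianFit(x)
  expect_lt(abs(g$std - 0.2) / 0.2, 0.1)
  expect_lt(abs(g$center), 0.02)
  expect_equal(g$n, 1800L)
  expect_equal(g$sampleStd, sd(x))
})

test_that("the Gaussian fit respects symmetry and degeneracy", {
  set.seed(4)
  half <- rnorm(400, 1, 0.5)
  sym <- c(half, -half)           # exactly symmetric about 0
  g <- gaussianFit(sym)
  expect_lt(abs(g$center), 1e-6)
  expect_warning(gd <- gaussianFit(rep(2.5, 50)), "degenerate")
  expect_equal(gd$center, 2.5)
  expect_equal(gd$std, 0)
})

test_that("ensemble runs produce one pooled row per snapshot-pair fit", {
  ens <- miniEnsemble()   # 5 snapshots
  pairs <- selectLabelPairs(ens, "rna", R = 6, nPairsMin = 2, nPairsMax = 2,
                            minSpread = 8, seed = 7)
  run <- cached("miniRun", runEnsemble(
    ens, pairs, baselineBeam(), DetectorParams(48, 234, 40),
    NoiseParams(poisson = FALSE, uniformMax = 0), FitConfig(), seed = 2,
    rnaScattering = FALSE))
  expect_equal(nrow(run$samples), 5L * 2L)
  expect_setequal(unique(run$samples$pair), c(1L, 2L))
  ## noiseless pure two-sphere images invert essentially exactly
  expect_true(all(abs(run$samples$dr) < 1e-3))
  expect_true(all(run$samples$converged))
  ## r_true in the table equals the labeled geometry after orientation
  expect_equal(run$samples$rTrue,
               sqrt(run$samples$xTrue^2 + run$samples$yTrue^2 +
                    run$samples$zTrue^2), tolerance = 1e-9)
})

test_that("ensemble runs are reproducible under a fixed seed", {
  ens <- miniEnsemble()
  pairs <- selectLabelPairs(ens, "rna", R = 6, nPairsMin = 2, nPairsMax = 2,
                            minSpread = 8, seed = 7)
  run1 <- cached("miniRun", stop("populated by the previous test"))
  run2 <- runEnsemble(ens, pairs, baselineBeam(), DetectorParams(48, 234, 40),
                      NoiseParams(poisson = FALSE, uniformMax = 0),
                      FitConfig(), seed = 2, rnaScattering = FALSE)
  expect_equal(run1$samples$rFit, run2$samples$rFit, tolerance = 0)
})

test_that("pooled delta statistics and histograms are well-formed", {
  run <- cached("miniRun", stop("populated earlier"))
  st <- run$stats
  expect_equal(st$nSamples, 10L)
  for (q in c("dr", "dx", "dy", "dz")) expect_true(st[[q]]$std >= 0)
  h <- distanceHistograms(run$samples)
  expect_equal(sum(h$rFit$probability), 1, tolerance = 1e-12)
  expect_equal(sum(h$rTrue$probability), 1, tolerance = 1e-12)
  ## failed fits are excluded with an explicit error when all fail
  bad <- run$samples
  bad$converged <- FALSE
  expect_error(deltaStats(bad), "empty-stats")
})

test_that("sweeps validate their arguments", {
  ens <- miniEnsemble()
  expect_error(runSweep("tilt", c(1, 2), ens, baselineBeam(), tinyDetector(16)),
               "unknown parameter.*R, energy, n_pixels, photons, focal_size, distance")
  expect_error(runSweep("R", numeric(0), ens, baselineBeam(), tinyDetector(16)),
               "non-empty")
  expect_error(runSweep("R", c(9, 6), ens, baselineBeam(), tinyDetector(16)),
               "strictly increasing")
})

test_that("radius sweeps keep sites fixed and flag infeasible radii", {
  ens <- miniEnsemble()
  ## under a 60 A distance cap the proximity rule 2.4 * 24 = 57.6 A leaves
  ## no room at R = 24 on this small helix: flagged, not fatal
  sw <- runSweep("R", c(6, 7, 24), ens, baselineBeam(),
                 DetectorParams(48, 234, 40),
                 NoiseParams(poisson = FALSE, uniformMax = 0), FitConfig(),
                 nPairsMin = 1, nPairsMax = 2, minSpread = 8, seed = 7,
                 maxDistance = 60, rnaScattering = FALSE)
  expect_equal(nrow(sw$table), 3L)
  expect_false(sw$table$feasible[3])
  expect_true(all(sw$table$feasible[1:2]))
  expect_true(all(is.na(sw$table$sigmaDr[3])))
  r1 <- sw$runs[[1]]$samples; r2 <- sw$runs[[2]]$samples
  expect_gt(nrow(r1), 0L); expect_gt(nrow(r2), 0L)
  ## smaller spheres anchored on the same sites sit closer to the oxygen,
  ## so the same pair is slightly shorter at R = 6 than at R = 7
  expect_true(all(r1$rTrue < r2$rTrue[seq_len(nrow(r1))] + 5))
})
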