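dmTiny <- function(n = 9, beam = baselineBeam()) buildDetector(beam, tinyDetector(n))

test_that("an empty scatterer yields an all-zero image", {
  img <- simulateImage(NULL, baselineBeam(), dmTiny())
  expect_true(all(counts(img) == 0))
})

test_that("a single gold atom reproduces the bare atomic envelope", {
  beam <- baselineBeam(); dm <- dmTiny(9)
  cf <- toyConformer("AU1", rbind(c(0, 0, 0)))
  cf@atoms$element <- "Au"
  img <- simulateImage(cf, beam, dm)
  pref <- dm@polarization * dm@solidAngle * BioSOSS:::.re_A^2 * fluence(beam)
  expect_equal(counts(img),
               pref * matrix(atomicFormFactor("Au", dm@qmag), 9, 9)^2,
               tolerance = 1e-12)
})

test_that("vectorized image synthesis matches the brute-force double loop", {
  beam <- BeamParams(9, 5e13, 150)
  dm <- dmTiny(8, beam)
  cf <- randomCloud(10, seed = 3)
  img <- simulateImage(cf, beam, dm)
  expect_equal(counts(img), bruteForceImage(cf, beam, dm), tolerance = 1e-10)
})

test_that("unsupported elements in the scatterer are rejected", {
  cf <- toyConformer("X1", rbind(c(0, 0, 0)))
  expect_error(simulateImage(cf, baselineBeam(), dmTiny()),
               "unsupported element")
})

test_that("two coincident spheres quadruple the single-sphere envelope", {
  beam <- baselineBeam(); dm <- dmTiny(9)
  img <- twoAuNPImage(c(0, 0, 0), 9, beam, dm)
  pref <- dm@polarization * dm@solidAngle * BioSOSS:::.re_A^2 * fluence(beam)
  single <- pref * matrix(aunpFormFactor(dm@qmag, 9), 9, 9)^2
  expect_equal(counts(img), 4 * single, tolerance = 1e-12)
})

test_that("the analytic two-sphere model agrees with the forward simulator", {
  beam <- baselineBeam(); dm <- dmTiny(11)
  d <- c(17, -24, 8)
  ## translation invariance: arbitrary common offset of both centres
  centers <- rbind(c(3, 4, 5), c(3, 4, 5) + d)
  full <- simulateImage(NULL, beam, dm, centers = centers, R = 9)
  model <- twoAuNPImage(d, 9, beam, dm)
  expect_equal(counts(model), counts(full), tolerance = 1e-10)
  ## parity: d and -d give identical patterns
  expect_equal(counts(twoAuNPImage(-d, 9, beam, dm)), counts(model),
               tolerance = 0)
})

test_that("component images reconstruct the composite exactly", {
  beam <- baselineBeam(); dm <- dmTiny(9)
  ens <- miniEnsemble()
  pairs <- selectLabelPairs(ens, "rna", R = 6, nPairsMin = 2, nPairsMax = 4,
                            minSpread = 8, seed = 7)
  ls <- labeledStructure(conformers(ens)[[1]], pairs[[1]], 1)
  img <- simulateImage(ls, beam, dm, components = TRUE)
  comp <- imageComponents(img)
  expect_named(comp, c("SAuNP", "SAuNP1x2", "SRNA", "SAuNPxRNA"))
  total <- comp$SAuNP + comp$SRNA + comp$SAuNPxRNA
  expect_lt(max(abs(total - counts(img)) / pmax(counts(img), 1e-300)), 1e-9)
  ## the sphere term minus its interference part is the incoherent
  ## two-sphere envelope
  pref <- dm@polarization * dm@solidAngle * BioSOSS:::.re_A^2 * fluence(beam)
  env <- pref * 2 * matrix(aunpFormFactor(dm@qmag, pairs[[1]]@radius), 9, 9)^2
  expect_equal(comp$SAuNP - comp$SAuNP1x2, env, tolerance = 1e-9)
})

test_that("expected counts scale linearly in fluence", {
  dm <- dmTiny(9)
  cf <- randomCloud(8, seed = 4)
  b1 <- BeamParams(12, 1e13, 100)
  b2 <- BeamParams(12, 2e13, 100)
  i1 <- simulateImage(cf, b1, buildDetector(b1, tinyDetector(9)))
  i2 <- simulateImage(cf, b2, buildDetector(b2, tinyDetector(9)))
  expect_equal(counts(i2), 2 * counts(i1), tolerance = 0)
})

test_that("noise sampling is seeded, additive, and degenerate-safe", {
  beam <- baselineBeam(); dm <- dmTiny(9)
  zero <- simulateImage(NULL, beam, dm)
  ## degenerate distributions: zero expectation, zero uniform
  out <- addNoise(zero, NoiseParams(poisson = TRUE, uniformMax = 0, seed = 1))
  expect_true(all(counts(out) == 0))
  ## determinism
  img <- twoAuNPImage(c(20, 5, 3), 9, beam, dm)
  n1 <- addNoise(img, NoiseParams(seed = 99))
  n2 <- addNoise(img, NoiseParams(seed = 99))
  expect_identical(counts(n1), counts(n2))
  expect_false(identical(counts(addNoise(img, NoiseParams(seed = 100))),
                         counts(n1)))
})

test_that("noise obeys the law of large numbers", {
  ## 10,000 draws of a pixel with expectation 50 plus U(0, 4):
  ## mean should be 52 within 3 standard errors
  img <- new("ScatterImage", counts = matrix(50, 100, 100),
             components = list(), beam = baselineBeam(),
             det = tinyDetector(9), metadata = list())
  noisy <- addNoise(img, NoiseParams(poisson = TRUE, uniformMax = 4, seed = 8))
  se <- sqrt((50 + 16 / 12) / 1e4)
  expect_lt(abs(mean(counts(noisy)) - 52), 3 * se)
  expect_error(addNoise(initialize(img, counts = matrix(-1, 100, 100)),
                        NoiseParams()), "must be >= 0")
})
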