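## AuNP centre on a (possibly rotated) conformer from the site geometry
## alone: oxygen displaced by R along the anchor->oxygen bond direction.
.centerFromSite <- function(conformer, site, R) {
  o <- conformer@xyz[.siteRow(conformer, site), ]
  p <- conformer@xyz[.partnerRow(conformer, site), ]
  u <- o - p
  o + R * u / sqrt(sum(u^2))
}

#' Component-wise retrieval discrepancies
#'
#' `(dx, dy, dz) = dFit - dTrue` (both canonicalized beforehand) and
#' `dr = |dFit| - |dTrue|`. Note `dr` is a difference of lengths, not the
#' length of the difference.
#'
#' @param dFit,dTrue canonicalized 3-vectors, Angstrom.
#' @return named list with `dx`, `dy`, `dz`, `dr`.
#' @examples
#' componentDelta(c(3, 4, 0), c(0, 0, 5))  # dr = 0, components (3, 4, -5)
#' @export
componentDelta <- function(dFit, dTrue) {
  stopifnot(length(dFit) == 3L, length(dTrue) == 3L)
  list(dx = dFit[1] - dTrue[1], dy = dFit[2] - dTrue[2],
       dz = dFit[3] - dTrue[3],
       dr = sqrt(sum(dFit^2)) - sqrt(sum(dTrue^2)))
}

#' Least-squares Gaussian fit to a sample distribution
#'
#' Histograms the samples with Freedman-Diaconis bins and fits
#' `A exp(-(x - mu)^2 / (2 sigma^2))` to the bin counts by least squares,
#' as is done when extracting the centre and width of a discrepancy
#' distribution. The plain sample mean/sd are reported alongside.
#'
#' @param samples numeric vector (>= 10 values for a meaningful fit).
#' @return list with `center`, `std` (Gaussian fit), `sampleMean`,
#'   `sampleStd`, `n`. Degenerate all-equal input returns
#'   `(value, 0)` with a warning.
#' @export
gaussianFit <- function(samples) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 2L) stop("need at least 2 finite samples")
  m <- mean(samples); s <- sd(samples)
  if (s == 0) {
    warning("degenerate all-equal samples; returning std 0")
    return(list(center = m, std = 0, sampleMean = m, sampleStd = 0, n = n))
  }
  ## Freedman-Diaconis bin width, falling back to Scott if IQR collapses
  h <- 2 * IQR(samples) / n^(1 / 3)
  if (h <= 0) h <- 3.5 * s / n^(1 / 3)
  ## bin grid centred on the sample mean so symmetric samples give
  ## a symmetric histogram
  nbin <- max(5L, ceiling((max(samples) - m) / h), ceiling((m - min(samples)) / h))
  breaks <- m + h * seq(-nbin, nbin)
  cts <- tabulate(findInterval(samples, breaks, rightmost.closed = TRUE),
                  nbins = length(breaks) - 1L)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * sig^2)),
                      data = data.frame(x = mids, y = cts),
                      start = list(A = max(cts), mu = m, sig = s),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("Gaussian least-squares fit failed; using sample moments")
    return(list(center = m, std = s, sampleMean = m, sampleStd = s, n = n))
  }
  cf <- stats::coef(fit)
  list(center = unname(cf["mu"]), std = abs(unname(cf["sig"])),
       sampleMean = m, sampleStd = s, n = n)
}

#' Delta statistics of a per-sample retrieval table
#'
#' Gaussian-fit centre/width plus sample moments for each of
#' `dr, dx, dy, dz` over the converged fits of a [runEnsemble] table.
#'
#' @param samples the per-sample `data.table` from [runEnsemble].
#' @return nested list: one entry per quantity, each a [gaussianFit] list,
#'   plus `nSamples`.
#' @export
deltaStats <- function(samples) {
  ok <- samples$converged
  if (!any(ok)) stop("empty-stats: all fits failed")
  out <- lapply(c(dr = "dr", dx = "dx", dy = "dy", dz = "dz"),
                function(col) gaussianFit(samples[[col]][ok]))
  out$nSamples <- sum(ok)
  out
}

#' Run the full simulate-and-retrieve pipeline over an ensemble
#'
#' For every (conformer, label pair) combination: optionally apply a
#' random rigid orientation, attach the two nanoparticles, simulate the
#' composite noisy image (molecule + spheres + noise), fit the two-sphere
#' model, and record true and fitted vectors. Samples from all pairs are
#' pooled, as when gathering the full set of fitted/true distance pairs
#' across labeling sites.
#'
#' @param ensemble an [Ensemble-class].
#' @param labelPairs list of [LabelPair-class] from [selectLabelPairs].
#' @param beam a [BeamParams-class].
#' @param det a [DetectorParams-class].
#' @param noise a [NoiseParams-class] (its seed slot is ignored here; the
#'   run seed drives all randomness).
#' @param cfg a [FitConfig-class].
#' @param seed integer seed for orientations and noise.
#' @param rnaScattering include the biomolecule in the simulated signal?
#'   (FALSE gives pure two-sphere images, useful for exactness checks.)
#' @param randomOrientation random rigid orientation per snapshot?
#' @param removeLabeledOxygen drop substituted oxygens from the
#'   scattering sum?
#' @return list with `samples` (a `data.table`, one row per fit) and
#'   `stats` (the pooled [deltaStats]).
#' @export
runEnsemble <- function(ensemble, labelPairs, beam, det,
                        noise = NoiseParams(), cfg = FitConfig(), seed = 1,
                        rnaScattering = TRUE, randomOrientation = TRUE,
                        removeLabeledOxygen = TRUE) {
  stopifnot(is(ensemble, "Ensemble"), length(labelPairs) >= 1L)
  detModel <- buildDetector(beam, det)
  set.seed(as.integer(seed))
  nConf <- length(ensemble@conformers)
  angles <- randomEulerAngles(nConf)
  noiseSeeds <- sample.int(.Machine$integer.max, nConf * length(labelPairs))

  rows <- vector("list", nConf * length(labelPairs))
  k <- 0L
  for (ci in seq_len(nConf)) {
    cf <- ensemble@conformers[[ci]]
    if (randomOrientation)
      cf <- rotateConformer(cf, angles[ci, 1], angles[ci, 2], angles[ci, 3])
    aAll <- if (rnaScattering) .atomicAmplitude(detModel, cf@xyz, cf@atoms$element)
            else complex(length(detModel@qmag))
    pref <- as.numeric(.pixelPrefactor(beam, detModel))
    n <- det@nPixels
    for (pi in seq_along(labelPairs)) {
      pair <- labelPairs[[pi]]
      k <- k + 1L
      ca <- .centerFromSite(cf, pair@siteA, pair@radius)
      cb <- .centerFromSite(cf, pair@siteB, pair@radius)
      dT <- cb - ca
      aMol <- aAll
      if (rnaScattering && removeLabeledOxygen) {
        drop <- c(.siteRow(cf, pair@siteA), .siteRow(cf, pair@siteB))
        aMol <- aMol - .atomicAmplitude(detModel, cf@xyz[drop, , drop = FALSE],
                                        cf@atoms$element[drop])
      }
      aN <- .sphereAmplitude(detModel, rbind(ca, cb), pair@radius)
      img <- new("ScatterImage",
                 counts = .asImageMatrix(pref * Mod(aMol + aN)^2, n),
                 components = list(), beam = beam, det = det,
                 metadata = list(dTrue = dT, radius = pair@radius))
      img <- addNoise(img, NoiseParams(poisson = noise@poisson,
                                       uniformMax = noise@uniformMax,
                                       seed = noiseSeeds[k]))
      res <- fitDistance(img, pair@radius, beam, detModel, cfg)
      dTc <- canonicalizeVector(dT)
      del <- if (res@converged) componentDelta(res@dFit, dTc)
             else list(dx = NA_real_, dy = NA_real_, dz = NA_real_, dr = NA_real_)
      rows[[k]] <- data.table::data.table(
        snapshot = cf@snapshotId, pair = pi,
        rTrue = sqrt(sum(dT^2)), rFit = res@rFit,
        xTrue = dTc[1], yTrue = dTc[2], zTrue = dTc[3],
        xFit = res@dFit[1], yFit = res@dFit[2], zFit = res@dFit[3],
        dx = del$dx, dy = del$dy, dz = del$dz, dr = del$dr,
        chi2 = res@chi2, nEvaluations = res@nEvaluations,
        converged = res@converged)
    }
  }
  samples <- data.table::rbindlist(rows)
  list(samples = samples, stats = deltaStats(samples))
}

#' Probability histograms of fitted and true distances
#'
#' Freedman-Diaconis-binned histograms of `r_fit` and `r_AuNP` over the
#' converged fits, normalized to probability (bin counts divided by the
#' total count, so each histogram sums to 1).
#'
#' @param samples the per-sample table from [runEnsemble].
#' @return list with `rFit` and `rTrue`, each a data.frame of bin `mid`,
#'   `width`, and `probability`.
#' @export
distanceHistograms <- function(samples) {
  ok <- samples$converged
  mk <- function(x) {
    x <- x[ok & is.finite(samples$rFit)]
    h <- 2 * IQR(x) / length(x)^(1 / 3)
    if (h <= 0) h <- max(1e-6, 3.5 * sd(x) / length(x)^(1 / 3))
    breaks <- seq(min(x) - h, max(x) + h, by = h)
    cts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                    nbins = length(breaks) - 1L)
    data.frame(mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
               width = h, probability = cts / sum(cts))
  }
  list(rFit = mk(samples$rFit), rTrue = mk(samples$rTrue))
}

#' Distance-retrieval accuracy study on a static structure
#'
#' The pipeline applied to a single rigid structure observed in many
#' random orientations (the protocol for assessing accuracy on deposited
#' structures, where conformational flexibility is not sampled): build an
#' orientation ensemble, select label pairs, then [runEnsemble] with the
#' per-snapshot random orientation disabled (the ensemble already
#' contains the orientations).
#'
#' @param conformer a [Conformer-class] (e.g. from [readPDB]).
#' @param nOrient number of random orientations.
#' @param moleculeKind,R,nPairsMin,nPairsMax,minSpread,clashMargin,maxDistance
#'   labeling settings, see [selectLabelPairs].
#' @param beam,det,noise,cfg,seed as in [runEnsemble].
#' @param ... further arguments passed to [runEnsemble].
#' @return as [runEnsemble].
#' @export
orientationStudy <- function(conformer, nOrient = 30, moleculeKind = "rna",
                             R = 9, beam = BeamParams(),
                             det = DetectorParams(), noise = NoiseParams(),
                             cfg = FitConfig(), nPairsMin = 2, nPairsMax = 6,
                             minSpread = 10, clashMargin = 1.5,
                             maxDistance = 85, seed = 1, ...) {
  ens <- orientationEnsemble(conformer, nOrient, seed = seed)
  pairs <- selectLabelPairs(ens, moleculeKind, R = R, nPairsMin = nPairsMin,
                            nPairsMax = nPairsMax, minSpread = minSpread,
                            clashMargin = clashMargin,
                            maxDistance = maxDistance, seed = seed)
  runEnsemble(ens, pairs, beam, det, noise, cfg, seed = seed,
              randomOrientation = FALSE, ...)
}

#' Sweep one experimental parameter
#'
#' Re-runs [runEnsemble] at each grid value of one parameter, all other
#' settings held at their base values, and collects the per-value delta
#' statistics into a tidy table. The labeling sites are selected once —
#' for the nanoparticle-radius sweep at the largest radius of the grid,
#' whose `2.4 R` and steric constraints are the most restrictive — and
#' held fixed across the grid, so the swept parameter is not confounded
#' with a changing set of pair distances; for the radius sweep the sphere
#' centres and ground-truth distances are recomputed at each radius from
#' the fixed sites. A grid value with no feasible labeling is flagged
#' (`feasible = FALSE`, statistics NA), not fatal.
#'
#' @param parameter one of `"R"`, `"energy"`, `"n_pixels"`, `"photons"`,
#'   `"focal_size"`, `"distance"`.
#' @param grid numeric grid values, strictly increasing (Angstrom, keV,
#'   pixels, photons, nm, mm respectively).
#' @param ensemble an [Ensemble-class].
#' @param beam,det,noise,cfg base settings, as in [runEnsemble].
#' @param moleculeKind passed to [selectLabelPairs].
#' @param R base nanoparticle radius (used unless `parameter = "R"`).
#' @param nPairsMin,nPairsMax,minSpread,clashMargin,maxDistance
#'   label-selection settings (see [selectLabelPairs]).
#' @param seed integer seed.
#' @param ... further arguments passed to [runEnsemble].
#' @return list with `table` (a tidy `data.table`: one row per grid point
#'   with sigma and centre columns) and `runs` (per-point [runEnsemble]
#'   results or NULL where infeasible).
#' @export
runSweep <- function(parameter, grid, ensemble, beam, det,
                     noise = NoiseParams(), cfg = FitConfig(),
                     moleculeKind = "rna", R = 9, nPairsMin = 2,
                     nPairsMax = 6, minSpread = 10, clashMargin = 1.5,
                     maxDistance = 85, seed = 1, ...) {
  supported <- c("R", "energy", "n_pixels", "photons", "focal_size", "distance")
  if (!parameter %in% supported)
    stop("unknown parameter '", parameter, "'; supported: ",
         paste(supported, collapse = ", "))
  if (length(grid) == 0L) stop("grid must be non-empty")
  if (any(diff(grid) <= 0)) stop("grid values must be strictly increasing")

  ## select sites at the most restrictive radius of the grid; if that is
  ## infeasible, walk down the grid (the skipped radii are then flagged
  ## infeasible rather than aborting the sweep)
  selectGrid <- if (parameter == "R") rev(grid) else R
  basePairs <- NULL; selectR <- NA_real_
  for (Rsel in selectGrid) {
    basePairs <- tryCatch(
      selectLabelPairs(ensemble, moleculeKind, R = Rsel,
                       nPairsMin = nPairsMin, nPairsMax = nPairsMax,
                       minSpread = minSpread, clashMargin = clashMargin,
                       maxDistance = maxDistance, seed = seed),
      error = function(e) NULL)
    if (!is.null(basePairs)) { selectR <- Rsel; break }
  }
  if (is.null(basePairs))
    stop("no-feasible-labeling at any radius of the sweep grid")

  runs <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    v <- grid[g]
    beamG <- beam; detG <- det; pairsG <- basePairs; Rg <- R
    switch(parameter,
      R = { Rg <- v },
      energy = { beamG@energyKeV <- v },
      n_pixels = { detG@nPixels <- as.integer(v) },
      photons = { beamG@photons <- v },
      focal_size = { beamG@focalSizeNm <- v },
      distance = { detG@distanceMm <- v })
    if (parameter == "R" && v != selectR) {
      ## same sites, sphere centres recomputed for this radius
      pairsG <- lapply(basePairs, function(p) {
        ca <- .siteCenters(ensemble, p@siteA, v, clashMargin)
        cb <- .siteCenters(ensemble, p@siteB, v, clashMargin)
        if (is.null(ca) || is.null(cb)) return(NULL)
        r <- sqrt(rowSums((cb - ca)^2))
        if (any(r <= 2.4 * v)) return(NULL)
        new("LabelPair", siteA = p@siteA, siteB = p@siteB, radius = v,
            centersA = ca, centersB = cb, rAuNP = r)
      })
      pairsG <- Filter(Negate(is.null), pairsG)
      if (length(pairsG) == 0L) pairsG <- NULL
    }
    if (is.null(pairsG)) {
      rows[[g]] <- data.table::data.table(
        parameter = parameter, value = v, feasible = FALSE,
        sigmaDr = NA_real_, sigmaDx = NA_real_, sigmaDy = NA_real_,
        sigmaDz = NA_real_, centerDr = NA_real_, sampleStdDr = NA_real_,
        nSamples = 0L)
      next
    }
    ## common random numbers across grid points (same orientations and
    ## noise streams), so the trend is not masked by sampling noise
    run <- runEnsemble(ensemble, pairsG, beamG, detG, noise, cfg,
                       seed = seed, ...)
    st <- run$stats
    runs[[g]] <- run
    rows[[g]] <- data.table::data.table(
      parameter = parameter, value = v, feasible = TRUE,
      sigmaDr = st$dr$std, sigmaDx = st$dx$std, sigmaDy = st$dy$std,
      sigmaDz = st$dz$std, centerDr = st$dr$center,
      sampleStdDr = st$dr$sampleStd, nSamples = st$nSamples)
  }
  list(table = data.table::rbindlist(rows), runs = runs)
}
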