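#' Canonicalize an inter-particle vector
#'
#' The two-sphere interference pattern determines `d` only up to a global
#' sign (`cos(q.d)` is even). The canonical representative flips the
#' overall sign so that `z > 0`; if `|z| < 1e-9`, so that `x > 0`; if also
#' `|x| < 1e-9`, so that `y >= 0`.
#'
#' @param d numeric 3-vector.
#' @return the canonicalized 3-vector.
#' @examples
#' canonicalizeVector(c(-1, 2, -3))  # (1, -2, 3)
#' @export
canonicalizeVector <- function(d) {
  stopifnot(length(d) == 3L)
  s <- if (abs(d[3]) >= 1e-9) sign(d[3])
       else if (abs(d[1]) >= 1e-9) sign(d[1])
       else if (d[2] < 0) -1 else 1
  s * d
}

## Internal fit context: flattened experiment image, envelope, q arrays,
## and weights, shared by chi-square evaluation / initialization / fit.
.fitContext <- function(image, R, beam, detModel, cfg) {
  n <- detModel@det@nPixels
  if (!identical(dim(image@counts), c(n, n)))
    stop("geometry mismatch: image is ", nrow(image@counts), "x",
         ncol(image@counts), " but the detector model is ", n, "x", n)
  sexp <- as.numeric(image@counts)
  list(n = n,
       sexp = sexp,
       env = .twoSphereEnvelope(R, beam, detModel),
       qx = as.numeric(detModel@qx), qy = as.numeric(detModel@qy),
       qz = as.numeric(detModel@qz),
       w = 1 / pmax(sexp, cfg@pixelErrorFloor))
}

.chi2At <- function(ctx, d) {
  ph <- ctx$qx * d[1] + ctx$qy * d[2] + ctx$qz * d[3]
  sum((ctx$sexp - ctx$env * (1 + cos(ph)))^2 * ctx$w)
}

#' Chi-square of the two-sphere model against an image
#'
#' `sum_pixels (S_exp - S_theo(d))^2 / sigma_pix^2` with the Poisson-style
#' measured-variance weighting `sigma_pix^2 = max(S_exp, pixelErrorFloor)`.
#' Exactly even in `d` (the model depends on `d` only through `cos(q.d)`).
#'
#' @param image the (mock) experimental [ScatterImage-class].
#' @param d candidate inter-particle vector, Angstrom.
#' @param R sphere radius, Angstrom.
#' @param beam a [BeamParams-class].
#' @param detModel a [DetectorModel-class] sharing the image geometry.
#' @param cfg a [FitConfig-class].
#' @return the weighted residual sum of squares (dimensionless).
#' @export
chiSquare <- function(image, d, R, beam, detModel, cfg = FitConfig()) {
  .chi2At(.fitContext(image, R, beam, detModel, cfg), d)
}

## Parabolic sub-bin interpolation of a peak at index i in power p
## (1-based, with wraparound length n). Returns fractional offset in bins.
.parabolicOffset <- function(p, i, n) {
  pm <- p[(i - 2) %% n + 1]; p0 <- p[i]; pp <- p[i %% n + 1]
  den <- pm - 2 * p0 + pp
  if (den == 0) return(0)
  off <- 0.5 * (pm - pp) / den
  max(-0.5, min(0.5, off))
}

#' Initialization candidates for the two-sphere fit
#'
#' The fringe pattern is isolated by envelope normalization,
#' `ratio = S_exp / envelope - 1 ~ cos(q . d)`, masked to pixels whose
#' envelope stands above the shot-noise floor. Because the Ewald-sphere
#' curvature chirps the fringe radially through the `q_z d_z` phase, a
#' plain 2D FFT smears the peak for large `|d_z|`; instead a matched
#' filter scans a `zGridPoints` grid of `z` over `[-rMax, rMax]`,
#' demodulates `ratio * exp(-i q_z z)`, and Fourier-analyses each slice.
#' The sharpest transverse peak over all slices yields joint `(x, y, z)`
#' candidates (sub-bin peak position by parabolic interpolation), ranked
#' by chi-square; the best `multistart` are returned. A featureless image
#' (no fringe or DC signal above the noise floor) yields an empty list
#' with a warning.
#'
#' @inheritParams chiSquare
#' @return list of candidate 3-vectors (possibly empty), best first.
#' @export
initialCandidates <- function(image, R, beam, detModel, cfg = FitConfig()) {
  ctx <- .fitContext(image, R, beam, detModel, cfg)
  .initialCandidates(ctx, beam, detModel, cfg)
}

.initialCandidates <- function(ctx, beam, detModel, cfg) {
  n <- ctx$n
  ## keep only pixels whose model envelope stands above the shot-noise
  ## floor; elsewhere the normalized ratio is pure noise
  envFloor <- min(5, 1e-3 * max(ctx$env))
  mask <- ctx$env >= envFloor
  ratio <- (ctx$sexp - ctx$env) / pmax(ctx$env, envFloor)
  ratio[!mask] <- 0
  ratio <- pmax(pmin(ratio, 2), -2)  # clamp noise blow-ups near the nulls
  ## remove the in-mask mean: a flat ratio carries no fringe; its level
  ## (+1 for in-phase spheres, -1 for no signal) is judged separately
  ratioMean <- mean(ratio[mask])
  ratio[mask] <- ratio[mask] - ratioMean

  ## transverse q step per pixel at the detector centre
  aq <- dqCenter(beam, detModel@det)
  zGrid <- seq(-cfg@rMax, cfg@rMax, length.out = cfg@zGridPoints)

  peaks <- matrix(NA_real_, length(zGrid), 4)  # power, fi, fj, z
  medPw <- NA_real_
  for (zi in seq_along(zGrid)) {
    demod <- ratio * complex(argument = -ctx$qz * zGrid[zi])
    pw <- Mod(fft(matrix(demod, n, n)))^2
    if (zi == 1L) medPw <- median(pw)
    ipk <- which.max(pw)
    ij <- arrayInd(ipk, dim(pw))
    rowPw <- pw[, ij[2L]]; colPw <- pw[ij[1L], ]
    fi <- (ij[1L] - 1 + .parabolicOffset(rowPw, ij[1L], n)) / n
    fj <- (ij[2L] - 1 + .parabolicOffset(colPw, ij[2L], n)) / n
    if (fi >= 0.5) fi <- fi - 1
    if (fj >= 0.5) fj <- fj - 1
    peaks[zi, ] <- c(pw[ipk], fi, fj, zGrid[zi])
  }
  hasFringe <- max(peaks[, 1]) > 100 * max(medPw, .Machine$double.eps)
  if (!hasFringe && ratioMean <= 0.5) {
    warning("featureless image: no fringe peak above the noise floor")
    return(list())
  }
  cands <- list()
  if (hasFringe) {
    ord <- order(peaks[, 1], decreasing = TRUE)
    cands <- lapply(ord, function(zi)
      c(2 * pi * peaks[zi, 2:3] / aq, peaks[zi, 4]))
  }
  if (ratioMean > 0.5) {
    ## data above the envelope everywhere: in-phase spheres, d near 0
    cands <- c(cands, list(c(0, 0, 0)))
  }
  chi <- vapply(cands, function(d) .chi2At(ctx, d), numeric(1))
  cands[order(chi)][seq_len(min(cfg@multistart, length(cands)))]
}

#' Fit the two-sphere model to an image
#'
#' Starting from each [initialCandidates] candidate, runs a Nelder-Mead
#' local refinement of the chi-square; the best refined optimum wins and
#' is canonicalized. The whole procedure is deterministic (no random
#' restarts), so identical images give identical results.
#'
#' @inheritParams chiSquare
#' @return a [RetrievalResult-class]. On failure (no candidates) `rFit`
#'   is NA and `converged` is FALSE.
#' @export
fitDistance <- function(image, R, beam, detModel, cfg = FitConfig()) {
  ctx <- .fitContext(image, R, beam, detModel, cfg)
  cands <- .initialCandidates(ctx, beam, detModel, cfg)
  nEval <- length(cands) + cfg@zGridPoints  # grid ranking cost
  if (length(cands) == 0L) {
    return(new("RetrievalResult", dFit = rep(NA_real_, 3), rFit = NA_real_,
               chi2 = NA_real_, nEvaluations = as.integer(nEval),
               converged = FALSE))
  }
  ## quadratic barrier keeps the derivative-free search inside |d_i| <= rMax
  barrierScale <- .chi2At(ctx, cands[[1L]]) + 1
  objective <- function(d) {
    excess <- pmax(abs(d) - cfg@rMax, 0)
    .chi2At(ctx, d) + barrierScale * sum(excess^2)
  }
  anyConverged <- FALSE
  ## stage 1: short refinement of every candidate
  stage1 <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    opt <- optim(cands[[i]], objective, method = "Nelder-Mead",
                 control = list(reltol = 1e-6, maxit = 400))
    nEval <- nEval + opt$counts[["function"]]
    stage1[[i]] <- opt
  }
  best1 <- stage1[[which.min(vapply(stage1, `[[`, numeric(1), "value"))]]

  ## stage 2: full refinement of the winner and of its fringe-shifted
  ## neighbours (the transverse chi-square landscape has local minima one
  ## fringe period apart; noise can favour the wrong one at stage 1)
  fringe <- 2 * pi / max(abs(ctx$qx))
  starts <- list(best1$par,
                 best1$par + c(fringe, 0, 0), best1$par - c(fringe, 0, 0),
                 best1$par + c(0, fringe, 0), best1$par - c(0, fringe, 0))
  best <- NULL
  for (d0 in starts) {
    opt <- optim(d0, objective, method = "Nelder-Mead",
                 control = list(reltol = cfg@refineTolerance, maxit = 3000))
    nEval <- nEval + opt$counts[["function"]]
    if (opt$convergence == 0L) anyConverged <- TRUE
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  d <- canonicalizeVector(best$par)
  new("RetrievalResult", dFit = d, rFit = sqrt(sum(d^2)), chi2 = best$value,
      nEvaluations = as.integer(nEval), converged = anyConverged)
}
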