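## Per-pixel prefactor of the elastic scattering intensity:
## polarization * Omega * r_e^2 * fluence  (counts per |amplitude|^2).
.pixelPrefactor <- function(beam, detModel) {
  detModel@polarization * detModel@solidAngle * .re_A^2 * fluence(beam)
}

## Complex atomic amplitude on the pixel grid (vector of length n^2).
.atomicAmplitude <- function(detModel, xyz, elements) {
  if (nrow(xyz) == 0L) return(complex(length(detModel@qmag)))
  elems <- unique(elements)
  unknown <- setdiff(elems, supportedElements())
  if (length(unknown))
    stop("unsupported element: ", paste(unknown, collapse = ", "))
  q <- as.numeric(detModel@qmag)
  fPix <- vapply(elems, function(e) atomicFormFactor(e, q),
                 numeric(length(q)))
  fPix <- matrix(fPix, ncol = length(elems))
  a <- cpp_atomic_amplitude(as.numeric(detModel@qx), as.numeric(detModel@qy),
                            as.numeric(detModel@qz), xyz,
                            match(elements, elems), fPix)
  complex(real = a[, 1], imaginary = a[, 2])
}

## Complex amplitude of 0, 1 or 2 identical spheres at `centers` (k x 3).
.sphereAmplitude <- function(detModel, centers, R) {
  A <- complex(length(detModel@qmag))
  if (is.null(centers) || nrow(centers) == 0L) return(A)
  fA <- aunpFormFactor(as.numeric(detModel@qmag), R)
  for (k in seq_len(nrow(centers))) {
    ph <- as.numeric(detModel@qx) * centers[k, 1] +
          as.numeric(detModel@qy) * centers[k, 2] +
          as.numeric(detModel@qz) * centers[k, 3]
    A <- A + fA * complex(real = cos(ph), imaginary = sin(ph))
  }
  A
}

.asImageMatrix <- function(v, n) matrix(v, n, n)

#' Simulate the scattering image of a labeled structure
#'
#' Per pixel, the coherent complex amplitude
#' `A(q) = sum_j f_j(|q|) exp(i q . x_j) + sum_k f_AuNP(|q|, R) exp(i q . c_k)`
#' over all atoms `j` and the (up to two) nanoparticle centres `c_k`, and
#' the expected photon count
#' `S = 0.5 (1 + cos^2 2 theta) * Omega * r_e^2 * Phi * |A(q)|^2`,
#' with `Phi` the fluence and `r_e` the classical electron radius.
#'
#' When `components = TRUE` the image additionally carries the
#' decomposition `S = S_AuNP + S_RNA + S_AuNPxRNA`, where `S_AuNP` is the
#' two-sphere term (including the inter-sphere interference, reported
#' separately as `SAuNP1x2`), `S_RNA` the biomolecule term, and
#' `S_AuNPxRNA` the sphere-molecule cross term; the components sum to the
#' composite exactly.
#'
#' @param labeled a [LabeledStructure-class] (atoms plus two spheres), a
#'   bare [Conformer-class] (atoms only), or NULL (no atoms; an empty
#'   scatterer unless sphere centres are supplied via `centers`).
#' @param beam a [BeamParams-class].
#' @param detModel a [DetectorModel-class].
#' @param components also return the component decomposition?
#' @param countCeiling expected counts are capped here (with a warning)
#'   as an overflow guard.
#' @param centers optional k x 3 matrix of sphere centres (ignored when
#'   `labeled` is a [LabeledStructure-class], which carries its own).
#' @param R sphere radius for `centers`, Angstrom.
#' @return a [ScatterImage-class] of expected (noise-free) counts.
#' @export
simulateImage <- function(labeled, beam, detModel, components = FALSE,
                          countCeiling = 1e12, centers = NULL, R = NULL) {
  stopifnot(is(beam, "BeamParams"), is(detModel, "DetectorModel"))
  n <- detModel@det@nPixels
  pref <- as.numeric(.pixelPrefactor(beam, detModel))

  if (is(labeled, "LabeledStructure")) {
    keep <- setdiff(seq_len(nrow(labeled@conformer@xyz)), labeled@removedAtoms)
    xyz <- labeled@conformer@xyz[keep, , drop = FALSE]
    elements <- labeled@conformer@atoms$element[keep]
    centers <- rbind(labeled@centerA, labeled@centerB)
    R <- labeled@radius
    meta <- list(dTrue = labeled@dTrue, radius = R,
                 snapshotId = labeled@conformer@snapshotId)
  } else if (is(labeled, "Conformer")) {
    xyz <- labeled@xyz
    elements <- labeled@atoms$element
    meta <- list(snapshotId = labeled@snapshotId)
  } else if (is.null(labeled)) {
    xyz <- matrix(numeric(0), 0, 3); elements <- character(0)
    meta <- list()
  } else stop("labeled must be a LabeledStructure, a Conformer, or NULL")
  if (is.null(R)) R <- 1
  if (!all(is.finite(xyz))) stop("atom coordinates must be finite")

  aR <- .atomicAmplitude(detModel, xyz, elements)
  aN <- .sphereAmplitude(detModel, centers, R)
  S <- pref * Mod(aR + aN)^2
  if (any(S > countCeiling)) {
    warning("expected counts capped at ceiling ", countCeiling)
    S <- pmin(S, countCeiling)
  }
  comp <- list()
  if (components) {
    sInter <- if (!is.null(centers) && nrow(centers) == 2L) {
      fA <- aunpFormFactor(as.numeric(detModel@qmag), R)
      d <- centers[2L, ] - centers[1L, ]
      ph <- as.numeric(detModel@qx) * d[1] + as.numeric(detModel@qy) * d[2] +
            as.numeric(detModel@qz) * d[3]
      pref * 2 * fA^2 * cos(ph)
    } else numeric(length(aN))
    comp <- list(
      SAuNP = .asImageMatrix(pref * Mod(aN)^2, n),
      SAuNP1x2 = .asImageMatrix(sInter, n),
      SRNA = .asImageMatrix(pref * Mod(aR)^2, n),
      SAuNPxRNA = .asImageMatrix(pref * 2 * Re(aR * Conj(aN)), n))
  }
  new("ScatterImage", counts = .asImageMatrix(S, n), components = comp,
      beam = beam, det = detModel@det, metadata = meta)
}

#' Two-sphere model image
#'
#' The analytic interference pattern of two identical spheres separated
#' by `d`:
#' `S_theo = polarization * Omega * r_e^2 * Phi * 2 f_AuNP(|q|, R)^2 (1 + cos(q . d))`.
#' It is translation invariant (depends only on `d`) and even in `d`.
#'
#' @param d inter-sphere vector, Angstrom.
#' @param R sphere radius, Angstrom.
#' @param beam a [BeamParams-class].
#' @param detModel a [DetectorModel-class].
#' @return a [ScatterImage-class].
#' @export
twoAuNPImage <- function(d, R, beam, detModel) {
  stopifnot(R > 0, length(d) == 3L)
  n <- detModel@det@nPixels
  S <- .twoSphereCounts(d, .twoSphereEnvelope(R, beam, detModel), detModel)
  new("ScatterImage", counts = .asImageMatrix(S, n), components = list(),
      beam = beam, det = detModel@det,
      metadata = list(dTrue = d, radius = R))
}

## envelope = pref * 2 f_AuNP^2  (so counts = envelope * (1 + cos(q.d)))
.twoSphereEnvelope <- function(R, beam, detModel) {
  as.numeric(.pixelPrefactor(beam, detModel)) *
    2 * aunpFormFactor(as.numeric(detModel@qmag), R)^2
}

.twoSphereCounts <- function(d, envelope, detModel) {
  ph <- as.numeric(detModel@qx) * d[1] + as.numeric(detModel@qy) * d[2] +
        as.numeric(detModel@qz) * d[3]
  envelope * (1 + cos(ph))
}

#' Add detector noise to an expected image
#'
#' Per pixel, the noisy count is a Poisson draw with the expected count as
#' mean (if `poisson`), plus an independent uniform draw on
#' `[0, uniformMax]`. Deterministic given the seed in `noise`.
#'
#' @param image a [ScatterImage-class] of expected counts (all `>= 0`).
#' @param noise a [NoiseParams-class].
#' @return a [ScatterImage-class] with noisy counts.
#' @export
addNoise <- function(image, noise) {
  stopifnot(is(image, "ScatterImage"), is(noise, "NoiseParams"))
  if (any(image@counts < 0)) stop("expected counts must be >= 0")
  if (!is.na(noise@seed)) set.seed(as.integer(noise@seed))
  cts <- image@counts
  if (noise@poisson) cts[] <- rpois(length(cts), lambda = as.numeric(cts))
  if (noise@uniformMax > 0)
    cts <- cts + runif(length(cts), 0, noise@uniformMax)
  meta <- image@metadata
  meta$noise <- list(poisson = noise@poisson, uniformMax = noise@uniformMax,
                     seed = noise@seed)
  initialize(image, counts = cts, metadata = meta)
}
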