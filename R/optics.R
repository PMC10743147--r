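#' Build the per-pixel Ewald-sphere detector model
#'
#' Places pixel `(i, j)` (1-based) at lab position
#' `((i - (n+1)/2) p, (j - (n+1)/2) p, l)` so the beam axis pierces the
#' detector centre, and evaluates at each pixel centre the elastic
#' momentum transfer `q = k (s_hat - z_hat)` (`k = 2 pi / lambda`,
#' incident beam along +z), the scattering angle `2 theta`, the pixel
#' solid angle `Omega = p^2 cos^3(2 theta) / l^2`, and the unpolarized
#' Thomson polarization factor `0.5 (1 + cos^2 2 theta)`.
#'
#' With this sign convention `q_z = k (cos 2 theta - 1) <= 0` everywhere,
#' vanishing only on the beam axis: the Ewald-sphere curvature that limits
#' z-resolution.
#'
#' @param beam a [BeamParams-class].
#' @param det a [DetectorParams-class].
#' @return a [DetectorModel-class].
#' @examples
#' dm <- buildDetector(BeamParams(12), DetectorParams(11, 234, 40))
#' max(dm@qmag)
#' @export
buildDetector <- function(beam, det) {
  stopifnot(is(beam, "BeamParams"), is(det, "DetectorParams"))
  n <- det@nPixels
  p <- det@pixelSizeUm * 1e-3   # mm
  l <- det@distanceMm           # mm
  k <- 2 * pi / wavelengthA(beam)  # 1/A

  off <- (seq_len(n) - (n + 1) / 2) * p
  X <- matrix(off, n, n)       # rows: x index
  Y <- matrix(off, n, n, byrow = TRUE)
  dist <- sqrt(X^2 + Y^2 + l^2)
  cos2t <- l / dist
  qx <- k * X / dist
  qy <- k * Y / dist
  qz <- k * (cos2t - 1)
  qmag <- sqrt(qx^2 + qy^2 + qz^2)
  new("DetectorModel", beam = beam, det = det,
      qx = qx, qy = qy, qz = qz, qmag = qmag,
      solidAngle = p^2 * cos2t / dist^2,
      polarization = 0.5 * (1 + cos2t^2),
      twoTheta = acos(pmin(cos2t, 1)))
}

#' Nominal real-space resolution limit
#'
#' `r_lim = 2 pi / q_max`, with `q_max` evaluated at the midpoint of the
#' detector edge, i.e. at scattering angle `2 theta_max = atan((n p / 2) / l)`.
#'
#' @inheritParams buildDetector
#' @return resolution limit in Angstrom.
#' @examples
#' rLim(BeamParams(12), DetectorParams(250, 234, 40))  # ~1.7 A
#' @export
rLim <- function(beam, det) {
  p <- det@pixelSizeUm * 1e-3
  twoTheta <- atan((det@nPixels * p / 2) / det@distanceMm)
  qmax <- 4 * pi * sin(twoTheta / 2) / wavelengthA(beam)
  2 * pi / qmax
}

#' Single-pixel momentum-transfer increment at the detector centre
#'
#' `|q|` at a pixel offset by one pixel pitch from the beam axis
#' (`2 theta = atan(p / l)`); this sets how finely the interference
#' fringes are sampled.
#'
#' @inheritParams buildDetector
#' @return dq in 1/Angstrom.
#' @examples
#' dqCenter(BeamParams(12), DetectorParams(250, 234, 40))  # ~0.036 1/A
#' @export
dqCenter <- function(beam, det) {
  p <- det@pixelSizeUm * 1e-3
  twoTheta <- atan(p / det@distanceMm)
  4 * pi * sin(twoTheta / 2) / wavelengthA(beam)
}

#' Incident fluence at the sample
#'
#' Photons per unit area for a uniform circular (top-hat) focal spot of
#' diameter `f`: `I / (pi (f/2)^2)`, in photons per square Angstrom.
#'
#' @param beam a [BeamParams-class].
#' @return fluence, photons / Angstrom^2.
#' @examples
#' fluence(BeamParams(12, photons = 1e14, focalSizeNm = 100))
#' @export
fluence <- function(beam) {
  radiusA <- beam@focalSizeNm * 10 / 2
  beam@photons / (pi * radiusA^2)
}
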