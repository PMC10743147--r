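## Cromer-Mann 4-Gaussian atomic form factor coefficients
## (International Tables for Crystallography, Vol. C, Table 6.1.1.4).
## f(q) = sum_i a_i exp(-b_i (q/4pi)^2) + c, q in 1/Angstrom.
.cromerMann <- rbind(
  H  = c(0.489918, 0.262003, 0.196767, 0.049879,
         20.6593,  7.74039, 49.5519,   2.20159,  0.001305),
  C  = c(2.31000,  1.02000,  1.58860,  0.865000,
         20.8439, 10.2075,   0.568700, 51.6512,  0.215600),
  N  = c(12.2126,  3.13220,  2.01250,  1.16630,
         0.005700, 9.89330, 28.9975,   0.582600, -11.5290),
  O  = c(3.04850,  2.28680,  1.54630,  0.867000,
         13.2771,  5.70110,  0.323900, 32.9089,  0.250800),
  P  = c(6.43450,  4.17910,  1.78000,  1.49080,
         1.90670, 27.1570,   0.526000, 68.1645,  1.11490),
  S  = c(6.90530,  5.20340,  1.43790,  1.58630,
         1.46790, 22.2151,   0.253600, 56.1720,  0.866900),
  Au = c(16.8819, 18.5913,  25.5582,   5.86000,
         0.461100, 8.62160,  1.48260, 36.3956,  12.0658)
)

#' Supported chemical elements
#'
#' Elements for which Cromer-Mann atomic form factor coefficients are
#' bundled.
#'
#' @return character vector of element symbols.
#' @export
supportedElements <- function() rownames(.cromerMann)

#' Atomic form factor
#'
#' Evaluates the standard Cromer-Mann 4-Gaussian-plus-constant
#' parameterization of the spherical atomic form factor,
#' `f(q) = sum a_i exp(-b_i s^2) + c` with `s = q / (4 pi)`.
#' At `q = 0` this equals the element's electron count to within 0.5%.
#'
#' @param element element symbol (one of [supportedElements()]).
#' @param qMag momentum-transfer magnitude(s), 1/Angstrom, `>= 0`.
#' @return form factor in electron units, same length as `qMag`.
#' @examples
#' atomicFormFactor("Au", 0)   # ~79
#' atomicFormFactor("C", c(0, 1, 2))
#' @export
atomicFormFactor <- function(element, qMag) {
  element <- as.character(element)
  if (length(element) != 1L || !element %in% rownames(.cromerMann))
    stop("unsupported element: '", element,
         "' (supported: ", paste(rownames(.cromerMann), collapse = ", "), ")")
  if (any(qMag < 0)) stop("qMag must be >= 0")
  cf <- .cromerMann[element, ]
  s2 <- (qMag / (4 * pi))^2
  cf[1L] * exp(-cf[5L] * s2) + cf[2L] * exp(-cf[6L] * s2) +
    cf[3L] * exp(-cf[7L] * s2) + cf[4L] * exp(-cf[8L] * s2) + cf[9L]
}

## Normalized homogeneous-sphere shape factor
## psi(x) = 3 (sin x - x cos x) / x^3, psi(0) = 1,
## with a Taylor series near 0 to avoid cancellation.
.sphereShape <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-3
  xs <- x[small]
  out[small] <- 1 - xs^2 / 10 + xs^4 / 280
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

#' Gold nanoparticle form factor
#'
#' Scattering amplitude of a homogeneous gold sphere of radius `R`:
#' `f_AuNP(q, R) = 3 f_Au(q) (sin(qR) - qR cos(qR)) / q^3`,
#' with the removable singularity at `q -> 0` replaced by its limit
#' `f_Au(0) R^3`. The amplitude first vanishes near `qR ~ 4.4934`.
#'
#' @param qMag momentum-transfer magnitude(s), 1/Angstrom.
#' @param R sphere radius, Angstrom.
#' @param fAu optionally precomputed `atomicFormFactor("Au", qMag)`.
#' @return amplitude (electron x Angstrom^3 units), same length as `qMag`.
#' @examples
#' aunpFormFactor(0, R = 9)            # ~ 79 * 9^3
#' aunpFormFactor(4.4934 / 9, R = 9)   # ~ 0 (first null)
#' @export
aunpFormFactor <- function(qMag, R, fAu = atomicFormFactor("Au", qMag)) {
  if (R <= 0) stop("R must be > 0")
  if (any(qMag < 0)) stop("qMag must be >= 0")
  fAu * R^3 * .sphereShape(qMag * R)
}
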