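#' @import methods
#' @importFrom stats fft rnorm rpois runif optim sd quantile IQR median setNames
#' @importFrom utils head
#' @useDynLib BioSOSS, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## Classical electron radius in Angstrom.
.re_A <- 2.8179403e-5

## keV <-> Angstrom conversion constant (hc in keV*A).
.hc_keVA <- 12.39842

#' X-ray beam parameters
#'
#' Describes the incident X-ray pulse: photon energy (equivalently
#' wavelength), total photons per pulse, and the focal spot diameter.
#' The molecule is assumed fully inside a uniform (top-hat) focal spot,
#' so the fluence seen by the sample is `photons / (pi (f/2)^2)`.
#'
#' @slot energyKeV photon energy in keV; wavelength is `12.39842 / E` Angstrom.
#' @slot photons photons per pulse.
#' @slot focalSizeNm focal spot diameter in nm.
#' @export
setClass("BeamParams", representation(
  energyKeV = "numeric", photons = "numeric", focalSizeNm = "numeric"
))

setValidity("BeamParams", function(object) {
  for (s in c("energyKeV", "photons", "focalSizeNm")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) return(sprintf("%s must be a finite scalar", s))
  }
  if (object@energyKeV <= 0) return("energyKeV must be > 0")
  if (object@photons < 0) return("photons must be >= 0")
  if (object@focalSizeNm <= 0) return("focalSizeNm must be > 0")
  TRUE
})

#' @param energyKeV photon energy (keV). Give either this or `wavelengthA`.
#' @param photons photons per pulse.
#' @param focalSizeNm focal spot diameter (nm).
#' @param wavelengthA X-ray wavelength (Angstrom), alternative to `energyKeV`.
#' @rdname BeamParams-class
#' @export
BeamParams <- function(energyKeV = 12, photons = 1e14, focalSizeNm = 100,
                       wavelengthA = NULL) {
  if (!is.null(wavelengthA)) energyKeV <- .hc_keVA / wavelengthA
  new("BeamParams", energyKeV = as.numeric(energyKeV),
      photons = as.numeric(photons), focalSizeNm = as.numeric(focalSizeNm))
}

#' Area-detector parameters
#'
#' A square pixel-array detector centred on and normal to the beam axis.
#'
#' @slot nPixels pixels per detector side.
#' @slot pixelSizeUm pixel pitch in micrometre.
#' @slot distanceMm sample-to-detector distance in millimetre.
#' @export
setClass("DetectorParams", representation(
  nPixels = "integer", pixelSizeUm = "numeric", distanceMm = "numeric"
))

setValidity("DetectorParams", function(object) {
  if (length(object@nPixels) != 1L || object@nPixels < 2L)
    return("nPixels must be an integer >= 2")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be > 0")
  if (object@distanceMm <= 0) return("distanceMm must be > 0")
  TRUE
})

#' @param nPixels pixels per side.
#' @param pixelSizeUm pixel pitch (um).
#' @param distanceMm sample-to-detector distance (mm).
#' @rdname DetectorParams-class
#' @export
DetectorParams <- function(nPixels = 250, pixelSizeUm = 234, distanceMm = 40) {
  new("DetectorParams", nPixels = as.integer(nPixels),
      pixelSizeUm = as.numeric(pixelSizeUm), distanceMm = as.numeric(distanceMm))
}

#' Per-pixel Ewald-sphere detector model
#'
#' Precomputed per-pixel momentum transfer `q = k(s_hat - z_hat)` (with
#' `k = 2 pi / lambda` and the incident beam along +z), scattering angle,
#' solid angle and unpolarized Thomson polarization factor. All per-pixel
#' slots are `n x n` matrices; rows index the detector x coordinate and
#' columns the y coordinate.
#'
#' @slot beam the [BeamParams-class] used to build the model.
#' @slot det the [DetectorParams-class] used to build the model.
#' @slot qx,qy,qz momentum-transfer components, 1/Angstrom.
#' @slot qmag `|q|` per pixel; equals `4 pi sin(theta) / lambda`.
#' @slot solidAngle pixel solid angle, steradian.
#' @slot polarization `0.5 (1 + cos^2 2theta)`.
#' @slot twoTheta scattering angle `2 theta`, radian.
#' @export
setClass("DetectorModel", representation(
  beam = "BeamParams", det = "DetectorParams",
  qx = "matrix", qy = "matrix", qz = "matrix", qmag = "matrix",
  solidAngle = "matrix", polarization = "matrix", twoTheta = "matrix"
))

#' A single structural snapshot
#'
#' One instantaneous conformation: an ordered atom table (element, atom
#' name, residue index) plus lab-frame coordinates in Angstrom.
#'
#' @slot atoms data.frame with columns `element`, `atomName`, `residueIndex`.
#' @slot xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @slot snapshotId integer snapshot identifier.
#' @export
setClass("Conformer", representation(
  atoms = "data.frame", xyz = "matrix", snapshotId = "integer"
))

setValidity("Conformer", function(object) {
  if (nrow(object@atoms) == 0L) return("conformer must contain at least one atom")
  if (!all(c("element", "atomName", "residueIndex") %in% names(object@atoms)))
    return("atoms must have element, atomName, residueIndex columns")
  if (nrow(object@xyz) != nrow(object@atoms) || ncol(object@xyz) != 3L)
    return("xyz must be an n_atom x 3 matrix")
  if (!all(is.finite(object@xyz))) return("coordinates must be finite")
  if (anyDuplicated(object@xyz)) return("no two atoms may share identical coordinates")
  TRUE
})

Conformer <- function(atoms, xyz, snapshotId = 1L) {
  new("Conformer", atoms = atoms, xyz = xyz, snapshotId = as.integer(snapshotId))
}

#' An ensemble of conformers with shared topology
#'
#' @slot conformers list of [Conformer-class] objects, identical atom count
#'   and ordering.
#' @slot source `"synthetic"` or `"pdb_multi_orientation"`.
#' @export
setClass("Ensemble", representation(conformers = "list", source = "character"))

setValidity("Ensemble", function(object) {
  if (length(object@conformers) == 0L) return("ensemble must contain conformers")
  if (!all(vapply(object@conformers, is, TRUE, "Conformer")))
    return("all elements must be Conformer objects")
  a1 <- object@conformers[[1L]]@atoms
  for (cf in object@conformers) {
    if (nrow(cf@atoms) != nrow(a1) || !identical(cf@atoms$atomName, a1$atomName))
      return("all conformers must share atom count and ordering")
  }
  if (!object@source %in% c("synthetic", "pdb_multi_orientation"))
    return("source must be 'synthetic' or 'pdb_multi_orientation'")
  TRUE
})

Ensemble <- function(conformers, source) {
  new("Ensemble", conformers = conformers, source = source)
}

#' A pair of nanoparticle labeling sites on an ensemble
#'
#' Two labeled sites (residue index + atom name) with the AuNP radius and,
#' for every conformer of the ensemble the pair was selected on, the two
#' sphere centres and their separation `r_AuNP = |c_b - c_a|`.
#'
#' @slot siteA,siteB lists with `residueIndex` and `atomName`.
#' @slot radius AuNP radius R, Angstrom.
#' @slot centersA,centersB per-conformer centre coordinates (n_conf x 3).
#' @slot rAuNP per-conformer inter-particle distance, Angstrom.
#' @export
setClass("LabelPair", representation(
  siteA = "list", siteB = "list", radius = "numeric",
  centersA = "matrix", centersB = "matrix", rAuNP = "numeric"
))

setValidity("LabelPair", function(object) {
  if (object@radius <= 0) return("radius must be > 0")
  n <- length(object@rAuNP)
  if (nrow(object@centersA) != n || nrow(object@centersB) != n)
    return("centersA/centersB must have one row per conformer")
  r <- sqrt(rowSums((object@centersB - object@centersA)^2))
  if (any(abs(r - object@rAuNP) > 1e-9))
    return("rAuNP must equal |centersB - centersA| in every conformer")
  if (any(object@rAuNP <= 2.4 * object@radius))
    return("rAuNP must exceed 2.4 R in every conformer")
  TRUE
})

#' A conformer carrying its two nanoparticle labels
#'
#' @slot conformer the labeled [Conformer-class].
#' @slot centerA,centerB AuNP centres, Angstrom.
#' @slot radius AuNP radius, Angstrom.
#' @slot dTrue ground-truth vector `centerB - centerA`.
#' @slot removedAtoms integer row indices of atoms removed from the
#'   scattering sum (the substituted oxygens), possibly empty.
#' @export
setClass("LabeledStructure", representation(
  conformer = "Conformer", centerA = "numeric", centerB = "numeric",
  radius = "numeric", dTrue = "numeric", removedAtoms = "integer"
))

setValidity("LabeledStructure", function(object) {
  d <- object@centerB - object@centerA
  if (max(abs(d - object@dTrue)) > 1e-9)
    return("dTrue must equal centerB - centerA")
  TRUE
})

#' A simulated scattering image
#'
#' Per-pixel expected (or noisy) photon counts, with an optional component
#' decomposition of the signal into nanoparticle, biomolecule, and cross
#' terms.
#'
#' @slot counts n x n matrix of photon counts.
#' @slot components named list of component images (possibly empty):
#'   `SAuNP` (two-sphere total), `SAuNP1x2` (inter-sphere interference),
#'   `SRNA` (biomolecule), `SAuNPxRNA` (sphere-molecule cross term).
#' @slot beam,det the geometry the image was simulated with.
#' @slot metadata free-form provenance list (seed, dTrue, radius, ...).
#' @export
setClass("ScatterImage", representation(
  counts = "matrix", components = "list",
  beam = "BeamParams", det = "DetectorParams", metadata = "list"
))

#' Noise model parameters
#'
#' Detector noise is the sum of Poisson shot noise on the expected counts
#' and an additive per-pixel uniform background on `[0, uniformMax]`.
#'
#' @slot poisson apply Poisson sampling?
#' @slot uniformMax upper bound of the uniform noise, counts/pixel.
#' @slot seed RNG seed (NA for "use current RNG state").
#' @export
setClass("NoiseParams", representation(
  poisson = "logical", uniformMax = "numeric", seed = "numeric"
))

setValidity("NoiseParams", function(object) {
  if (object@uniformMax < 0) return("uniformMax must be >= 0")
  TRUE
})

#' @param poisson apply Poisson shot noise?
#' @param uniformMax uniform noise amplitude (counts/pixel).
#' @param seed RNG seed, or NA to use the current RNG state.
#' @rdname NoiseParams-class
#' @export
NoiseParams <- function(poisson = TRUE, uniformMax = 1, seed = NA_real_) {
  new("NoiseParams", poisson = poisson, uniformMax = as.numeric(uniformMax),
      seed = as.numeric(seed))
}

#' Configuration of the two-sphere fit
#'
#' @slot rMax search bound on `|d|`, Angstrom.
#' @slot zGridPoints number of initial z grid points over `[-rMax, rMax]`.
#' @slot refineTolerance relative convergence tolerance of the local
#'   refinement.
#' @slot multistart number of ranked candidates refined locally.
#' @slot pixelErrorFloor floor on the per-pixel variance used in the
#'   chi-square weighting, counts.
#' @export
setClass("FitConfig", representation(
  rMax = "numeric", zGridPoints = "integer", refineTolerance = "numeric",
  multistart = "integer", pixelErrorFloor = "numeric"
))

setValidity("FitConfig", function(object) {
  if (object@rMax <= 0) return("rMax must be > 0")
  if (object@zGridPoints < 3L) return("zGridPoints must be >= 3")
  if (object@refineTolerance <= 0) return("refineTolerance must be > 0")
  if (object@multistart < 1L) return("multistart must be >= 1")
  TRUE
})

#' @param rMax search bound on |d| (Angstrom).
#' @param zGridPoints initial z-grid resolution.
#' @param refineTolerance relative tolerance of the refinement.
#' @param multistart number of candidates refined.
#' @param pixelErrorFloor variance floor (counts).
#' @rdname FitConfig-class
#' @export
FitConfig <- function(rMax = 100, zGridPoints = 41, refineTolerance = 1e-10,
                      multistart = 6, pixelErrorFloor = 1) {
  new("FitConfig", rMax = as.numeric(rMax), zGridPoints = as.integer(zGridPoints),
      refineTolerance = as.numeric(refineTolerance),
      multistart = as.integer(multistart),
      pixelErrorFloor = as.numeric(pixelErrorFloor))
}

#' Result of a two-sphere vector retrieval
#'
#' @slot dFit fitted vector `(x, y, z)` in Angstrom, canonicalized so the
#'   sign ambiguity `d <-> -d` of the interference pattern is resolved.
#' @slot rFit `|dFit|`, Angstrom (NA if the fit failed).
#' @slot chi2 weighted residual sum of squares at the optimum.
#' @slot nEvaluations number of chi-square evaluations spent.
#' @slot converged did any refinement start converge?
#' @export
setClass("RetrievalResult", representation(
  dFit = "numeric", rFit = "numeric", chi2 = "numeric",
  nEvaluations = "integer", converged = "logical"
))

## ---- show methods -------------------------------------------------------

setMethod("show", "BeamParams", function(object) {
  cat(sprintf("BeamParams: %.4g keV (lambda %.4f A), %.3g photons, focal %g nm\n",
              object@energyKeV, .hc_keVA / object@energyKeV,
              object@photons, object@focalSizeNm))
})

setMethod("show", "DetectorParams", function(object) {
  cat(sprintf("DetectorParams: %d x %d pixels, %g um pitch, %g mm from sample\n",
              object@nPixels, object@nPixels, object@pixelSizeUm,
              object@distanceMm))
})

setMethod("show", "DetectorModel", function(object) {
  cat("DetectorModel on Ewald sphere\n")
  show(object@beam); show(object@det)
  cat(sprintf("  |q| range: 0 .. %.4f 1/A\n", max(object@qmag)))
})

setMethod("show", "Conformer", function(object) {
  cat(sprintf("Conformer #%d: %d atoms, %d residues\n", object@snapshotId,
              nrow(object@atoms), length(unique(object@atoms$residueIndex))))
})

setMethod("show", "Ensemble", function(object) {
  cat(sprintf("Ensemble (%s): %d conformers x %d atoms\n", object@source,
              length(object@conformers), nrow(object@conformers[[1L]]@atoms)))
})

setMethod("show", "LabelPair", function(object) {
  cat(sprintf("LabelPair R=%g A: (%d|%s) -- (%d|%s), r_AuNP %.2f .. %.2f A (mean %.2f)\n",
              object@radius, object@siteA$residueIndex, object@siteA$atomName,
              object@siteB$residueIndex, object@siteB$atomName,
              min(object@rAuNP), max(object@rAuNP), mean(object@rAuNP)))
})

setMethod("show", "ScatterImage", function(object) {
  cat(sprintf("ScatterImage: %d x %d pixels, total %.4g counts%s\n",
              nrow(object@counts), ncol(object@counts), sum(object@counts),
              if (length(object@components)) ", with components" else ""))
})

setMethod("show", "RetrievalResult", function(object) {
  if (is.na(object@rFit)) {
    cat("RetrievalResult: FAILED (no candidates converged)\n")
  } else {
    cat(sprintf("RetrievalResult: d = (%.3f, %.3f, %.3f) A, r = %.3f A, chi2 = %.4g%s\n",
                object@dFit[1], object@dFit[2], object@dFit[3], object@rFit,
                object@chi2, if (object@converged) "" else " (not converged)"))
  }
})

## ---- accessors ----------------------------------------------------------

#' @rdname BeamParams-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("energyKeV", function(object) standardGeneric("energyKeV"))
#' @rdname BeamParams-class
#' @export
setMethod("energyKeV", "BeamParams", function(object) object@energyKeV)

#' @rdname BeamParams-class
#' @export
setGeneric("wavelengthA", function(object) standardGeneric("wavelengthA"))
#' @rdname BeamParams-class
#' @export
setMethod("wavelengthA", "BeamParams", function(object) .hc_keVA / object@energyKeV)

#' @rdname BeamParams-class
#' @export
setGeneric("photons", function(object) standardGeneric("photons"))
#' @rdname BeamParams-class
#' @export
setMethod("photons", "BeamParams", function(object) object@photons)

#' @rdname DetectorParams-class
#' @export
setGeneric("nPixels", function(object) standardGeneric("nPixels"))
#' @rdname DetectorParams-class
#' @export
setMethod("nPixels", "DetectorParams", function(object) object@nPixels)
#' @rdname DetectorParams-class
#' @export
setMethod("nPixels", "DetectorModel", function(object) object@det@nPixels)

#' @rdname ScatterImage-class
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @rdname ScatterImage-class
#' @export
setMethod("counts", "ScatterImage", function(object) object@counts)

#' @rdname ScatterImage-class
#' @export
setGeneric("imageComponents", function(object) standardGeneric("imageComponents"))
#' @rdname ScatterImage-class
#' @export
setMethod("imageComponents", "ScatterImage", function(object) object@components)

#' @rdname Conformer-class
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))
#' @rdname Conformer-class
#' @export
setMethod("atoms", "Conformer", function(object) object@atoms)

#' @rdname Conformer-class
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))
#' @rdname Conformer-class
#' @export
setMethod("coords", "Conformer", function(object) object@xyz)

#' @rdname Ensemble-class
#' @export
setGeneric("conformers", function(object) standardGeneric("conformers"))
#' @rdname Ensemble-class
#' @export
setMethod("conformers", "Ensemble", function(object) object@conformers)

#' @rdname RetrievalResult-class
#' @export
setGeneric("dFit", function(object) standardGeneric("dFit"))
#' @rdname RetrievalResult-class
#' @export
setMethod("dFit", "RetrievalResult", function(object) object@dFit)

#' @rdname RetrievalResult-class
#' @export
setGeneric("rFit", function(object) standardGeneric("rFit"))
#' @rdname RetrievalResult-class
#' @export
setMethod("rFit", "RetrievalResult", function(object) object@rFit)

#' @rdname RetrievalResult-class
#' @export
setGeneric("chiSq", function(object) standardGeneric("chiSq"))
#' @rdname RetrievalResult-class
#' @export
setMethod("chiSq", "RetrievalResult", function(object) object@chi2)

#' @rdname LabelPair-class
#' @export
setGeneric("rAuNP", function(object) standardGeneric("rAuNP"))
#' @rdname LabelPair-class
#' @export
setMethod("rAuNP", "LabelPair", function(object) object@rAuNP)

#' @rdname LabeledStructure-class
#' @export
setGeneric("dTrue", function(object) standardGeneric("dTrue"))
#' @rdname LabeledStructure-class
#' @export
setMethod("dTrue", "LabeledStructure", function(object) object@dTrue)
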