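#' @import methods
NULL

#' Parameters of a simulated 2D worm-like chain
#'
#' Defines one simulation condition: persistence length \eqn{\xi} (nm), the
#' discretisation step \eqn{\delta} (nm, 0.34 nm per base pair for B-DNA), the
#' number of steps, the molecular diameter used by the renderer, and an
#' optional per-chain seed. The chain contour length is
#' \eqn{L_C = n_{steps}\,\delta} by construction.
#'
#' @slot persistenceLength persistence length \eqn{\xi} in nm (> 0)
#' @slot stepLength discretisation step \eqn{\delta} in nm (> 0)
#' @slot nSteps number of steps (>= 1); the chain has \code{nSteps + 1} vertices
#' @slot diameter molecular diameter in nm (> 0), used when rasterising
#' @slot seed integer seed for this chain's random substream (NA = use the
#'   current stream)
#' @export
setClass("WLCParams",
  representation(persistenceLength = "numeric", stepLength = "numeric",
                 nSteps = "integer", diameter = "numeric", seed = "integer"),
  prototype(stepLength = 0.34, diameter = 2.0, seed = NA_integer_))

setValidity("WLCParams", function(object) {
  msg <- character()
  if (length(object@persistenceLength) != 1L || !is.finite(object@persistenceLength) ||
      object@persistenceLength <= 0)
    msg <- c(msg, "persistenceLength must be a single positive number")
  if (length(object@stepLength) != 1L || !is.finite(object@stepLength) ||
      object@stepLength <= 0)
    msg <- c(msg, "stepLength must be a single positive number")
  if (length(object@nSteps) != 1L || is.na(object@nSteps) || object@nSteps < 1L)
    msg <- c(msg, "nSteps must be a positive integer")
  if (length(object@diameter) != 1L || !is.finite(object@diameter) ||
      object@diameter <= 0)
    msg <- c(msg, "diameter must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @param persistenceLength,stepLength,nSteps,diameter,seed see slot docs
#' @rdname WLCParams-class
#' @export
WLCParams <- function(persistenceLength, nSteps, stepLength = 0.34,
                      diameter = 2.0, seed = NA_integer_) {
  new("WLCParams", persistenceLength = as.numeric(persistenceLength),
      stepLength = as.numeric(stepLength), nSteps = as.integer(nSteps),
      diameter = as.numeric(diameter), seed = as.integer(seed))
}

#' A simulated worm-like-chain conformation
#'
#' Ordered 2D vertex coordinates (nm) of one equilibrium chain together with
#' the parameters that generated it. Consecutive vertices are exactly one step
#' length apart.
#'
#' @slot vertices numeric matrix with columns \code{x}, \code{y} (nm)
#' @slot params the generating \linkS4class{WLCParams}
#' @export
setClass("PolymerChain",
  representation(vertices = "matrix", params = "WLCParams"))

setValidity("PolymerChain", function(object) {
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L)
    return("vertices must be a numeric matrix with two columns (x, y)")
  if (nrow(v) != object@params@nSteps + 1L)
    return("vertex count must equal nSteps + 1")
  d <- sqrt(diff(v[, 1L])^2 + diff(v[, 2L])^2)
  if (any(abs(d - object@params@stepLength) > 1e-9 * max(1, object@params@stepLength)))
    return("consecutive vertices must be exactly one step length apart")
  TRUE
})

#' AFM tip model
#'
#' The scanning tip used to broaden simulated molecules: a spherical cap of
#' radius \code{radius} (physically motivated default) or a flat disk of the
#' same radius (pure max-filter).
#'
#' @slot radius tip radius \eqn{R_T} in nm (> 0)
#' @slot profile \code{"cap"} (spherical cap) or \code{"disk"} (flat disk)
#' @export
setClass("TipModel",
  representation(radius = "numeric", profile = "character"),
  prototype(radius = 3.0, profile = "cap"))

setValidity("TipModel", function(object) {
  if (length(object@radius) != 1L || !is.finite(object@radius) || object@radius <= 0)
    return("radius must be a single positive number")
  if (!object@profile %in% c("cap", "disk"))
    return("profile must be 'cap' or 'disk'")
  TRUE
})

#' @param radius,profile see slot docs
#' @rdname TipModel-class
#' @export
TipModel <- function(radius = 3.0, profile = c("cap", "disk")) {
  new("TipModel", radius = as.numeric(radius), profile = match.arg(profile))
}

#' A square-pixel AFM height image
#'
#' The unit exchanged with files: a rectangular grid of heights in nm with its
#' pixel size (nm per pixel), the Gaussian background-noise level (0 for
#' noiseless synthetic images, estimated for measured ones) and a provenance
#' tag. Pixel (1, 1) is the top-left corner; row indexes y, column indexes x,
#' and physical position is (index - 1) * pixelSize at the pixel center.
#'
#' @slot heights numeric matrix of heights (nm), all finite
#' @slot pixelSize nm per pixel (> 0)
#' @slot noiseSigma Gaussian background noise sigma in nm (>= 0)
#' @slot provenance \code{"simulated"} or \code{"measured"}
#' @export
setClass("HeightImage",
  representation(heights = "matrix", pixelSize = "numeric",
                 noiseSigma = "numeric", provenance = "character"),
  prototype(pixelSize = 1.0, noiseSigma = 0.0, provenance = "simulated"))

setValidity("HeightImage", function(object) {
  if (!is.numeric(object@heights) || !all(is.finite(object@heights)))
    return("heights must be a numeric matrix of finite values")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  if (length(object@noiseSigma) != 1L || !is.finite(object@noiseSigma) ||
      object@noiseSigma < 0)
    return("noiseSigma must be a single non-negative number")
  if (!object@provenance %in% c("simulated", "measured"))
    return("provenance must be 'simulated' or 'measured'")
  TRUE
})

#' @param heights,pixelSize,noiseSigma,provenance see slot docs
#' @rdname HeightImage-class
#' @export
HeightImage <- function(heights, pixelSize = 1.0, noiseSigma = 0.0,
                        provenance = c("simulated", "measured")) {
  new("HeightImage", heights = heights, pixelSize = as.numeric(pixelSize),
      noiseSigma = as.numeric(noiseSigma), provenance = match.arg(provenance))
}

#' An ordered single-pixel contour trace
#'
#' The product of the tracing pipeline for one molecule: an ordered path of
#' 8-connected skeleton pixels, its Freeman chain code, and the chain-code
#' length estimate in nm. Rejected components keep their pixels (unordered)
#' and a reason, with an NA length.
#'
#' @slot pixelPath integer matrix with columns \code{row}, \code{col}
#' @slot chainCode integer vector of 8-connectivity move codes (0-7; even =
#'   axial, odd = diagonal), of length \code{nrow(pixelPath) - 1}
#' @slot lengthEstimate Freeman length estimate \eqn{L_C^*} in nm
#' @slot pixelSize nm per pixel of the source image
#' @slot sourceImageId identifier of the source image
#' @slot quality \code{"clean"}, \code{"repaired"} or \code{"rejected"}
#' @slot note free-text detail (e.g. rejection reason)
#' @export
setClass("ContourTrace",
  representation(pixelPath = "matrix", chainCode = "integer",
                 lengthEstimate = "numeric", pixelSize = "numeric",
                 sourceImageId = "character", quality = "character",
                 note = "character"),
  prototype(lengthEstimate = NA_real_, pixelSize = 1.0,
            sourceImageId = "", quality = "clean", note = ""))

setValidity("ContourTrace", function(object) {
  if (!object@quality %in% c("clean", "repaired", "rejected"))
    return("quality must be 'clean', 'repaired' or 'rejected'")
  if (object@quality == "rejected") return(TRUE)
  p <- object@pixelPath
  if (ncol(p) != 2L || nrow(p) < 2L)
    return("pixelPath must have >= 2 rows and columns (row, col)")
  if (length(object@chainCode) != nrow(p) - 1L)
    return("chainCode length must equal path length - 1")
  if (any(object@chainCode < 0L | object@chainCode > 7L))
    return("chainCode symbols must lie in 0..7")
  step <- cbind(diff(p[, 1L]), diff(p[, 2L]))
  if (any(pmax(abs(step[, 1L]), abs(step[, 2L])) != 1L))
    return("consecutive path pixels must be 8-neighbors")
  if (!is.na(object@lengthEstimate) && object@lengthEstimate <= 0)
    return("lengthEstimate must be positive for paths of >= 2 pixels")
  TRUE
})

#' Contour-length bias calibration model
#'
#' The tracer's contour-length bias: a constant endpoint bias C (nm) and the
#' stiffness-dependent multiplicative factor
#' \eqn{f(\xi) = scale\,(1 - A/\xi)}. With \code{scale = 1} (the default)
#' this is the classical one-parameter form; the scale factor accommodates
#' tracers whose rigid-rod response differs from unity, such as plain
#' chain-code length estimation on fine pixel grids (the bias form is
#' empirical and tracer-specific). The model is tagged with the tracer/imager
#' configuration hash that produced it and the persistence-length range of
#' the calibration grid.
#'
#' @slot A bias-slope parameter in nm
#' @slot Cconst constant endpoint bias C in nm (slot named to avoid partial
#'   matching against the \code{Class} argument of \code{new()})
#' @slot scale rigid-limit response \eqn{f(\infty)} (dimensionless, default 1)
#' @slot pixelSize nm per pixel the calibration was run at
#' @slot tracerConfigHash identifier of the tracer/imager configuration
#' @slot validityRange numeric length-2: the xi interval covered (nm)
#' @export
setClass("CalibrationModel",
  representation(A = "numeric", Cconst = "numeric", scale = "numeric",
                 pixelSize = "numeric", tracerConfigHash = "character",
                 validityRange = "numeric"),
  prototype(scale = 1.0, pixelSize = 1.0, tracerConfigHash = "",
            validityRange = c(NA_real_, NA_real_)))

setValidity("CalibrationModel", function(object) {
  if (length(object@A) != 1L || !is.finite(object@A))
    return("A must be a single finite number")
  if (length(object@Cconst) != 1L || !is.finite(object@Cconst))
    return("C must be a single finite number")
  if (length(object@scale) != 1L || !is.finite(object@scale) || object@scale <= 0)
    return("scale must be a single positive number")
  if (length(object@validityRange) != 2L)
    return("validityRange must have length 2")
  r <- object@validityRange
  if (all(is.finite(r)) && object@A > 0 && min(r) <= object@A)
    return("f(xi) must stay positive over validityRange (need min(xi) > A)")
  TRUE
})

#' @param A,C,scale,pixelSize,tracerConfigHash,validityRange see slot docs
#' @rdname CalibrationModel-class
#' @export
CalibrationModel <- function(A, C, scale = 1.0, pixelSize = 1.0,
                             tracerConfigHash = "",
                             validityRange = c(NA_real_, NA_real_)) {
  new("CalibrationModel", A = as.numeric(A), Cconst = as.numeric(C),
      scale = as.numeric(scale), pixelSize = as.numeric(pixelSize),
      tracerConfigHash = as.character(tracerConfigHash),
      validityRange = as.numeric(validityRange))
}

#' One calibration condition: measured lengths at known truth
#'
#' Measured (traced) contour lengths of an ensemble simulated at a known
#' persistence length and true contour length.
#'
#' @slot trueXi simulated persistence length (nm)
#' @slot trueContour simulated contour length \eqn{L_S} (nm)
#' @slot measuredLengths traced Freeman lengths \eqn{L_C^*} (nm)
#' @export
setClass("CalibrationEnsemble",
  representation(trueXi = "numeric", trueContour = "numeric",
                 measuredLengths = "numeric"))

setValidity("CalibrationEnsemble", function(object) {
  if (object@trueXi <= 0 || object@trueContour <= 0)
    return("trueXi and trueContour must be positive")
  if (length(object@measuredLengths) < 1L || any(object@measuredLengths <= 0))
    return("measuredLengths must be a non-empty vector of positive lengths")
  TRUE
})

#' @param trueXi,trueContour,measuredLengths see slot docs
#' @rdname CalibrationEnsemble-class
#' @export
CalibrationEnsemble <- function(trueXi, trueContour, measuredLengths) {
  new("CalibrationEnsemble", trueXi = as.numeric(trueXi),
      trueContour = as.numeric(trueContour),
      measuredLengths = as.numeric(measuredLengths))
}

#' A pooled persistence-length estimate at one segment length
#'
#' Result of pooling non-overlapping equal-arc-length segments across
#' molecules: the pooled mean-square end-to-end distance, the raw (uncorrected)
#' inversion of the 2D worm-like-chain relation, the calibrated self-consistent
#' estimate, and a bootstrap standard error over molecules.
#'
#' @slot segmentLength requested segment length \eqn{\ell^*} (nm, measured scale)
#' @slot meanSegmentLength mean realised segment Freeman length (nm)
#' @slot nSegments number of pooled segments
#' @slot nMolecules number of molecules contributing
#' @slot meanR2 pooled mean-square end-to-end distance (nm^2)
#' @slot xiRaw uncorrected persistence-length estimate (nm)
#' @slot xiCorrected calibrated estimate (nm; NA when no model given)
#' @slot se bootstrap standard error of the reported estimate (nm)
#' @export
setClass("StiffnessEstimate",
  representation(segmentLength = "numeric", meanSegmentLength = "numeric",
                 nSegments = "integer", nMolecules = "integer",
                 meanR2 = "numeric", xiRaw = "numeric",
                 xiCorrected = "numeric", se = "numeric"))

## show() methods -----------------------------------------------------------

setMethod("show", "WLCParams", function(object) {
  cat(sprintf("WLCParams: xi = %g nm, step = %g nm, %d steps (L_C = %g nm), diameter = %g nm\n",
              object@persistenceLength, object@stepLength, object@nSteps,
              object@nSteps * object@stepLength, object@diameter))
})

setMethod("show", "PolymerChain", function(object) {
  v <- object@vertices
  cat(sprintf("PolymerChain: %d vertices, L_C = %g nm, xi = %g nm, end-to-end R = %.2f nm\n",
              nrow(v), object@params@nSteps * object@params@stepLength,
              object@params@persistenceLength,
              sqrt(sum((v[nrow(v), ] - v[1L, ])^2))))
})

setMethod("show", "HeightImage", function(object) {
  cat(sprintf("HeightImage: %d x %d px at %g nm/px (%s), height range [%.3g, %.3g] nm, noise sigma %g nm\n",
              nrow(object@heights), ncol(object@heights), object@pixelSize,
              object@provenance, min(object@heights), max(object@heights),
              object@noiseSigma))
})

setMethod("show", "TipModel", function(object) {
  cat(sprintf("TipModel: %s, R_T = %g nm\n",
              if (object@profile == "cap") "spherical cap" else "flat disk",
              object@radius))
})

setMethod("show", "ContourTrace", function(object) {
  if (object@quality == "rejected") {
    cat(sprintf("ContourTrace [rejected: %s] (%d px, image '%s')\n",
                object@note, nrow(object@pixelPath), object@sourceImageId))
  } else {
    cat(sprintf("ContourTrace [%s]: %d px, L_C* = %.2f nm (image '%s')\n",
                object@quality, nrow(object@pixelPath), object@lengthEstimate,
                object@sourceImageId))
  }
})

setMethod("show", "CalibrationModel", function(object) {
  form <- if (abs(object@scale - 1) < 1e-12) "f(xi) = 1 - A/xi"
          else sprintf("f(xi) = %.4f (1 - A/xi)", object@scale)
  cat(sprintf("CalibrationModel: %s with A = %.4f nm, C = %.4f nm\n",
              form, object@A, object@Cconst))
  cat(sprintf("  pixel size %g nm/px, valid for xi in [%g, %g] nm, tracer config '%s'\n",
              object@pixelSize, object@validityRange[1L], object@validityRange[2L],
              object@tracerConfigHash))
})

setMethod("show", "CalibrationEnsemble", function(object) {
  cat(sprintf("CalibrationEnsemble: xi = %g nm, L_S = %g nm, n = %d, mean L_C* = %.2f nm\n",
              object@trueXi, object@trueContour, length(object@measuredLengths),
              mean(object@measuredLengths)))
})

setMethod("show", "StiffnessEstimate", function(object) {
  cat(sprintf("StiffnessEstimate at l* = %g nm: xi_raw = %.2f nm, xi_corrected = %.2f nm (SE %.2f)\n",
              object@segmentLength, object@xiRaw, object@xiCorrected, object@se))
  cat(sprintf("  %d segments from %d molecules, <R^2> = %.1f nm^2, mean segment length %.2f nm\n",
              object@nSegments, object@nMolecules, object@meanR2,
              object@meanSegmentLength))
})
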