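#' Accessors for wlcAFM classes
#'
#' Small generic accessors so downstream code never touches slots directly.
#'
#' @param object a wlcAFM S4 object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setMethod("vertices", "PolymerChain", function(object) object@vertices)

#' @rdname accessors
#' @export
setGeneric("chainParams", function(object) standardGeneric("chainParams"))
#' @rdname accessors
#' @export
setMethod("chainParams", "PolymerChain", function(object) object@params)

#' @rdname accessors
#' @export
setGeneric("persistenceLength", function(object) standardGeneric("persistenceLength"))
#' @rdname accessors
#' @export
setMethod("persistenceLength", "WLCParams", function(object) object@persistenceLength)
#' @rdname accessors
#' @export
setMethod("persistenceLength", "PolymerChain", function(object) object@params@persistenceLength)

#' @rdname accessors
#' @export
setGeneric("contourLength", function(object) standardGeneric("contourLength"))
#' @rdname accessors
#' @export
setMethod("contourLength", "WLCParams", function(object) object@nSteps * object@stepLength)
#' @rdname accessors
#' @export
setMethod("contourLength", "PolymerChain", function(object) contourLength(object@params))

#' @rdname accessors
#' @export
setGeneric("heights", function(object) standardGeneric("heights"))
#' @rdname accessors
#' @export
setMethod("heights", "HeightImage", function(object) object@heights)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "HeightImage", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "ContourTrace", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "CalibrationModel", function(object) object@pixelSize)

#' @rdname accessors
#' @export
setGeneric("noiseSigma", function(object) standardGeneric("noiseSigma"))
#' @rdname accessors
#' @export
setMethod("noiseSigma", "HeightImage", function(object) object@noiseSigma)

#' @rdname accessors
#' @export
setGeneric("pixelPath", function(object) standardGeneric("pixelPath"))
#' @rdname accessors
#' @export
setMethod("pixelPath", "ContourTrace", function(object) object@pixelPath)

#' @rdname accessors
#' @export
setGeneric("chainCode", function(object) standardGeneric("chainCode"))
#' @rdname accessors
#' @export
setMethod("chainCode", "ContourTrace", function(object) object@chainCode)

#' @rdname accessors
#' @export
setGeneric("traceLength", function(object) standardGeneric("traceLength"))
#' @rdname accessors
#' @export
setMethod("traceLength", "ContourTrace", function(object) object@lengthEstimate)

#' @rdname accessors
#' @export
setGeneric("quality", function(object) standardGeneric("quality"))
#' @rdname accessors
#' @export
setMethod("quality", "ContourTrace", function(object) object@quality)

#' @rdname accessors
#' @export
setGeneric("biasA", function(object) standardGeneric("biasA"))
#' @rdname accessors
#' @export
setMethod("biasA", "CalibrationModel", function(object) object@A)

#' @rdname accessors
#' @export
setGeneric("biasC", function(object) standardGeneric("biasC"))
#' @rdname accessors
#' @export
setMethod("biasC", "CalibrationModel", function(object) object@Cconst)

#' Stiffness-dependent length-bias factor f(xi)
#'
#' Evaluates the calibrated multiplicative contour-length bias
#' \eqn{f(\xi) = scale\,(1 - A/\xi)}: the ratio of the traced to the true
#' contour length for molecules of persistence length \eqn{\xi}. With the
#' default \code{scale = 1} this is the classical one-parameter form.
#'
#' @param object a \linkS4class{CalibrationModel}
#' @param xi persistence length(s) in nm
#' @return numeric vector of positive bias factors
#' @export
setGeneric("biasFactor", function(object, xi) standardGeneric("biasFactor"))
#' @rdname biasFactor
#' @export
setMethod("biasFactor", "CalibrationModel", function(object, xi) {
  if (any(xi <= object@A))
    stopf("biasFactor undefined: xi must exceed A = %.4g nm", object@A)
  object@scale * (1 - object@A / xi)
})

#' @rdname accessors
#' @export
setGeneric("biasScale", function(object) standardGeneric("biasScale"))
#' @rdname accessors
#' @export
setMethod("biasScale", "CalibrationModel", function(object) object@scale)

#' Convert a StiffnessEstimate (or list of them) to a data.frame
#'
#' @param x a \linkS4class{StiffnessEstimate} or a list of them
#' @param row.names,optional,... passed on for compatibility with the generic
#' @return a data.frame with one row per estimate
#' @export
as.data.frame.StiffnessEstimate <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(segment_length_nm = x@segmentLength,
             mean_segment_length_nm = x@meanSegmentLength,
             n_segments = x@nSegments, n_molecules = x@nMolecules,
             mean_R2_nm2 = x@meanR2, xi_raw_nm = x@xiRaw,
             xi_corr_nm = x@xiCorrected, se_nm = x@se)
}

#' @rdname as.data.frame.StiffnessEstimate
#' @param estimates list of \linkS4class{StiffnessEstimate}
#' @export
estimatesTable <- function(estimates) {
  if (is(estimates, "StiffnessEstimate")) estimates <- list(estimates)
  do.call(rbind, lapply(estimates, as.data.frame))
}
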