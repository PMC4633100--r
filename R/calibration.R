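#' Estimate the constant endpoint bias C
#'
#' The tracer's contour-length bias is modelled as
#' \eqn{L_S = L_C^*/f(\xi) + C}: a stiffness-dependent multiplicative
#' underestimation f plus a constant endpoint bias C. Comparing two simulated
#' ensembles with the same persistence length but different true contour
#' lengths cancels f: with \eqn{\alpha} the ratio of mean measured lengths
#' (long over short), \eqn{C = (\alpha L_S^{short} - L_S^{long})/(\alpha - 1)}.
#' The estimate is invariant to which ensemble is called long or short.
#'
#' @param ensLong,ensShort two \linkS4class{CalibrationEnsemble}s sharing
#'   \code{trueXi} but with different \code{trueContour}
#' @return C in nm
#' @export
estimateC <- function(ensLong, ensShort) {
  stopifnot(is(ensLong, "CalibrationEnsemble"), is(ensShort, "CalibrationEnsemble"))
  if (abs(ensLong@trueXi - ensShort@trueXi) > 1e-9)
    stopf("ensembles must share the same true persistence length")
  if (abs(ensLong@trueContour - ensShort@trueContour) < 1e-9)
    stopf("ensembles must have different true contour lengths")
  alpha <- mean(ensLong@measuredLengths) / mean(ensShort@measuredLengths)
  if (abs(alpha - 1) < 1e-6)
    stopf("measured lengths are indistinguishable (alpha = %.6f): C is ill-conditioned", alpha)
  (alpha * ensShort@trueContour - ensLong@trueContour) / (alpha - 1)
}

#' Estimate the constant endpoint bias from several contour lengths
#'
#' Generalises \code{\link{estimateC}}: under the bias model
#' \eqn{\overline{L_C^*} = f\,(L_S - C)} at fixed persistence length, the mean
#' measured length is linear in the true length with slope f and intercept
#' \eqn{-fC}. A weighted least-squares line through ensembles at two or more
#' contour lengths gives \eqn{C = -intercept/slope}; with exactly two lengths
#' this reproduces the pairwise ratio formula exactly, and additional lengths
#' (especially a short one) tighten the estimate considerably.
#'
#' @param ensembles list of \linkS4class{CalibrationEnsemble}s sharing
#'   \code{trueXi}, at >= 2 distinct contour lengths
#' @return list with \code{C}, \code{f} (the slope at this stiffness) and
#'   \code{se} (first-order standard error of C)
#' @export
estimateCFromLengths <- function(ensembles) {
  stopifnot(length(ensembles) >= 2L)
  xis <- vapply(ensembles, function(e) e@trueXi, numeric(1L))
  if (diff(range(xis)) > 1e-9)
    stopf("all ensembles must share the same true persistence length")
  LS <- vapply(ensembles, function(e) e@trueContour, numeric(1L))
  if (length(unique(LS)) < 2L)
    stopf("need at least two distinct true contour lengths")
  m <- vapply(ensembles, function(e) mean(e@measuredLengths), numeric(1L))
  v <- vapply(ensembles, function(e)
    stats::var(e@measuredLengths) / length(e@measuredLengths), numeric(1L))
  w <- 1 / pmax(v, 1e-12)
  fit <- stats::lm.wfit(cbind(1, LS), m, w)
  b0 <- fit$coefficients[1L]; b1 <- fit$coefficients[2L]
  if (!is.finite(b1) || abs(b1) < 1e-6)
    stopf("measured lengths do not resolve the contour lengths: C is ill-conditioned")
  C <- -b0 / b1
  # delta-method SE from the weighted regression covariance
  XtWX <- crossprod(cbind(1, LS) * sqrt(w))
  covb <- solve(XtWX)
  g <- c(-1 / b1, b0 / b1^2)
  se <- sqrt(drop(t(g) %*% covb %*% g))
  list(C = unname(C), f = unname(b1), se = unname(se))
}

#' Measure the multiplicative length-bias factor for one ensemble
#'
#' With the constant bias removed (\eqn{L_C = L_S - C}), the factor is
#' \eqn{\hat f = \overline{L_C^*} / L_C}, with a bootstrap standard error over
#' molecules.
#'
#' @param ens a \linkS4class{CalibrationEnsemble}
#' @param C constant endpoint bias in nm (from \code{\link{estimateC}}, with a
#'   matching tracer configuration)
#' @param B bootstrap resamples for the standard error
#' @param seed optional seed for the bootstrap
#' @return list with \code{fHat}, \code{se}, \code{n}, \code{xi}
#' @export
measureF <- function(ens, C, B = 200L, seed = NULL) {
  stopifnot(is(ens, "CalibrationEnsemble"))
  LC <- ens@trueContour - C
  if (LC <= 0)
    stopf("invalid calibration: true contour %.3g nm does not exceed C = %.3g nm",
          ens@trueContour, C)
  x <- ens@measuredLengths
  fHat <- mean(x) / LC
  se <- withSeed(seed, {
    boot <- vapply(seq_len(B),
                   function(i) mean(sample(x, replace = TRUE)) / LC,
                   numeric(1L))
    stats::sd(boot)
  })
  list(fHat = fHat, se = se, n = length(x), xi = ens@trueXi)
}

#' Fit the bias function f(xi) = 1 - A/xi
#'
#' Weighted least squares of the measured bias factors on the model
#' \eqn{1 - \hat f = A/\xi} (a straight line through the origin in
#' \eqn{1/\xi}), weighted by inverse variance when standard errors are given.
#'
#' @param xi persistence lengths of the calibration grid (nm; >= 3 distinct
#'   values)
#' @param fHat measured bias factors
#' @param se optional standard errors of \code{fHat} (inverse-variance
#'   weights); \code{NULL} = unweighted
#' @param C the constant bias to store in the model
#' @param pixelSize nm/px the calibration was run at
#' @param tracerConfigHash configuration tag (see \code{\link{configHash}})
#' @return a \linkS4class{CalibrationModel} with attributes \code{"fitted"}
#'   (fitted f values) and \code{"seA"} (standard error of A)
#' @export
fitA <- function(xi, fHat, se = NULL, C = 0, pixelSize = 1.0,
                 tracerConfigHash = "") {
  if (length(unique(xi)) < 3L)
    stopf("need >= 3 distinct persistence lengths to fit A (got %d)",
          length(unique(xi)))
  stopifnot(length(xi) == length(fHat))
  w <- if (is.null(se)) rep(1, length(xi)) else 1 / pmax(se, 1e-12)^2
  u <- 1 / xi
  y <- 1 - fHat
  A <- sum(w * u * y) / sum(w * u^2)
  seA <- sqrt(1 / sum(w * u^2)) * sqrt(max(0, sum(w * (y - A * u)^2) /
                                              max(1, length(xi) - 1L)) /
                                         mean(w))
  model <- CalibrationModel(A = A, C = C, pixelSize = pixelSize,
                            tracerConfigHash = tracerConfigHash,
                            validityRange = range(xi))
  attr(model, "fitted") <- 1 - A * u
  attr(model, "seA") <- seA
  model
}

#' Fit the generalised bias function f(xi) = scale * (1 - A/xi)
#'
#' Weighted least squares of \eqn{\hat f} on \eqn{B - BA/\xi}, linear in
#' \eqn{(1, 1/\xi)}. The intercept B is the tracer's rigid-rod response; for
#' a tracer that recovers straight contours exactly, B = 1 and the fit
#' reduces to the one-parameter form of \code{\link{fitA}}. The bias form is
#' empirical and tracer-specific: plain chain-code length estimation on a
#' fine pixel grid over-reads straight digitised curves by a few percent
#' (orientation average of the axial/diagonal weights), giving B > 1, while
#' skeleton smoothing shortens soft molecules, giving the \eqn{-BA/\xi} term.
#'
#' @inheritParams fitA
#' @return a \linkS4class{CalibrationModel} with attributes \code{"fitted"}
#'   and \code{"residuals"}
#' @export
fitBiasModel <- function(xi, fHat, se = NULL, C = 0, pixelSize = 1.0,
                         tracerConfigHash = "") {
  if (length(unique(xi)) < 3L)
    stopf("need >= 3 distinct persistence lengths to fit the bias model (got %d)",
          length(unique(xi)))
  stopifnot(length(xi) == length(fHat))
  w <- if (is.null(se)) rep(1, length(xi)) else 1 / pmax(se, 1e-12)^2
  u <- 1 / xi
  fit <- stats::lm.wfit(cbind(1, u), fHat, w)
  B <- fit$coefficients[1L]
  slope <- fit$coefficients[2L]
  if (!is.finite(B) || B <= 0)
    stopf("bias-model fit failed: non-positive rigid-limit response")
  A <- -slope / B
  model <- CalibrationModel(A = A, C = C, scale = B, pixelSize = pixelSize,
                            tracerConfigHash = tracerConfigHash,
                            validityRange = range(xi))
  attr(model, "fitted") <- B * (1 - A * u)
  attr(model, "residuals") <- fHat - attr(model, "fitted")
  model
}

#' Correct a measured contour length for the calibrated bias
#'
#' Inverts the multiplicative bias: \eqn{L_C = L_C^* / f(\xi^*)} with
#' \eqn{f(\xi) = 1 - A/\xi}. The constant bias C applies only to whole
#' molecules during calibration, not to internally cut segments.
#'
#' @param lengthStar measured length(s) \eqn{L_C^*} in nm
#' @param xiStar measured persistence length in nm (must exceed A)
#' @param model a \linkS4class{CalibrationModel}
#' @return corrected length(s) in nm
#' @examples
#' m <- CalibrationModel(A = 0.4310, C = 0.7428, validityRange = c(10, 100))
#' correctLength(19.8, 50, m)   # 19.9721...
#' @export
correctLength <- function(lengthStar, xiStar, model) {
  stopifnot(is(model, "CalibrationModel"))
  if (any(xiStar <= model@A))
    stopf("correction undefined: xi* = %.4g nm does not exceed A = %.4g nm (out of validity)",
          min(xiStar), model@A)
  lengthStar / biasFactor(model, xiStar)
}

#' Persist / load a calibration model as JSON
#'
#' The JSON records A, C, pixel size, the tracer configuration hash, the
#' validity range and optional ensemble sizes. On load, a hash mismatch with
#' the supplied current configuration is refused unless \code{override = TRUE},
#' because the constants are only meaningful for the configuration that
#' produced them.
#'
#' @param model a \linkS4class{CalibrationModel}
#' @param path JSON file path
#' @param ensembleSizes optional named list recorded alongside
#' @return \code{writeCalibrationModel} returns \code{path} invisibly;
#'   \code{readCalibrationModel} returns a \linkS4class{CalibrationModel}
#' @export
writeCalibrationModel <- function(model, path, ensembleSizes = NULL) {
  stopifnot(is(model, "CalibrationModel"))
  jsonlite::write_json(list(A_nm = model@A, C_nm = model@Cconst,
                            scale = model@scale,
                            pixel_size_nm = model@pixelSize,
                            tracer_config_hash = model@tracerConfigHash,
                            xi_range_nm = model@validityRange,
                            ensemble_sizes = ensembleSizes),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibrationModel
#' @param expectedHash current tracer configuration hash to check against
#'   (\code{NULL} skips the check)
#' @param override load despite a hash mismatch
#' @export
readCalibrationModel <- function(path, expectedHash = NULL, override = FALSE) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(expectedHash) && !identical(j$tracer_config_hash, expectedHash) &&
      !override)
    stopf(paste0("calibration model was built with tracer config '%s' but the ",
                 "current config is '%s'; refusing to load (use override = TRUE ",
                 "to force)"), j$tracer_config_hash, expectedHash)
  CalibrationModel(A = j$A_nm, C = j$C_nm, scale = j$scale %||% 1,
                   pixelSize = j$pixel_size_nm,
                   tracerConfigHash = j$tracer_config_hash,
                   validityRange = j$xi_range_nm)
}
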