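#' Mean-square end-to-end distance of a 2D worm-like chain
#'
#' Evaluates the 2D worm-like-chain relation
#' \deqn{\langle R^2\rangle = 4\xi L_C\left(1 - \frac{2\xi}{L_C}
#'   \left(1 - e^{-L_C/2\xi}\right)\right),}
#' switching to a series expansion in \eqn{x = L_C/2\xi} for \eqn{x < 10^{-3}}
#' to avoid catastrophic cancellation in the rigid limit. Stable for
#' \eqn{L_C/\xi} between 1e-6 and 1e3 and beyond.
#'
#' @param xi persistence length in nm (> 0)
#' @param L contour length in nm (> 0)
#' @return \eqn{\langle R^2\rangle} in nm^2 (vectorised over both arguments)
#' @examples
#' wlcMSD(50, 170)          # 17653.67 nm^2
#' wlcMSD(1e9, 100) / 100^2 # -> 1 (rigid rod)
#' @export
wlcMSD <- function(xi, L) {
  if (any(!is.finite(xi)) || any(xi <= 0)) stopf("xi must be positive")
  if (any(!is.finite(L)) || any(L <= 0)) stopf("L must be positive")
  n <- max(length(xi), length(L))
  xi <- rep_len(xi, n); L <- rep_len(L, n)
  x <- L / (2 * xi)
  out <- numeric(n)
  small <- x < 1e-3
  # <R^2> = L^2 (1 - x/3 + x^2/12 - x^3/60 + ...) for small x
  if (any(small)) {
    xs <- x[small]
    out[small] <- L[small]^2 * (1 - xs / 3 + xs^2 / 12 - xs^3 / 60)
  }
  if (any(!small)) {
    xl <- x[!small]
    out[!small] <- 4 * xi[!small] * L[!small] * (1 - (-expm1(-xl)) / xl)
  }
  out
}

#' Invert the 2D worm-like-chain relation for the persistence length
#'
#' \code{\link{wlcMSD}} is strictly increasing in \eqn{\xi} at fixed contour
#' length, from 0 (flexible limit) to \eqn{L^2} (rigid rod), so the root is
#' unique. Found by bracketed root-finding on \eqn{\log\xi} to a relative
#' tolerance of 1e-10.
#'
#' @param meanR2 measured mean-square end-to-end distance in nm^2
#'   (0 < meanR2 < L^2)
#' @param L contour length in nm
#' @return persistence length in nm
#' @export
invertMSD <- function(meanR2, L) {
  if (!is.finite(meanR2) || meanR2 <= 0) stopf("meanR2 must be positive")
  if (!is.finite(L) || L <= 0) stopf("L must be positive")
  if (meanR2 >= L^2)
    stopf("non-physical input: meanR2 = %.6g >= L^2 = %.6g (straighter than a rigid rod)",
          meanR2, L^2)
  f <- function(t) wlcMSD(exp(t), L) - meanR2
  lo <- log(1e-8); hi <- log(1e12)
  # expand the bracket if ever needed (extremely flexible / stiff input)
  while (f(lo) > 0) lo <- lo - 5
  while (f(hi) < 0) hi <- hi + 5
  r <- stats::uniroot(f, c(lo, hi), tol = 1e-12)
  exp(r$root)
}

#' Persistence-length error from a contour-length error
#'
#' Holds the mean-square end-to-end distance at its true worm-like-chain value
#' and re-inverts the relation with a mis-measured contour length,
#' \eqn{L_C^* = (1 + \epsilon) L_C}; the steep nonlinearity near the rigid
#' limit makes short molecules exquisitely sensitive (for a 100 bp molecule a
#' -2\% contour error gives roughly +60\% in \eqn{\xi}).
#'
#' @param L true contour length in nm
#' @param xiTrue true persistence length in nm
#' @param relErrors vector of relative contour-length errors (e.g.
#'   \code{-0.02} for a 2\% underestimate)
#' @return data.frame with \code{rel_contour_error}, \code{rel_xi_error}
#'   (NA where the perturbed inversion is non-physical, i.e. the perturbed
#'   length falls below the fixed root-mean-square end-to-end distance)
#' @export
errorPropagationCurve <- function(L, xiTrue, relErrors) {
  stopifnot(L > 0, xiTrue > 0)
  R2 <- wlcMSD(xiTrue, L)
  relXi <- vapply(relErrors, function(e) {
    Lp <- L * (1 + e)
    if (Lp <= 0 || R2 >= Lp^2) return(NA_real_)
    invertMSD(R2, Lp) / xiTrue - 1
  }, numeric(1L))
  data.frame(rel_contour_error = relErrors, rel_xi_error = relXi)
}

#' Cut a trace into non-overlapping equal-arc-length segments
#'
#' Walks the chain code from the trace's first endpoint, accumulating Freeman
#' length; a segment is cut each time the running length first reaches the
#' requested \code{segmentLength}, and the incomplete remainder is discarded.
#' Each segment records its realised arc length (within one chain-code step of
#' the request) and the Euclidean end-to-end distance between its cut pixels.
#'
#' @param trace an accepted \linkS4class{ContourTrace}
#' @param segmentLength requested segment arc length in nm
#' @return data.frame with one row per segment: \code{start_idx},
#'   \code{end_idx} (path indices), \code{length_nm}, \code{R_nm}; zero rows
#'   if the trace is shorter than one segment
#' @export
segmentContour <- function(trace, segmentLength) {
  stopifnot(is(trace, "ContourTrace"))
  if (trace@quality == "rejected") stopf("cannot segment a rejected trace")
  px <- trace@pixelSize
  if (segmentLength < 4 * px)
    stopf("segmentLength must be at least 4 pixels of arc length")
  stepLen <- ifelse(trace@chainCode %% 2L == 1L, sqrt(2), 1) * px
  cum <- cumsum(stepLen)
  start <- 1L; startLen <- 0
  res <- list()
  for (i in seq_along(cum)) {
    if (cum[i] - startLen >= segmentLength - 1e-12) {
      endIdx <- i + 1L
      p1 <- trace@pixelPath[start, ]; p2 <- trace@pixelPath[endIdx, ]
      res[[length(res) + 1L]] <- data.frame(
        start_idx = start, end_idx = endIdx,
        length_nm = cum[i] - startLen,
        R_nm = sqrt(sum((p2 - p1)^2)) * px)
      start <- endIdx; startLen <- cum[i]
    }
  }
  if (!length(res))
    return(data.frame(start_idx = integer(0), end_idx = integer(0),
                      length_nm = numeric(0), R_nm = numeric(0)))
  do.call(rbind, res)
}

# Self-consistent calibrated inversion: find xi* with
#   meanR2 = wlcMSD(xi*, Lbar / f(xi*)),
# by fixed-point iteration from the uncorrected inversion. f depends on the
# measured stiffness itself, so one-shot substitution is not enough; the
# iteration reduces to one shot when f is flat and typically converges in a
# handful of steps.
.calibratedInversion <- function(meanR2, Lbar, model, tol = 1e-8, maxIter = 100L) {
  xi <- invertMSD(meanR2, Lbar)
  trace <- xi
  for (k in seq_len(maxIter)) {
    if (xi <= model@A)
      stopf("calibrated inversion left the validity range (xi* = %.3g <= A = %.3g nm)",
            xi, model@A)
    Lcorr <- Lbar / biasFactor(model, xi)
    if (meanR2 >= Lcorr^2)
      stopf("non-physical after correction: meanR2 >= corrected L^2")
    xiNew <- invertMSD(meanR2, Lcorr)
    done <- abs(xiNew - xi) / xi < tol
    xi <- xiNew
    trace <- c(trace, xi)
    if (done) return(xi)
  }
  stopf("calibrated inversion did not converge in %d iterations (trace: %s)",
        maxIter, paste(sprintf("%.4g", utils::tail(trace, 6L)), collapse = " -> "))
}

#' Estimate the persistence length from pooled trace segments
#'
#' Cuts every accepted trace into non-overlapping segments of the requested
#' arc length, pools the segments across molecules, and inverts the 2D
#' worm-like-chain relation on the pooled mean-square end-to-end distance at
#' the mean realised segment length. With a calibration model, the
#' self-consistent corrected estimate solves
#' \eqn{\langle R^2\rangle = \langle R^2\rangle_{WLC}(\xi^*, \ell^*/f(\xi^*))}
#' by fixed-point iteration. The standard error is a bootstrap over molecules
#' (not segments), respecting within-molecule correlation.
#'
#' @param traces list of \linkS4class{ContourTrace} (rejected ones are
#'   skipped)
#' @param segmentLength requested segment arc length in nm (measured scale)
#' @param model a \linkS4class{CalibrationModel}, or \code{NULL} for the raw
#'   estimate only
#' @param B bootstrap resamples (0 disables the standard error)
#' @param seed optional bootstrap seed
#' @param minSegments minimum pooled segments required
#' @return a \linkS4class{StiffnessEstimate}
#' @export
estimateXi <- function(traces, segmentLength, model = NULL, B = 200L,
                       seed = NULL, minSegments = 10L) {
  if (is(traces, "ContourTrace")) traces <- list(traces)
  ok <- vapply(traces, function(t) t@quality != "rejected", logical(1L))
  traces <- traces[ok]
  segs <- lapply(traces, segmentContour, segmentLength = segmentLength)
  nPer <- vapply(segs, nrow, integer(1L))
  segAll <- do.call(rbind, segs)
  if (is.null(segAll) || nrow(segAll) < minSegments)
    stopf("only %d pooled segments (need >= %d) at segment length %g nm",
          if (is.null(segAll)) 0L else nrow(segAll), minSegments, segmentLength)
  r2s <- lapply(segs, function(s) s$R_nm^2)
  lens <- lapply(segs, function(s) s$length_nm)
  pooled <- function(idx) {
    meanR2 <- mean(unlist(r2s[idx], use.names = FALSE))
    Lbar <- mean(unlist(lens[idx], use.names = FALSE))
    raw <- invertMSD(meanR2, Lbar)
    corr <- if (is.null(model)) NA_real_
            else .calibratedInversion(meanR2, Lbar, model)
    c(meanR2 = meanR2, Lbar = Lbar, raw = raw, corr = corr)
  }
  contrib <- which(nPer > 0L)
  est <- pooled(contrib)
  se <- NA_real_
  if (B > 0L && length(contrib) > 1L) {
    se <- withSeed(seed, {
      boot <- vapply(seq_len(B), function(i) {
        idx <- sample(contrib, replace = TRUE)
        out <- tryCatch(pooled(idx), error = function(e) c(NA, NA, NA, NA))
        if (is.null(model)) out[3L] else out[4L]
      }, numeric(1L))
      stats::sd(boot, na.rm = TRUE)
    })
  }
  new("StiffnessEstimate", segmentLength = segmentLength,
      meanSegmentLength = unname(est["Lbar"]),
      nSegments = nrow(segAll), nMolecules = length(contrib),
      meanR2 = unname(est["meanR2"]), xiRaw = unname(est["raw"]),
      xiCorrected = unname(est["corr"]), se = se)
}

#' Linear trend of stiffness across segment length
#'
#' Ordinary least squares of the (corrected) persistence length on segment
#' length. For a homogeneous worm-like chain the persistence length is scale
#' free, so a slope confidence interval containing zero is reported as
#' WLC-consistent; protein-stiffened DNA shows a scale-dependent trend
#' instead.
#'
#' @param estimates list of \linkS4class{StiffnessEstimate} (>= 3 segment
#'   lengths) or a data.frame from \code{\link{estimatesTable}}
#' @param level confidence level for the slope interval
#' @param useRaw regress the raw instead of the corrected estimates
#' @return list with \code{slope} (nm per nm), \code{intercept} (nm),
#'   \code{ci} (slope confidence interval), \code{wlcConsistent} (logical),
#'   and the underlying \code{fit}
#' @export
trendFit <- function(estimates, level = 0.95, useRaw = FALSE) {
  df <- if (is.data.frame(estimates)) estimates else estimatesTable(estimates)
  if (length(unique(df$segment_length_nm)) < 3L)
    stopf("need >= 3 distinct segment lengths for a trend fit")
  y <- if (useRaw) df$xi_raw_nm else df$xi_corr_nm
  if (all(is.na(y))) stopf("no estimates to fit (all NA)")
  fit <- stats::lm(y ~ df$segment_length_nm)
  ci <- stats::confint(fit, level = level)[2L, ]
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       ci = unname(ci),
       wlcConsistent = ci[1L] <= 0 && ci[2L] >= 0,
       fit = fit)
}
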