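#' Rasterize a chain into a noiseless molecular height field
#'
#' Renders the molecule as a flat-topped ridge: every pixel whose center lies
#' within \code{diameter/2} of the chain backbone gets height \code{diameter}
#' (2 nm for B-DNA), all other pixels are 0. Because the vertex spacing
#' (0.34 nm by default) is much smaller than a pixel, the capsule around the
#' polyline is realised as the union of disks around the vertices; the
#' scalloping error is below 0.02 px. An optional hemicylindrical cross
#' section is available for sensitivity studies.
#'
#' The image extent covers the chain bounding box plus \code{margin} on every
#' side, which must leave room for the subsequent tip dilation.
#'
#' @param chain a \linkS4class{PolymerChain}
#' @param pixelSize nm per pixel (default 1)
#' @param margin margin around the chain bounding box, nm
#' @param profile cross-section model: \code{"flat"} ridge of height
#'   \code{diameter} (default) or \code{"hemicylinder"}
#' @param maxPixels refuse to build images larger than this on a side
#' @return a noiseless \linkS4class{HeightImage}
#' @export
rasterizeChain <- function(chain, pixelSize = 1.0, margin = 8.0,
                           profile = c("flat", "hemicylinder"),
                           maxPixels = 4096L) {
  stopifnot(is(chain, "PolymerChain"), pixelSize > 0, margin >= 0)
  profile <- match.arg(profile)
  v <- chain@vertices
  if (nrow(v) < 1L) stopf("chain has no vertices")
  r <- chain@params@diameter / 2
  ox <- min(v[, 1L]) - margin
  oy <- min(v[, 2L]) - margin
  nc <- floor((max(v[, 1L]) + margin - ox) / pixelSize) + 1L
  nr <- floor((max(v[, 2L]) + margin - oy) / pixelSize) + 1L
  if (nc > maxPixels || nr > maxPixels)
    stopf("chain spans %d x %d px, larger than maxPixels = %d", nr, nc, maxPixels)
  # vertex positions in 0-based pixel-center coordinates
  cx <- (v[, 1L] - ox) / pixelSize
  cy <- (v[, 2L] - oy) / pixelSize
  rpx <- r / pixelSize
  w <- ceiling(rpx)
  off <- expand.grid(dr = -w:w, dc = -w:w)
  n <- length(cx)
  baseR <- round(cy); baseC <- round(cx)
  rows <- rep(baseR, nrow(off)) + rep(off$dr, each = n)
  cols <- rep(baseC, nrow(off)) + rep(off$dc, each = n)
  d2 <- (rows - rep(cy, nrow(off)))^2 + (cols - rep(cx, nrow(off)))^2
  keep <- d2 <= rpx^2 + 1e-12 & rows >= 0 & rows < nr & cols >= 0 & cols < nc
  m <- matrix(0, nr, nc)
  if (any(keep)) {
    idx <- rows[keep] + nr * cols[keep] + 1L   # 1-based linear index
    if (profile == "flat") {
      m[idx] <- chain@params@diameter
    } else {
      h <- (r + sqrt(pmax(0, r^2 - d2[keep] * pixelSize^2)))
      agg <- tapply(h, idx, max)
      m[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  HeightImage(m, pixelSize = pixelSize, noiseSigma = 0, provenance = "simulated")
}

#' Grey-scale dilation of a height image by an AFM tip
#'
#' Simulates tip convolution: the recorded height at x is the highest position
#' at which the tip, centred at x, first touches the sample,
#' \eqn{out(x) = \max_u [h(u) - z(|u - x|)]}, where the structuring function z
#' is the tip drop \eqn{z(r) = R_T - \sqrt{R_T^2 - r^2}} for a spherical cap
#' and 0 (flat max-filter) for a disk. The output is everywhere >= the input.
#'
#' @param img a noiseless molecular \linkS4class{HeightImage}
#' @param tip a \linkS4class{TipModel}
#' @return the dilated \linkS4class{HeightImage}
#' @export
dilateWithTip <- function(img, tip = TipModel()) {
  stopifnot(is(img, "HeightImage"), is(tip, "TipModel"))
  px <- img@pixelSize
  if (tip@radius < px / 2) {
    warning("tip radius smaller than half a pixel: dilation is the identity")
    return(img)
  }
  w <- floor(tip@radius / px + 1e-9)
  off <- expand.grid(dr = -w:w, dc = -w:w)
  rr <- sqrt(off$dr^2 + off$dc^2) * px
  off <- off[rr <= tip@radius + 1e-9, ]
  rr <- rr[rr <= tip@radius + 1e-9]
  drop <- if (tip@profile == "cap") tip@radius - sqrt(tip@radius^2 - rr^2)
          else rep(0, length(rr))
  h <- img@heights
  out <- h                               # offset (0,0) has drop 0
  for (k in seq_len(nrow(off))) {
    if (off$dr[k] == 0L && off$dc[k] == 0L) next
    out <- pmax(out, shiftMatrix(h, -off$dr[k], -off$dc[k], fill = 0) - drop[k])
  }
  HeightImage(out, pixelSize = px, noiseSigma = img@noiseSigma,
              provenance = img@provenance)
}

#' Add i.i.d. Gaussian background noise
#'
#' @param img a \linkS4class{HeightImage}
#' @param sigma noise standard deviation in nm (>= 0)
#' @param seed optional seed for reproducible noise
#' @return the noisy image, with \code{noiseSigma} recorded
#' @export
addNoise <- function(img, sigma, seed = NULL) {
  stopifnot(is(img, "HeightImage"))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stopf("sigma must be a single non-negative number")
  if (sigma == 0) return(img)
  h <- img@heights
  noisy <- h + withSeed(seed, stats::rnorm(length(h), 0, sigma))
  HeightImage(matrix(noisy, nrow(h), ncol(h)), pixelSize = img@pixelSize,
              noiseSigma = sigma, provenance = img@provenance)
}

# Robust foreground mask: pixels well above the background median. Used as a
# default exclusion mask when none is supplied; the molecule occupies a small
# fraction of the image so median/MAD of all pixels estimate the background.
backgroundMask <- function(img, k = 3) {
  h <- img@heights
  s <- stats::mad(h)
  if (s == 0) s <- stats::sd(h)
  h <= stats::median(h) + k * s
}

#' Estimate the background noise level of an image
#'
#' Robust scale estimate (median absolute deviation x 1.4826) of the
#' DNA-free background pixels, mirroring how the noise statistics of
#' measured scans are extracted from areas free of molecules. Invariant to a
#' constant height offset.
#'
#' @param img a \linkS4class{HeightImage}
#' @param exclusionMask logical matrix marking foreground (molecule) pixels to
#'   exclude; \code{NULL} (default) excludes pixels far above the background
#'   median
#' @param minBackground minimum number of background pixels required
#' @return estimated sigma in nm
#' @export
estimateNoise <- function(img, exclusionMask = NULL, minBackground = 1000L) {
  stopifnot(is(img, "HeightImage"))
  bg <- if (is.null(exclusionMask)) backgroundMask(img) else !exclusionMask
  if (sum(bg) < minBackground)
    stopf("only %d background pixels (need >= %d) to estimate noise",
          sum(bg), minBackground)
  stats::mad(img@heights[bg])
}

#' Remove the background plane of an image
#'
#' Fits a least-squares plane a + b*x + c*y to the background (non-excluded)
#' pixels and subtracts it everywhere, the standard slope removal applied to
#' raw AFM scans before analysis. After flattening, the background mean is
#' ~0.
#'
#' @param img a \linkS4class{HeightImage}
#' @param exclusionMask logical matrix marking molecule pixels to exclude from
#'   the fit; \code{NULL} uses a robust default (see
#'   \code{\link{estimateNoise}})
#' @return the flattened \linkS4class{HeightImage}
#' @export
flattenImage <- function(img, exclusionMask = NULL) {
  stopifnot(is(img, "HeightImage"))
  h <- img@heights
  nr <- nrow(h); nc <- ncol(h)
  px <- img@pixelSize
  xs <- rep((seq_len(nc) - 1) * px, each = nr)
  ys <- rep((seq_len(nr) - 1) * px, times = nc)
  fitPlane <- function(hcur, bg) {
    if (!any(bg)) stopf("all pixels excluded: cannot fit background plane")
    fit <- stats::lm.fit(cbind(1, xs[bg], ys[bg]), hcur[bg])
    matrix(cbind(1, xs, ys) %*% fit$coefficients, nr, nc)
  }
  if (is.null(exclusionMask)) {
    # With a strong slope the robust mask is dominated by the plane itself,
    # so fit, subtract, re-mask on the flattened image and refit.
    out <- h
    for (i in 1:2) {
      bg <- backgroundMask(HeightImage(out, pixelSize = px))
      out <- out - fitPlane(out, bg)
    }
    h <- out
  } else {
    h <- h - fitPlane(h, !exclusionMask)
  }
  HeightImage(h, pixelSize = px, noiseSigma = img@noiseSigma,
              provenance = img@provenance)
}

#' Write / read height images (float TIFF or plain-text matrix)
#'
#' Images travel as single-channel 32-bit float TIFF (heights in nm) or as a
#' whitespace-delimited plain-text matrix, with a JSON sidecar
#' (\code{<path>.json}) carrying \code{pixel_size_nm}, \code{noise_sigma_nm}
#' and \code{provenance}. On read, a missing sidecar falls back to the
#' \code{pixelSize} argument and \code{provenance = "measured"}.
#'
#' @param img a \linkS4class{HeightImage}
#' @param path file path; extension \code{.tif}/\code{.tiff} selects TIFF,
#'   anything else the text format
#' @return \code{writeHeightImage} returns \code{path} invisibly;
#'   \code{readHeightImage} returns a \linkS4class{HeightImage}
#' @export
writeHeightImage <- function(img, path) {
  stopifnot(is(img, "HeightImage"))
  meta <- list(pixel_size_nm = img@pixelSize, noise_sigma_nm = img@noiseSigma,
               provenance = img@provenance)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    # TIFF samples are stored normalised to [0, 1]; the affine height scale
    # travels in the sidecar so the round trip is exact in nm.
    h <- img@heights
    off <- min(h); sc <- max(h) - off
    if (sc == 0) sc <- 1
    tiff::writeTIFF((h - off) / sc, path, bits.per.sample = 32L, reduce = FALSE)
    meta$height_offset_nm <- off
    meta$height_scale_nm <- sc
  } else {
    utils::write.table(img@heights, path, row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeHeightImage
#' @param pixelSize fallback nm/px when no sidecar is present
#' @export
readHeightImage <- function(path, pixelSize = 1.0) {
  h <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    m
  } else {
    as.matrix(utils::read.table(path))
  }
  dimnames(h) <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$height_scale_nm))
      h <- h * meta$height_scale_nm + (meta$height_offset_nm %||% 0)
    HeightImage(h, pixelSize = meta$pixel_size_nm,
                noiseSigma = meta$noise_sigma_nm %||% 0,
                provenance = meta$provenance %||% "measured")
  } else {
    HeightImage(h, pixelSize = pixelSize, noiseSigma = 0,
                provenance = "measured")
  }
}
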