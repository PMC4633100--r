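# Freeman 8-connectivity codes: 0 = E, then counter-clockwise. In image
# coordinates (row down, col right): code k moves by (dr, dc) below. Even
# codes are axial (length 1 px), odd codes diagonal (sqrt(2) px).
.freemanDr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
.freemanDc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)

#' Tracing configuration
#'
#' Bundles the tunable knobs of the tracing pipeline. The calibration
#' constants (A, C) are only meaningful for a frozen configuration, so the
#' config carries a deterministic hash used to tag calibration models.
#'
#' @param thresholdK binarisation threshold in units of the background noise
#'   sigma above the background median (default 3)
#' @param sigma noise sigma override in nm; \code{NULL} = estimate per image
#' @param spurPx prune skeleton spurs up to this many pixels (default 3)
#' @param minLengthPx reject accepted paths shorter than this many pixels
#' @param flatten remove the background plane before thresholding
#' @param repairGapPx optional repair hook: merge two trace fragments whose
#'   endpoints are within this many pixels (0 = off, the default; replaces
#'   interactive repair with a deterministic rule)
#' @return a list of class \code{traceConfig}
#' @export
traceConfig <- function(thresholdK = 3, sigma = NULL, spurPx = 3L,
                        minLengthPx = 10L, flatten = TRUE, repairGapPx = 0L) {
  cfg <- list(thresholdK = thresholdK, sigma = sigma, spurPx = as.integer(spurPx),
              minLengthPx = as.integer(minLengthPx), flatten = isTRUE(flatten),
              repairGapPx = as.integer(repairGapPx))
  class(cfg) <- "traceConfig"
  cfg
}

#' Deterministic identifier of a tracer/imager configuration
#'
#' @param cfg a \code{\link{traceConfig}}
#' @param pixelSize nm/px the images are analysed at
#' @param extra optional named list folded into the hash (e.g. tip model)
#' @return a character scalar
#' @export
configHash <- function(cfg, pixelSize = 1.0, extra = NULL) {
  stopifnot(inherits(cfg, "traceConfig"))
  parts <- c(sprintf("k=%g", cfg$thresholdK),
             sprintf("sigma=%s", if (is.null(cfg$sigma)) "auto" else format(cfg$sigma)),
             sprintf("spur=%d", cfg$spurPx), sprintf("min=%d", cfg$minLengthPx),
             sprintf("flatten=%d", as.integer(cfg$flatten)),
             sprintf("repair=%d", cfg$repairGapPx),
             sprintf("px=%g", pixelSize))
  if (!is.null(extra))
    parts <- c(parts, vapply(names(extra),
                             function(n) sprintf("%s=%s", n, format(extra[[n]])),
                             character(1L)))
  paste(parts, collapse = ";")
}

#' Threshold an image into a binary molecule map
#'
#' A pixel is foreground iff its height exceeds the background median by
#' \code{thresholdK} times the background noise sigma (estimated robustly when
#' not supplied).
#'
#' @param img a flattened \linkS4class{HeightImage}
#' @param cfg a \code{\link{traceConfig}}
#' @return logical matrix (TRUE = molecule); attribute \code{"threshold"}
#'   records the height cutoff in nm
#' @export
binarizeImage <- function(img, cfg = traceConfig()) {
  stopifnot(is(img, "HeightImage"), inherits(cfg, "traceConfig"))
  h <- img@heights
  s <- cfg$sigma
  if (is.null(s)) s <- if (img@noiseSigma > 0) img@noiseSigma else estimateNoise(img)
  thr <- stats::median(h) + cfg$thresholdK * s
  mask <- h > thr
  attr(mask, "threshold") <- thr
  mask
}

# number of 8-neighbors of each TRUE pixel
.neighborCount <- function(m) {
  s <- matrix(0L, nrow(m), ncol(m))
  for (k in 1:8)
    s <- s + shiftMatrix(m, .freemanDr[k], .freemanDc[k], fill = FALSE)
  s
}

#' Thin a binary map to a single-pixel skeleton
#'
#' Classical two-subiteration (Zhang-Suen) thinning: border pixels are
#' iteratively removed without breaking 8-connectivity until no further pixel
#' can be deleted, leaving a one-pixel-wide, connectivity-preserving skeleton.
#' A final corner clean-up removes redundant pixels whose two neighbours are
#' themselves adjacent, so that every interior skeleton pixel has an
#' unambiguous predecessor and successor.
#'
#' @param mask logical matrix
#' @return logical skeleton matrix
#' @export
thinBinary <- function(mask) {
  stopifnot(is.logical(mask))
  if (!any(mask)) return(mask)
  # operate on the foreground bounding box (plus a 1-px guard) for speed
  rows <- range(which(rowSums(mask) > 0L))
  cols <- range(which(colSums(mask) > 0L))
  r0 <- max(1L, rows[1L] - 1L); r1 <- min(nrow(mask), rows[2L] + 1L)
  c0 <- max(1L, cols[1L] - 1L); c1 <- min(ncol(mask), cols[2L] + 1L)
  m <- mask[r0:r1, c0:c1, drop = FALSE]
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- vector("list", 8L)
      for (k in 1:8) nb[[k]] <- shiftMatrix(m, .freemanDr[k], .freemanDc[k], fill = FALSE)
      # Zhang-Suen ordering: P2..P9 = N, NE, E, SE, S, SW, W, NW
      P <- nb[c(3L, 2L, 1L, 8L, 7L, 6L, 5L, 4L)]
      B <- Reduce(`+`, P)
      A <- matrix(0L, nrow(m), ncol(m))
      for (k in 1:8) {
        nxt <- if (k == 8L) P[[1L]] else P[[k + 1L]]
        A <- A + (!P[[k]] & nxt)
      }
      cond <- m & B >= 2L & B <= 6L & A == 1L
      if (sub == 1L) {
        cond <- cond & !(P[[1L]] & P[[3L]] & P[[5L]]) & !(P[[3L]] & P[[5L]] & P[[7L]])
      } else {
        cond <- cond & !(P[[1L]] & P[[3L]] & P[[7L]]) & !(P[[1L]] & P[[5L]] & P[[7L]])
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m <- .cleanCorners(m)
  out <- mask & FALSE
  out[r0:r1, c0:c1] <- m
  out
}

# Remove redundant skeleton pixels left by the thinning (thick staircase
# corners): a non-endpoint pixel is deleted when its occupied neighbours stay
# mutually 8-connected without it, so removal cannot break the curve.
# Processed sequentially in a fixed order for determinism.
.cleanCorners <- function(m) {
  repeat {
    nc2 <- .neighborCount(m)
    cand <- which(m & nc2 >= 2L)
    if (!length(cand)) break
    removed <- FALSE
    nr <- nrow(m)
    for (i in cand) {
      if (!m[i]) next
      r <- (i - 1L) %% nr + 1L; c <- (i - 1L) %/% nr + 1L
      nbr <- .neighborsOf(m, r, c)
      if (nrow(nbr) >= 2L && .mutuallyConnected(nbr)) {
        m[r, c] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  m
}

# Are the given pixels a single 8-connected cluster (ignoring the removed
# center)? At most 8 points, so a tiny reachability iteration suffices.
.mutuallyConnected <- function(pts) {
  n <- nrow(pts)
  if (n <= 1L) return(TRUE)
  dr <- pts[, 1L]; dc <- pts[, 2L]
  adj <- pmax(abs(outer(dr, dr, "-")), abs(outer(dc, dc, "-"))) == 1L
  seen <- c(TRUE, rep(FALSE, n - 1L))
  repeat {
    nxt <- (colSums(adj[seen, , drop = FALSE]) > 0L) & !seen
    if (!any(nxt)) break
    seen <- seen | nxt
  }
  all(seen)
}

# coordinates of TRUE 8-neighbors of (r, c)
.neighborsOf <- function(m, r, c) {
  rs <- r + .freemanDr; cs <- c + .freemanDc
  ok <- rs >= 1L & rs <= nrow(m) & cs >= 1L & cs <= ncol(m)
  rs <- rs[ok]; cs <- cs[ok]
  hit <- m[cbind(rs, cs)]
  cbind(row = rs[hit], col = cs[hit])
}

#' Label connected components of a binary map
#'
#' 8-connectivity component labelling via a pixel-adjacency graph.
#'
#' @param mask logical matrix
#' @return integer matrix of component labels (0 = background)
#' @export
labelComponents <- function(mask) {
  stopifnot(is.logical(mask))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  pix <- which(mask)
  if (!length(pix)) return(lab)
  nr <- nrow(mask)
  id <- match(pix, pix)                  # 1..n in order of linear index
  edges <- integer(0)
  for (k in c(1L, 2L, 3L, 8L)) {         # E, NE, N, SE: each pair once
    dr <- .freemanDr[k]; dc <- .freemanDc[k]
    sh <- shiftMatrix(mask, -dr, -dc, fill = FALSE)   # neighbor present?
    both <- which(mask & sh)
    if (!length(both)) next
    nbLin <- both + dr + nr * dc
    a <- match(both, pix); b <- match(nbLin, pix)
    ok <- !is.na(b)
    edges <- c(edges, rbind(a[ok], b[ok]))
  }
  g <- igraph::make_graph(edges, n = length(pix), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[pix] <- as.integer(comp)
  lab
}

#' Estimate the length of a digital curve from its chain code
#'
#' The Freeman estimator: axial moves count one pixel, diagonal moves
#' \eqn{\sqrt{2}} pixels, which equals the Euclidean length of the polyline
#' through the pixel centers exactly.
#'
#' @param code integer vector of 8-connectivity codes (0-7)
#' @param pixelSize nm per pixel
#' @return length in nm
#' @examples
#' freemanLength(c(0, 0, 0, 0))          # 4 axial moves -> 4 nm
#' freemanLength(c(1, 3, 5))             # 3 diagonal moves -> 3*sqrt(2) nm
#' @export
freemanLength <- function(code, pixelSize = 1.0) {
  if (length(code) == 0L) return(0)
  code <- as.integer(code)
  if (any(is.na(code)) || any(code < 0L | code > 7L))
    stopf("invalid chain-code symbol: codes must lie in 0..7")
  nOdd <- sum(code %% 2L == 1L)
  (length(code) - nOdd + nOdd * sqrt(2)) * pixelSize
}

# chain code of an ordered 8-connected pixel path
.chainCodeOf <- function(path) {
  if (nrow(path) < 2L) return(integer(0))
  dr <- diff(path[, 1L]); dc <- diff(path[, 2L])
  code <- match(paste(dr, dc), paste(.freemanDr, .freemanDc)) - 1L
  if (any(is.na(code))) stopf("path pixels are not 8-connected")
  as.integer(code)
}

# Walk an ordered path through a clean (spur-free, corner-free) skeleton
# component, starting at `start`. Returns the ordered pixel matrix or NULL if
# the walk is ambiguous / does not cover the component.
.walkPath <- function(m, start, nPixels) {
  path <- matrix(0L, nPixels, 2L)
  path[1L, ] <- start
  visited <- matrix(FALSE, nrow(m), ncol(m))
  visited[start[1L], start[2L]] <- TRUE
  cur <- start
  for (i in seq_len(nPixels - 1L)) {
    nbr <- .neighborsOf(m, cur[1L], cur[2L])
    nbr <- nbr[!visited[nbr], , drop = FALSE]
    if (nrow(nbr) == 0L) return(NULL)
    if (nrow(nbr) > 1L) {
      # prefer an axial continuation; any residual tie means ambiguity
      ax <- (nbr[, 1L] == cur[1L]) | (nbr[, 2L] == cur[2L])
      if (sum(ax) == 1L) nbr <- nbr[ax, , drop = FALSE]
      else return(NULL)
    }
    cur <- nbr[1L, ]
    visited[cur[1L], cur[2L]] <- TRUE
    path[i + 1L, ] <- cur
  }
  colnames(path) <- c("row", "col")
  path
}

#' Extract ordered single-pixel contours from a skeleton
#'
#' Each connected skeleton component becomes one \linkS4class{ContourTrace}:
#' components with exactly two endpoints (degree-1 pixels) and no branch
#' pixels after pruning short spurs are accepted and ordered from their
#' lexicographically smallest endpoint; components touching the image border,
#' closed loops, and irreducibly branched components are marked rejected with
#' a reason (mirroring the deletion of bad traces in manual workflows, but
#' deterministic).
#'
#' @param skeleton logical skeleton matrix (from \code{\link{thinBinary}})
#' @param cfg a \code{\link{traceConfig}} (spur and minimum-length limits)
#' @param pixelSize nm per pixel, for the Freeman length
#' @param imageId identifier recorded on each trace
#' @return list of \linkS4class{ContourTrace}
#' @export
extractPaths <- function(skeleton, cfg = traceConfig(), pixelSize = 1.0,
                         imageId = "image") {
  stopifnot(is.logical(skeleton))
  lab <- labelComponents(skeleton)
  nComp <- max(lab)
  out <- vector("list", nComp)
  nr <- nrow(skeleton); ncl <- ncol(skeleton)
  for (ci in seq_len(nComp)) {
    pix <- which(lab == ci)
    rows <- (pix - 1L) %% nr + 1L; cols <- (pix - 1L) %/% nr + 1L
    comp <- matrix(FALSE, nr, ncl); comp[pix] <- TRUE
    reject <- function(reason) new("ContourTrace",
      pixelPath = cbind(row = rows, col = cols), chainCode = integer(0),
      lengthEstimate = NA_real_, pixelSize = pixelSize,
      sourceImageId = imageId, quality = "rejected", note = reason)
    if (any(rows <= 1L | rows >= nr | cols <= 1L | cols >= ncl)) {
      out[[ci]] <- reject("border"); next
    }
    comp <- .pruneSpurs(comp, cfg$spurPx)
    npix <- sum(comp)
    if (npix < 2L) { out[[ci]] <- reject("short"); next }
    deg <- .neighborCount(comp); deg[!comp] <- 0L
    ends <- which(comp & deg == 1L)
    if (length(ends) == 0L) { out[[ci]] <- reject("loop"); next }
    if (any(deg[comp] > 2L) || length(ends) != 2L) {
      out[[ci]] <- reject("branched"); next
    }
    if (npix < cfg$minLengthPx) { out[[ci]] <- reject("short"); next }
    er <- (ends - 1L) %% nr + 1L; ec <- (ends - 1L) %/% nr + 1L
    ord <- order(er, ec)
    start <- c(er[ord[1L]], ec[ord[1L]])
    path <- .walkPath(comp, start, npix)
    if (is.null(path)) { out[[ci]] <- reject("ambiguous"); next }
    code <- .chainCodeOf(path)
    out[[ci]] <- new("ContourTrace", pixelPath = path, chainCode = code,
                     lengthEstimate = freemanLength(code, pixelSize),
                     pixelSize = pixelSize, sourceImageId = imageId,
                     quality = "clean", note = "")
  }
  out
}

# Remove dangling branches of up to `spurPx` pixels: walk from each endpoint;
# if a junction (degree >= 3) is reached within the limit, delete the walked
# pixels. Repeated until stable; the main two ends of an open contour survive
# because they never reach a junction.
.pruneSpurs <- function(comp, spurPx) {
  if (spurPx < 1L) return(comp)
  for (iter in 1:10) {
    deg <- .neighborCount(comp); deg[!comp] <- 0L
    if (!any(deg[comp] > 2L)) break
    nr <- nrow(comp)
    ends <- which(comp & deg == 1L)
    if (!length(ends)) break
    toDrop <- integer(0)
    for (e in ends) {
      walk <- integer(0)
      cur <- c((e - 1L) %% nr + 1L, (e - 1L) %/% nr + 1L)
      prev <- c(NA_integer_, NA_integer_)
      hitJunction <- FALSE
      for (s in seq_len(spurPx)) {
        lin <- cur[1L] + nr * (cur[2L] - 1L)
        if (deg[lin] >= 3L) { hitJunction <- TRUE; break }
        walk <- c(walk, lin)
        nbr <- .neighborsOf(comp, cur[1L], cur[2L])
        nbr <- nbr[!(nbr[, 1L] == prev[1L] & nbr[, 2L] == prev[2L]) |
                     is.na(prev[1L]), , drop = FALSE]
        if (nrow(nbr) != 1L) break
        prev <- cur; cur <- nbr[1L, ]
      }
      if (!hitJunction) {
        lin <- cur[1L] + nr * (cur[2L] - 1L)
        if (deg[lin] >= 3L) hitJunction <- TRUE
      }
      if (hitJunction) toDrop <- c(toDrop, walk)
    }
    if (!length(toDrop)) break
    comp[toDrop] <- FALSE
    comp <- .cleanCorners(comp)
  }
  comp
}

# Optional deterministic repair: merge exactly two accepted fragments whose
# closest endpoints are within `repairGapPx`, bridging them with a straight
# run of pixels. Replaces interactive trace fixing with a reproducible rule.
.repairTraces <- function(traces, gapPx, pixelSize, imageId) {
  acc <- which(vapply(traces, function(t) t@quality == "clean", logical(1L)))
  if (length(acc) != 2L) return(traces)
  t1 <- traces[[acc[1L]]]; t2 <- traces[[acc[2L]]]
  e1 <- rbind(t1@pixelPath[1L, ], t1@pixelPath[nrow(t1@pixelPath), ])
  e2 <- rbind(t2@pixelPath[1L, ], t2@pixelPath[nrow(t2@pixelPath), ])
  d <- outer(seq_len(2L), seq_len(2L),
             Vectorize(function(i, j) max(abs(e1[i, ] - e2[j, ]))))
  if (min(d) > gapPx) return(traces)
  best <- which(d == min(d), arr.ind = TRUE)[1L, ]
  p1 <- if (best[1L] == 1L) t1@pixelPath[rev(seq_len(nrow(t1@pixelPath))), ] else t1@pixelPath
  p2 <- if (best[2L] == 1L) t2@pixelPath else t2@pixelPath[rev(seq_len(nrow(t2@pixelPath))), ]
  a <- p1[nrow(p1), ]; b <- p2[1L, ]
  nfill <- max(abs(b - a)) - 1L
  bridge <- if (nfill > 0L)
    cbind(round(seq(a[1L], b[1L], length.out = nfill + 2L))[-c(1L, nfill + 2L)],
          round(seq(a[2L], b[2L], length.out = nfill + 2L))[-c(1L, nfill + 2L)])
  else NULL
  path <- rbind(p1, bridge, p2)
  colnames(path) <- c("row", "col")
  code <- .chainCodeOf(path)
  merged <- new("ContourTrace", pixelPath = path, chainCode = code,
                lengthEstimate = freemanLength(code, pixelSize),
                pixelSize = pixelSize, sourceImageId = imageId,
                quality = "repaired", note = "merged 2 fragments")
  c(traces[-acc], list(merged))
}

#' Trace all molecules in a height image
#'
#' The full tracing pipeline: optional plane flattening, noise-scaled
#' thresholding, connectivity-preserving thinning, ordered path extraction
#' with spur pruning and deterministic rejection, and Freeman length
#' estimation. Returns every trace (accepted and rejected); the
#' \code{"log"} attribute summarises rejection counts for the image.
#'
#' @param img a \linkS4class{HeightImage}
#' @param cfg a \code{\link{traceConfig}}
#' @param imageId identifier recorded on each trace
#' @return list of \linkS4class{ContourTrace} with attribute \code{"log"}
#' @export
traceImage <- function(img, cfg = traceConfig(), imageId = "image") {
  stopifnot(is(img, "HeightImage"), inherits(cfg, "traceConfig"))
  if (cfg$flatten) img <- flattenImage(img)
  mask <- binarizeImage(img, cfg)
  if (!any(mask)) {
    out <- list()
    attr(out, "log") <- data.frame(image_id = imageId, n_components = 0L,
                                   n_clean = 0L, n_repaired = 0L, n_rejected = 0L)
    return(out)
  }
  skel <- thinBinary(mask)
  traces <- extractPaths(skel, cfg, pixelSize = img@pixelSize, imageId = imageId)
  if (cfg$repairGapPx > 0L)
    traces <- .repairTraces(traces, cfg$repairGapPx, img@pixelSize, imageId)
  q <- vapply(traces, quality, character(1L))
  attr(traces, "log") <- data.frame(image_id = imageId,
                                    n_components = length(traces),
                                    n_clean = sum(q == "clean"),
                                    n_repaired = sum(q == "repaired"),
                                    n_rejected = sum(q == "rejected"))
  traces
}

#' Export / import traces as CSV
#'
#' One row per path pixel (\code{trace_id, image_id, vertex, row, col}) plus a
#' JSON summary (\code{length_nm, quality, pixel_size_nm}) per trace at
#' \code{paste0(csvPath, ".json")}.
#'
#' @param traces list of \linkS4class{ContourTrace}
#' @param csvPath output path
#' @return \code{writeTraces} returns \code{csvPath} invisibly;
#'   \code{readTraces} a list of \linkS4class{ContourTrace}
#' @export
writeTraces <- function(traces, csvPath) {
  rows <- do.call(rbind, lapply(seq_along(traces), function(i) {
    t <- traces[[i]]
    data.frame(trace_id = i, image_id = t@sourceImageId,
               vertex = seq_len(nrow(t@pixelPath)),
               row = t@pixelPath[, 1L], col = t@pixelPath[, 2L])
  }))
  utils::write.csv(rows, csvPath, row.names = FALSE)
  meta <- lapply(traces, function(t)
    list(length_nm = t@lengthEstimate, quality = t@quality,
         pixel_size_nm = t@pixelSize, note = t@note))
  jsonlite::write_json(meta, paste0(csvPath, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(csvPath)
}

#' @rdname writeTraces
#' @export
readTraces <- function(csvPath) {
  rows <- utils::read.csv(csvPath)
  meta <- jsonlite::read_json(paste0(csvPath, ".json"), simplifyVector = FALSE)
  lapply(seq_along(meta), function(i) {
    df <- rows[rows$trace_id == i, ]
    df <- df[order(df$vertex), ]
    path <- cbind(row = df$row, col = df$col)
    q <- meta[[i]]$quality
    code <- if (q == "rejected") integer(0) else .chainCodeOf(path)
    len <- meta[[i]]$length_nm
    new("ContourTrace", pixelPath = path, chainCode = code,
        lengthEstimate = if (is.null(len)) NA_real_ else as.numeric(len),
        pixelSize = meta[[i]]$pixel_size_nm,
        sourceImageId = df$image_id[1L], quality = q,
        note = meta[[i]]$note %||% "")
  })
}
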