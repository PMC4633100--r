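#' Draw bend angles of a 2D worm-like chain
#'
#' In two dimensions the equilibrium bend angle of a worm-like chain over an
#' arc length \code{l} is Gaussian with mean zero and variance \code{l / xi}.
#' For \code{xi >> l} the weight beyond +/- pi is negligible, so the draw is a
#' plain (unwrapped) normal deviate.
#'
#' @param xi persistence length in nm (> 0)
#' @param l arc length over which the bend occurs, nm (> 0)
#' @param n number of draws
#' @return numeric vector of \code{n} angles in radians
#' @examples
#' set.seed(1)
#' var(sampleBendAngle(50, 0.34, 1e5))  # ~ 0.34/50 = 0.0068
#' @export
sampleBendAngle <- function(xi, l, n = 1L) {
  if (!is.numeric(xi) || length(xi) != 1L || !is.finite(xi) || xi <= 0)
    stopf("xi must be a single positive number (got %s)", format(xi))
  if (!is.numeric(l) || length(l) != 1L || !is.finite(l) || l <= 0)
    stopf("l must be a single positive number (got %s)", format(l))
  stats::rnorm(n, mean = 0, sd = sqrt(l / xi))
}

#' Generate one 2D worm-like chain
#'
#' Monte-Carlo growth of an equilibrium chain: the first vertex sits at the
#' origin, the initial heading is drawn uniformly on [0, 2*pi) (or fixed via
#' \code{initialHeading}), and each of the \code{nSteps} steps rotates the
#' heading by an independent Gaussian bend angle of variance
#' \code{stepLength / persistenceLength} before advancing one step length.
#' Excluded volume is not enforced; chains may self-cross (see
#' \code{\link{isSelfCrossing}}).
#'
#' @param params a \linkS4class{WLCParams}; if its \code{seed} slot is set the
#'   chain is drawn from that substream (reproducibly), otherwise from the
#'   current RNG stream
#' @param initialHeading fixed initial heading in radians, or \code{NULL}
#'   (default) for a uniform random heading
#' @return a \linkS4class{PolymerChain}
#' @examples
#' ch <- generateChain(WLCParams(50, 500, seed = 1))
#' contourLength(ch)
#' @export
generateChain <- function(params, initialHeading = NULL) {
  stopifnot(is(params, "WLCParams"))
  validObject(params)
  seed <- if (is.na(params@seed)) NULL else params@seed
  withSeed(seed, {
    theta0 <- if (is.null(initialHeading)) stats::runif(1L, 0, 2 * pi)
              else as.numeric(initialHeading)
    bends <- sampleBendAngle(params@persistenceLength, params@stepLength,
                             params@nSteps)
    heading <- theta0 + cumsum(bends)
    d <- params@stepLength
    v <- rbind(c(0, 0),
               cbind(cumsum(d * cos(heading)), cumsum(d * sin(heading))))
    colnames(v) <- c("x", "y")
    new("PolymerChain", vertices = v, params = params)
  })
}

#' Generate a reproducible ensemble of chains
#'
#' One master seed spawns independent per-chain substreams, so the ensemble is
#' reproducible as a whole while individual molecules stay statistically
#' independent.
#'
#' @param n number of chains
#' @param persistenceLength,nSteps,stepLength,diameter shared chain parameters
#'   (see \linkS4class{WLCParams})
#' @param seed master seed (\code{NULL} = current stream)
#' @param initialHeading passed to \code{\link{generateChain}}
#' @return list of \linkS4class{PolymerChain}
#' @export
generateEnsemble <- function(n, persistenceLength, nSteps, stepLength = 0.34,
                             diameter = 2.0, seed = NULL, initialHeading = NULL) {
  stopifnot(n >= 1L)
  seeds <- withSeed(seed, spawnSeeds(n))
  lapply(seeds, function(s)
    generateChain(WLCParams(persistenceLength, nSteps, stepLength, diameter,
                            seed = s),
                  initialHeading = initialHeading))
}

#' Squared end-to-end distance of a chain
#'
#' @param chain a \linkS4class{PolymerChain}
#' @return \eqn{R^2} in nm^2
#' @export
endToEndSquared <- function(chain) {
  v <- chain@vertices
  sum((v[nrow(v), ] - v[1L, ])^2)
}

#' Does a chain cross itself?
#'
#' Exact segment-pair intersection test over all non-adjacent step pairs.
#' Ideal worm-like chains carry no excluded volume, so soft chains routinely
#' self-cross; the flag lets the tracer's handling of such molecules be
#' studied (self-crossing molecules typically skeletonise into branched or
#' looped components and are rejected).
#'
#' @param chain a \linkS4class{PolymerChain}
#' @return logical
#' @export
isSelfCrossing <- function(chain) {
  v <- chain@vertices
  n <- nrow(v) - 1L                      # number of segments
  if (n < 3L) return(FALSE)
  p <- v[seq_len(n), , drop = FALSE]
  q <- v[seq_len(n) + 1L, , drop = FALSE]
  idx <- which(outer(seq_len(n), seq_len(n), function(i, j) j > i + 1L),
               arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  d1x <- q[i, 1L] - p[i, 1L]; d1y <- q[i, 2L] - p[i, 2L]
  d2x <- q[j, 1L] - p[j, 1L]; d2y <- q[j, 2L] - p[j, 2L]
  o1 <- cross2(d1x, d1y, p[j, 1L] - p[i, 1L], p[j, 2L] - p[i, 2L])
  o2 <- cross2(d1x, d1y, q[j, 1L] - p[i, 1L], q[j, 2L] - p[i, 2L])
  o3 <- cross2(d2x, d2y, p[i, 1L] - p[j, 1L], p[i, 2L] - p[j, 2L])
  o4 <- cross2(d2x, d2y, q[i, 1L] - p[j, 1L], q[i, 2L] - p[j, 2L])
  any(o1 * o2 < 0 & o3 * o4 < 0)
}

#' Write / read chain ensembles as CSV + JSON sidecar
#'
#' The ground-truth interchange format: one CSV row per vertex
#' (\code{chain_id, vertex_index, x_nm, y_nm}) plus a JSON sidecar carrying the
#' shared simulation parameters and per-chain seeds.
#'
#' @param chains list of \linkS4class{PolymerChain}
#' @param csvPath output CSV path; the sidecar goes to
#'   \code{paste0(csvPath, ".json")}
#' @return \code{writeChainEnsemble} returns \code{csvPath} invisibly;
#'   \code{readChainEnsemble} returns a list of \linkS4class{PolymerChain}
#' @export
writeChainEnsemble <- function(chains, csvPath) {
  stopifnot(length(chains) >= 1L)
  rows <- do.call(rbind, lapply(seq_along(chains), function(i) {
    v <- chains[[i]]@vertices
    data.frame(chain_id = i, vertex_index = seq_len(nrow(v)) - 1L,
               x_nm = v[, 1L], y_nm = v[, 2L])
  }))
  utils::write.csv(rows, csvPath, row.names = FALSE)
  p <- chains[[1L]]@params
  meta <- list(persistence_length_nm = p@persistenceLength,
               step_length_nm = p@stepLength, n_steps = p@nSteps,
               diameter_nm = p@diameter, n_chains = length(chains),
               seeds = vapply(chains, function(ch) ch@params@seed, integer(1L)))
  jsonlite::write_json(meta, paste0(csvPath, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(csvPath)
}

#' @rdname writeChainEnsemble
#' @export
readChainEnsemble <- function(csvPath) {
  rows <- utils::read.csv(csvPath)
  meta <- jsonlite::read_json(paste0(csvPath, ".json"), simplifyVector = TRUE)
  lapply(split(rows, rows$chain_id), function(df) {
    df <- df[order(df$vertex_index), ]
    v <- cbind(x = df$x_nm, y = df$y_nm)
    id <- df$chain_id[1L]
    params <- WLCParams(meta$persistence_length_nm, meta$n_steps,
                        meta$step_length_nm, meta$diameter_nm,
                        seed = meta$seeds[id])
    new("PolymerChain", vertices = v, params = params)
  })
}
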