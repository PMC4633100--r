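# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Runs \code{code} with the global random-number stream set from \code{seed},
#' restoring the caller's stream afterwards. With \code{seed = NULL} the code
#' runs on the current stream.
#' @noRd
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# One master seed spawns per-molecule substream seeds, so ensembles are
# reproducible while individual molecules stay independent.
spawnSeeds <- function(n) sample.int(2147483646L, n, replace = FALSE)

# Zero-padded matrix shift: moves content by (dr, dc), vacated cells get `fill`.
shiftMatrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
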