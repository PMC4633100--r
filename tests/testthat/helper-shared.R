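# Shared fixtures, built once per test run and memoised. Seeds are fixed so
# every stochastic check is reproducible. Problem sizes: the calibration uses
# the package default of 500 molecules per grid condition; the analysis set
# uses 400 molecules, matching the experimental throughput the method is
# designed around.

.shared <- new.env(parent = emptyenv())

# a rigid, axis-aligned rod chain of given contour length (nm)
rodChain <- function(lengthNm, stepLength = 0.34) {
  n <- round(lengthNm / stepLength)
  generateChain(WLCParams(1e12, n, stepLength, seed = 1L), initialHeading = 0)
}

# straight synthetic trace along a row: nPix pixels, axial moves only
straightTrace <- function(nPix, pixelSize = 1) {
  path <- cbind(row = rep(10L, nPix), col = seq_len(nPix) + 4L)
  code <- rep(0L, nPix - 1L)
  new("ContourTrace", pixelPath = path, chainCode = code,
      lengthEstimate = freemanLength(code, pixelSize), pixelSize = pixelSize,
      sourceImageId = "synthetic", quality = "clean", note = "")
}

# a nearly straight synthetic trace: a diagonal jog every 20th move
bentTrace <- function(nMoves, pixelSize = 1) {
  code <- rep(0L, nMoves)
  code[seq(20L, nMoves, by = 20L)] <- 1L
  drs <- c(0L, -1L); dcs <- c(1L, 1L)
  path <- cbind(row = cumsum(c(50L, drs[code + 1L])),
                col = cumsum(c(5L, dcs[code + 1L])))
  new("ContourTrace", pixelPath = path, chainCode = code,
      lengthEstimate = freemanLength(code, pixelSize), pixelSize = pixelSize,
      sourceImageId = "synthetic", quality = "clean", note = "")
}

# trace a simulated image set, keeping molecules with exactly one accepted trace
traceSet <- function(images, cfg = traceConfig(), prefix = "t") {
  out <- list()
  for (i in seq_along(images)) {
    tr <- traceImage(images[[i]], cfg, imageId = sprintf("%s-%04d", prefix, i))
    acc <- Filter(function(t) quality(t) != "rejected", tr)
    if (length(acc) == 1L) out <- c(out, acc)
  }
  out
}

# full-size calibration shared by the acceptance checks (about 3 minutes)
sharedCalibration <- function() {
  if (is.null(.shared$cal))
    .shared$cal <- calibrateFromSimulation(nPerCondition = 500L, seed = 42001L)
  .shared$cal
}

# 400 traced molecules at xi = 50 nm, L_C = 170 nm, independent of calibration
sharedAnalysisTraces <- function() {
  if (is.null(.shared$traces)) {
    images <- simulateImageSet(400L, 50, 500L, seed = 73011L)
    .shared$traces <- traceSet(images, prefix = "acc")
  }
  .shared$traces
}
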