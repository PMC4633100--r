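#' Render one chain into a mock AFM image
#'
#' Rasterisation, tip dilation and Gaussian background noise in one call:
#' the forward model that turns a simulated molecule into the kind of image
#' the tracer sees.
#'
#' @param chain a \linkS4class{PolymerChain}
#' @param pixelSize nm per pixel
#' @param margin margin around the chain bounding box, nm
#' @param tip a \linkS4class{TipModel}
#' @param noiseSigma Gaussian background noise in nm (0.15 nm default for
#'   synthetic fixtures)
#' @param seed optional seed for the noise field
#' @return a \linkS4class{HeightImage}
#' @export
simulateMockImage <- function(chain, pixelSize = 1.0, margin = 8.0,
                              tip = TipModel(), noiseSigma = 0.15,
                              seed = NULL) {
  img <- rasterizeChain(chain, pixelSize = pixelSize, margin = margin)
  img <- dilateWithTip(img, tip)
  addNoise(img, noiseSigma, seed = seed)
}

#' Simulate a reproducible set of mock AFM images
#'
#' One image per molecule. The master seed spawns independent substreams for
#' each chain conformation and each noise field.
#'
#' @param n number of molecules
#' @param persistenceLength,nSteps,stepLength,diameter chain parameters
#' @param pixelSize,margin,tip,noiseSigma imaging parameters (see
#'   \code{\link{simulateMockImage}})
#' @param seed master seed
#' @return list of \linkS4class{HeightImage}
#' @export
simulateImageSet <- function(n, persistenceLength, nSteps, stepLength = 0.34,
                             diameter = 2.0, pixelSize = 1.0, margin = 8.0,
                             tip = TipModel(), noiseSigma = 0.15, seed = NULL) {
  chains <- generateEnsemble(n, persistenceLength, nSteps, stepLength,
                             diameter, seed = seed)
  noiseSeeds <- withSeed(if (is.null(seed)) NULL else seed + 1L, spawnSeeds(n))
  lapply(seq_len(n), function(i)
    simulateMockImage(chains[[i]], pixelSize = pixelSize, margin = margin,
                      tip = tip, noiseSigma = noiseSigma,
                      seed = noiseSeeds[i]))
}

# Trace a list of images and pool the accepted traces.
.traceImageSet <- function(images, cfg, idPrefix = "sim") {
  out <- list(); logs <- list()
  for (i in seq_along(images)) {
    tr <- traceImage(images[[i]], cfg, imageId = sprintf("%s-%04d", idPrefix, i))
    logs[[i]] <- attr(tr, "log")
    out <- c(out, tr)
  }
  attr(out, "log") <- do.call(rbind, logs)
  out
}

#' Measured whole-molecule lengths for one calibration condition
#'
#' Simulates an ensemble at known persistence and contour length, images and
#' traces it, and collects the measured Freeman lengths of molecules whose
#' image yielded exactly one accepted trace (multi-component or rejected
#' images are dropped, mirroring the deletion of bad traces).
#'
#' @inheritParams simulateImageSet
#' @param cfg a \code{\link{traceConfig}}
#' @return a \linkS4class{CalibrationEnsemble}; attribute
#'   \code{"nRejected"} counts dropped molecules
#' @export
measuredLengthEnsemble <- function(n, persistenceLength, nSteps,
                                   stepLength = 0.34, diameter = 2.0,
                                   pixelSize = 1.0, margin = 8.0,
                                   tip = TipModel(), noiseSigma = 0.15,
                                   cfg = traceConfig(), seed = NULL) {
  images <- simulateImageSet(n, persistenceLength, nSteps, stepLength,
                             diameter, pixelSize, margin, tip, noiseSigma,
                             seed = seed)
  lens <- numeric(0); nRej <- 0L
  for (i in seq_along(images)) {
    tr <- traceImage(images[[i]], cfg, imageId = sprintf("cal-%04d", i))
    acc <- Filter(function(t) t@quality != "rejected", tr)
    if (length(acc) == 1L) lens <- c(lens, acc[[1L]]@lengthEstimate)
    else nRej <- nRej + 1L
  }
  if (!length(lens))
    stopf("no accepted traces at xi = %g nm, L_S = %g nm", persistenceLength,
          nSteps * stepLength)
  ens <- CalibrationEnsemble(persistenceLength, nSteps * stepLength, lens)
  attr(ens, "nRejected") <- nRej
  ens
}

#' Build a calibration model from simulated ensembles
#'
#' The calibrate-from-simulation workflow: simulate ensembles over a grid of
#' persistence lengths at a fixed contour length, plus shorter-length
#' ensembles at a reference stiffness; trace everything; estimate the
#' constant endpoint bias C from the regression of mean measured length on
#' true contour length (\code{\link{estimateCFromLengths}}); measure the bias
#' factor \eqn{\hat f(\xi)} on the grid; and fit the generalised form
#' \eqn{f(\xi) = scale\,(1 - A/\xi)} by inverse-variance weighted least
#' squares (\code{\link{fitBiasModel}}).
#'
#' The default grid brackets both the stiff (~50 nm) and the soft
#' surface-adsorbed (~13 nm) regimes. Because an error in C rescales every
#' measured bias factor by the same amount, C is the precision bottleneck of
#' the whole calibration; the default uses two companion lengths (~34 and
#' ~85 nm) against the 170 nm grid point, which tightens C several-fold over
#' a single pair.
#'
#' @param xiGrid persistence-length grid in nm
#' @param nPerCondition molecules per grid condition
#' @param nSteps steps of the main (long) contour (0.34 nm each)
#' @param cSteps step counts of the companion contour lengths used for C
#' @param refXi stiffness at which the C ensembles are simulated
#' @param stepLength,diameter,pixelSize,margin,tip,noiseSigma forward-model
#'   parameters
#' @param cfg a \code{\link{traceConfig}}
#' @param seed master seed
#' @param verbose print per-condition progress
#' @return list with \code{model} (a \linkS4class{CalibrationModel}),
#'   \code{table} (per-grid-point data.frame: xi, f_hat, se, n, rejected),
#'   \code{C}, and \code{ensembles}
#' @export
calibrateFromSimulation <- function(xiGrid = c(10, 15, 25, 50, 75, 100),
                                    nPerCondition = 500L, nSteps = 500L,
                                    cSteps = c(100L, 250L), refXi = 50,
                                    stepLength = 0.34, diameter = 2.0,
                                    pixelSize = 1.0, margin = 8.0,
                                    tip = TipModel(), noiseSigma = 0.15,
                                    cfg = traceConfig(), seed = NULL,
                                    verbose = FALSE) {
  stopifnot(length(xiGrid) >= 3L, length(cSteps) >= 1L)
  seeds <- withSeed(seed, spawnSeeds(length(xiGrid) + length(cSteps) + 1L))
  enss <- vector("list", length(xiGrid))
  for (i in seq_along(xiGrid)) {
    enss[[i]] <- measuredLengthEnsemble(nPerCondition, xiGrid[i], nSteps,
                                        stepLength, diameter, pixelSize,
                                        margin, tip, noiseSigma, cfg,
                                        seed = seeds[i])
    if (verbose)
      message(sprintf("xi = %5.1f nm: %d accepted, %d rejected", xiGrid[i],
                      length(enss[[i]]@measuredLengths),
                      attr(enss[[i]], "nRejected")))
  }
  k <- length(xiGrid)
  ensLongRef <- if (refXi %in% xiGrid) enss[[match(refXi, xiGrid)]]
                else measuredLengthEnsemble(nPerCondition, refXi, nSteps,
                                            stepLength, diameter, pixelSize,
                                            margin, tip, noiseSigma, cfg,
                                            seed = seeds[k + length(cSteps) + 1L])
  ensC <- lapply(seq_along(cSteps), function(j)
    measuredLengthEnsemble(nPerCondition, refXi, cSteps[j], stepLength,
                           diameter, pixelSize, margin, tip, noiseSigma, cfg,
                           seed = seeds[k + j]))
  cFit <- estimateCFromLengths(c(ensC, list(ensLongRef)))
  C <- cFit$C
  hash <- configHash(cfg, pixelSize,
                     extra = list(tipR = tip@radius, tipProfile = tip@profile,
                                  noise = noiseSigma))
  fs <- lapply(seq_along(xiGrid), function(i)
    measureF(enss[[i]], C, seed = seeds[i]))
  tab <- data.frame(xi = xiGrid,
                    f_hat = vapply(fs, `[[`, numeric(1L), "fHat"),
                    se = vapply(fs, `[[`, numeric(1L), "se"),
                    n = vapply(fs, `[[`, numeric(1L), "n"),
                    rejected = vapply(enss, function(e)
                      as.numeric(attr(e, "nRejected")), numeric(1L)))
  model <- fitBiasModel(tab$xi, tab$f_hat, tab$se, C = C,
                        pixelSize = pixelSize, tracerConfigHash = hash)
  list(model = model, table = tab, C = C, Cse = cFit$se,
       ensembles = c(enss, ensC))
}

#' Analyze a set of AFM images for persistence length
#'
#' The analyze workflow: trace every image (paths to TIFF / text-matrix files
#' or in-memory \linkS4class{HeightImage}s), pool the accepted traces, cut
#' them at each requested segment length, and report raw and calibrated
#' stiffness estimates plus the linear trend across segment length. Results
#' are independent of image ordering.
#'
#' @param images list of \linkS4class{HeightImage} or a character vector of
#'   file paths
#' @param model a \linkS4class{CalibrationModel}; its tracer configuration
#'   hash must match the current configuration unless \code{override = TRUE}
#' @param segmentLengths segment arc lengths in nm
#' @param cfg a \code{\link{traceConfig}}
#' @param tip,noiseSigma imaging parameters used only to form the current
#'   configuration hash for the model check
#' @param override accept a calibration model with a mismatching hash
#' @param B bootstrap resamples per estimate
#' @param seed bootstrap seed
#' @return list with \code{estimates} (data.frame), \code{trend}
#'   (\code{\link{trendFit}} output, or NULL if fewer than 3 segment
#'   lengths), \code{traces}, and \code{log}
#' @export
analyzeImages <- function(images, model, segmentLengths = c(20, 30, 50, 80, 120, 160),
                          cfg = traceConfig(), tip = TipModel(),
                          noiseSigma = 0.15, override = FALSE, B = 200L,
                          seed = NULL) {
  stopifnot(is(model, "CalibrationModel"))
  if (is.character(images)) {
    if (!length(images)) stopf("no input images")
    images <- lapply(images, readHeightImage)
  }
  if (!length(images)) stopf("no input images")
  px <- images[[1L]]@pixelSize
  hash <- configHash(cfg, px, extra = list(tipR = tip@radius,
                                           tipProfile = tip@profile,
                                           noise = noiseSigma))
  if (nzchar(model@tracerConfigHash) && !identical(model@tracerConfigHash, hash) &&
      !override)
    stopf(paste0("calibration model hash '%s' does not match the current ",
                 "configuration '%s' (use override = TRUE to force)"),
          model@tracerConfigHash, hash)
  traces <- .traceImageSet(images, cfg, idPrefix = "img")
  acc <- Filter(function(t) t@quality != "rejected", traces)
  if (!length(acc)) stopf("zero accepted traces in the image set")
  seeds <- withSeed(seed, spawnSeeds(length(segmentLengths)))
  ests <- list()
  for (i in seq_along(segmentLengths)) {
    e <- tryCatch(estimateXi(acc, segmentLengths[i], model, B = B,
                             seed = seeds[i]),
                  error = function(err) NULL)
    if (!is.null(e)) ests[[length(ests) + 1L]] <- e
  }
  if (!length(ests)) stopf("no segment length yielded enough segments")
  tab <- estimatesTable(ests)
  trend <- if (nrow(tab) >= 3L) trendFit(tab) else NULL
  list(estimates = tab, trend = trend, traces = traces,
       log = attr(traces, "log"))
}

#' Uncertainty of the stiffness estimate vs sample size
#'
#' Repeats the full simulate-image-trace-estimate pipeline across independent
#' replicates and reports the mean and standard deviation of the calibrated
#' estimate for each molecule count and segment length. Within a replicate,
#' smaller sample sizes are nested subsets of the largest simulated set, so a
#' whole replicate costs one maximal pipeline run; replicates are
#' independent. The sampling error initially scales as \eqn{N^{-1/2}}, with
#' segment pooling contributing an extra \eqn{1/\sqrt{n_S}}.
#'
#' @param model a \linkS4class{CalibrationModel}
#' @param segmentLengths segment lengths in nm
#' @param Ns molecule counts (evaluated as nested subsets)
#' @param replicates independent pipeline replicates
#' @param persistenceLength,nSteps,stepLength,diameter,pixelSize,margin,tip,noiseSigma
#'   forward-model parameters
#' @param cfg a \code{\link{traceConfig}}
#' @param seed master seed; the full table is reproducible given the seed
#' @return data.frame with \code{segment_length_nm}, \code{N},
#'   \code{mean_xi_nm}, \code{sd_xi_nm}, \code{replicates}
#' @export
uncertaintyVsSampleSize <- function(model, segmentLengths = c(30, 160),
                                    Ns = c(25, 50, 100, 200),
                                    replicates = 50L, persistenceLength = 50,
                                    nSteps = 500L, stepLength = 0.34,
                                    diameter = 2.0, pixelSize = 1.0,
                                    margin = 8.0, tip = TipModel(),
                                    noiseSigma = 0.15, cfg = traceConfig(),
                                    seed = NULL) {
  Ns <- sort(Ns)
  nMax <- max(Ns)
  repSeeds <- withSeed(seed, spawnSeeds(replicates))
  xiHat <- array(NA_real_, c(replicates, length(Ns), length(segmentLengths)))
  for (r in seq_len(replicates)) {
    images <- simulateImageSet(nMax, persistenceLength, nSteps, stepLength,
                               diameter, pixelSize, margin, tip, noiseSigma,
                               seed = repSeeds[r])
    traces <- vector("list", nMax)
    for (i in seq_len(nMax)) {
      tr <- traceImage(images[[i]], cfg, imageId = sprintf("unc-%03d-%04d", r, i))
      acc <- Filter(function(t) t@quality != "rejected", tr)
      traces[[i]] <- if (length(acc) == 1L) acc[[1L]] else NULL
    }
    for (j in seq_along(Ns)) {
      sub <- Filter(Negate(is.null), traces[seq_len(Ns[j])])
      for (k in seq_along(segmentLengths)) {
        e <- tryCatch(estimateXi(sub, segmentLengths[k], model, B = 0L),
                      error = function(err) NULL)
        if (!is.null(e)) xiHat[r, j, k] <- e@xiCorrected
      }
    }
  }
  out <- expand.grid(N = Ns, segment_length_nm = segmentLengths)[, 2:1]
  out$mean_xi_nm <- NA_real_; out$sd_xi_nm <- NA_real_
  for (k in seq_along(segmentLengths)) for (j in seq_along(Ns)) {
    v <- xiHat[, j, k]
    row <- (k - 1L) * length(Ns) + j
    out$mean_xi_nm[row] <- mean(v, na.rm = TRUE)
    out$sd_xi_nm[row] <- stats::sd(v, na.rm = TRUE)
  }
  out$replicates <- replicates
  out
}
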