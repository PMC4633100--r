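test_that("the 2D WLC end-to-end relation is exact, stable, and has correct limits", {
  # frozen high-precision evaluation at the reference condition
  expect_equal(wlcMSD(50, 170), 17653.670481, tolerance = 1e-9)
  # rigid-rod limit: <R^2>/L^2 -> 1
  expect_equal(wlcMSD(1e3 * 170, 170) / 170^2, 1, tolerance = 1e-3)
  expect_equal(wlcMSD(1e9, 1) / 1, 1, tolerance = 1e-6)
  # coil limit: <R^2>/(4 xi L) -> 1
  expect_equal(wlcMSD(1, 1e3) / (4 * 1e3), 1, tolerance = 1e-2)
  # series/direct switchover is seamless
  L <- 1
  xiA <- L / (2 * (1e-3 - 1e-9)); xiB <- L / (2 * (1e-3 + 1e-9))
  expect_equal(wlcMSD(xiA, L) / wlcMSD(xiB, L), 1, tolerance = 1e-9)
  # vectorised
  expect_equal(wlcMSD(c(10, 50), 170), c(wlcMSD(10, 170), wlcMSD(50, 170)))
  expect_error(wlcMSD(-1, 10), "positive")
  expect_error(wlcMSD(10, 0), "positive")
})

test_that("inversion round-trips the forward relation and is monotone", {
  for (xi0 in c(5, 13, 50, 200)) for (L in c(20, 170)) {
    expect_equal(invertMSD(wlcMSD(xi0, L), L), xi0, tolerance = 1e-8)
  }
  # strict monotonicity of the forward relation on a dense grid
  xis <- exp(seq(log(0.1), log(1e4), length.out = 300))
  expect_true(all(diff(wlcMSD(xis, 170)) > 0))
  # non-physical and invalid inputs
  expect_error(invertMSD(170^2, 170), "non-physical")
  expect_error(invertMSD(-5, 170), "positive")
})

test_that("contour-length error propagates steeply into the inferred stiffness", {
  # no contour error, no stiffness error
  curve <- errorPropagationCurve(34, 50, c(-0.05, -0.02, 0, 0.02))
  expect_equal(curve$rel_xi_error[curve$rel_contour_error == 0], 0,
               tolerance = 1e-8)
  # a ~2% underestimate on 100 bp inflates xi by roughly 60%
  err2 <- curve$rel_xi_error[curve$rel_contour_error == -0.02]
  expect_gt(err2, 0.5)
  expect_lt(err2, 0.7)
  # longer molecules are less sensitive at the same relative error
  errs <- vapply(c(34, 102, 170), function(L)
    errorPropagationCurve(L, 50, -0.02)$rel_xi_error, numeric(1))
  expect_true(all(diff(abs(errs)) < 0))
  # strong overestimates of the contour make the inversion non-physical or
  # drive xi down; strong underestimates are flagged NA when R exceeds L
  big <- errorPropagationCurve(34, 5000, c(-0.05))
  expect_true(is.na(big$rel_xi_error))
})

test_that("segmentation cuts non-overlapping segments of the requested arc length", {
  tr <- straightTrace(171)                   # 170 nm of axial moves
  s80 <- segmentContour(tr, 80)
  expect_identical(nrow(s80), 2L)
  s30 <- segmentContour(tr, 30)
  expect_identical(nrow(s30), 5L)
  # straight trace: R equals the segment length within one pixel step
  expect_true(all(abs(s30$R_nm - s30$length_nm) < 1 + 1e-9))
  expect_true(all(abs(s30$length_nm - 30) < sqrt(2) + 1e-9))
  # segments tile the contour without overlap
  expect_identical(s30$start_idx[-1], s30$end_idx[-5])
  # too short a trace gives an empty frame; tiny segments are refused
  expect_identical(nrow(segmentContour(tr, 200)), 0L)
  expect_error(segmentContour(tr, 2), "4 pixels")
})

test_that("pooled segment statistics on raw chains reproduce the closed form", {
  # independent of any imaging or tracing: cut simulated chains into
  # consecutive runs of k steps and compare <R^2> with the analytic value
  delta <- 0.34; xi <- 50
  chains <- generateEnsemble(800, xi, 500, seed = 909)
  for (k in c(59L, 235L)) {                  # ~20 nm and ~80 nm segments
    L <- k * delta
    r2 <- unlist(lapply(chains, function(ch) {
      v <- vertices(ch)
      nseg <- nrow(v) %/% k
      idx0 <- (seq_len(nseg) - 1L) * k + 1L
      (v[idx0 + k, 1] - v[idx0, 1])^2 + (v[idx0 + k, 2] - v[idx0, 2])^2
    }))
    se <- sd(r2) / sqrt(800)                 # conservative: molecules independent
    expect_lt(abs(mean(r2) - wlcMSD(xi, L)), 3.5 * se)
  }
})

test_that("estimateXi pools segments, corrects self-consistently, and degrades gracefully", {
  traces <- replicate(12, bentTrace(171), simplify = FALSE)
  # nearly straight traces: the estimate sits at the stiff end
  e <- estimateXi(traces, 30, model = NULL, B = 0)
  expect_identical(e@nMolecules, 12L)
  expect_gte(e@nSegments, 60L)
  expect_gt(e@xiRaw, 10)
  expect_true(is.na(e@xiCorrected))
  # A = 0 model: corrected equals raw exactly
  m0 <- CalibrationModel(A = 0, C = 0)
  e0 <- estimateXi(traces, 30, m0, B = 0)
  expect_equal(e0@xiCorrected, e0@xiRaw, tolerance = 1e-9)
  expect_error(estimateXi(traces[1:2], 100, B = 0), "pooled segments")
  # bootstrap SE present and positive on heterogeneous data
  set.seed(31)
  wob <- lapply(1:15, function(i) {
    img <- simulateImageSet(1, 50, 400, seed = 800L + i)[[1]]
    acc <- Filter(function(t) quality(t) != "rejected", traceImage(img))
    if (length(acc) == 1L) acc[[1]] else NULL
  })
  wob <- Filter(Negate(is.null), wob)
  ew <- estimateXi(wob, 30, m0, B = 50L, seed = 2)
  expect_gt(ew@se, 0)
  expect_gt(ew@xiRaw, 0)
})

test_that("trend fitting flags scale-free stiffness and recovers injected trends", {
  mk <- function(xi) data.frame(segment_length_nm = c(20, 50, 80, 120, 160),
                                mean_segment_length_nm = c(20, 50, 80, 120, 160),
                                n_segments = 100L, n_molecules = 50L,
                                mean_R2_nm2 = NA, xi_raw_nm = xi,
                                xi_corr_nm = xi, se_nm = 0.5)
  # constant stiffness: slope exactly zero
  flat <- suppressWarnings(trendFit(mk(rep(50, 5))))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_true(flat$wlcConsistent)
  # injected linear stiffening recovered within the confidence interval
  set.seed(8)
  b <- 0.12
  noisy <- mk(30 + b * c(20, 50, 80, 120, 160) + rnorm(5, 0, 0.4))
  fit <- trendFit(noisy)
  expect_gt(b, fit$ci[1]); expect_lt(b, fit$ci[2])
  expect_false(fit$wlcConsistent)
  expect_error(trendFit(mk(rep(50, 5))[1:2, ]), "3 distinct")
})

test_that("estimate tables collect one row per segment length", {
  e <- new("StiffnessEstimate", segmentLength = 30, meanSegmentLength = 30.4,
           nSegments = 100L, nMolecules = 20L, meanR2 = 700, xiRaw = 26,
           xiCorrected = 49.5, se = 1.2)
  tab <- estimatesTable(list(e, e))
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$xi_corr_nm, c(49.5, 49.5))
})
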