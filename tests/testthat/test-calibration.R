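test_that("the long/short-pair algebra recovers the constant endpoint bias exactly", {
  # synthetic tracer: L* = (L_S - c0) * f0 with known constants
  c0 <- 0.7; f0 <- 0.95
  mk <- function(LS) CalibrationEnsemble(50, LS, rep((LS - c0) * f0, 40))
  expect_equal(estimateC(mk(170), mk(85)), c0, tolerance = 1e-12)
  # invariant to which ensemble is labelled long/short
  expect_equal(estimateC(mk(85), mk(170)), estimateC(mk(170), mk(85)),
               tolerance = 1e-12)
  # the multiplicative factor cancels: any f0 gives the same C
  mk2 <- function(LS) CalibrationEnsemble(50, LS, rep((LS - c0) * 1.06, 40))
  expect_equal(estimateC(mk2(170), mk2(85)), c0, tolerance = 1e-12)
  # unbiased tracer: C = 0
  mk3 <- function(LS) CalibrationEnsemble(50, LS, rep(LS, 40))
  expect_equal(estimateC(mk3(170), mk3(85)), 0, tolerance = 1e-12)
  # guards
  expect_error(estimateC(mk(170), CalibrationEnsemble(25, 85, rep(80, 5))), "share")
  expect_error(estimateC(mk(170), mk(170)), "different")
  expect_error(estimateC(mk3(170), CalibrationEnsemble(50, 170.00001, rep(170, 5))),
               "ill-conditioned")
})

test_that("the bias factor is the mean measured over the bias-corrected true length", {
  ens <- CalibrationEnsemble(50, 170, rep(170, 30))
  f <- measureF(ens, C = 0, seed = 1)
  expect_equal(f$fHat, 1)
  expect_equal(f$se, 0)
  # bootstrap SE is consistent with the direct ratio
  set.seed(2)
  lens <- rnorm(200, 160, 4)
  ens2 <- CalibrationEnsemble(50, 170, lens)
  f2 <- measureF(ens2, C = 0.7, B = 400L, seed = 3)
  expect_equal(f2$fHat, mean(lens) / 169.3, tolerance = 1e-12)
  expect_equal(f2$se, sd(lens) / sqrt(200) / 169.3, tolerance = 0.25)
  expect_error(measureF(ens2, C = 171), "exceed")
})

test_that("fitting f(xi) = 1 - A/xi recovers exact and noisy synthetic inputs", {
  xi <- c(10, 15, 25, 50, 75, 100)
  A0 <- 0.4310
  m <- fitA(xi, 1 - A0 / xi)
  expect_equal(biasA(m), A0, tolerance = 1e-7)
  expect_equal(m@validityRange, c(10, 100))
  # a perfect tracer gives A = 0
  expect_equal(biasA(fitA(xi, rep(1, 6))), 0, tolerance = 1e-12)
  # noisy recovery: mean over replicates within 3 standard errors
  set.seed(5)
  Ahat <- replicate(200, biasA(fitA(xi, 1 - A0 / xi + rnorm(6, 0, 0.005),
                                    se = rep(0.005, 6))))
  expect_lt(abs(mean(Ahat) - A0), 3 * sd(Ahat) / sqrt(200))
  expect_error(fitA(c(10, 50), c(0.9, 0.99)), "3 distinct")
})

test_that("the generalised bias fit recovers a scaled form and nests the classic one", {
  xi <- c(10, 15, 25, 50, 75, 100)
  B0 <- 1.055; A0 <- 0.58
  m <- fitBiasModel(xi, B0 * (1 - A0 / xi))
  expect_equal(biasScale(m), B0, tolerance = 1e-9)
  expect_equal(biasA(m), A0, tolerance = 1e-9)
  expect_equal(biasFactor(m, 50), B0 * (1 - A0 / 50), tolerance = 1e-9)
  # with unit scale it reproduces the one-parameter fit
  m1 <- fitBiasModel(xi, 1 - 0.4310 / xi)
  expect_equal(biasScale(m1), 1, tolerance = 1e-9)
  expect_equal(biasA(m1), 0.4310, tolerance = 1e-7)
})

test_that("length correction inverts the bias and respects its validity range", {
  m <- CalibrationModel(A = 0.4310, C = 0.7428, validityRange = c(10, 100))
  expect_equal(correctLength(19.8, 50, m), 19.8 / (1 - 0.4310 / 50),
               tolerance = 1e-12)
  expect_equal(correctLength(19.8, 50, m), 19.97216, tolerance = 1e-6)
  # corrected exceeds measured whenever A > 0
  expect_true(all(correctLength(c(20, 80, 160), 13, m) > c(20, 80, 160)))
  # A = 0: identity
  m0 <- CalibrationModel(A = 0, C = 0)
  expect_equal(correctLength(42, 5, m0), 42)
  expect_error(correctLength(20, 0.4, m), "validity")
})

test_that("calibration models persist to JSON and refuse mismatched tracer configs", {
  m <- CalibrationModel(A = 0.5, C = 2.1, scale = 1.04, pixelSize = 1,
                        tracerConfigHash = "cfgA", validityRange = c(10, 100))
  f <- file.path(tempdir(), "model.json")
  writeCalibrationModel(m, f, ensembleSizes = list(long = 500))
  back <- readCalibrationModel(f, expectedHash = "cfgA")
  expect_equal(biasA(back), 0.5)
  expect_equal(biasC(back), 2.1)
  expect_equal(biasScale(back), 1.04)
  expect_equal(back@validityRange, c(10, 100))
  expect_error(readCalibrationModel(f, expectedHash = "cfgB"), "refusing")
  expect_equal(biasA(readCalibrationModel(f, expectedHash = "cfgB",
                                          override = TRUE)), 0.5)
  unlink(f)
})
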