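test_that("the chain-code length estimator equals the pixel-centre polyline length", {
  expect_equal(freemanLength(c(0, 0, 0, 0)), 4)
  expect_equal(freemanLength(c(1, 3, 5)), 3 * sqrt(2))
  # mixed code at half-nm pixels: matches the summed Euclidean distances
  code <- c(rep(0L, 10), rep(1L, 5))
  expect_equal(freemanLength(code, 0.5), (10 + 5 * sqrt(2)) / 2)
  drs <- c(0, -1, -1, -1, 0, 1, 1, 1); dcs <- c(1, 1, 0, -1, -1, -1, 0, 1)
  set.seed(3)
  for (rep in 1:20) {
    code <- sample(0:7, 30, replace = TRUE)
    path <- cbind(cumsum(c(0, drs[code + 1])), cumsum(c(0, dcs[code + 1])))
    euclid <- sum(sqrt(diff(path[, 1])^2 + diff(path[, 2])^2))
    expect_equal(freemanLength(code, 1), euclid, tolerance = 1e-12)
  }
  expect_equal(freemanLength(integer(0)), 0)
  expect_error(freemanLength(c(0, 8)), "0..7")
})

test_that("thresholding reproduces the brute-force per-pixel rule", {
  ch <- rodChain(20)
  img <- rasterizeChain(ch)                      # noiseless 2 nm ridge
  cfg <- traceConfig(sigma = 0.15)               # threshold = 0 + 3*0.15
  mask <- binarizeImage(img, cfg)
  expect_identical(unclass(mask)[, ], heights(img) > 0.45)
  expect_identical(sum(mask), sum(heights(img) == 2))
  # noisy image: identical to direct comparison against the stored threshold
  noisy <- addNoise(dilateWithTip(img), 0.15, seed = 8)
  m2 <- binarizeImage(noisy, traceConfig())
  expect_identical(unclass(m2)[, ], heights(noisy) > attr(m2, "threshold"))
  # blank image: empty trace list from the full pipeline
  blank <- HeightImage(matrix(0, 60, 60))
  expect_length(traceImage(blank, traceConfig(flatten = FALSE, sigma = 0.15)), 0L)
})

test_that("thinning yields single-pixel, idempotent, component-preserving skeletons", {
  # a 3-px-wide horizontal bar thins to a 1-px line
  bar <- matrix(FALSE, 20, 40); bar[9:11, 5:35] <- TRUE
  sk <- thinBinary(bar)
  expect_true(all(which(sk, arr.ind = TRUE)[, "row"] == 10L))
  expect_true(all(colSums(sk) <= 1))
  expect_gte(sum(sk), 25)
  # idempotence
  expect_identical(thinBinary(sk), sk)
  # component count preserved on simulated images
  imgs <- simulateImageSet(30, 25, 400, seed = 301)
  for (img in imgs) {
    mask <- binarizeImage(img, traceConfig())
    sk <- thinBinary(mask)
    before <- max(labelComponents(mask))
    after <- max(labelComponents(sk))
    expect_identical(after, before)
  }
})

test_that("path extraction orders open curves, rejects loops and branches", {
  # single open curve
  curve <- matrix(FALSE, 15, 15)
  for (i in 1:10) curve[3 + (i > 5) * (i - 5), 2 + i] <- TRUE
  tr <- extractPaths(curve, traceConfig(minLengthPx = 5), imageId = "toy")
  expect_length(tr, 1L)
  expect_equal(quality(tr[[1]]), "clean")
  p <- pixelPath(tr[[1]])
  expect_identical(nrow(p), sum(curve))
  deg1 <- c(p[1, ], p[nrow(p), ])
  expect_true(all(deg1 > 0))
  # closed loop: rejected, no endpoints
  th <- seq(0, 2 * pi, length.out = 200)
  ring <- matrix(FALSE, 30, 30)
  ring[cbind(round(15 + 8 * sin(th)), round(15 + 8 * cos(th)))] <- TRUE
  ring <- thinBinary(ring)
  trl <- extractPaths(ring, traceConfig(), imageId = "loop")
  expect_true(all(vapply(trl, quality, character(1)) == "rejected"))
  expect_true(any(vapply(trl, function(t) t@note, character(1)) == "loop"))
  # border-touching components are rejected
  edge <- matrix(FALSE, 12, 12); edge[1, 3:9] <- TRUE
  tre <- extractPaths(edge, traceConfig(), imageId = "edge")
  expect_identical(vapply(tre, function(t) t@note, character(1)), "border")
})

test_that("accepted traces visit each skeleton pixel exactly once on simulated images", {
  imgs <- simulateImageSet(50, 50, 400, seed = 401)
  nAccepted <- 0L
  for (img in imgs) {
    traces <- traceImage(img, imageId = "prop")
    for (t in traces) {
      if (quality(t) == "rejected") next
      nAccepted <- nAccepted + 1L
      p <- pixelPath(t)
      expect_identical(anyDuplicated(paste(p[, 1], p[, 2])), 0L)
      # path pixels are exactly the component's skeleton pixels
      expect_identical(length(chainCode(t)), nrow(p) - 1L)
      # consecutive pixels are 8-neighbours
      expect_true(all(pmax(abs(diff(p[, 1])), abs(diff(p[, 2]))) == 1))
    }
  }
  expect_gt(nAccepted, 40L)
})

test_that("a rigid rod traces to one contour with length close to truth", {
  ch <- generateChain(WLCParams(1e12, 294, seed = 12L), initialHeading = 0)
  img <- simulateMockImage(ch, seed = 13)
  traces <- traceImage(img, imageId = "rod")
  acc <- Filter(function(t) quality(t) != "rejected", traces)
  expect_length(acc, 1L)
  expect_equal(traceLength(acc[[1]]), 100, tolerance = 0.03)
  expect_s3_class(attr(traces, "log"), "data.frame")
})

test_that("tracing is deterministic and mean measured length increases with stiffness", {
  img <- simulateImageSet(1, 25, 400, seed = 77)[[1]]
  t1 <- traceImage(img, imageId = "det")
  t2 <- traceImage(img, imageId = "det")
  expect_identical(lapply(t1, pixelPath), lapply(t2, pixelPath))
  expect_identical(vapply(t1, quality, character(1)),
                   vapply(t2, quality, character(1)))
  # soft molecules lose more contour than stiff ones (ratio increasing in xi)
  meanLen <- vapply(c(10, 25, 50, 100), function(xi) {
    images <- simulateImageSet(60, xi, 500, seed = 500L + xi)
    lens <- vapply(traceSet(images), traceLength, numeric(1))
    mean(lens)
  }, numeric(1))
  expect_true(all(diff(meanLen) > 0))
})

test_that("traces survive the CSV round trip", {
  img <- simulateImageSet(1, 50, 300, seed = 55)[[1]]
  traces <- traceImage(img, imageId = "io")
  acc <- Filter(function(t) quality(t) != "rejected", traces)
  f <- file.path(tempdir(), "traces.csv")
  writeTraces(acc, f)
  back <- readTraces(f)
  expect_length(back, length(acc))
  expect_equal(unname(pixelPath(back[[1]])), unname(pixelPath(acc[[1]])))
  expect_equal(traceLength(back[[1]]), traceLength(acc[[1]]))
  unlink(c(f, paste0(f, ".json")))
})
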