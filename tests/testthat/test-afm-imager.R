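test_that("a straight rod rasterises to a flat-topped capsule ridge", {
  ch <- rodChain(3.4)                       # 10 steps along +x
  img <- rasterizeChain(ch, pixelSize = 1, margin = 8)
  h <- heights(img)
  expect_true(all(h %in% c(0, 2)))
  # ridge length ~ contour + diameter (capsule caps), width ~ diameter
  ridgeCols <- range(which(colSums(h > 0) > 0))
  expect_equal(diff(ridgeCols) + 1, 3.4 + 2, tolerance = 1)
  ridgeRows <- range(which(rowSums(h > 0) > 0))
  expect_lte(diff(ridgeRows) + 1, 3)
  # margins are empty
  expect_true(all(h[1:4, ] == 0) && all(h[, 1:4] == 0))
  # extent covers bounding box plus margin on each side
  expect_gte(ncol(h), 3.4 + 2 * 8)
  expect_error(rasterizeChain(ch, pixelSize = 1, maxPixels = 10L), "larger")
})

test_that("ridge area grows with chain length at fixed stiffness", {
  areas <- vapply(c(100L, 250L, 500L), function(n) {
    ch <- generateChain(WLCParams(50, n, seed = 31L))
    sum(heights(rasterizeChain(ch)) > 0)
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("tip dilation is extensive, exact for known cases, and matches brute force", {
  # flat image stays flat
  flat <- HeightImage(matrix(0, 30, 30))
  expect_equal(heights(dilateWithTip(flat, TipModel(3, "disk"))), matrix(0, 30, 30))
  # single tall pixel under a disk tip becomes a plateau of that radius
  m <- matrix(0, 21, 21); m[11, 11] <- 2
  d <- heights(dilateWithTip(HeightImage(m), TipModel(3, "disk")))
  idx <- which(d == 2, arr.ind = TRUE)
  r <- sqrt((idx[, 1] - 11)^2 + (idx[, 2] - 11)^2)
  expect_lte(max(r), 3 + 1e-9)
  expect_equal(nrow(idx), sum(outer((-3:3)^2, (-3:3)^2, "+") <= 9 + 1e-9))
  # spherical-cap dilation equals the direct point-by-point maximisation
  set.seed(21)
  img <- rasterizeChain(generateChain(WLCParams(50, 60, seed = 6L)), margin = 6)
  tip <- TipModel(3, "cap")
  fast <- heights(dilateWithTip(img, tip))
  h <- heights(img)
  slow <- h
  for (dr in -3:3) for (dc in -3:3) {
    rr <- sqrt(dr^2 + dc^2)
    if (rr > 3) next
    drop <- 3 - sqrt(9 - rr^2)
    sh <- matrix(0, nrow(h), ncol(h))
    rs <- max(1, 1 - dr):min(nrow(h), nrow(h) - dr)
    cs <- max(1, 1 - dc):min(ncol(h), ncol(h) - dc)
    sh[rs, cs] <- h[rs + dr, cs + dc]
    slow <- pmax(slow, sh - drop)
  }
  expect_equal(fast, slow, tolerance = 1e-12)
  # extensive: output >= input everywhere
  expect_true(all(fast >= h - 1e-12))
  # translation equivariance
  m2 <- matrix(0, 25, 25); m2[8, 9] <- 1.5
  m3 <- matrix(0, 25, 25); m3[13, 15] <- 1.5
  d2 <- heights(dilateWithTip(HeightImage(m2), tip))
  d3 <- heights(dilateWithTip(HeightImage(m3), tip))
  expect_equal(d2[3:13, 4:14], d3[8:18, 10:20], tolerance = 1e-12)
  # degenerate tip: identity with a warning
  expect_warning(tiny <- dilateWithTip(HeightImage(m2, pixelSize = 2), TipModel(0.5)),
                 "identity")
  expect_equal(heights(tiny), m2)
})

test_that("Gaussian noise has the requested scale and is seed-reproducible", {
  img <- HeightImage(matrix(0, 512, 512))
  expect_identical(heights(addNoise(img, 0)), heights(img))
  n1 <- addNoise(img, 0.1, seed = 9)
  expect_equal(sd(heights(n1)), 0.1, tolerance = 0.02)
  expect_equal(noiseSigma(n1), 0.1)
  expect_identical(heights(addNoise(img, 0.1, seed = 9)), heights(n1))
  expect_error(addNoise(img, -0.1), "non-negative")
})

test_that("noise estimation is robust, consistent, and offset-invariant", {
  img <- addNoise(HeightImage(matrix(0, 200, 200)), 0.1, seed = 4)
  expect_equal(estimateNoise(img), 0.1, tolerance = 0.05)
  # constant image: zero noise
  expect_equal(estimateNoise(HeightImage(matrix(5, 60, 60))), 0)
  # invariant to a constant offset
  shifted <- HeightImage(heights(img) + 3.7, noiseSigma = 0.1)
  expect_equal(estimateNoise(shifted), estimateNoise(img), tolerance = 1e-12)
  # exclusion mask leaves too few pixels
  mask <- matrix(TRUE, 200, 200); mask[1:10, 1:10] <- FALSE
  expect_error(estimateNoise(img, exclusionMask = mask), "background")
})

test_that("flattening removes an exact plane and centres the background", {
  nr <- 80; nc <- 100
  xs <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  ys <- matrix(rep(0:(nr - 1), nc), nr, nc)
  plane <- 0.5 + 0.01 * xs - 0.02 * ys
  flat <- flattenImage(HeightImage(plane))
  expect_lt(max(abs(heights(flat))), 1e-9)
  # plane + ridge + noise: background slope removed within noise bounds
  ch <- rodChain(40)
  img <- rasterizeChain(ch, margin = 15)
  h <- heights(img)
  nr <- nrow(h); nc <- ncol(h)
  xs <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  ys <- matrix(rep(0:(nr - 1), nc), nr, nc)
  noisy <- addNoise(HeightImage(h + 1 + 0.03 * xs - 0.01 * ys), 0.1, seed = 2)
  flat2 <- flattenImage(noisy)
  bg <- heights(flat2)[h == 0]
  # residual slope: refit a plane on the background and check coefficients
  fit <- lm(z ~ x + y, data.frame(z = heights(flat2)[h == 0],
                                  x = xs[h == 0], y = ys[h == 0]))
  expect_lt(abs(coef(fit)["x"]), 3 * summary(fit)$coefficients["x", 2])
  expect_lt(abs(coef(fit)["y"]), 3 * summary(fit)$coefficients["y", 2])
  expect_lt(abs(mean(bg)), 0.01)
  expect_error(flattenImage(img, exclusionMask = matrix(TRUE, nr, nc)), "excluded")
})

test_that("height images round-trip through float TIFF and text formats", {
  m <- matrix(rnorm(400, 1, 0.4), 20, 20)
  img <- HeightImage(m, pixelSize = 2, noiseSigma = 0.12)
  for (ext in c(".tif", ".txt")) {
    f <- file.path(tempdir(), paste0("img", ext))
    writeHeightImage(img, f)
    back <- readHeightImage(f)
    expect_equal(heights(back), m, tolerance = 1e-6)
    expect_equal(pixelSize(back), 2)
    expect_equal(noiseSigma(back), 0.12)
    unlink(c(f, paste0(f, ".json")))
  }
  # no sidecar: fall back to the supplied pixel size, provenance measured
  f <- file.path(tempdir(), "bare.txt")
  write.table(m, f, row.names = FALSE, col.names = FALSE)
  bare <- readHeightImage(f, pixelSize = 1.5)
  expect_equal(pixelSize(bare), 1.5)
  expect_equal(bare@provenance, "measured")
  unlink(f)
})
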