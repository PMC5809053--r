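# Image I/O, ROI cropping, automatic thresholding, Sobel magnitude and
# border extraction.

test_that("PNG round-trip preserves the pixel grid and RGB converts by channel mean", {
  img <- GrayImage(matrix(c(0, 255, 255, 0), 2, 2))
  f <- withr::local_tempfile(fileext = ".png")
  writeGrayImage(img, f)
  expect_equal(pixels(readGrayImage(f)), pixels(img))

  ft <- withr::local_tempfile(fileext = ".tif")
  img2 <- GrayImage(matrix(round(seq(0, 255, length.out = 48)), 6, 8))
  writeGrayImage(img2, ft)
  expect_equal(pixels(readGrayImage(ft)), pixels(img2))

  # RGB (30, 60, 90) -> gray 60
  frgb <- withr::local_tempfile(fileext = ".png")
  arr <- array(0, c(2, 2, 3))
  arr[, , 1] <- 30 / 255; arr[, , 2] <- 60 / 255; arr[, , 3] <- 90 / 255
  png::writePNG(arr, frgb)
  expect_equal(unname(pixels(readGrayImage(frgb))[1, 1]), 60)

  expect_error(readGrayImage(file.path(tempdir(), "absent.png")), "not found")
})

test_that("cropRoi extracts the half-open rectangle and validates bounds", {
  m <- matrix(1:30, 5, 6)
  img <- GrayImage(m)
  expect_equal(pixels(cropRoi(img, 0, 0, 5, 6)), m)
  expect_equal(pixels(cropRoi(img, 1, 2, 2, 3)), m[2:3, 3:5])
  expect_error(cropRoi(img, 0, 3, 2, 4), "right edge")
  expect_error(cropRoi(img, 4, 0, 3, 2), "bottom edge")
  expect_error(cropRoi(img, -1, 0, 2, 2), "non-negative")
})

test_that("isodataThreshold finds the intermeans fixed point", {
  half <- GrayImage(matrix(c(0, 0, 255, 255), 2, 2))
  expect_equal(isodataThreshold(half), 127.5)

  img <- GrayImage(matrix(c(10, 10, 10, 10, 200, 200, 200, 200, 200), 3, 3))
  t <- isodataThreshold(img)
  # exhaustive scan for integer fixed points of the intermeans condition
  px <- as.numeric(pixels(img))
  fixed <- Filter(function(cand) {
    lo <- px[px <= cand]; hi <- px[px > cand]
    length(lo) > 0 && length(hi) > 0 &&
      abs((mean(lo) + mean(hi)) / 2 - cand) < 0.5
  }, 0:254)
  expect_true(any(abs(t - fixed) < 1))
  expect_equal(t, 105)  # means 10 and 200 -> fixed point 105

  expect_error(isodataThreshold(GrayImage(matrix(7, 3, 3))), "constant image")
})

test_that("binarize respects polarity and is idempotent on binary images", {
  img <- GrayImage(matrix(c(50, 150, 50, 150), 2, 2))
  expect_equal(pixels(binarize(img, 100, "bright")),
               matrix(c(0, 1, 0, 1), 2, 2))
  expect_equal(pixels(binarize(img, 100, "dark")),
               matrix(c(1, 0, 1, 0), 2, 2))

  # auto picks the brighter class as foreground
  expect_equal(pixels(binarize(img, 100, "auto")),
               matrix(c(0, 1, 0, 1), 2, 2))

  # idempotence: re-thresholding a {0,255} image reproduces the partition
  bin <- GrayImage(matrix(c(0, 255, 255, 0), 2, 2))
  once <- binarize(bin, 127.5)
  again <- binarize(GrayImage(pixels(once) * 255), 127.5)
  expect_equal(pixels(again), pixels(once))

  # binarize(isodata) on a two-level image recovers the two classes exactly
  two <- GrayImage(matrix(c(30, 30, 30, 180, 180, 180, 180, 30, 30), 3, 3))
  mask <- binarize(two, isodataThreshold(two))
  expect_equal(pixels(mask), matrix(as.numeric(pixels(two) == 180), 3, 3))
})

test_that("sobelMagnitude matches a nested-loop convolution oracle", {
  expect_equal(sobelMagnitude(GrayImage(matrix(42, 4, 4))), matrix(0, 4, 4))

  # vertical step edge: strongest response along the step
  step <- matrix(0, 5, 6); step[, 4:6] <- 255
  sm <- sobelMagnitude(GrayImage(step))
  expect_true(all(sm[, 1] == 0) && all(sm[, 6] == 0))
  expect_true(all(sm[, 3] > 0) && all(sm[, 4] > 0))

  set.seed(42)
  m <- matrix(sample(0:255, 25), 5, 5)
  expect_equal(sobelMagnitude(GrayImage(m)), oracleSobel(m), tolerance = 1e-12)

  expect_error(sobelMagnitude(GrayImage(matrix(1:4, 2, 2))), "3x3")
})

test_that("sobelMagnitude is equivariant under 90-degree rotation", {
  set.seed(7)
  m <- matrix(sample(0:255, 64), 8, 8)
  rot90 <- function(a) t(a)[, nrow(a):1]
  a <- rot90(sobelMagnitude(GrayImage(m)))
  b <- sobelMagnitude(GrayImage(rot90(m)))
  # interior only: the replicated border ring differs by construction
  expect_equal(a[2:7, 2:7], b[2:7, 2:7], tolerance = 1e-12)
})

test_that("extractBorder yields the 8-connected inner boundary", {
  m <- matrix(0, 5, 5); m[2:4, 2:4] <- 1
  b <- pixels(extractBorder(BinaryMask(m)))
  expect_equal(sum(b), 8)       # perimeter of the 3x3 block
  expect_equal(b[3, 3], 0)      # center removed

  single <- matrix(0, 4, 4); single[2, 3] <- 1
  expect_equal(pixels(extractBorder(BinaryMask(single))), single)

  expect_error(extractBorder(BinaryMask(matrix(0, 3, 3))), "no object")
})

test_that("disc border matches the boundary-scan oracle and the taxicab perimeter", {
  x <- matrix(rep(1:101, 101), 101); y <- t(x)
  disc <- (x - 51)^2 + (y - 51)^2 <= 50^2
  b <- pixels(extractBorder(BinaryMask(disc)))
  expect_equal(b, oracleBoundary(disc * 1))
  # each boundary move is a unit 4-step, so a digital disc's inner
  # 8-boundary counts ~ the taxicab circumference 8 r
  expect_lt(abs(sum(b) - 8 * 50) / (8 * 50), 0.2)
})

test_that("extractBorder is idempotent and its output has no 8-interior pixel", {
  for (s in 1:5) {
    m <- randomMask(24, 30, p = 0.45, seed = s)
    if (!any(m == 1)) next
    b1 <- extractBorder(BinaryMask(m))
    expect_true(all(pixels(b1) <= m))  # subset of source foreground
    expect_equal(pixels(b1), oracleBoundary(m))
    b2 <- extractBorder(b1)
    expect_equal(pixels(b2), pixels(b1))
  }
})
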