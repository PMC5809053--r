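# Box-counting machinery: scale series, per-grid counts, log-log fit and
# the assembled FD estimator.

test_that("defaultScales yields powers of two capped at 40% of the larger side", {
  expect_equal(defaultScales(512, 512), c(2L, 4L, 8L, 16L, 32L, 64L, 128L))
  expect_equal(max(defaultScales(2187, 600)), 512L)
  expect_error(defaultScales(64, 64), "fewer than 5")
  expect_error(defaultScales(8, 512), "too small")
})

test_that("countBoxes agrees with the nested-loop cell-scan oracle", {
  # exact tiling
  full <- BorderMask(matrix(1, 32, 32))
  expect_equal(countBoxes(full, 16), 4L)

  # single pixel is always one box
  sp <- matrix(0, 32, 32); sp[17, 9] <- 1
  for (eps in c(2, 3, 5, 16)) {
    expect_equal(countBoxes(BorderMask(sp), eps, c(0, 0)), 1L)
    expect_equal(countBoxes(BorderMask(sp), eps, c(eps - 1, 1)), 1L)
  }

  for (s in 1:10) {
    m <- randomMask(32, 32, p = 0.15, seed = 100 + s)
    if (!any(m == 1)) next
    b <- BorderMask(m)
    for (eps in c(2, 3, 4, 7, 8, 13)) {
      for (off in list(c(0, 0), c(1, 0), c(eps - 1, eps - 1),
                       c(eps %/% 2, 1))) {
        expect_equal(countBoxes(b, eps, off), oracleBoxCount(m, eps, off[1], off[2]),
                     info = sprintf("seed %d eps %d off %d,%d", s, eps, off[1], off[2]))
      }
    }
  }

  expect_error(countBoxes(BorderMask(matrix(0, 8, 8)), 2), "empty")
  expect_error(countBoxes(full, 4, c(4, 0)), "offsets")
})

test_that("fitLogLog matches the closed-form OLS oracle", {
  # exact power law N = C / eps
  eps <- c(2, 4, 8, 16, 32, 64)
  f <- fitLogLog(eps, 512 / eps)
  expect_equal(f$slope, -1, tolerance = 1e-12)
  expect_equal(f$rSquared, 1, tolerance = 1e-12)

  # constant counts: slope 0, flat line fits exactly
  f0 <- fitLogLog(eps, rep(7, 6))
  expect_equal(f0$slope, 0, tolerance = 1e-12)
  expect_equal(f0$rSquared, 1)

  counts <- c(973, 311, 97, 34, 12, 5)
  f2 <- fitLogLog(eps, counts)
  o <- oracleOLS(log(eps), log(counts))
  expect_equal(f2$slope, o$slope, tolerance = 1e-12)
  expect_equal(f2$intercept, o$intercept, tolerance = 1e-12)

  expect_error(fitLogLog(c(2, 4, 8, 16), c(8, 4, 2, 1)), "at least 5")
  expect_error(fitLogLog(eps, c(0, 311, 97, 34, 12, 5)), "at least 1")
})

test_that("boxCountFD recovers known dimensions and is deterministic", {
  line <- matrix(0, 512, 512); line[256, ] <- 1
  el <- boxCountFD(BorderMask(line), seed = 3)
  expect_equal(fd(el), 1, tolerance = 0.05)

  sq <- boxCountFD(BorderMask(matrix(1, 256, 256)))
  expect_equal(fd(sq), 2, tolerance = 0.05)

  # single pixel: all counts 1, slope 0, FD 0
  sp <- matrix(0, 128, 128); sp[64, 64] <- 1
  esp <- boxCountFD(BorderMask(sp))
  expect_equal(fd(esp), 0)
  expect_true(any(grepl("out-of-range", fdWarnings(esp))))

  # determinism and offset monotonicity
  m <- randomMask(128, 128, p = 0.05, seed = 9)
  e1 <- boxCountFD(BorderMask(m), seed = 42)
  e2 <- boxCountFD(BorderMask(m), seed = 42)
  expect_identical(boxRecords(e1), boxRecords(e2))
  expect_identical(fd(e1), fd(e2))
  # min over offsets never exceeds the (0,0)-grid count
  expect_true(all(boxRecords(e1)$count <= e1@offsetCounts[, 1]))

  expect_error(boxCountFD(BorderMask(matrix(0, 64, 64))), "empty")
})

test_that("FD is stable under re-rasterization at doubled resolution and under rotation", {
  k5 <- kochCurve(5)
  f1 <- fd(boxCountFD(rasterizePolyline(k5, 1024)))
  f2 <- fd(boxCountFD(rasterizePolyline(k5, 2048)))
  expect_lt(abs(f1 - f2), 0.03)

  th <- 30 * pi / 180
  rot <- k5 %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  f3 <- fd(boxCountFD(rasterizePolyline(rot, 2048)))
  expect_lt(abs(f2 - f3), 0.05)
})

test_that("mean FD decreases as the Hurst exponent rises", {
  means <- vapply(c(0.2, 0.5, 0.8), function(H) {
    mean(vapply(1:20, function(s) {
      p <- fbmProfile(H, 1025, seed = round(100 * H) * 100 + s)
      fd(boxCountFD(rasterizePolyline(p, 384)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})
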