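# Per-patient aggregation and the agreement/association statistics.

test_that("aggregatePatient computes mFD and gFD with the calcification rule", {
  segs <- data.frame(
    patient_id = "p1", side = "right",
    segment = c("common-carotid", "bulb", "internal-carotid", "bulb"),
    fd = c(1.12, 1.14, 1.16, 1.10),
    is_main = c(FALSE, TRUE, FALSE, FALSE),
    calcified_shadow = FALSE)
  a <- aggregatePatient(segs)
  expect_equal(a$mfd, 1.14)
  expect_equal(a$gfd, 1.13)
  expect_equal(a$n_segments, 4L)

  one <- segs[2, ]; one$fd <- 1.137
  a1 <- aggregatePatient(one)
  expect_equal(a1$mfd, 1.137)
  expect_equal(a1$gfd, 1.137)

  # a calcified non-main segment blocks gFD but not mFD
  segs$calcified_shadow[4] <- TRUE
  segs$fd[4] <- NA
  a2 <- aggregatePatient(segs)
  expect_equal(a2$mfd, 1.14)
  expect_true(is.na(a2$gfd))

  segs$is_main <- FALSE
  expect_error(aggregatePatient(segs), "exactly one")
  segs$is_main <- c(TRUE, TRUE, FALSE, FALSE)
  expect_error(aggregatePatient(segs), "exactly one")
})

test_that("fdSpearman matches the no-ties closed form and is monotone-invariant", {
  x <- c(1, 2, 3, 4, 5); y <- c(3, 1, 2, 5, 4)
  r <- fdSpearman(x, y)
  expect_equal(r$rho, oracleSpearmanNoTies(x, y), tolerance = 1e-12)
  expect_equal(r$rho, 0.6)

  # invariance under strictly monotone transforms; perfect for y = x^3
  xs <- c(-2, -1, 0.5, 1, 3, 7)
  expect_equal(fdSpearman(xs, xs^3)$rho, 1)
  expect_equal(fdSpearman(xs, xs)$rho, 1)
  expect_equal(fdSpearman(xs, -xs)$rho, -1)
  expect_equal(fdSpearman(xs, exp(xs))$rho, fdSpearman(xs, xs)$rho)

  # agreement with the reference implementation (tie-corrected rho)
  set.seed(31)
  a <- rnorm(30); b <- a + rnorm(30)
  ref <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
  expect_equal(fdSpearman(a, b)$rho, unname(ref$estimate), tolerance = 1e-12)

  # pairwise deletion
  a[3] <- NA
  expect_equal(fdSpearman(a, b)$n, 29)

  expect_error(fdSpearman(rep(1, 6), 1:6), "constant")
  expect_error(fdSpearman(1:3, 3:1), "at least 4")
})

test_that("iccAgreement matches the ANOVA mean-squares oracle", {
  set.seed(11)
  truth <- rnorm(20, 1.14, 0.04)
  m1 <- truth + rnorm(20, 0, 0.015)
  m2 <- truth + rnorm(20, 0, 0.015)
  r <- iccAgreement(m1, m2)
  expect_equal(r$icc, oracleICC21(m1, m2), tolerance = 1e-10)
  expect_true(r$ci[1] < r$icc && r$icc < r$ci[2])

  # identical raters: perfect agreement
  p <- iccAgreement(truth, truth)
  expect_equal(p$icc, 1)
  expect_equal(p$ci[2], 1)

  # absolute agreement penalizes a constant offset on one rater
  off <- iccAgreement(m1, m2 + 0.05)
  expect_lt(off$icc, r$icc)

  expect_error(iccAgreement(rep(1, 6), rep(1, 6)), "zero total variance")
  expect_error(iccAgreement(1:4, 1:4 + 0.1), "at least 5")
})

test_that("blandAltman and the repeatability coefficient follow the difference formulas", {
  same <- c(1.1, 1.15, 1.2, 1.08)
  b0 <- blandAltman(same, same)
  expect_equal(b0$bias, 0)
  expect_equal(b0$loa, c(0, 0))
  expect_equal(b0$rc, 0)

  d <- c(0.01, -0.01, 0.02, 0.00)
  m2 <- c(1.10, 1.12, 1.15, 1.18)
  ba <- blandAltman(m2 + d, m2)
  # two-pass oracle: mean, then squared deviations with n-1
  mu <- sum(d) / 4
  sdd <- sqrt(sum((d - mu)^2) / 3)
  expect_equal(ba$bias, mu, tolerance = 1e-12)
  expect_equal(ba$rc, 1.96 * sdd, tolerance = 1e-12)
  expect_equal(ba$loa, mu + c(-1.96, 1.96) * sdd, tolerance = 1e-12)
  # rc is exactly half the width of the limits of agreement
  expect_equal(ba$rc, (ba$loa[2] - ba$loa[1]) / 2, tolerance = 1e-15)
  expect_equal(ba$data$difference, d)
  expect_equal(ba$data$mean, m2 + d / 2)

  expect_error(blandAltman(1:2, 2:3), "at least 3")
})

test_that("variationCoefficient is sd(diff)/sqrt(2) over the grand mean", {
  expect_equal(variationCoefficient(c(1.1, 1.2, 1.3), c(1.1, 1.2, 1.3)), 0)

  m1 <- c(1.10, 1.20, 1.16); m2 <- c(1.12, 1.18, 1.15)
  # stepwise closed form
  d <- m1 - m2
  sw <- sqrt(sum((d - mean(d))^2) / 2) / sqrt(2)
  expect_equal(variationCoefficient(m1, m2),
               100 * sw / mean(c(m1, m2)), tolerance = 1e-12)

  expect_error(variationCoefficient(c(-2, -2, -2), c(2, 2, 2)),
               "not positive")
})

test_that("agreementStats bundles a consistent AgreementResult", {
  pairs <- synthPairedMeasures(20, seed = 5)
  res <- agreementStats(pairs$m1, pairs$m2)
  expect_s4_class(res, "AgreementResult")
  expect_equal(unname(icc(res)), iccAgreement(pairs$m1, pairs$m2)$icc,
               ignore_attr = TRUE)
  expect_equal(res@rc, (res@loa[2] - res@loa[1]) / 2)
  expect_equal(res@n, 20L)
  # realistic reproducibility settings give high reliability and CV < 2%
  expect_gt(res@icc, 0.75)
  expect_lt(res@cvPercent, 2)
})

test_that("cohortSummary averages only defined values", {
  pats <- data.frame(patient_id = c("a", "b", "c"),
                     mfd = c(1.1, 1.2, 1.15),
                     gfd = c(1.12, NA, 1.18),
                     n_segments = c(2L, 3L, 1L))
  s <- cohortSummary(pats)
  expect_equal(s$mfd$mean, mean(c(1.1, 1.2, 1.15)))
  expect_equal(s$mfd$n, 3)
  expect_equal(s$gfd$mean, 1.15)
  expect_equal(s$gfd$n, 2)
  pats$gfd <- NA_real_
  expect_error(cohortSummary(pats), "gFD")
})

test_that("aggregate-then-summarize recovers planted cohort means", {
  coh <- synthCohort(60, seed = 77, mfdMean = 1.15, mfdSD = 0.03)
  s <- cohortSummary(aggregateCohort(coh$segments))
  expect_lt(abs(s$mfd$mean - 1.15), 3 * 0.03 / sqrt(60))
  expect_lt(abs(s$mfd$sd - 0.03), 0.015)
})
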