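# Per-patient aggregation of segment fractal dimensions and the
# method-agreement statistics used to validate FD as a measurement:
# Spearman rank correlation, ICC(2,1) with F-based confidence interval,
# Bland-Altman bias and limits of agreement, repeatability coefficient,
# and within-subject coefficient of variation.

segmentColumns <- c("patient_id", "side", "segment", "fd", "is_main",
                    "calcified_shadow")

#' Read a per-segment FD table
#'
#' Expected CSV schema (header required, "." decimal): columns
#' \code{patient_id, side, segment, fd, is_main, calcified_shadow}.
#' \code{fd} may be empty for calcified segments; the flags are 0/1 or
#' TRUE/FALSE.
#'
#' @param path CSV file path.
#' @return data.frame with the schema above.
#' @export
readSegmentTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(segmentColumns, names(df))
  if (length(missing))
    stop("segment table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  df$is_main <- as.logical(df$is_main)
  df$calcified_shadow <- as.logical(df$calcified_shadow)
  df$fd <- as.numeric(df$fd)
  df
}

#' Read a paired-measurements table
#'
#' Expected CSV schema: columns \code{subject_id, m1, m2} holding the two
#' FD measurements of the same plaques (two raters or two sessions).
#'
#' @param path CSV file path.
#' @return data.frame with columns subject_id, m1, m2.
#' @export
readPairedMeasures <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("subject_id", "m1", "m2"), names(df))
  if (length(missing))
    stop("paired-measures table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Aggregate one patient's segment measurements
#'
#' The main-plaque FD (mFD) is the FD of the segment flagged
#' \code{is_main} (the plaque with the highest degree of stenosis). The
#' global FD (gFD) is the arithmetic mean FD over all the patient's
#' atherosclerotic segments; it is undefined (NA) whenever any segment's
#' border is hidden by a calcification shadow, since that segment's FD
#' cannot be measured.
#'
#' @param segments data.frame with the [readSegmentTable()] schema, all
#'   rows belonging to one patient; exactly one row must have
#'   \code{is_main = TRUE}.
#' @return One-row data.frame: \code{patient_id, mfd, gfd, n_segments}.
#' @examples
#' segs <- data.frame(patient_id = "p1", side = "right",
#'   segment = c("common-carotid", "bulb", "internal-carotid", "bulb"),
#'   fd = c(1.12, 1.14, 1.16, 1.10),
#'   is_main = c(FALSE, TRUE, FALSE, FALSE), calcified_shadow = FALSE)
#' aggregatePatient(segs)  # mfd 1.14, gfd 1.13
#' @export
aggregatePatient <- function(segments) {
  if (nrow(segments) < 1L)
    stop("at least one segment measurement is required")
  nMain <- sum(segments$is_main)
  if (nMain != 1L)
    stop("patient ", segments$patient_id[1], " has ", nMain,
         " main-plaque segments; exactly one is required")
  main <- segments[segments$is_main, ]
  mfd <- if (isTRUE(main$calcified_shadow)) NA_real_ else main$fd
  gfd <- if (any(segments$calcified_shadow)) NA_real_
         else mean(segments$fd)
  data.frame(patient_id = segments$patient_id[1], mfd = mfd, gfd = gfd,
             n_segments = nrow(segments))
}

#' Aggregate a whole segment table into per-patient FDs
#'
#' @param segments data.frame with the [readSegmentTable()] schema.
#' @return data.frame with one row per patient
#'   (\code{patient_id, mfd, gfd, n_segments}), ordered by patient_id.
#' @export
aggregateCohort <- function(segments) {
  parts <- split(segments, segments$patient_id)
  out <- do.call(rbind, lapply(parts, aggregatePatient))
  rownames(out) <- NULL
  out[order(out$patient_id), , drop = FALSE]
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Ranks use average ties; rho is the Pearson correlation of the ranks and
#' the two-sided p-value comes from \code{t = rho * sqrt((n-2)/(1-rho^2))}
#' on \code{n - 2} degrees of freedom. Pairs with a missing value in either
#' variable are dropped (pairwise deletion). For small samples without ties
#' an exact p-value is available via \code{exact = TRUE} (delegated to
#' [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length.
#' @param exact use the exact null distribution (n <= 10, no ties).
#' @return List with \code{rho}, \code{p_value} and \code{n} (pairs used).
#' @export
fdSpearman <- function(x, y, exact = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L)
    stop("at least 4 complete pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined: an input vector is constant after deletion")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  hasTies <- anyDuplicated(x) || anyDuplicated(y)
  if (exact && n <= 10L && !hasTies) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tval), df = n - 2)
    }
  }
  list(rho = rho, p_value = p, n = n)
}

# Two-way mean squares for n subjects x 2 raters, used by iccAgreement.
twoWayMeanSquares <- function(m1, m2) {
  x <- cbind(m1, m2)
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  ssr <- k * sum((rowMeans(x) - grand)^2)
  ssc <- n * sum((colMeans(x) - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  list(n = n, k = k,
       msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), sst = sst)
}

#' Intraclass correlation ICC(2,1) with confidence interval
#'
#' Single-measure, absolute-agreement, two-way random-effects intraclass
#' correlation (Shrout-Fleiss ICC(2,1)) computed from the two-way ANOVA
#' mean squares, with the F-distribution confidence interval of McGraw and
#' Wong. Pairs with a missing member are dropped.
#'
#' @param m1,m2 paired measurements (rater/session 1 and 2), at least 5
#'   complete pairs.
#' @param conf confidence level (default 0.95).
#' @return List with \code{icc}, \code{ci} (length 2) and \code{n}.
#' @export
iccAgreement <- function(m1, m2, conf = 0.95) {
  ok <- is.finite(m1) & is.finite(m2)
  m1 <- m1[ok]; m2 <- m2[ok]
  if (length(m1) < 5L)
    stop("at least 5 complete pairs are required for the ICC")
  ms <- twoWayMeanSquares(m1, m2)
  if (ms$sst == 0)
    stop("ICC undefined: zero total variance")
  n <- ms$n; k <- ms$k
  iccVal <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
  alpha <- 1 - conf
  if (ms$mse == 0 && ms$msc == 0) {
    ci <- c(1, 1)  # perfect agreement: no residual or rater variance
  } else {
    fj <- ms$msc / ms$mse
    a <- k * iccVal / (n * (1 - iccVal))
    b <- 1 + k * iccVal * (n - 1) / (n * (1 - iccVal))
    v <- (a * ms$msc + b * ms$mse)^2 /
      ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (ms$msr - fl * ms$mse) /
      (fl * (k * ms$msc + (k * n - n - k) * ms$mse) + n * ms$msr)
    upper <- n * (fu * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - n - k) * ms$mse + n * fu * ms$msr)
    ci <- c(lower, upper)
  }
  list(icc = iccVal, ci = ci, n = n)
}

#' Bland-Altman analysis of paired measurements
#'
#' Differences are taken as \code{d = m1 - m2}. The bias is their mean,
#' the limits of agreement are \code{bias +/- 1.96 sd(d)} (sample standard
#' deviation), and the repeatability coefficient is \code{1.96 sd(d)}.
#' The returned \code{data} (per-pair mean and difference) is the input for
#' the conventional mean-vs-difference plot.
#'
#' @param m1,m2 paired measurements, at least 3 complete pairs.
#' @return List with \code{bias}, \code{loa} (length 2), \code{rc},
#'   \code{n}, and \code{data} (data.frame: mean, difference).
#' @export
blandAltman <- function(m1, m2) {
  ok <- is.finite(m1) & is.finite(m2)
  m1 <- m1[ok]; m2 <- m2[ok]
  if (length(m1) < 3L)
    stop("at least 3 complete pairs are required")
  d <- m1 - m2
  bias <- mean(d)
  sdd <- stats::sd(d)
  list(bias = bias, loa = bias + c(-1.96, 1.96) * sdd, rc = 1.96 * sdd,
       n = length(d),
       data = data.frame(mean = (m1 + m2) / 2, difference = d))
}

#' Within-subject coefficient of variation of paired measurements
#'
#' The within-subject standard deviation for duplicate measurements is
#' \code{sd(m1 - m2) / sqrt(2)}; the coefficient of variation is that
#' divided by the grand mean of all measurements, as a percentage.
#'
#' @param m1,m2 paired measurements, at least 3 complete pairs; the grand
#'   mean must be positive.
#' @return Percent coefficient of variation (single numeric).
#' @export
variationCoefficient <- function(m1, m2) {
  ok <- is.finite(m1) & is.finite(m2)
  m1 <- m1[ok]; m2 <- m2[ok]
  if (length(m1) < 3L)
    stop("at least 3 complete pairs are required")
  grand <- mean(c(m1, m2))
  if (grand <= 0)
    stop("coefficient of variation undefined: grand mean is not positive")
  sw <- stats::sd(m1 - m2) / sqrt(2)
  100 * sw / grand
}

#' All agreement statistics for paired FD measurements
#'
#' Convenience wrapper combining [iccAgreement()], [blandAltman()] and
#' [variationCoefficient()] into one [AgreementResult-class].
#'
#' @param m1,m2 paired measurements, at least 5 complete pairs.
#' @param conf confidence level for the ICC interval.
#' @return An [AgreementResult-class].
#' @examples
#' set.seed(1)
#' truth <- rnorm(20, 1.14, 0.04)
#' agreementStats(truth + rnorm(20, 0, 0.01), truth + rnorm(20, 0, 0.01))
#' @export
agreementStats <- function(m1, m2, conf = 0.95) {
  ic <- iccAgreement(m1, m2, conf = conf)
  ba <- blandAltman(m1, m2)
  cv <- variationCoefficient(m1, m2)
  new("AgreementResult", icc = ic$icc, iccCI = ic$ci, bias = ba$bias,
      loa = ba$loa, rc = ba$rc, cvPercent = cv, n = as.integer(ba$n))
}

#' Cohort summary of per-patient FDs
#'
#' Mean and sample standard deviation of mFD and gFD over patients with a
#' defined value; the per-statistic n reports how many patients contribute
#' (patients whose gFD is undefined because of calcification shadows are
#' excluded from the gFD summary only).
#'
#' @param patients data.frame from [aggregateCohort()] (columns
#'   \code{mfd}, \code{gfd}).
#' @return List with elements \code{mfd} and \code{gfd}, each a list of
#'   \code{mean}, \code{sd}, \code{n}.
#' @export
cohortSummary <- function(patients) {
  summarize <- function(v, name) {
    v <- v[is.finite(v)]
    if (length(v) < 2L)
      stop("fewer than 2 patients with a defined ", name,
           "; cannot summarize")
    list(mean = mean(v), sd = stats::sd(v), n = length(v))
  }
  list(mfd = summarize(patients$mfd, "mFD"),
       gfd = summarize(patients$gfd, "gFD"))
}

#' Correlations between per-patient FD and clinical variables
#'
#' Runs [fdSpearman()] of mFD (and gFD when present) against each requested
#' clinical column, with pairwise deletion per test. Columns that are
#' absent, constant, or leave fewer than 4 complete pairs are skipped with
#' a warning.
#'
#' @param patients data.frame from [aggregateCohort()].
#' @param clinical data.frame with a \code{patient_id} column plus clinical
#'   columns (e.g. hdl_c, triglycerides, trig_to_hdl).
#' @param columns clinical column names to test; default all numeric
#'   columns except patient_id.
#' @return data.frame with columns fd_measure, variable, rho, p_value, n.
#' @export
cohortCorrelations <- function(patients, clinical, columns = NULL) {
  merged <- merge(patients, clinical, by = "patient_id")
  if (is.null(columns)) {
    columns <- setdiff(names(clinical)[vapply(clinical, is.numeric,
                                              logical(1))], "patient_id")
  }
  rows <- list()
  for (fdcol in intersect(c("mfd", "gfd"), names(merged))) {
    for (cl in columns) {
      if (!cl %in% names(merged)) {
        warning("clinical column '", cl, "' not found; skipped")
        next
      }
      res <- tryCatch(fdSpearman(merged[[fdcol]], merged[[cl]]),
                      error = function(e) {
                        warning("correlation ", fdcol, " ~ ", cl,
                                " skipped: ", conditionMessage(e))
                        NULL
                      })
      if (!is.null(res))
        rows[[length(rows) + 1L]] <- data.frame(
          fd_measure = fdcol, variable = cl, rho = res$rho,
          p_value = res$p_value, n = res$n)
    }
  }
  if (!length(rows))
    return(data.frame(fd_measure = character(), variable = character(),
                      rho = numeric(), p_value = numeric(), n = integer()))
  do.call(rbind, rows)
}
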