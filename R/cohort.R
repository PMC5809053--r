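# Synthetic cohort generator. Emulates the study conditions under which
# plaque-border FD was validated clinically: ~42 asymptomatic patients with
# non-obstructive carotid stenosis, a median of 4 atherosclerotic segments
# each, main-plaque FD ~ 1.136 +/- 0.039, HDL-C median ~41 mg/dL
# (IQR 36-47), triglycerides median ~133 mg/dL (IQR 99-164), and a planted
# inverse monotone association between mFD and HDL-C.

#' Synthetic patient cohort with a planted FD-lipid association
#'
#' Generates a per-segment FD table and a per-patient clinical table whose
#' marginals emulate an asymptomatic carotid-stenosis cohort: main-plaque
#' fractal dimension centered at \code{mfdMean} with SD \code{mfdSD},
#' log-normal HDL-C and triglycerides, and a planted latent correlation of
#' \code{-assoc} between mFD and log HDL-C (low HDL-C goes with a more
#' irregular border). A fraction of patients carry one non-main segment
#' whose border is hidden by a calcification shadow (FD unmeasurable, so
#' their gFD is undefined).
#'
#' @param nPatients number of patients (default 42).
#' @param seed RNG seed; the cohort is a pure function of (parameters, seed).
#' @param mfdMean,mfdSD distribution of main-plaque FD (defaults 1.136,
#'   0.039).
#' @param assoc magnitude of the planted (negative) latent correlation
#'   between mFD and log HDL-C, in [0, 1) (default 0.4).
#' @param segmentSD within-patient SD of non-main segment FDs around the
#'   patient's main FD (default 0.03).
#' @param calcifiedFrac fraction of patients with one calcified non-main
#'   segment (default 0.1).
#' @return List with \code{segments} (the [readSegmentTable()] schema) and
#'   \code{clinical} (patient_id, hdl_c, ldl_c, total_chol, triglycerides,
#'   trig_to_hdl, statin_use).
#' @examples
#' coh <- synthCohort(42, seed = 1)
#' head(aggregateCohort(coh$segments))
#' @export
synthCohort <- function(nPatients = 42, seed, mfdMean = 1.136,
                        mfdSD = 0.039, assoc = 0.4, segmentSD = 0.03,
                        calcifiedFrac = 0.1) {
  if (missing(seed)) stop("a seed is required: the cohort is stochastic")
  if (assoc < 0 || assoc >= 1) stop("assoc must lie in [0, 1)")
  withSeed(seed, {
    ids <- sprintf("p%03d", seq_len(nPatients))
    zHdl <- stats::rnorm(nPatients)
    hdl <- exp(log(41) + 0.2 * zHdl)
    trig <- exp(log(133) + 0.35 * stats::rnorm(nPatients))
    ldl <- pmax(stats::rnorm(nPatients, 103, 26), 20)
    totChol <- pmax(stats::rnorm(nPatients, 175, 32), 80)
    statin <- stats::runif(nPatients) < 0.57
    mfd <- mfdMean +
      mfdSD * (-assoc * zHdl + sqrt(1 - assoc^2) * stats::rnorm(nPatients))

    nSeg <- sample(1:6, nPatients, replace = TRUE,
                   prob = c(0.05, 0.10, 0.20, 0.30, 0.20, 0.15))
    calcified <- stats::runif(nPatients) < calcifiedFrac & nSeg >= 2

    segs <- lapply(seq_len(nPatients), function(i) {
      k <- nSeg[i]
      fds <- c(mfd[i], mfd[i] + stats::rnorm(k - 1, 0, segmentSD))
      calc <- rep(FALSE, k)
      if (calcified[i]) {
        j <- sample(2:k, 1)
        calc[j] <- TRUE
        fds[j] <- NA_real_
      }
      data.frame(
        patient_id = ids[i],
        side = sample(c("left", "right"), k, replace = TRUE),
        segment = sample(c("common-carotid", "bulb", "internal-carotid"),
                         k, replace = TRUE),
        fd = fds,
        is_main = c(TRUE, rep(FALSE, k - 1)),
        calcified_shadow = calc
      )
    })
    clinical <- data.frame(
      patient_id = ids, hdl_c = hdl, ldl_c = ldl, total_chol = totChol,
      triglycerides = trig, trig_to_hdl = trig / hdl, statin_use = statin
    )
    list(segments = do.call(rbind, segs), clinical = clinical)
  })
}

#' Synthetic paired FD measurements for reproducibility studies
#'
#' Emulates repeated FD readings of the same plaques by two raters (or two
#' sessions): each subject's true FD is drawn from
#' \code{Normal(mfdMean, mfdSD)} and each reading adds independent
#' measurement noise of SD \code{withinSD}. The default \code{withinSD} of
#' 0.0145 yields a repeatability coefficient near 0.04 and an ICC near 0.9,
#' the order of magnitude expected for a usable border measurement.
#'
#' @param nSubjects number of plaques measured twice (default 20).
#' @param seed RNG seed.
#' @param mfdMean,mfdSD distribution of true FD (defaults 1.136, 0.039).
#' @param withinSD per-reading measurement SD (default 0.0145).
#' @return data.frame with columns subject_id, m1, m2.
#' @export
synthPairedMeasures <- function(nSubjects = 20, seed, mfdMean = 1.136,
                                mfdSD = 0.039, withinSD = 0.0145) {
  if (missing(seed)) stop("a seed is required")
  withSeed(seed, {
    truth <- stats::rnorm(nSubjects, mfdMean, mfdSD)
    data.frame(
      subject_id = sprintf("s%03d", seq_len(nSubjects)),
      m1 = truth + stats::rnorm(nSubjects, 0, withinSD),
      m2 = truth + stats::rnorm(nSubjects, 0, withinSD)
    )
  })
}
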