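# Box-counting fractal dimension of a border raster.
# The raster is covered with square grids of side epsilon; for each side the
# number of occupied cells is minimized over several grid offsets (grid
# placement bias reduction), and FD is minus the slope of the OLS fit of
# log(count) on log(epsilon).

# Evaluate code under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default box-side series for a raster
#'
#' Powers of two from 2 up to the largest power not exceeding 40\% of the
#' larger raster dimension. At least five scales are required for a stable
#' log-log fit.
#'
#' @param height,width raster dimensions in pixels (smaller one at least 16).
#' @return Integer vector of box sides (px), strictly increasing.
#' @examples
#' defaultScales(512, 512)  # 2 4 8 16 32 64 128
#' @export
defaultScales <- function(height, width) {
  if (min(height, width) < 16)
    stop("raster too small for box counting (min dimension < 16); ",
         "consider upsampling or embedding in a larger canvas")
  kmax <- floor(log2(0.4 * max(height, width)))
  if (kmax < 5)
    stop("fewer than 5 box scales fit this raster; ",
         "consider upsampling the image")
  as.integer(2^(1:kmax))
}

validateScales <- function(scales, height, width) {
  if (length(scales) < 5L)
    stop("at least 5 box scales are required")
  if (any(scales < 2))
    stop("box sides must be at least 2 px")
  if (any(diff(scales) <= 0))
    stop("box sides must be strictly increasing")
  if (max(scales) > 0.45 * max(height, width))
    stop("largest box side exceeds 45% of the larger raster dimension")
  as.integer(scales)
}

#' Count occupied boxes for one grid
#'
#' Counts the cells of the square grid of side \code{epsilon}, anchored at
#' \code{(-offset[1], -offset[2])}, that contain at least one border pixel.
#'
#' @param border a [BorderMask-class] with at least one foreground pixel.
#' @param epsilon box side in pixels.
#' @param offset integer length-2 (row shift, col shift), each in
#'   \code{[0, epsilon)}.
#' @return Integer count, between 1 and the number of border pixels.
#' @export
countBoxes <- function(border, epsilon, offset = c(0L, 0L)) {
  m <- pixels(border)
  idx <- which(m == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("empty border: nothing to count")
  if (epsilon < 1) stop("box side must be at least 1")
  if (any(offset < 0) || any(offset >= epsilon))
    stop("grid offsets must lie in [0, epsilon)")
  br <- (idx[, 1] - 1L + offset[1]) %/% epsilon
  bc <- (idx[, 2] - 1L + offset[2]) %/% epsilon
  length(unique(br * (max(bc) + 1) + bc))
}

#' Ordinary least-squares fit of log(count) on log(epsilon)
#'
#' @param epsilon box sides (at least 5).
#' @param count occupied-box counts, all at least 1.
#' @return List with \code{slope}, \code{intercept} and \code{rSquared}
#'   (squared correlation; defined as 1 when the counts are constant, i.e.
#'   the flat line fits exactly).
#' @export
fitLogLog <- function(epsilon, count) {
  if (length(epsilon) < 5L)
    stop("at least 5 (epsilon, count) records are required for the fit")
  if (length(count) != length(epsilon))
    stop("epsilon and count must have the same length")
  if (any(count < 1))
    stop("all box counts must be at least 1")
  x <- log(epsilon); y <- log(count)
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::sd(y) == 0) 1 else stats::cor(x, y)^2
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       rSquared = r2)
}

#' Box-counting fractal dimension of a border raster
#'
#' For every box side, the occupied-box count is taken as the minimum over
#' \code{nOffsets} grid placements: the un-shifted grid plus
#' \code{nOffsets - 1} offsets drawn uniformly from \code{[0, epsilon)^2}
#' with the given seed. FD is minus the slope of the ordinary least-squares
#' fit of log(count) on log(epsilon). Identical inputs and seed give an
#' identical estimate.
#'
#' Quality flags recorded on the estimate (never fatal): \code{"low-r2"}
#' when the log-log fit has squared correlation below 0.9, and
#' \code{"fd-out-of-range"} when the estimate falls outside [0.9, 2.1],
#' which for a plaque border usually indicates a segmentation failure.
#'
#' @param border a [BorderMask-class].
#' @param scales box sides, or \code{NULL} for [defaultScales()] of the
#'   raster. User-supplied scales must be strictly increasing, at least 2 px,
#'   at least five of them, and at most 45\% of the larger raster dimension.
#' @param nOffsets grid placements per box side (at least 1; default 10).
#' @param seed RNG seed for the random offsets (default 0).
#' @param aggregate \code{"min"} (default): per-scale count is the minimum
#'   over offsets, then one FD is fitted; \code{"mean-fd"}: one FD is fitted
#'   per offset (each offset's own counts) and the FDs averaged.
#' @return An [FDEstimate-class].
#' @examples
#' m <- matrix(0, 64, 512); m[32, ] <- 1  # straight line
#' fd(boxCountFD(BorderMask(m)))          # ~1
#' @export
boxCountFD <- function(border, scales = NULL, nOffsets = 10L, seed = 0L,
                       aggregate = c("min", "mean-fd")) {
  aggregate <- match.arg(aggregate)
  m <- pixels(border)
  if (!any(m == 1))
    stop("empty border: nothing to measure")
  if (nOffsets < 1L)
    stop("nOffsets must be at least 1")
  scales <- if (is.null(scales)) defaultScales(nrow(m), ncol(m))
            else validateScales(scales, nrow(m), ncol(m))
  nOffsets <- as.integer(nOffsets)
  seed <- as.integer(seed)

  counts <- withSeed(seed, {
    vapply(scales, function(eps) {
      offs <- cbind(0L, 0L)
      if (nOffsets > 1L) {
        extra <- cbind(sample.int(eps, nOffsets - 1L, replace = TRUE) - 1L,
                       sample.int(eps, nOffsets - 1L, replace = TRUE) - 1L)
        offs <- rbind(offs, extra)
      }
      apply(offs, 1, function(o) countBoxes(border, eps, o))
    }, numeric(nOffsets))
  })
  counts <- matrix(counts, nrow = nOffsets)  # scales in columns
  offsetCounts <- t(counts)                  # rows = scales

  if (aggregate == "min") {
    perScale <- apply(offsetCounts, 1, min)
    fit <- fitLogLog(scales, perScale)
    fdVal <- -fit$slope
  } else {
    fits <- apply(offsetCounts, 2, function(ct) fitLogLog(scales, ct)$slope)
    fdVal <- -mean(fits)
    perScale <- apply(offsetCounts, 1, min)
    fit <- fitLogLog(scales, perScale)
    fit$slope <- -fdVal
    fit$intercept <- mean(log(perScale)) + fdVal * mean(log(scales))
  }

  warn <- character()
  if (is.finite(fit$rSquared) && fit$rSquared < 0.9)
    warn <- c(warn, "low-r2: log-log fit has R^2 < 0.9")
  if (fdVal < 0.9 || fdVal > 2.1)
    warn <- c(warn, "fd-out-of-range: estimate outside [0.9, 2.1]; possible segmentation failure")

  new("FDEstimate",
      fd = fdVal, slope = -fdVal, intercept = fit$intercept,
      rSquared = fit$rSquared,
      records = data.frame(epsilon = scales, count = perScale),
      offsetCounts = offsetCounts, nOffsets = nOffsets, seed = seed,
      warnings = warn)
}

#' Serialize an FD estimate to JSON
#'
#' @param est an [FDEstimate-class].
#' @param config optional named list (run configuration) embedded verbatim
#'   for provenance.
#' @return A JSON string.
#' @export
fdToJSON <- function(est, config = NULL) {
  out <- list(
    fd = est@fd, slope = est@slope, intercept = est@intercept,
    r_squared = est@rSquared,
    scales = est@records$epsilon, counts = est@records$count,
    n_offsets = est@nOffsets, seed = est@seed,
    warnings = est@warnings,
    package_version = as.character(utils::packageVersion("plaquefractal"))
  )
  if (!is.null(config)) out$config <- config
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null")
}
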