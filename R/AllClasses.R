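#' @import methods
NULL

#' GrayImage: an 8-bit grayscale raster
#'
#' A thin S4 wrapper around a numeric matrix holding pixel intensities in
#' 0--255. Rows are image rows (top to bottom), columns are image columns
#' (left to right). All pipeline stages operate on this container.
#'
#' @slot .Data numeric matrix of intensities in [0, 255].
#' @seealso [readGrayImage()], [cropRoi()], [isodataThreshold()]
#' @export
setClass("GrayImage", contains = "matrix", validity = function(object) {
  m <- object@.Data
  if (length(dim(m)) != 2L)
    return("pixel grid must be a 2-D matrix")
  if (nrow(m) < 2L || ncol(m) < 2L)
    return("image must be at least 2x2 pixels")
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m)))
    return("pixel values must be finite numbers")
  if (any(m < 0) || any(m > 255))
    return("pixel values must lie in [0, 255]")
  TRUE
})

#' Construct a GrayImage from a matrix
#'
#' @param pixels numeric matrix with values in [0, 255].
#' @return A [GrayImage-class] object.
#' @examples
#' img <- GrayImage(matrix(c(0, 255, 255, 0), 2, 2))
#' @export
GrayImage <- function(pixels) {
  new("GrayImage", as.matrix(pixels))
}

#' BinaryMask: a 0/1 raster marking object pixels
#'
#' Product of thresholding a [GrayImage-class]; 1 marks plaque (foreground)
#' pixels, 0 background.
#'
#' @slot .Data numeric matrix with values in \{0, 1\}.
#' @seealso [binarize()], [extractBorder()]
#' @export
setClass("BinaryMask", contains = "matrix", validity = function(object) {
  m <- object@.Data
  if (length(dim(m)) != 2L)
    return("mask must be a 2-D matrix")
  if (anyNA(m) || !all(m %in% c(0, 1)))
    return("mask values must be exactly 0 or 1")
  TRUE
})

#' Construct a BinaryMask
#'
#' @param pixels matrix of 0/1 (logical matrices are coerced).
#' @return A [BinaryMask-class] object.
#' @export
BinaryMask <- function(pixels) {
  m <- as.matrix(pixels)
  storage.mode(m) <- "double"
  new("BinaryMask", m)
}

#' BorderMask: a thin binary curve raster
#'
#' Marks the border pixels of an object: the foreground pixels of a
#' [BinaryMask-class] that touch background through 8-adjacency. This is the
#' raster whose fractal dimension is measured.
#'
#' @seealso [extractBorder()], [boxCountFD()], [rasterizePolyline()]
#' @export
setClass("BorderMask", contains = "BinaryMask")

#' Construct a BorderMask
#'
#' @param pixels matrix of 0/1 (logical matrices are coerced).
#' @return A [BorderMask-class] object.
#' @export
BorderMask <- function(pixels) {
  m <- as.matrix(pixels)
  storage.mode(m) <- "double"
  new("BorderMask", m)
}

#' FDEstimate: result of a box-counting fractal dimension fit
#'
#' Holds the estimated fractal dimension together with the full evidence:
#' box sides, occupied-box counts (minimum over grid offsets, and the full
#' per-offset count matrix), the log-log regression, and any quality
#' warnings (poor fit, estimate outside the plausible curve range).
#'
#' @slot fd fractal dimension; equals \code{-slope}.
#' @slot slope,intercept ordinary least-squares fit of
#'   \code{log(count) ~ log(epsilon)}.
#' @slot rSquared squared correlation of the fit, in [0, 1].
#' @slot records data.frame with columns \code{epsilon} and \code{count}
#'   (count = minimum over grid offsets for that box side).
#' @slot offsetCounts integer matrix, one row per box side and one column
#'   per grid offset; column 1 is the un-shifted (0,0) grid.
#' @slot nOffsets number of grid offsets used per box side.
#' @slot seed RNG seed used to draw the random grid offsets.
#' @slot warnings character vector of quality flags (may be empty).
#' @seealso [boxCountFD()], [fd()]
#' @export
setClass("FDEstimate",
  representation(
    fd = "numeric", slope = "numeric", intercept = "numeric",
    rSquared = "numeric", records = "data.frame",
    offsetCounts = "matrix", nOffsets = "integer", seed = "integer",
    warnings = "character"
  ),
  validity = function(object) {
    if (length(object@fd) != 1L || !is.finite(object@fd))
      return("fd must be a single finite number")
    if (abs(object@fd + object@slope) > 1e-9)
      return("fd must equal -slope")
    if (object@fd < -1e-9 || object@fd > 2.2)
      return("fd outside the plausible [0, 2.2] range for planar rasters")
    if (!is.na(object@rSquared) &&
        (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12))
      return("rSquared must lie in [0, 1]")
    if (!all(c("epsilon", "count") %in% names(object@records)))
      return("records must have columns epsilon and count")
    TRUE
  }
)

#' AgreementResult: reliability statistics for paired FD measurements
#'
#' Bundle of the agreement statistics computed from paired measurements of
#' the same plaques (two raters, or two sessions of one rater): intraclass
#' correlation with its 95\% confidence interval, Bland-Altman bias and
#' limits of agreement, the repeatability coefficient and the within-subject
#' coefficient of variation.
#'
#' @slot icc single-measure, absolute-agreement, two-way random-effects
#'   intraclass correlation (Shrout-Fleiss ICC(2,1)).
#' @slot iccCI numeric length-2 confidence interval for the ICC.
#' @slot bias mean difference m1 - m2.
#' @slot loa numeric length-2 limits of agreement, bias +/- 1.96 sd(diff).
#' @slot rc repeatability coefficient, 1.96 sd(diff).
#' @slot cvPercent within-subject coefficient of variation, percent.
#' @slot n number of complete pairs used.
#' @seealso [agreementStats()], [iccAgreement()], [blandAltman()]
#' @export
setClass("AgreementResult",
  representation(
    icc = "numeric", iccCI = "numeric", bias = "numeric",
    loa = "numeric", rc = "numeric", cvPercent = "numeric", n = "integer"
  ),
  validity = function(object) {
    if (object@icc < -1 - 1e-9 || object@icc > 1 + 1e-9)
      return("icc must lie in [-1, 1]")
    if (length(object@loa) != 2L || length(object@iccCI) != 2L)
      return("loa and iccCI must have length 2")
    if (abs(mean(object@loa) - object@bias) > 1e-9)
      return("limits of agreement must be symmetric about the bias")
    if (object@rc < 0)
      return("repeatability coefficient must be non-negative")
    if (object@cvPercent < 0)
      return("coefficient of variation must be non-negative")
    TRUE
  }
)

setMethod("show", "GrayImage", function(object) {
  m <- object@.Data
  cat(sprintf("GrayImage: %d x %d pixels, intensity range [%g, %g]\n",
              nrow(m), ncol(m), min(m), max(m)))
})

setMethod("show", "BinaryMask", function(object) {
  m <- object@.Data
  cat(sprintf("%s: %d x %d, %d foreground pixel(s)\n",
              class(object), nrow(m), ncol(m), sum(m == 1)))
})

setMethod("show", "FDEstimate", function(object) {
  cat("Box-counting fractal dimension estimate\n")
  cat(sprintf("  FD      : %.4f  (slope %.4f, intercept %.3f, R^2 %.4f)\n",
              object@fd, object@slope, object@intercept, object@rSquared))
  cat(sprintf("  scales  : %s px\n",
              paste(object@records$epsilon, collapse = ", ")))
  cat(sprintf("  counts  : %s\n",
              paste(object@records$count, collapse = ", ")))
  cat(sprintf("  offsets : %d per scale (seed %d)\n",
              object@nOffsets, object@seed))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "AgreementResult", function(object) {
  cat("Agreement statistics for paired FD measurements\n")
  cat(sprintf("  n pairs : %d\n", object@n))
  cat(sprintf("  ICC(2,1): %.3f  (95%% CI %.3f - %.3f)\n",
              object@icc, object@iccCI[1], object@iccCI[2]))
  cat(sprintf("  bias    : %.4f  (LoA %.4f to %.4f)\n",
              object@bias, object@loa[1], object@loa[2]))
  cat(sprintf("  RC      : %.4f\n", object@rc))
  cat(sprintf("  CV      : %.2f%%\n", object@cvPercent))
})
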