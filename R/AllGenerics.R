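#' Extract the fractal dimension from an estimate
#'
#' @param object an [FDEstimate-class].
#' @return Numeric fractal dimension (equal to minus the log-log slope).
#' @export
setGeneric("fd", function(object) standardGeneric("fd"))

#' @describeIn fd fractal dimension of a box-counting estimate
#' @export
setMethod("fd", "FDEstimate", function(object) object@fd)

#' Box-count records of an estimate
#'
#' @param object an [FDEstimate-class].
#' @return data.frame with columns \code{epsilon} (box side, px) and
#'   \code{count} (occupied boxes, minimum over grid offsets).
#' @export
setGeneric("boxRecords", function(object) standardGeneric("boxRecords"))

#' @describeIn boxRecords records of a box-counting estimate
#' @export
setMethod("boxRecords", "FDEstimate", function(object) object@records)

#' Goodness of fit of the log-log regression
#'
#' @param object an [FDEstimate-class].
#' @return Squared correlation of the log-log fit, in [0, 1].
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' @describeIn rSquared fit quality of a box-counting estimate
#' @export
setMethod("rSquared", "FDEstimate", function(object) object@rSquared)

#' Quality warnings attached to an estimate
#'
#' @param object an [FDEstimate-class].
#' @return Character vector of warnings (empty when the fit is clean).
#' @export
setGeneric("fdWarnings", function(object) standardGeneric("fdWarnings"))

#' @describeIn fdWarnings warnings of a box-counting estimate
#' @export
setMethod("fdWarnings", "FDEstimate", function(object) object@warnings)

#' Pixel matrix of a raster object
#'
#' @param object a [GrayImage-class], [BinaryMask-class] or
#'   [BorderMask-class].
#' @return The underlying numeric matrix.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @describeIn pixels pixel matrix of a grayscale image
#' @export
setMethod("pixels", "GrayImage", function(object) object@.Data)

#' @describeIn pixels pixel matrix of a binary mask
#' @export
setMethod("pixels", "BinaryMask", function(object) object@.Data)

#' Intraclass correlation of an agreement result
#'
#' @param object an [AgreementResult-class].
#' @return Numeric ICC(2,1); \code{attr(, "ci")} holds the 95\% interval.
#' @export
setGeneric("icc", function(object) standardGeneric("icc"))

#' @describeIn icc ICC of an agreement result
#' @export
setMethod("icc", "AgreementResult", function(object) {
  structure(object@icc, ci = object@iccCI)
})
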