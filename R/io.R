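# Image input/output and ROI handling.
# PNG via the png package, TIFF via the tiff package; both return arrays
# scaled to [0,1], which we rescale to the 8-bit range. RGB input is
# converted to gray by the plain channel mean.

#' Read an 8-bit grayscale image
#'
#' Reads a PNG or TIFF raster and returns it as a [GrayImage-class]. RGB
#' images are converted to grayscale by averaging the three channels; an
#' alpha channel, if present, is dropped. Values are rescaled to 0--255 and
#' rounded to integers.
#'
#' @param path path to a \code{.png}, \code{.tif} or \code{.tiff} file.
#' @return A [GrayImage-class].
#' @examples
#' f <- tempfile(fileext = ".png")
#' writeGrayImage(GrayImage(matrix(c(0, 255, 255, 0), 2, 2)), f)
#' readGrayImage(f)
#' @export
readGrayImage <- function(path) {
  if (!file.exists(path))
    stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      stop("unsupported image format '", ext, "' for ", path,
           " (expected png/tif/tiff)")
    ),
    error = function(e) stop("failed to decode image ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    if (nch >= 3L) {
      arr <- (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3
    } else {
      arr <- arr[, , 1]
    }
  }
  if (length(arr) == 0L || is.null(dim(arr)))
    stop("image has zero area: ", path)
  GrayImage(round(arr * 255))
}

#' Write a raster to a PNG or TIFF file
#'
#' @param img a [GrayImage-class], [BinaryMask-class] or [BorderMask-class];
#'   masks are written with foreground as white (255).
#' @param path output path; format chosen by extension (png/tif/tiff).
#' @return \code{path}, invisibly.
#' @export
writeGrayImage <- function(img, path) {
  m <- if (is(img, "BinaryMask")) pixels(img) * 255 else pixels(img)
  arr <- m / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    stop("unsupported image format '", ext, "' (expected png/tif/tiff)")
  )
  invisible(path)
}

#' Crop a rectangular region of interest
#'
#' Coordinates are 0-based and half-open: the ROI covers rows
#' \code{row0 .. row0+height-1} and columns \code{col0 .. col0+width-1} of
#' the source image.
#'
#' @param img a [GrayImage-class].
#' @param row0,col0 0-based top-left pixel of the ROI.
#' @param height,width ROI extent in pixels (each at least 2).
#' @return The cropped [GrayImage-class].
#' @export
cropRoi <- function(img, row0, col0, height, width) {
  m <- pixels(img)
  if (row0 < 0 || col0 < 0)
    stop("ROI origin must be non-negative (got row0=", row0,
         ", col0=", col0, ")")
  if (height < 2 || width < 2)
    stop("ROI must be at least 2x2 pixels")
  if (row0 + height > nrow(m))
    stop("ROI extends past the bottom edge: row0+height = ", row0 + height,
         " > image height ", nrow(m))
  if (col0 + width > ncol(m))
    stop("ROI extends past the right edge: col0+width = ", col0 + width,
         " > image width ", ncol(m))
  GrayImage(m[(row0 + 1):(row0 + height), (col0 + 1):(col0 + width),
              drop = FALSE])
}

#' Parse a "row0,col0,height,width" ROI string
#'
#' Convenience for command-line use.
#'
#' @param s character like \code{"10,20,100,200"}.
#' @return Named numeric vector with elements row0, col0, height, width.
#' @export
parseRoi <- function(s) {
  v <- suppressWarnings(as.numeric(strsplit(s, ",")[[1]]))
  if (length(v) != 4L || anyNA(v))
    stop("ROI must be four comma-separated integers: row0,col0,height,width")
  names(v) <- c("row0", "col0", "height", "width")
  v
}
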