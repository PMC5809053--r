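# End-to-end pipeline: image -> ROI crop -> automatic threshold ->
# binarize -> border extraction -> box-counting FD, plus batch processing
# of a manifest of images into segment and per-patient tables.

#' Pipeline run configuration
#'
#' Collects every tunable of the image-to-FD pipeline with its default.
#' The full configuration is embedded in result JSON for provenance.
#'
#' @param roi optional ROI as c(row0, col0, height, width), 0-based.
#' @param threshold manual threshold level, or NULL for the automatic
#'   iterative-intermeans threshold.
#' @param polarity foreground polarity passed to [binarize()].
#' @param minComponent drop foreground components smaller than this many
#'   pixels before border extraction (0 = off, the default: no despeckling).
#' @param scales box sides for [boxCountFD()], or NULL for the default
#'   power-of-two series.
#' @param nOffsets,seed grid offsets per scale and their RNG seed.
#' @param aggregate offset aggregation mode, \code{"min"} or
#'   \code{"mean-fd"}.
#' @return Named list of class \code{fdConfig}.
#' @export
fdConfig <- function(roi = NULL, threshold = NULL,
                     polarity = c("auto", "bright", "dark"),
                     minComponent = 0L, scales = NULL, nOffsets = 10L,
                     seed = 0L, aggregate = c("min", "mean-fd")) {
  structure(list(
    roi = roi, threshold = threshold, polarity = match.arg(polarity),
    minComponent = as.integer(minComponent), scales = scales,
    nOffsets = as.integer(nOffsets), seed = as.integer(seed),
    aggregate = match.arg(aggregate)
  ), class = "fdConfig")
}

#' Measure the plaque-border fractal dimension of an image
#'
#' Runs the full pipeline on a grayscale image: optional ROI crop,
#' automatic (or manual) threshold, binarization, optional small-component
#' removal, inner-border extraction, and box-counting FD estimation.
#'
#' @param img a [GrayImage-class] (see [readGrayImage()]).
#' @param config an [fdConfig()].
#' @param full if TRUE, also return the intermediate rasters.
#' @return With \code{full = FALSE} (default) an [FDEstimate-class]; with
#'   \code{full = TRUE} a list \code{estimate, threshold, mask, border}.
#' @examples
#' sp <- synthPlaqueImage(fbmProfile(0.5, 513, seed = 7), 256, 512)
#' fd(plaqueBorderFD(sp$image))
#' @export
plaqueBorderFD <- function(img, config = fdConfig(), full = FALSE) {
  if (!is.null(config$roi)) {
    r <- config$roi
    img <- cropRoi(img, r[1], r[2], r[3], r[4])
  }
  thr <- if (is.null(config$threshold)) isodataThreshold(img)
         else config$threshold
  mask <- binarize(img, thr, config$polarity)
  if (config$minComponent > 0L)
    mask <- dropSmallComponents(mask, config$minComponent)
  border <- extractBorder(mask)
  est <- boxCountFD(border, scales = config$scales,
                    nOffsets = config$nOffsets, seed = config$seed,
                    aggregate = config$aggregate)
  if (full)
    list(estimate = est, threshold = thr, mask = mask, border = border)
  else est
}

manifestColumns <- c("image", "patient_id", "side", "segment", "is_main",
                     "calcified_shadow")

#' Read a batch manifest
#'
#' Expected CSV schema: columns \code{image, patient_id, side, segment,
#' is_main, calcified_shadow}, plus an optional \code{roi} column holding
#' "row0,col0,height,width" strings.
#'
#' @param path CSV file path.
#' @return data.frame with the schema above.
#' @export
readManifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(manifestColumns, names(df))
  if (length(missing))
    stop("manifest ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  df$is_main <- as.logical(df$is_main)
  df$calcified_shadow <- as.logical(df$calcified_shadow)
  df
}

#' Batch-process a manifest of plaque images
#'
#' Measures the border FD of every non-calcified segment image and
#' aggregates per-patient mFD/gFD. Rows flagged \code{calcified_shadow}
#' are kept with an empty FD (the border cannot be measured). A missing or
#' unreadable image is recorded in the row's \code{error} column and the
#' run continues. Output rows are ordered by (patient_id, side, segment),
#' so results do not depend on manifest row order.
#'
#' @param manifest data.frame with the [readManifest()] schema.
#' @param config an [fdConfig()] applied to every image (a per-row
#'   \code{roi} column overrides \code{config$roi}).
#' @return List with \code{segments} (manifest columns + fd, r_squared,
#'   error) and \code{patients} (from [aggregateCohort()], computed over
#'   error-free patients).
#' @export
runBatch <- function(manifest, config = fdConfig()) {
  missing <- setdiff(manifestColumns, names(manifest))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  if (any(!manifest$calcified_shadow & !file.exists(manifest$image))) {
    # per-row errors recorded below; a malformed manifest (bad flags) aborts
  }
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    out <- data.frame(patient_id = row$patient_id, side = row$side,
                      segment = row$segment, is_main = row$is_main,
                      calcified_shadow = row$calcified_shadow,
                      fd = NA_real_, r_squared = NA_real_,
                      error = NA_character_)
    if (isTRUE(row$calcified_shadow)) return(out)
    cfg <- config
    if (!is.null(row$roi) && !is.na(row$roi) && nzchar(row$roi))
      cfg$roi <- parseRoi(row$roi)
    res <- tryCatch({
      est <- plaqueBorderFD(readGrayImage(row$image), cfg)
      out$fd <- fd(est)
      out$r_squared <- rSquared(est)
      out
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
    res
  })
  segments <- do.call(rbind, rows)
  segments <- segments[order(segments$patient_id, segments$side,
                             segments$segment), , drop = FALSE]
  rownames(segments) <- NULL
  clean <- segments[is.na(segments$error), , drop = FALSE]
  badPatients <- unique(segments$patient_id[!is.na(segments$error)])
  clean <- clean[!clean$patient_id %in% badPatients, , drop = FALSE]
  patients <- if (nrow(clean)) aggregateCohort(clean) else
    data.frame(patient_id = character(), mfd = numeric(), gfd = numeric(),
               n_segments = integer())
  list(segments = segments, patients = patients)
}
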