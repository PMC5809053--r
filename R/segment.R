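# Segmentation of the plaque and extraction of its border:
# iterative-intermeans (IsoData) automatic threshold, Sobel gradient
# magnitude, and the 8-connected inner boundary of the thresholded object.

# Replicate-pad a matrix by one pixel on each side (kernel edge handling).
padReplicate <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(1, 1:nr, nr), c(1, 1:nc, nc)]
}

# The 8 one-pixel shifts of a replicate-padded matrix, as a list of
# matrices aligned with the unpadded original.
shiftedNeighbors <- function(p, nr, nc) {
  sh <- function(dr, dc) p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  list(sh(-1, -1), sh(-1, 0), sh(-1, 1),
       sh(0, -1),             sh(0, 1),
       sh(1, -1),  sh(1, 0),  sh(1, 1))
}

#' Automatic threshold by iterative intermeans (IsoData)
#'
#' Computes an automatic threshold on the 256-bin intensity histogram by the
#' classic iterative intermeans scheme: start from the global mean, then
#' repeatedly replace the threshold with the average of the mean intensity
#' at or below it and the mean intensity above it, until the update is
#' smaller than 0.5. The returned level is a fixed point of that map (to
#' within the 0.5 convergence tolerance) and may be fractional.
#'
#' This is a deterministic approximation of the "Default" (modified
#' IsoData) automatic threshold found in common image-analysis software;
#' pass a manual threshold to [binarize()] to override it.
#'
#' @param img a [GrayImage-class] with at least two distinct intensities.
#' @return A single numeric threshold level in (0, 255).
#' @examples
#' img <- GrayImage(matrix(c(0, 0, 255, 255), 2, 2))
#' isodataThreshold(img)  # 127.5
#' @export
isodataThreshold <- function(img) {
  m <- pixels(img)
  bins <- tabulate(pmin(pmax(floor(m), 0), 255) + 1L, nbins = 256L)
  vals <- 0:255
  if (sum(bins > 0) < 2L)
    stop("constant image: no threshold exists; supply a manual threshold")
  classMeans <- function(t) {
    lo <- vals <= t
    c(sum(vals[lo] * bins[lo]) / sum(bins[lo]),
      sum(vals[!lo] * bins[!lo]) / sum(bins[!lo]))
  }
  t <- sum(vals * bins) / sum(bins)
  for (i in 1:256) {
    cm <- classMeans(t)
    tn <- mean(cm)
    if (abs(tn - t) < 0.5) return(tn)
    t <- tn
  }
  t
}

#' Binarize an image at a threshold
#'
#' @param img a [GrayImage-class].
#' @param threshold intensity level in [0, 255], e.g. from
#'   [isodataThreshold()].
#' @param polarity \code{"bright"}: pixels strictly above the threshold
#'   become foreground (echogenic plaque on dark lumen, the usual case);
#'   \code{"dark"}: pixels at or below the threshold become foreground;
#'   \code{"auto"}: the polarity whose foreground mean intensity exceeds its
#'   background mean (which selects bright-object whenever the threshold
#'   lies strictly inside the intensity range).
#' @return A [BinaryMask-class] of the same shape.
#' @export
binarize <- function(img, threshold, polarity = c("auto", "bright", "dark")) {
  polarity <- match.arg(polarity)
  m <- pixels(img)
  if (threshold < 0 || threshold > 255)
    stop("threshold must lie in [0, 255]")
  bright <- m > threshold
  pick <- switch(polarity,
    bright = bright,
    dark = !bright,
    auto = {
      sel <- bright
      # choose the polarity whose foreground is the brighter class
      if (any(bright) && any(!bright)) {
        if (mean(m[bright]) < mean(m[!bright])) sel <- !bright
      } else if (!any(bright)) {
        sel <- !bright
      }
      sel
    }
  )
  BinaryMask(pick)
}

#' Sobel gradient magnitude
#'
#' Convolves the image with the standard 3x3 Sobel kernels and returns
#' \code{sqrt(Gx^2 + Gy^2)}. Image edges are handled by edge replication, so
#' a constant image yields zero everywhere including the border ring.
#'
#' @param img a [GrayImage-class] or [BinaryMask-class] of at least 3x3.
#' @return Numeric matrix of non-negative gradient magnitudes, same shape.
#' @export
sobelMagnitude <- function(img) {
  m <- if (is(img, "BinaryMask")) pixels(img) * 255 else pixels(img)
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L)
    stop("image must be at least 3x3 for the Sobel operator")
  nb <- shiftedNeighbors(padReplicate(m), nr, nc)
  # nb order: up-left, up, up-right, left, right, down-left, down, down-right
  gx <- (nb[[3]] + 2 * nb[[5]] + nb[[8]]) - (nb[[1]] + 2 * nb[[4]] + nb[[6]])
  gy <- (nb[[6]] + 2 * nb[[7]] + nb[[8]]) - (nb[[1]] + 2 * nb[[2]] + nb[[3]])
  sqrt(gx^2 + gy^2)
}

#' Extract the plaque border from a binary mask
#'
#' The border is the 8-connected inner boundary: every foreground pixel with
#' at least one background pixel among its 8 neighbors (neighbors outside
#' the image are treated by edge replication, so an object flush against the
#' image edge has no border there). This locus coincides with the non-zero
#' support of the Sobel gradient magnitude of the \{0,255\}-scaled mask
#' restricted to the foreground, and is computed directly from the boundary
#' definition for exactness. The operation is idempotent.
#'
#' @param mask a [BinaryMask-class] with at least one foreground pixel.
#' @return A [BorderMask-class]; foreground is a subset of \code{mask}'s.
#' @examples
#' m <- matrix(0, 5, 5); m[2:4, 2:4] <- 1
#' sum(pixels(extractBorder(BinaryMask(m))))  # 8: perimeter of the block
#' @export
extractBorder <- function(mask) {
  m <- pixels(mask)
  if (!any(m == 1))
    stop("no object found: mask has no foreground pixels")
  nb <- shiftedNeighbors(padReplicate(m), nrow(m), ncol(m))
  nbMin <- Reduce(pmin, nb)
  BorderMask(m == 1 & nbMin == 0)
}

#' Drop small connected components from a mask
#'
#' Optional pre-measurement cleanup: removes 8-connected foreground
#' components smaller than \code{minPixels}. Off by default in the pipeline
#' (no despeckling is applied unless requested).
#'
#' @param mask a [BinaryMask-class].
#' @param minPixels components with fewer foreground pixels are removed.
#' @return A [BinaryMask-class].
#' @export
dropSmallComponents <- function(mask, minPixels) {
  m <- pixels(mask)
  if (minPixels <= 1) return(mask)
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  todo <- which(m == 1)
  off <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  rowOf <- function(i) ((i - 1L) %% nr) + 1L
  for (s in todo) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    lab[s] <- cur
    while (length(frontier)) {
      cand <- rep(frontier, each = 8L) + off
      fr <- rep(rowOf(frontier), each = 8L)
      keep <- cand >= 1L & cand <= nr * nc
      # discard wrap-around across matrix columns
      keep <- keep & abs(rowOf(pmax(cand, 1L)) - fr) <= 1L
      cand <- unique(cand[keep])
      cand <- cand[m[cand] == 1 & lab[cand] == 0L]
      lab[cand] <- cur
      frontier <- cand
    }
  }
  sizes <- tabulate(lab[lab > 0L], nbins = cur)
  keepLab <- which(sizes >= minPixels)
  BinaryMask(matrix(as.numeric(lab %in% keepLab & m == 1), nr, nc))
}
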