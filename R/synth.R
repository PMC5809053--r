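# Synthetic contours and plaque-like images of known fractal dimension.
# These generators let every pipeline stage be validated against analytic
# ground truth: a straight line (FD 1), the Koch curve (FD ln4/ln3), and
# the graph of fractional Brownian motion with Hurst exponent H (FD 2-H).

#' Koch curve polyline
#'
#' Classic Koch construction on the unit segment: each iteration replaces
#' every segment by four segments of one third the length, with a bump
#' raised on an equilateral triangle. After \code{iterations} steps the
#' curve has \code{4^iterations} segments and total length
#' \code{(4/3)^iterations}; its similarity dimension is
#' \code{log(4)/log(3) ~ 1.2619}.
#'
#' @param iterations integer in 0..8.
#' @return Polyline: numeric matrix with columns \code{x}, \code{y} and
#'   \code{4^iterations + 1} rows.
#' @examples
#' nrow(kochCurve(2))  # 17 vertices = 16 segments
#' @export
kochCurve <- function(iterations) {
  if (iterations < 0 || iterations > 8)
    stop("iterations must lie in 0..8")
  z <- c(0 + 0i, 1 + 0i)
  rot <- exp(1i * pi / 3)
  for (i in seq_len(iterations)) {
    p <- z[-length(z)]
    d <- diff(z) / 3
    m1 <- p + d
    m2 <- m1 + d * rot
    m3 <- p + 2 * d
    z <- c(rbind(p, m1, m2, m3), z[length(z)])
  }
  cbind(x = Re(z), y = Im(z))
}

#' Fractional Brownian motion graph by midpoint displacement
#'
#' Generates the graph of a fractional-Brownian-motion-like profile on
#' [0, 1] by random midpoint displacement with successive random additions:
#' at level \code{l}, midpoints are interpolated and every already-placed
#' point receives an independent Gaussian displacement with standard
#' deviation \code{sigma * 2^(-hurst * l)}. The additions step restores the
#' small-scale roughness that plain midpoint displacement lacks, so that
#' mean-squared increments over lag tau scale approximately as
#' \code{tau^(2*hurst)} and the graph's fractal dimension approaches the
#' fBm value \code{2 - hurst}.
#'
#' @param hurst Hurst exponent, strictly between 0 and 1. Lower H = rougher
#'   profile = higher fractal dimension.
#' @param n number of points: a power of two plus one, at least 65.
#' @param seed RNG seed; the profile is a pure function of
#'   \code{(hurst, n, seed)}.
#' @param sigma base displacement amplitude relative to the unit horizontal
#'   span (default 1, giving a vertical extent comparable to the span).
#' @return Polyline: numeric matrix with columns \code{x} (in [0,1]) and
#'   \code{y}, \code{n} rows.
#' @export
fbmProfile <- function(hurst, n, seed, sigma = 1) {
  if (!(hurst > 0 && hurst < 1))
    stop("hurst must lie strictly between 0 and 1")
  m <- log2(n - 1)
  if (n < 65 || m != round(m))
    stop("n must be a power of two plus one, at least 65 (e.g. 1025)")
  y <- numeric(n)
  withSeed(seed, {
    step <- n - 1L
    for (lev in seq_len(m)) {
      half <- step %/% 2L
      mid <- seq(1L + half, n, by = step)
      y[mid] <- (y[mid - half] + y[mid + half]) / 2
      placed <- seq(1L, n, by = half)
      y[placed] <- y[placed] +
        stats::rnorm(length(placed), 0, sigma * 2^(-hurst * lev))
      step <- half
    }
  })
  cbind(x = seq(0, 1, length.out = n), y = y)
}

#' Rasterize a polyline to a one-pixel-thick curve
#'
#' The polyline is scaled isotropically so that its larger extent maps to
#' \code{widthPx} pixels, then drawn with 8-connected one-pixel segments
#' (digital differential analyzer with rounding). Every vertex maps to a
#' foreground pixel and the result is a connected curve raster.
#'
#' @param line polyline matrix with columns x, y (at least 2 distinct
#'   consecutive vertices, finite coordinates).
#' @param widthPx target raster width in pixels (at least 64). Row index
#'   increases with y.
#' @return A [BorderMask-class] sized to the curve's bounding box.
#' @examples
#' sum(pixels(rasterizePolyline(cbind(c(0, 1), c(0, 0)), 512)))  # 512
#' @export
rasterizePolyline <- function(line, widthPx) {
  line <- as.matrix(line)
  if (widthPx < 64) stop("widthPx must be at least 64")
  if (nrow(line) < 2) stop("polyline needs at least 2 vertices")
  if (anyNA(line) || any(!is.finite(line)))
    stop("polyline coordinates must be finite")
  if (any(rowSums(abs(diff(line))) == 0))
    stop("consecutive polyline vertices must be distinct")
  xs <- line[, 1]; ys <- line[, 2]
  xext <- diff(range(xs)); yext <- diff(range(ys))
  if (xext == 0 && yext == 0)
    stop("degenerate polyline: zero extent")
  s <- (widthPx - 1) / max(xext, yext)
  cx <- round((xs - min(xs)) * s)
  cy <- round((ys - min(ys)) * s)
  nr <- max(cy) + 1L
  nc <- max(cx) + 1L
  pts <- lapply(seq_len(length(cx) - 1L), function(i) {
    n <- max(abs(cx[i + 1] - cx[i]), abs(cy[i + 1] - cy[i])) + 1L
    cbind(round(seq(cy[i], cy[i + 1], length.out = n)),
          round(seq(cx[i], cx[i + 1], length.out = n)))
  })
  pts <- do.call(rbind, pts)
  m <- matrix(0, nr, nc)
  m[pts[, 1] + nr * pts[, 2] + 1L] <- 1
  BorderMask(m)
}

#' Synthetic plaque-like image with known border
#'
#' Emulates a far-wall plaque on a long-axis B-mode view: the region below
#' the (rasterized) profile takes the echogenic plaque intensity, the
#' region above the dark lumen intensity, and multiplicative speckle-like
#' noise is applied. The exact plaque mask and its inner border are
#' returned as ground truth so the segmentation pipeline can be scored.
#'
#' The noise model is multiplicative uniform: each pixel is scaled by a
#' factor drawn from \code{1 +/- noiseAmp/255}, then clipped to 0--255 and
#' rounded. \code{noiseAmp} is thus the noise amplitude in intensity units
#' at full scale; brighter tissue carries proportionally more noise, as in
#' ultrasound speckle, though real Rayleigh speckle statistics are not
#' modeled.
#'
#' @param profile polyline of the plaque surface (e.g. from
#'   [fbmProfile()]); rasterized at \code{widthPx}.
#' @param heightPx image height; must accommodate the rasterized profile.
#' @param widthPx image width (the profile spans it).
#' @param lumenLevel,plaqueLevel intensities of the two regions;
#'   \code{plaqueLevel > lumenLevel}.
#' @param noiseAmp noise amplitude in intensity units (0 disables noise).
#' @param seed RNG seed for the noise.
#' @return List with \code{image} ([GrayImage-class]), \code{mask} (ground
#'   truth [BinaryMask-class]) and \code{border} (ground truth
#'   [BorderMask-class], the mask's inner boundary).
#' @export
synthPlaqueImage <- function(profile, heightPx = 256, widthPx = 512,
                             lumenLevel = 40, plaqueLevel = 160,
                             noiseAmp = 0, seed = 0) {
  if (plaqueLevel <= lumenLevel)
    stop("plaqueLevel must exceed lumenLevel")
  if (noiseAmp < 0) stop("noiseAmp must be non-negative")
  curve <- pixels(rasterizePolyline(profile, widthPx))
  hr <- nrow(curve); wc <- ncol(curve)
  if (hr > heightPx - 2)
    stop("rasterized profile (", hr, " rows) too tall for heightPx = ",
         heightPx, "; increase heightPx or reduce the profile amplitude")
  idx <- which(curve == 1, arr.ind = TRUE)
  # topmost curve row per column, shifted to center the curve vertically
  b <- tapply(idx[, 1], idx[, 2], min)
  bCol <- as.integer(names(b))
  rowOff <- (heightPx - hr) %/% 2L
  boundary <- rep.int(NA_integer_, wc)
  boundary[bCol] <- as.integer(b) + rowOff
  if (anyNA(boundary))
    stop("profile does not span every raster column; supply a function-like profile")
  mask <- outer(seq_len(heightPx), boundary, ">=")
  img <- matrix(lumenLevel, heightPx, wc)
  img[mask] <- plaqueLevel
  if (noiseAmp > 0) {
    img <- withSeed(seed, {
      f <- 1 + (noiseAmp / 255) * stats::runif(length(img), -1, 1)
      matrix(pmin(pmax(round(img * f), 0), 255), heightPx, wc)
    })
  }
  maskObj <- BinaryMask(mask)
  list(image = GrayImage(img), mask = maskObj,
       border = extractBorder(maskObj))
}
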