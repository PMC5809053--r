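# Independent brute-force oracles used to cross-check the implementation.
# All of these are written as plain nested loops or textbook closed forms
# and deliberately share no code with the package internals.

# Direct 3x3 Sobel convolution with replicated edges, nested loops.
oracleSobel <- function(m) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # columns: -1, 0, +1
  ky <- t(kx)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  clampR <- function(i) min(max(i, 1), nr)
  clampC <- function(j) min(max(j, 1), nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    gx <- 0; gy <- 0
    for (di in -1:1) for (dj in -1:1) {
      v <- m[clampR(i + di), clampC(j + dj)]
      gx <- gx + v * kx[di + 2, dj + 2]
      gy <- gy + v * ky[di + 2, dj + 2]
    }
    out[i, j] <- sqrt(gx^2 + gy^2)
  }
  out
}

# Cell-by-cell scan of the epsilon-grid: count cells holding >= 1 pixel.
oracleBoxCount <- function(m, eps, offR, offC) {
  nr <- nrow(m); nc <- ncol(m)
  count <- 0L
  # grid anchored at (-offR, -offC) in 0-based pixel coordinates
  for (top in seq(-offR, nr - 1, by = eps)) {
    for (left in seq(-offC, nc - 1, by = eps)) {
      rows <- max(top, 0):min(top + eps - 1, nr - 1)
      cols <- max(left, 0):min(left + eps - 1, nc - 1)
      if (any(m[rows + 1, cols + 1, drop = FALSE] == 1)) count <- count + 1L
    }
  }
  count
}

# Boundary scan: foreground pixels with a background 8-neighbor, treating
# out-of-image neighbors as replicated (no border contact at image edges).
oracleBoundary <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (m[i, j] != 1) next
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- min(max(i + di, 1), nr)
      jj <- min(max(j + dj, 1), nc)
      if (m[ii, jj] == 0) out[i, j] <- 1
    }
  }
  out
}

# OLS by the normal equations, no lm().
oracleOLS <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  list(slope = slope, intercept = intercept)
}

# ICC(2,1) from stats::aov mean squares (independent ANOVA route).
oracleICC21 <- function(m1, m2) {
  n <- length(m1)
  d <- data.frame(y = c(m1, m2),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = d))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# No-ties Spearman closed form 1 - 6 sum(d^2) / (n (n^2 - 1)).
oracleSpearmanNoTies <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# True if the foreground of a mask forms one 8-connected component.
is8Connected <- function(m) {
  idx <- which(m == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) return(FALSE)
  seen <- rep(FALSE, nrow(idx))
  key <- idx[, 1] * (ncol(m) + 2) + idx[, 2]
  lookup <- new.env()
  for (i in seq_len(nrow(idx))) assign(as.character(key[i]), i, lookup)
  queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      k2 <- as.character((idx[i, 1] + di) * (ncol(m) + 2) + idx[i, 2] + dj)
      j <- mget(k2, lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(j) && !seen[j]) {
        seen[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  all(seen)
}

# Random sparse binary mask for property tests.
randomMask <- function(nr, nc, p = 0.2, seed = 1) {
  set.seed(seed)
  matrix(as.numeric(stats::runif(nr * nc) < p), nr, nc)
}
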