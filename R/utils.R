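# Small numerical helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Replicate-pad a matrix by `k` rows/cols on every side.
#' @noRd
pad_replicate <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, k), seq_len(nr), rep(nr, k))
  ci <- c(rep(1L, k), seq_len(nc), rep(nc, k))
  m[ri, ci, drop = FALSE]
}

# 1-D correlation of each row (axis = "x") or column (axis = "y") of a
# matrix with symmetric-length taps, replicate boundary, "same" output size.
# Correlation convention: out[i] = sum_n taps[n] * in[i + n], n = -k..k.
#' @noRd
correlate_axis <- function(m, taps, axis = c("x", "y")) {
  axis <- match.arg(axis)
  k <- (length(taps) - 1L) %/% 2L
  stopifnot(length(taps) == 2L * k + 1L)
  p <- pad_replicate(m, k)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (n in seq_along(taps)) {
    off <- n - 1L  # shift of -k..k relative to centre
    if (axis == "x") {
      out <- out + taps[n] * p[k + seq_len(nr), off + seq_len(nc), drop = FALSE]
    } else {
      out <- out + taps[n] * p[off + seq_len(nr), k + seq_len(nc), drop = FALSE]
    }
  }
  out
}

# Separable Gaussian blur with replicate padding. Kernel truncated at 3 sigma.
#' @noRd
blur_gaussian <- function(m, sigma) {
  stopifnot(sigma > 0)
  k <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq(-k, k)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  correlate_axis(correlate_axis(m, g, "x"), g, "y")
}

# Half-band blur (binomial 1-4-6-4-1) followed by 2x decimation, floor on
# odd dimensions.
#' @noRd
downsample2 <- function(m) {
  b <- c(1, 4, 6, 4, 1) / 16
  s <- correlate_axis(correlate_axis(m, b, "x"), b, "y")
  s[2L * seq_len(nrow(m) %/% 2L), 2L * seq_len(ncol(m) %/% 2L), drop = FALSE]
}

# Zero-phase Butterworth filtering of every column of a matrix.
#' @noRd
filtfilt_cols <- function(filt, x) {
  if (is.null(dim(x))) return(signal::filtfilt(filt, x))
  apply(x, 2L, function(col) signal::filtfilt(filt, col))
}

# Cross product of two 3-vectors.
#' @noRd
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @noRd
vnorm <- function(v) sqrt(sum(v^2))

#' @noRd
unitize <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero-length vector")
  v / n
}
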