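# Oriented complex (quadrature) filter pyramid and local-phase operations.
#
# The decomposition follows the complex steerable pyramid idea restricted
# to two orientations: each level is built by half-band blurring and 2x
# decimating the previous level's base image, then correlating with a
# quadrature (even/odd) filter pair along the horizontal and the vertical
# axis. The complex response magnitude is local amplitude (texture
# strength) and its argument is local phase; spatial shifts of texture
# appear as phase shifts, the image analogue of the Fourier shift theorem.

# 9-tap quadrature pair: Gabor-style even/odd taps at centre frequency
# 0.25 cycles/pixel with Gaussian envelope sigma = 2 px. The even filter's
# residual DC is removed by subtracting a scaled copy of the envelope
# (minimal in-band perturbation), and both filters are normalized to unit
# magnitude response at the centre frequency so that the complex argument
# tracks the phase of a centre-frequency grating exactly.
#' @noRd
quadrature_taps <- function() {
  fc <- 0.25
  n <- -4:4
  g <- exp(-n^2 / (2 * 2^2))
  even <- g * cospi(2 * fc * n)
  even <- even - g * (sum(even) / sum(g))        # zero DC
  odd <- g * sinpi(2 * fc * n)                   # zero DC by symmetry
  he <- abs(sum(even * exp(-2i * pi * fc * n)))
  ho <- abs(sum(odd * exp(-2i * pi * fc * n)))
  list(even = even / he, odd = odd / ho, fc = fc, length = length(n))
}

#' Build an oriented complex filter pyramid for one frame
#'
#' @param frame Numeric H x W matrix of intensities in `[0, 1]`.
#' @param levels Number of pyramid levels (level 0 is full resolution;
#'   each further level halves both dimensions).
#' @return Object of class `complex_pyramid`: per level, complex response
#'   matrices `h` (horizontal orientation, sensitive to motion along image
#'   u) and `v` (vertical orientation, motion along image v), plus the
#'   filter centre frequency `fc` in cycles/pixel at that level's
#'   resolution.
#' @export
#' @examples
#' p <- build_pyramid(matrix(runif(64 * 64), 64), levels = 2)
#' Mod(p$levels[[1]]$h[30, 30])   # local amplitude
#' Arg(p$levels[[1]]$h[30, 30])   # local phase
build_pyramid <- function(frame, levels = 2L) {
  stopifnot(is.matrix(frame), levels >= 1)
  q <- quadrature_taps()
  if (min(dim(frame)) / 2^(levels - 1) < q$length) {
    stop("too many pyramid levels for this crop size: level ",
         levels - 1, " would be smaller than the filter length")
  }
  base <- frame
  lv <- vector("list", levels)
  for (l in seq_len(levels)) {
    resp_h <- correlate_axis(base, q$even, "x") +
      1i * correlate_axis(base, q$odd, "x")
    resp_v <- correlate_axis(base, q$even, "y") +
      1i * correlate_axis(base, q$odd, "y")
    lv[[l]] <- list(h = resp_h, v = resp_v, fc = q$fc, dim = dim(base))
    if (l < levels) base <- downsample2(base)
  }
  structure(list(levels = lv, n_levels = levels), class = "complex_pyramid")
}

#' Per-pixel phase difference between two pyramids
#'
#' Computes the wrapped phase change `Arg(curr * Conj(prev))` per pixel,
#' orientation, and level — the raw motion signal: a texture shift of
#' `delta` pixels along an orientation changes that orientation's phase by
#' `2 * pi * fc * delta`. The attached amplitude map (geometric mean of the
#' two frames' amplitudes) weights later denoising and averaging.
#'
#' @param prev,curr [build_pyramid()] results with identical geometry.
#' @return List per level with `h`/`v` sublists containing `dphase`
#'   (radians, wrapped to `(-pi, pi]`) and `amplitude` matrices, plus `fc`.
#' @export
phase_step <- function(prev, curr) {
  stopifnot(inherits(prev, "complex_pyramid"),
            inherits(curr, "complex_pyramid"),
            prev$n_levels == curr$n_levels)
  lapply(seq_len(prev$n_levels), function(l) {
    a <- prev$levels[[l]]; b <- curr$levels[[l]]
    if (!identical(a$dim, b$dim)) stop("pyramid shape mismatch at level ", l)
    one <- function(pa, pb) {
      d <- pb * Conj(pa)
      list(dphase = Arg(d), amplitude = sqrt(Mod(pa) * Mod(pb)))
    }
    c(list(fc = a$fc), list(h = one(a$h, b$h), v = one(a$v, b$v)))
  })
}

#' Amplitude-weighted spatial blur of a phase map
#'
#' Smooths phase with weights `amplitude^2`, so textureless pixels (whose
#' phase is noise) inherit phase from textured neighbours:
#' `G(amplitude^2 * phase) / G(amplitude^2)` with `G` a Gaussian blur of
#' scale `sigma`. Where the amplitude is spatially constant this reduces
#' to a plain Gaussian blur of the phase.
#'
#' @param phase Numeric matrix (radians).
#' @param amplitude Numeric matrix, same shape, >= 0.
#' @param sigma Blur scale, pixels (> 0).
#' @return Denoised phase matrix. If the amplitude is identically zero the
#'   result is all zeros with attribute `flagged = TRUE` and a warning.
#' @export
spatial_denoise <- function(phase, amplitude, sigma) {
  stopifnot(identical(dim(phase), dim(amplitude)), sigma > 0)
  w <- amplitude^2
  if (max(w) == 0) {
    warning("all-zero amplitude: phase denoising undefined, returning zeros")
    out <- matrix(0, nrow(phase), ncol(phase))
    attr(out, "flagged") <- TRUE
    return(out)
  }
  num <- blur_gaussian(w * phase, sigma)
  den <- blur_gaussian(w, sigma)
  floor_w <- 1e-12 * max(den)
  out <- num / pmax(den, floor_w)
  out[den < floor_w] <- 0
  out
}
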