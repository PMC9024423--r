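# Shared fixtures and measurement utilities. Rendered scenes are cached so
# several test files can reuse the same clips without re-rendering.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# One straight-on camera at 1 m plus the standard verged pair.
frontal_camera <- function() {
  camera_model(c(0, 0, 1000), pan = 0, tilt = 0, focal_distance = 20,
               pixel_pitch = 0.01, resolution = c(800, 600))
}

# mm of world-X motion per image pixel for the frontal camera and a patch
# at the cage centre (z = -150): distance 1150 mm, f/pitch = 2000 px.
MM_PER_PX_FRONTAL <- 1150 * 0.01 / 20

# 0.3 px, 20 Hz sinusoid seen by the frontal camera; 0.6 s at 1000 fps.
fix_subpix <- function() fixture("subpix", function() {
  cams <- list(frontal_camera(), make_camera_pair()$b)
  motion <- sinusoid_motion(1000, 0.6, c(0.3 * MM_PER_PX_FRONTAL, 0, 0), 20)
  sp <- scene_spec(cams, motion, 1000, make_texture(256, seed = 7),
                   texel_mm = 0.5, noise_sigma = 0.005, supersample = 8,
                   seed = 11, crop_size = 48)
  c(render_mono(sp, 1), list(spec = sp))
})

# Static stereo scene with sensor noise; 0.3 s at 1000 fps.
fix_static_stereo <- function() fixture("static_stereo", function() {
  cams <- make_camera_pair()
  sp <- scene_spec(cams, matrix(0, 300, 3), 1000,
                   make_texture(256, seed = 7), texel_mm = 0.5,
                   noise_sigma = 0.005, supersample = 4, seed = 11,
                   crop_size = 48)
  r <- render_stereo(sp)
  r$trace_a <- motion_trace(r$clip_a, levels = 2)
  r$trace_b <- motion_trace(r$clip_b, levels = 2)
  r$spec <- sp
  r
})

# 5 mm, 15 Hz commanded Y motion, verged pair; 0.5 s at 1000 fps.
fix_y15 <- function() fixture("y15", function() {
  cams <- make_camera_pair()
  motion <- sinusoid_motion(1000, 0.5, c(0, 5, 0), 15)
  sp <- scene_spec(cams, motion, 1000, make_texture(256, seed = 7),
                   texel_mm = 0.5, noise_sigma = 0.005, supersample = 4,
                   seed = 11, crop_size = 48)
  r <- render_stereo(sp)
  r$trace_a <- motion_trace(r$clip_a, levels = 2)
  r$trace_b <- motion_trace(r$clip_b, levels = 2)
  r$spec <- sp
  r
})

# Least-squares sinusoid fit: frequency by 1-D search, then amplitude.
fit_sinusoid <- function(x, t, f_grid) {
  rss <- vapply(f_grid, function(f) {
    X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t), 1)
    sum(qr.resid(qr(X), x)^2)
  }, 0)
  f <- f_grid[which.min(rss)]
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  b <- qr.solve(X, x - mean(x))
  list(freq = f, amplitude = sqrt(sum(b^2)))
}

# Independent sub-pixel registration oracle: per-frame horizontal shift of
# each frame relative to frame 1, by minimizing the sum of squared
# differences against a per-row cubic-spline interpolation of frame 1.
register_shift_u <- function(frames) {
  n <- dim(frames)[1]
  h <- dim(frames)[2]; w <- dim(frames)[3]
  rows <- 5:(h - 4); cols <- 5:(w - 4)
  splines <- lapply(rows, function(r)
    stats::splinefun(seq_len(w), frames[1, r, ], method = "natural"))
  vapply(seq_len(n), function(k) {
    obj <- function(d) {
      s <- 0
      for (i in seq_along(rows)) {
        s <- s + sum((frames[k, rows[i], cols] - splines[[i]](cols - d))^2)
      }
      s
    }
    stats::optimize(obj, c(-1.5, 1.5), tol = 1e-8)$minimum
  }, 0)
}

# Quadratic closed-form minimizer of the summed squared distance from a
# point to a set of lines: assembles the projection-operator normal
# equations sum(I - d d^T) P = sum(I - d d^T) p and solves them. Serves as
# the independent numerical-minimization oracle for triangulate().
min_line_distance_point <- function(origins, dirs) {
  a <- matrix(0, 3, 3); b <- numeric(3)
  for (i in seq_len(nrow(origins))) {
    d <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
    proj <- diag(3) - outer(d, d)
    a <- a + proj
    b <- b + proj %*% origins[i, ]
  }
  as.numeric(solve(a, b))
}
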