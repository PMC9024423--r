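# Synthetic stereo scene renderer: textured planar patches undergoing
# commanded 3D motion, imaged by two pinhole cameras, with exact ground
# truth. Frames are rasterized by casting supersampled per-pixel rays onto
# the moving patch plane, bilinearly sampling a band-limited noise texture,
# and box-averaging down — so commanded sub-pixel motion produces the
# smooth intensity modulation that phase vibrometry reads, and the
# generator shares no code path with the vibrometry filters it validates.

#' Band-limited noise texture
#'
#' Seeded white noise filtered to an annular frequency band (raised-cosine
#' edges), rescaled to `[lo, hi]` intensities. Band-limited texture
#' guarantees nonzero quadrature-filter amplitude everywhere in a crop —
#' the visual analogue of a well-textured patch of web or spider body.
#'
#' @param n Texture side length, texels.
#' @param seed Integer seed.
#' @param band `(f0, f1)` passband, cycles/texel.
#' @param lo,hi Output intensity range.
#' @return `n x n` numeric matrix.
#' @export
make_texture <- function(n = 256, seed = 1, band = c(0.10, 0.35),
                         lo = 0.15, hi = 0.85) {
  set.seed(seed)
  w <- matrix(stats::rnorm(n * n), n, n)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  fr <- sqrt(outer(f^2, f^2, `+`))
  ramp <- function(x) 0.5 * (1 + cos(pi * pmin(pmax(x, 0), 1)))
  width <- 0.04
  mask <- ifelse(fr < band[1], ramp((band[1] - fr) / width),
                 ifelse(fr > band[2], ramp((fr - band[2]) / width), 1))
  tex <- Re(stats::fft(stats::fft(w) * mask, inverse = TRUE)) / (n * n)
  tex <- (tex - min(tex)) / (max(tex) - min(tex))
  lo + (hi - lo) * tex
}

#' Commanded motion time series
#'
#' Sum of decaying sinusoid events: each event contributes
#' `a * exp(-(t - t0) / tau) * sin(2 pi f (t - t0) + phase)` along its
#' direction for `t >= t0`.
#'
#' @param framerate Hz.
#' @param duration Seconds.
#' @param events Data frame with columns `t0` (s), `amp` (mm),
#'   `dir_x, dir_y, dir_z` (direction, normalized internally), `freq`
#'   (Hz), `tau` (s), and optional `phase` (radians).
#' @return `T x 3` matrix of world offsets, mm.
#' @export
decaying_sinusoid_motion <- function(framerate, duration, events) {
  t <- seq(0, duration - 1 / framerate, by = 1 / framerate)
  m <- matrix(0, length(t), 3)
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    d <- unitize(c(e$dir_x, e$dir_y, e$dir_z))
    ph <- if ("phase" %in% names(events)) e$phase else 0
    tt <- t - e$t0
    s <- ifelse(tt >= 0,
                e$amp * exp(-tt / e$tau) * sin(2 * pi * e$freq * tt + ph), 0)
    m <- m + outer(s, d)
  }
  m
}

#' Pure sinusoidal motion
#'
#' @param framerate Hz.
#' @param duration Seconds.
#' @param amplitude Numeric 3-vector, mm (peak, per axis).
#' @param freq Hz.
#' @param phase Radians.
#' @return `T x 3` matrix of world offsets, mm.
#' @export
sinusoid_motion <- function(framerate, duration, amplitude, freq, phase = 0) {
  t <- seq(0, duration - 1 / framerate, by = 1 / framerate)
  outer(sin(2 * pi * freq * t + phase), as.numeric(amplitude))
}

#' Specify a synthetic stereo scene
#'
#' @param cameras List of two [camera_model()]s.
#' @param motion `T x 3` matrix of commanded world offsets (mm) of the
#'   patch, sampled at `framerate`; the first row should be zero so that
#'   frame 0 is the reference.
#' @param framerate Hz.
#' @param texture Texture matrix (see [make_texture()]).
#' @param texel_mm Millimetres per texel.
#' @param patch_origin World position (mm) of the texture centre at rest.
#' @param patch_e1,patch_e2 In-plane unit vectors of the patch (world
#'   frame); the patch normal is their cross product.
#' @param noise_sigma Zero-mean Gaussian sensor noise, intensity units.
#' @param supersample Sub-pixel rasterization factor (>= 4).
#' @param seed Integer seed for the sensor noise.
#' @param crop_size Rendered crop side, pixels.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(cameras, motion, framerate, texture, texel_mm,
                       patch_origin = c(0, 0, -150),
                       patch_e1 = c(1, 0, 0), patch_e2 = c(0, 1, 0),
                       noise_sigma = 0.005, supersample = 4L, seed = 1L,
                       crop_size = 48L) {
  motion <- matrix(motion, ncol = 3)
  stopifnot(length(cameras) == 2,
            inherits(cameras[[1]], "camera_model"),
            inherits(cameras[[2]], "camera_model"),
            nrow(motion) >= 2, framerate > 0, is.matrix(texture),
            texel_mm > 0, supersample >= 4, noise_sigma >= 0,
            crop_size >= 16)
  structure(list(cameras = cameras, motion = motion, framerate = framerate,
                 texture = texture, texel_mm = texel_mm,
                 patch_origin = as.numeric(patch_origin),
                 patch_e1 = unitize(patch_e1), patch_e2 = unitize(patch_e2),
                 noise_sigma = noise_sigma,
                 supersample = as.integer(supersample),
                 seed = as.integer(seed), crop_size = as.integer(crop_size)),
            class = "scene_spec")
}

# Bilinear texture sample at fractional texel coordinates (1-based,
# centre of texture at (n+1)/2). Errors when samples leave the texture.
#' @noRd
sample_texture <- function(tex, a, b) {
  n <- nrow(tex)
  if (any(a < 1 | a > ncol(tex) | b < 1 | b > n)) {
    stop("patch out of view: ray samples fall outside the texture extent")
  }
  j0 <- pmin(floor(a), ncol(tex) - 1L); i0 <- pmin(floor(b), n - 1L)
  fa <- a - j0; fb <- b - i0
  idx <- function(i, j) tex[cbind(i, j)]
  (1 - fa) * (1 - fb) * idx(i0, j0) + fa * (1 - fb) * idx(i0, j0 + 1L) +
    (1 - fa) * fb * idx(i0 + 1L, j0) + fa * fb * idx(i0 + 1L, j0 + 1L)
}

# Box-average an (S*H) x (S*W) matrix down to H x W.
#' @noRd
box_average <- function(m, s) {
  h <- nrow(m) %/% s; w <- ncol(m) %/% s
  m1 <- colMeans(array(m, c(s, h, s * w)))           # h x (s*w)
  m2 <- colMeans(array(t(m1), c(s, w, h)))           # w x h
  t(m2)
}

# Render one camera's crop of the scene. Returns video_clip + per-frame
# true pixel displacement.
#' @noRd
render_view <- function(spec, cam) {
  s <- spec$supersample
  cs <- spec$crop_size
  ref0 <- spec$patch_origin
  centre_px <- project_points(cam, ref0)
  origin_px <- round(centre_px - cs / 2)   # crop top-left, full-frame px

  # supersampled full-frame pixel coordinates of the crop
  sub <- (seq_len(cs * s) - 0.5) / s - 0.5
  us <- origin_px[1] + sub
  vs <- origin_px[2] + sub
  grid <- cbind(rep(us, each = cs * s), rep(vs, times = cs * s))
  dirs <- ray_directions(cam, grid)
  nrm <- cross3(spec$patch_e1, spec$patch_e2)
  dn <- as.numeric(dirs %*% nrm)
  if (any(abs(dn) < 1e-12)) stop("patch plane edge-on to a viewing ray")

  nT <- nrow(spec$motion)
  frames <- array(0, c(nT, cs, cs))
  ntex <- nrow(spec$texture)
  for (k in seq_len(nT)) {
    q <- ref0 + spec$motion[k, ]
    tt <- as.numeric((q - cam$position) %*% nrm) / dn
    w <- sweep(dirs * tt, 2, cam$position, `+`)
    rel <- sweep(w, 2, q)
    a <- as.numeric(rel %*% spec$patch_e1) / spec$texel_mm + (ntex + 1) / 2
    b <- -as.numeric(rel %*% spec$patch_e2) / spec$texel_mm + (ntex + 1) / 2
    img <- matrix(sample_texture(spec$texture, a, b), cs * s, cs * s)
    frames[k, , ] <- box_average(img, s)
  }
  if (spec$noise_sigma > 0) {
    frames <- frames + stats::rnorm(length(frames), sd = spec$noise_sigma)
    frames <- pmin(pmax(frames, 0), 1)
  }
  px <- project_points(cam, sweep(spec$motion, 2, ref0, `+`))
  truth_px <- sweep(px, 2, px[1, ])
  list(clip = video_clip(frames, spec$framerate, origin_px),
       truth_px = truth_px, px0 = px[1, ])
}

#' Render a single camera's view of a scene
#'
#' Same rasterization as [render_stereo()] but for one camera only —
#' convenient for pure 2D vibrometry validation where the second view is
#' not needed.
#'
#' @param spec A [scene_spec()].
#' @param camera Index (1 or 2) of the camera to render.
#' @return List with `clip` ([video_clip()]), `truth_px` (per-frame true
#'   image displacement, px) and `px0` (frame-0 pixel of the patch
#'   reference point).
#' @export
render_mono <- function(spec, camera = 1) {
  stopifnot(inherits(spec, "scene_spec"), camera %in% c(1, 2))
  check_supersample(spec)
  set.seed(spec$seed)
  render_view(spec, spec$cameras[[camera]])
}

#' @noRd
check_supersample <- function(spec) {
  step_px <- apply(spec$motion, 2, function(x) max(abs(diff(x)))) /
    spec$texel_mm   # conservative image-plane bound, mm ~ texel scale
  if (any(step_px > 0) && max(step_px) < 1 / (4 * spec$supersample)) {
    stop("supersample too low for the commanded amplitude: increase ",
         "supersample or the motion step")
  }
  invisible(spec)
}

#' Render a stereo pair of clips with exact ground truth
#'
#' @param spec A [scene_spec()].
#' @return List with `clip_a`, `clip_b` ([video_clip()]s cropped around
#'   the patch) and `truth`: per-frame true 3D position (mm), per-frame
#'   true image-plane displacement (px) and frame-0 pixel per camera, and
#'   the true cameras.
#' @export
render_stereo <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  # sub-pixel fidelity: nonzero commanded steps must exceed the
  # rasterization quantum 1 / (4 * supersample) px
  check_supersample(spec)
  set.seed(spec$seed)
  va <- render_view(spec, spec$cameras[[1]])
  vb <- render_view(spec, spec$cameras[[2]])
  pos <- sweep(spec$motion, 2, spec$patch_origin, `+`)
  # render/projection consistency (asserted every render)
  chk_a <- sweep(project_points(spec$cameras[[1]], pos), 2,
                 project_points(spec$cameras[[1]], pos[1, , drop = FALSE]))
  stopifnot(max(abs(chk_a - va$truth_px)) < 1e-9)
  truth <- list(position = pos,
                px_a = va$truth_px, px_b = vb$truth_px,
                px0_a = va$px0, px0_b = vb$px0,
                cameras = spec$cameras)
  list(clip_a = va$clip, clip_b = vb$clip, truth = truth)
}

#' Render a synthetic calibration scene
#'
#' Generates pixel observations of a cage-front calibration layout from a
#' known camera: the world origin and the two wall points on the epipolar
#' row (absolute points on the front face `z = 0`), square-grid corners as
#' known-distance pairs, and eight image segments of world lines parallel
#' to the XZ plane for [fit_epipolar_row()]. Optional zero-mean Gaussian
#' pixel jitter emulates hand-clicked point selection.
#'
#' @param camera The true [camera_model()].
#' @param cage_mm Cage side length (front face width), mm.
#' @param square_mm Calibration square side, mm.
#' @param jitter_px Pixel jitter standard deviation.
#' @param seed Integer seed for the jitter.
#' @return List with `calib` (a [calibration_set()]) and `truth` (camera
#'   and world layout).
#' @export
render_calibration <- function(camera, cage_mm = 300, square_mm = 25.4,
                               jitter_px = 0, seed = 1) {
  set.seed(seed)
  half <- cage_mm / 2
  abs_world <- rbind(c(0, 0, 0), c(-half, 0, 0), c(half, 0, 0))
  px <- project_points(camera, abs_world)
  jit <- function(m) m + stats::rnorm(length(m), sd = jitter_px)
  px <- jit(px)
  abs_pts <- data.frame(u = px[, 1], v = px[, 2],
                        x = abs_world[, 1], y = abs_world[, 2],
                        z = abs_world[, 3], plane = "z=0")

  sq_centres <- rbind(c(-80, -55), c(70, 45))
  pairs <- NULL
  corners_world <- NULL
  for (i in seq_len(nrow(sq_centres))) {
    cx <- sq_centres[i, 1]; cy <- sq_centres[i, 2]
    h <- square_mm / 2
    corners <- rbind(c(cx - h, cy - h, 0), c(cx + h, cy - h, 0),
                     c(cx + h, cy + h, 0), c(cx - h, cy + h, 0))
    corners_world <- rbind(corners_world, corners)
    cpx <- jit(project_points(camera, corners))
    edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
    pairs <- rbind(pairs, data.frame(
      u_i = cpx[edges[, 1], 1], v_i = cpx[edges[, 1], 2],
      u_j = cpx[edges[, 2], 1], v_j = cpx[edges[, 2], 2],
      distance = square_mm, plane = "z=0"))
  }

  ys <- c(-100, -50, 50, 100)
  zs <- c(0, -60)
  lines <- NULL
  for (z in zs) for (y in ys) {
    ends <- jit(project_points(camera, rbind(c(-120, y, z), c(120, y, z))))
    lines <- rbind(lines, data.frame(u0 = ends[1, 1], v0 = ends[1, 2],
                                     u1 = ends[2, 1], v1 = ends[2, 2]))
  }

  list(calib = calibration_set(abs_pts, pairs, lines),
       truth = list(camera = camera, absolute_world = abs_world,
                    square_corners = corners_world,
                    epipolar_row = unname(project_points(camera,
                                                         c(0, 0, -1000))[1, 2])))
}

#' Default camera rig emulating the experimental geometry
#'
#' Two cameras 1 m from the cage front, panned about 15 degrees either
#' side of the Z axis, 800 x 600 px sensors with a 2000 px focal length
#' (about 0.5 mm per pixel at the cage plane).
#'
#' @param vergence_deg Half-angle between the optical axes, degrees.
#' @param distance_mm Camera distance from the world origin.
#' @param tilt Tilt angle applied to both cameras, radians.
#' @return List of two [camera_model()]s.
#' @export
make_camera_pair <- function(vergence_deg = 15, distance_mm = 1000,
                             tilt = 0) {
  th <- vergence_deg * pi / 180
  mk <- function(sgn) {
    camera_model(position = c(distance_mm * sin(sgn * th), 0,
                              distance_mm * cos(th)),
                 pan = sgn * th, tilt = tilt,
                 focal_distance = 20, pixel_pitch = 0.01,
                 resolution = c(800, 600))
  }
  list(a = mk(-1), b = mk(+1))
}

#' Scene specification mirroring the validation experiment
#'
#' 1000 fps, 800 x 600 px cameras about 15 degrees either side of the Z
#' axis and 1 m from a 30 cm cage, imaging a textured patch at the cage
#' centre whose motion is three decaying-sinusoid "web jerk" events with
#' peak amplitudes drawn uniformly in 20 to 30 mm, directed mostly along
#' world Y. Deterministic given `seed`.
#'
#' @param seed Integer seed (texture, event draws, sensor noise).
#' @param duration Rendered duration, seconds.
#' @return A [scene_spec()].
#' @export
make_paper_like_scene <- function(seed = 1, duration = 3) {
  set.seed(seed)
  n_events <- 3L
  events <- data.frame(
    t0 = 0.4 + (seq_len(n_events) - 1) * (duration - 0.8) / n_events,
    amp = stats::runif(n_events, 20, 30),
    dir_x = 0.15, dir_y = 0.92, dir_z = 0.36,
    freq = stats::runif(n_events, 9, 14),
    tau = 0.15)
  motion <- decaying_sinusoid_motion(1000, duration, events)
  scene_spec(cameras = make_camera_pair(),
             motion = motion, framerate = 1000,
             texture = make_texture(256, seed = seed + 1000L),
             texel_mm = 0.5, noise_sigma = 0.005,
             supersample = 4L, seed = seed, crop_size = 48L)
}
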