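# Exact synthetic 2D traces (projected ground truth fed straight into
# stereo_trace) isolate the stereo composition from vibrometry error.

exact_traces <- function(cams, p0, motion, framerate = 1000) {
  path <- sweep(motion, 2, p0, `+`)
  mk <- function(cam) {
    px <- project_points(cam, path)
    motion_trace2d(t = (seq_len(nrow(px)) - 1) / framerate,
                   du = px[, 1] - px[1, 1], dv = px[, 2] - px[1, 2],
                   quality = rep(1, nrow(px)), framerate)
  }
  list(a = mk(cams[[1]]), b = mk(cams[[2]]),
       px0_a = project_points(cams[[1]], p0)[1, ],
       px0_b = project_points(cams[[2]], p0)[1, ])
}

test_that("initial_position recovers a point from its exact projections", {
  cams <- make_camera_pair()
  p <- c(23.4, -41.2, -160.5)
  got <- initial_position(cams[[1]], project_points(cams[[1]], p)[1, ],
                          cams[[2]], project_points(cams[[2]], p)[1, ])
  expect_lt(max(abs(got$point - p)), 1e-9)
  expect_lt(got$gap, 1e-9)
})

test_that("triangulation error shrinks as camera vergence grows", {
  p <- c(0, 0, -150)
  set.seed(8)
  err_at <- function(verg) {
    cams <- make_camera_pair(vergence_deg = verg)
    errs <- replicate(40, {
      da <- runif(2, -0.5, 0.5); db <- runif(2, -0.5, 0.5)
      got <- initial_position(cams[[1]],
                              project_points(cams[[1]], p)[1, ] + da,
                              cams[[2]],
                              project_points(cams[[2]], p)[1, ] + db)
      sqrt(sum((got$point - p)^2))
    })
    mean(errs)
  }
  e <- vapply(c(10, 30, 60, 90) / 2, err_at, 0)
  expect_true(all(diff(e) < 0))
})

test_that("zero-baseline stereo is rejected", {
  cam <- frontal_camera()
  expect_error(initial_position(cam, c(400, 300), cam, c(400, 300)),
               "parallel")
})

test_that("zero traces reproduce the static initial position", {
  cams <- make_camera_pair()
  p0 <- c(10, -20, -140)
  tr <- exact_traces(cams, p0, matrix(0, 50, 3))
  got <- stereo_trace(cams[[1]], tr$a, tr$px0_a, cams[[2]], tr$b, tr$px0_b)
  expect_lt(max(abs(got$p0 - p0)), 1e-9)
  expect_lt(max(abs(c(got$dx, got$dy, got$dz))), 1e-9)
  ip <- initial_position(cams[[1]], tr$px0_a, cams[[2]], tr$px0_b)
  expect_equal(got$p0, ip$point)
})

test_that("exact 2D traces reconstruct commanded 3D motion to machine precision", {
  cams <- make_camera_pair()
  p0 <- c(5, 12, -155)
  motion <- cbind(sinusoid_motion(1000, 0.05, c(2, 0, 0), 40)[, 1],
                  sinusoid_motion(1000, 0.05, c(0, 3, 0), 25)[, 2],
                  sinusoid_motion(1000, 0.05, c(0, 0, 4), 15)[, 3])
  tr <- exact_traces(cams, p0, motion)
  got <- stereo_trace(cams[[1]], tr$a, tr$px0_a, cams[[2]], tr$b, tr$px0_b)
  expect_lt(max(abs(got$dx - motion[, 1])), 1e-8)
  expect_lt(max(abs(got$dy - motion[, 2])), 1e-8)
  expect_lt(max(abs(got$dz - motion[, 3])), 1e-8)
  expect_lt(max(got$gap), 1e-8)
})

test_that("a world rotation of rig and motion rotates the recovered trace", {
  cams <- make_camera_pair()
  p0 <- c(0, 0, -150)
  motion <- sinusoid_motion(1000, 0.05, c(1.5, 2.5, 1), 30)
  base <- {
    tr <- exact_traces(cams, p0, motion)
    stereo_trace(cams[[1]], tr$a, tr$px0_a, cams[[2]], tr$b, tr$px0_b)
  }
  al <- 0.3
  rot <- rbind(c(cos(al), 0, sin(al)), c(0, 1, 0), c(-sin(al), 0, cos(al)))
  rcams <- lapply(cams, function(cm)
    camera_model(as.numeric(rot %*% cm$position), cm$pan + al, cm$tilt,
                 cm$focal_distance, cm$pixel_pitch, cm$resolution,
                 cm$principal_point))
  rp0 <- as.numeric(rot %*% p0)
  rmotion <- motion %*% t(rot)
  tr <- exact_traces(rcams, rp0, rmotion)
  got <- stereo_trace(rcams[[1]], tr$a, tr$px0_a, rcams[[2]], tr$b, tr$px0_b)
  want <- cbind(base$dx, base$dy, base$dz) %*% t(rot)
  expect_equal(cbind(got$dx, got$dy, got$dz), want, tolerance = 1e-6)
})

test_that("gap and geometry are invariant to camera order", {
  cams <- make_camera_pair()
  p0 <- c(8, -15, -150)
  motion <- sinusoid_motion(1000, 0.03, c(1, 1, 2), 50)
  tr <- exact_traces(cams, p0, motion)
  ab <- stereo_trace(cams[[1]], tr$a, tr$px0_a, cams[[2]], tr$b, tr$px0_b)
  ba <- stereo_trace(cams[[2]], tr$b, tr$px0_b, cams[[1]], tr$a, tr$px0_a)
  expect_equal(ab$gap, ba$gap)
  expect_equal(ab$dx, ba$dx)
})

test_that("out-of-bounds augmented pixels are flagged, not dropped", {
  cams <- make_camera_pair()
  n <- 10
  tr_a <- motion_trace2d((0:(n - 1)) / 1000, c(0, rep(900, n - 1)),
                         numeric(n), rep(1, n), 1000)
  tr_b <- motion_trace2d((0:(n - 1)) / 1000, numeric(n), numeric(n),
                         rep(1, n), 1000)
  p <- c(0, 0, -150)
  got <- stereo_trace(cams[[1]], tr_a, project_points(cams[[1]], p)[1, ],
                      cams[[2]], tr_b, project_points(cams[[2]], p)[1, ])
  expect_false(got$out_of_bounds[1])
  expect_true(all(got$out_of_bounds[-1]))
  expect_equal(length(got$dx), n)
})

test_that("depth-axis noise exceeds image-plane-axis noise on a static scene", {
  fx <- fix_static_stereo()
  tr3 <- stereo_trace(fx$spec$cameras[[1]], fx$trace_a, fx$truth$px0_a,
                      fx$spec$cameras[[2]], fx$trace_b, fx$truth$px0_b)
  sel <- 50:250
  rms <- function(x) sqrt(mean(x^2))
  expect_gt(rms(tr3$dz[sel]), rms(tr3$dy[sel]))
  expect_gt(rms(tr3$dz[sel]), rms(tr3$dx[sel]))
})

test_that("commanded Y motion is recovered through the rendered stereo pipeline", {
  fx <- fix_y15()
  tr3 <- stereo_trace(fx$spec$cameras[[1]], fx$trace_a, fx$truth$px0_a,
                      fx$spec$cameras[[2]], fx$trace_b, fx$truth$px0_b)
  sel <- 80:420
  expect_equal(max(abs(tr3$dy[sel])), 5, tolerance = 0.15)
  expect_lt(max(abs(tr3$p0 - c(0, 0, -150))), 0.5)
})

test_that("motion along the camera bisector is recovered with bounded extra error", {
  fy <- fix_y15()
  cams <- fy$spec$cameras
  motion_z <- sinusoid_motion(1000, 0.5, c(0, 0, 5), 15)
  sp <- scene_spec(cams, motion_z, 1000, make_texture(256, seed = 7),
                   texel_mm = 0.5, noise_sigma = 0.005, supersample = 4,
                   seed = 11, crop_size = 48)
  r <- render_stereo(sp)
  tr3z <- stereo_trace(cams[[1]], motion_trace(r$clip_a, 2), r$truth$px0_a,
                       cams[[2]], motion_trace(r$clip_b, 2), r$truth$px0_b)
  tr3y <- stereo_trace(cams[[1]], fy$trace_a, fy$truth$px0_a,
                       cams[[2]], fy$trace_b, fy$truth$px0_b)
  sel <- 80:420
  err_z <- sqrt(mean((tr3z$dz[sel] - motion_z[sel, 3])^2))
  err_y <- sqrt(mean((tr3y$dy[sel] - sinusoid_motion(1000, 0.5, c(0, 5, 0),
                                                     15)[sel, 2])^2))
  expect_lt(err_z, 3 * err_y)
  # correct sign and frequency
  expect_gt(cor(tr3z$dz[sel], motion_z[sel, 3]), 0.99)
})

test_that("align_by_events finds a known delay and flags white noise", {
  fr <- 1000
  t <- seq(0, 0.999, by = 1 / fr)
  s <- exp(-(t - 0.3) / 0.08) * sin(2 * pi * 12 * (t - 0.3)) * (t >= 0.3)
  delayed <- c(rep(0, 250), s[1:750])
  got <- align_by_events(delayed, s, fr, max_lag = 0.4)
  expect_equal(got$lag, 0.25, tolerance = 1e-9)
  expect_true(got$reliable)

  set.seed(9)
  peaks <- replicate(200, {
    align_by_events(rnorm(400), rnorm(400), fr, 0.05)$peak_correlation
  })
  expect_lt(stats::quantile(peaks, 0.9), 0.2)
  expect_gt(mean(peaks < 0.2), 0.8)

  expect_error(align_by_events(rnorm(100), rep(1, 100), fr, 0.01), "flat")
  expect_error(align_by_events(rnorm(10), rnorm(10), fr, 0.05), "overlap")
})
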