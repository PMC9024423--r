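# Fusion of two calibrated 2D motion traces into a 3D displacement trace.
#
# Per frame, each camera's frame-0 pixel is augmented by that camera's
# cumulative sub-pixel displacement estimate; the two augmented rays are
# triangulated (midpoint of the common perpendicular) and the motion is
# reported relative to the frame-0 position. Sub-pixel coordinates feed
# the continuous pinhole model directly — nothing is re-rasterized.

#' Triangulated initial position of an object seen by two cameras
#'
#' @param cam_a,cam_b Calibrated [camera_model()]s.
#' @param px_a,px_b Pixel coordinates `(u, v)` of the object in the first
#'   frame of each video.
#' @return List with `point` (world mm) and `gap` (closest-approach
#'   distance between the two rays, mm — a triangulation quality measure).
#' @export
initial_position <- function(cam_a, px_a, cam_b, px_b) {
  triangulate(cast_ray(cam_a, px_a), cast_ray(cam_b, px_b))
}

#' A 3D motion trace
#'
#' @param t Seconds.
#' @param p0 Initial triangulated world position, mm.
#' @param dx,dy,dz Displacement from `p0` per frame, mm.
#' @param gap Per-frame ray closest-approach distance, mm.
#' @param out_of_bounds Logical per frame: augmented pixel left the image
#'   in at least one camera (flagged, not dropped).
#' @return Object of class `motion_trace3d`.
#' @export
motion_trace3d <- function(t, p0, dx, dy, dz, gap,
                           out_of_bounds = rep(FALSE, length(t))) {
  stopifnot(length(dx) == length(t), length(dy) == length(t),
            length(dz) == length(t), length(gap) == length(t),
            abs(dx[1]) < 1e-9, abs(dy[1]) < 1e-9, abs(dz[1]) < 1e-9)
  structure(list(t = t, p0 = as.numeric(p0), dx = dx, dy = dy, dz = dz,
                 gap = gap, out_of_bounds = out_of_bounds),
            class = "motion_trace3d")
}

#' @export
as.data.frame.motion_trace3d <- function(x, ...) {
  data.frame(t = x$t,
             x = x$p0[1] + x$dx, y = x$p0[2] + x$dy, z = x$p0[3] + x$dz,
             dx = x$dx, dy = x$dy, dz = x$dz, gap = x$gap)
}

#' Compose two 2D motion traces into a 3D displacement trace
#'
#' For frame `k`, rays are cast through `px0 + (du[k], dv[k])` in each
#' camera and triangulated; displacement is `position[k] - position[1]`.
#' Frames whose augmented pixel leaves the image bounds are flagged in
#' `out_of_bounds` but still triangulated (the pinhole model extends
#' continuously beyond the sensor).
#'
#' @param cam_a,cam_b Calibrated [camera_model()]s.
#' @param trace_a,trace_b [motion_trace2d()]s of the same object, equal
#'   length and framerate.
#' @param px_a0,px_b0 Frame-0 pixel coordinates of the object.
#' @return A [motion_trace3d()].
#' @export
stereo_trace <- function(cam_a, trace_a, px_a0, cam_b, trace_b, px_b0) {
  stopifnot(inherits(trace_a, "motion_trace2d"),
            inherits(trace_b, "motion_trace2d"),
            length(trace_a$t) == length(trace_b$t),
            abs(trace_a$framerate - trace_b$framerate) < 1e-9)
  pa <- cbind(px_a0[1] + trace_a$du, px_a0[2] + trace_a$dv)
  pb <- cbind(px_b0[1] + trace_b$du, px_b0[2] + trace_b$dv)
  oob <- pa[, 1] < 0 | pa[, 1] > cam_a$resolution[1] |
    pa[, 2] < 0 | pa[, 2] > cam_a$resolution[2] |
    pb[, 1] < 0 | pb[, 1] > cam_b$resolution[1] |
    pb[, 2] < 0 | pb[, 2] > cam_b$resolution[2]
  da <- ray_directions(cam_a, pa)
  db <- ray_directions(cam_b, pb)
  tri <- triangulate_many(cam_a$position, da, db, cam_b$position)
  p0 <- tri$point[1, ]
  motion_trace3d(trace_a$t, p0,
                 tri$point[, 1] - p0[1], tri$point[, 2] - p0[2],
                 tri$point[, 3] - p0[3], tri$gap, oob)
}

#' Write a 3D trace as CSV plus a JSON header
#'
#' CSV columns `t, x, y, z, dx, dy, dz, gap`; `<path>.json` records the
#' initial position, camera files and configuration hash.
#'
#' @param trace A [motion_trace3d()].
#' @param path CSV path.
#' @param camera_files Optional character vector recorded in the header.
#' @param config_hash Optional string recorded in the header.
#' @export
write_trace3d <- function(trace, path, camera_files = NULL,
                          config_hash = NULL) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  jsonlite::write_json(
    list(p0 = trace$p0, camera_files = camera_files,
         config_hash = config_hash, n_frames = length(trace$t)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace3d
#' @export
read_trace3d <- function(path) {
  d <- utils::read.csv(path)
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  motion_trace3d(d$t, hdr$p0, d$dx, d$dy, d$dz, d$gap)
}

#' Estimate the time lag between a trace and a reference series
#'
#' Automated stand-in for manual event alignment: the lag maximizing the
#' normalized cross-correlation within `± max_lag`. A positive lag means
#' `trace` lags `reference` (shift `trace` earlier by `lag` to align).
#'
#' @param trace,reference Numeric series sampled at `framerate`.
#' @param framerate Hz.
#' @param max_lag Maximum lag searched, seconds. Series must overlap for
#'   more than `2 * max_lag`.
#' @param reliability_threshold Peak correlations below this are flagged
#'   `reliable = FALSE` (default 0.2).
#' @return List with `lag` (s), `peak_correlation`, `reliable`.
#' @export
align_by_events <- function(trace, reference, framerate, max_lag,
                            reliability_threshold = 0.2) {
  n <- min(length(trace), length(reference))
  lag_frames <- round(max_lag * framerate)
  if (n <= 2 * lag_frames) stop("overlap shorter than 2 * max_lag")
  if (stats::sd(reference) == 0) {
    stop("flat reference series: correlation undefined")
  }
  cc <- stats::ccf(trace[seq_len(n)], reference[seq_len(n)],
                   lag.max = lag_frames, plot = FALSE, demean = TRUE)
  i <- which.max(cc$acf)
  # ccf(x, y) peak at positive lag k means x[t + k] ~ y[t]: x lags y by k
  lag <- cc$lag[i] / framerate
  peak <- cc$acf[i]
  list(lag = lag, peak_correlation = peak,
       reliable = peak >= reliability_threshold)
}
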