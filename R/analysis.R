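# Time-domain analytics on displacement traces: windowed power, event
# detection, first-peak timing, and wave-speed estimation.

#' Sliding-window time-domain power of a 3D trace
#'
#' Windowed mean of the squared 3D displacement magnitude
#' `||(dx, dy, dz)||^2`. Peak locations are invariant to global scaling of
#' the trace, which makes the power trace a robust event detector even
#' when absolute amplitude calibration is uncertain.
#'
#' @param trace A [motion_trace3d()], or a numeric vector treated as a
#'   single-axis displacement series (then `framerate` is required).
#' @param window Window length, seconds (>= 3 frames).
#' @param framerate Needed only when `trace` is a bare numeric vector.
#' @return Object of class `power_trace`: `t` (window centres, s),
#'   `power` (mm^2), `window` (s), `framerate`.
#' @export
windowed_power <- function(trace, window, framerate = NULL) {
  if (inherits(trace, "motion_trace3d")) {
    mag2 <- trace$dx^2 + trace$dy^2 + trace$dz^2
    framerate <- 1 / stats::median(diff(trace$t))
    t0 <- trace$t[1]
  } else {
    stopifnot(!is.null(framerate))
    mag2 <- as.numeric(trace)^2
    t0 <- 0
  }
  wf <- round(window * framerate)
  if (wf < 3) stop("window must span at least 3 frames")
  if (wf > length(mag2)) stop("window longer than the trace")
  p <- zoo::rollmean(mag2, wf)
  centres <- t0 + (seq_along(p) - 1 + (wf - 1) / 2) / framerate
  structure(list(t = centres, power = p, window = window,
                 framerate = framerate),
            class = "power_trace")
}

#' @export
as.data.frame.power_trace <- function(x, ...) {
  data.frame(t = x$t, power = x$power)
}

#' Detect vibration events in a power trace
#'
#' Events are maximal runs of power above `threshold_factor` times the
#' baseline median power; runs separated by less than `min_separation`
#' are merged.
#'
#' @param power A [windowed_power()] result.
#' @param threshold_factor Multiple of the median power (> 1).
#' @param min_separation Minimum gap between distinct events, seconds.
#' @return Data frame with one row per event: `onset`, `peak_time`,
#'   `end`, `peak_power`. Zero rows when nothing crosses the threshold.
#' @export
detect_events <- function(power, threshold_factor = 5, min_separation = 0.5) {
  stopifnot(inherits(power, "power_trace"), threshold_factor > 1)
  thr <- threshold_factor * stats::median(power$power)
  above <- power$power > thr
  if (!any(above)) {
    return(data.frame(onset = numeric(0), peak_time = numeric(0),
                      end = numeric(0), peak_power = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by < min_separation
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- power$t[runs$start[i]] - power$t[merged$end[nrow(merged)]]
      if (gap < min_separation) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  do.call(rbind, lapply(seq_len(nrow(merged)), function(i) {
    idx <- merged$start[i]:merged$end[i]
    pk <- idx[which.max(power$power[idx])]
    data.frame(onset = power$t[merged$start[i]], peak_time = power$t[pk],
               end = power$t[merged$end[i]], peak_power = power$power[pk])
  }))
}

# Prominence of local maxima: height above the higher of the two minima
# separating the peak from the nearest higher peak (or series edge).
#' @noRd
peak_prominences <- function(x, peaks) {
  vapply(peaks, function(p) {
    # bases: minimum between the peak and the nearest strictly-higher
    # sample on each side (or the series edge)
    higher_left <- which(x[seq_len(p - 1)] > x[p])
    lb <- if (length(higher_left)) min(x[(max(higher_left) + 1):p]) else min(x[1:p])
    higher_right <- which(x[(p + 1):length(x)] > x[p]) + p
    rb <- if (length(higher_right)) min(x[p:(min(higher_right) - 1)]) else
      min(x[p:length(x)])
    x[p] - max(lb, rb)
  }, 0)
}

#' Time of the first qualifying displacement peak in a window
#'
#' Finds the first local maximum of `|trace|` inside `event_window` whose
#' prominence exceeds `min_prominence`, and refines its time below the
#' frame interval by parabolic interpolation over the three samples
#' around the peak.
#'
#' @param trace Numeric displacement series.
#' @param t Time stamps, seconds (same length).
#' @param event_window `(t0, t1)` seconds, within the trace.
#' @param min_prominence Required peak prominence (> 0), in `|trace|`
#'   units.
#' @return Peak time in seconds.
#' @export
first_peak_time <- function(trace, t, event_window, min_prominence) {
  stopifnot(length(trace) == length(t), min_prominence > 0,
            event_window[1] >= t[1] - 1e-12,
            event_window[2] <= t[length(t)] + 1e-12)
  sel <- which(t >= event_window[1] & t <= event_window[2])
  x <- abs(trace[sel])
  n <- length(x)
  if (n < 3) stop("event window too short")
  cand <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  if (length(cand) == 0) stop("no local maximum in the event window")
  prom <- peak_prominences(x, cand)
  cand <- cand[prom > min_prominence]
  if (length(cand) == 0) stop("no peak exceeds the prominence threshold")
  p <- cand[1]
  # parabolic sub-frame refinement
  y0 <- x[p - 1]; y1 <- x[p]; y2 <- x[p + 1]
  denom <- y0 - 2 * y1 + y2
  delta <- if (abs(denom) < 1e-300) 0 else 0.5 * (y0 - y2) / denom
  delta <- max(min(delta, 0.5), -0.5)
  dt <- t[sel[2]] - t[sel[1]]
  t[sel[p]] + delta * dt
}

#' Summarize per-event wave speeds
#'
#' @param events Data frame with at least `speed` (m/s); typically also
#'   `t_source`, `t_dest`, `delay`, `distance`.
#' @return Object of class `wave_speed_estimate` with the per-event table
#'   and `mean_speed` (arithmetic mean, m/s).
#' @export
wave_speed_estimate <- function(events) {
  events <- as.data.frame(events)
  stopifnot("speed" %in% names(events), nrow(events) >= 1)
  structure(list(events = events, mean_speed = mean(events$speed)),
            class = "wave_speed_estimate")
}

#' @export
print.wave_speed_estimate <- function(x, ...) {
  cat("<wave_speed_estimate>\n")
  print(x$events)
  cat(sprintf("mean speed: %.4g m/s over %d event(s)\n",
              x$mean_speed, nrow(x$events)))
  invisible(x)
}

#' Estimate wave speed from peak-arrival delays between two points
#'
#' For each event window, the first qualifying displacement peak is timed
#' at the source and destination traces ([first_peak_time()]); the speed
#' is the 3D distance between the measurement points divided by the
#' arrival delay. Events with non-positive delay are excluded and
#' flagged. Works on any scalar displacement series — an axis projection
#' ([project_onto_axis()]) or a 3D magnitude.
#'
#' @param trace_src,trace_dst Numeric displacement series (same sampling).
#' @param t Time stamps, seconds.
#' @param p_src,p_dst World positions of the two measurement points, mm;
#'   must differ.
#' @param events List of `(t0, t1)` event windows (or 2-column matrix).
#' @param min_prominence Passed to [first_peak_time()]; default 25% of
#'   each event's peak |displacement| at the source.
#' @return A [wave_speed_estimate()]; excluded events are kept in
#'   `attr(, "excluded")`.
#' @export
wave_speed <- function(trace_src, trace_dst, t, p_src, p_dst, events,
                       min_prominence = NULL) {
  p_src <- as.numeric(p_src); p_dst <- as.numeric(p_dst)
  dist_mm <- vnorm(p_dst - p_src)
  if (dist_mm == 0) stop("source and destination positions coincide")
  if (is.matrix(events)) events <- asplit(events, 1)
  rows <- lapply(events, function(win) {
    win <- as.numeric(win)
    sel <- t >= win[1] & t <= win[2]
    prom_s <- min_prominence %||% (0.25 * max(abs(trace_src[sel])))
    prom_d <- min_prominence %||% (0.25 * max(abs(trace_dst[sel])))
    t_s <- first_peak_time(trace_src, t, win, prom_s)
    t_d <- first_peak_time(trace_dst, t, win, prom_d)
    delay <- t_d - t_s
    data.frame(t_source = t_s, t_dest = t_d, delay = delay,
               distance = dist_mm,
               speed = if (delay > 0) dist_mm / delay / 1000 else NA_real_)
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$speed)
  if (!any(ok)) stop("all events have non-positive arrival delay")
  est <- wave_speed_estimate(tab[ok, , drop = FALSE])
  attr(est, "excluded") <- tab[!ok, , drop = FALSE]
  est
}

#' Write a wave-speed report as JSON
#'
#' @param estimate A [wave_speed_estimate()].
#' @param path Output path.
#' @export
write_wave_speed <- function(estimate, path) {
  jsonlite::write_json(
    list(mean_speed_m_per_s = estimate$mean_speed, events = estimate$events),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
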