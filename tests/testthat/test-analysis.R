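mk_trace3d <- function(dx, dy, dz, framerate = 1000) {
  n <- length(dx)
  motion_trace3d((0:(n - 1)) / framerate, c(0, 0, 0), dx, dy, dz,
                 gap = rep(0, n))
}

test_that("windowed_power follows its closed forms", {
  fr <- 1000
  n <- 1000
  # zero trace -> zero power
  z <- mk_trace3d(numeric(n), numeric(n), numeric(n))
  expect_true(all(windowed_power(z, 0.05)$power == 0))
  # unit sinusoid, window >> period -> 0.5 in the interior
  t <- (0:(n - 1)) / fr
  s <- mk_trace3d(c(0, sin(2 * pi * 20 * t[-1])), numeric(n), numeric(n))
  pw <- windowed_power(s, 0.5)
  expect_equal(mean(pw$power[200:300]), 0.5, tolerance = 1e-3)
  # quadratic scaling
  s3 <- mk_trace3d(3 * s$dx, numeric(n), numeric(n))
  expect_equal(windowed_power(s3, 0.5)$power, 9 * pw$power)
  # window preconditions
  expect_error(windowed_power(z, 0.001), "3 frames")
  expect_error(windowed_power(z, 2), "longer than")
})

test_that("windowed_power of a trace and its negation is symmetric", {
  set.seed(1)
  x <- cumsum(rnorm(300)) / 10
  joined <- c(x, -rev(x))
  pw <- windowed_power(joined, 0.05, framerate = 1000)
  expect_equal(pw$power, rev(pw$power), tolerance = 1e-12)
})

test_that("detect_events finds injected bursts and merges close ones", {
  fr <- 1000
  t <- (0:999) / fr
  y <- 0.02 * sin(2 * pi * 37 * t)
  for (t0 in c(0.2, 0.5, 0.8)) {
    y <- y + 2 * exp(-((t - t0) / 0.02)^2) * sin(2 * pi * 30 * (t - t0))
  }
  pw <- windowed_power(y, 0.05, framerate = fr)
  ev <- detect_events(pw, threshold_factor = 5, min_separation = 0.1)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$peak_time, c(0.2, 0.5, 0.8), tolerance = 0.06)
  # bursts closer than min_separation merge
  ev2 <- detect_events(pw, threshold_factor = 5, min_separation = 0.4)
  expect_equal(nrow(ev2), 1)
})

test_that("flat noise produces no events at a 5x threshold", {
  set.seed(2)
  fp <- replicate(100, {
    pw <- windowed_power(0.1 * rnorm(600), 0.05, framerate = 1000)
    nrow(detect_events(pw, threshold_factor = 5, min_separation = 0.1))
  })
  expect_lt(mean(fp > 0), 0.05)
})

test_that("event count is non-increasing in the threshold factor", {
  set.seed(3)
  t <- (0:999) / 1000
  y <- 0.1 * rnorm(1000)
  for (t0 in c(0.25, 0.65)) {
    y <- y + exp(-((t - t0) / 0.03)^2) * sin(2 * pi * 25 * (t - t0))
  }
  pw <- windowed_power(y, 0.05, framerate = 1000)
  counts <- vapply(c(1.5, 3, 5, 10, 50),
                   function(k) nrow(detect_events(pw, k, 0.1)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("first_peak_time honors the 'first' rule and refines sub-frame", {
  fr <- 1000
  t <- (0:1999) / fr
  # unique triangular pulse peaking exactly at 1.000 s
  tri <- pmax(0, 1 - abs(t - 1) / 0.05)
  expect_equal(first_peak_time(tri, t, c(0.8, 1.2), 0.2), 1.000)
  # first smaller peak above prominence wins over the larger later one
  two <- 0.5 * pmax(0, 1 - abs(t - 0.5) / 0.03) + pmax(0, 1 - abs(t - 0.8) / 0.03)
  expect_equal(first_peak_time(two, t, c(0.3, 1.0), 0.2), 0.5,
               tolerance = 1e-6)
  # sampled sinusoid with an off-sample peak
  s <- sin(2 * pi * 7.3 * (t - 0.0123))
  true_pk <- 0.0123 + 1 / (4 * 7.3)
  got <- first_peak_time(s, t, c(0, 0.09), 0.2)
  expect_lt(abs(got - true_pk), 0.2 / fr)
  # no qualifying peak
  expect_error(first_peak_time(tri, t, c(0.8, 1.2), 10), "prominence")
})

test_that("wave_speed follows its definition and the peak-delay pipeline", {
  # distance 1 m, delay 50 ms -> 20 m/s
  est <- wave_speed_estimate(data.frame(speed = 1000 / 0.050 / 1000))
  expect_equal(est$mean_speed, 20)

  fr <- 1000
  t <- seq(0, 0.999, by = 1 / fr)
  src <- 3 * exp(-(t - 0.3) / 0.08) * sin(2 * pi * 12 * (t - 0.3)) * (t >= 0.3)
  dst <- c(rep(0, 7), src[1:(length(src) - 7)])
  ws <- wave_speed(src, dst, t, c(0, 0, 0), c(140, 0, 0),
                   events = list(c(0.25, 0.7)))
  expect_equal(ws$events$delay, 0.007, tolerance = 0.05)
  expect_equal(ws$events$speed, 20, tolerance = 0.05)
})

test_that("wave_speed is invariant to common shifts of time and space", {
  fr <- 1000
  t <- seq(0, 0.999, by = 1 / fr)
  src <- exp(-(t - 0.3) / 0.05) * sin(2 * pi * 15 * (t - 0.3)) * (t >= 0.3)
  dst <- c(rep(0, 12), src[1:(length(src) - 12)])
  base <- wave_speed(src, dst, t, c(0, 0, 0), c(100, 50, -30),
                     events = list(c(0.25, 0.6)))
  shifted <- wave_speed(src, dst, t + 0.37, c(200, -100, 5) + c(0, 0, 0),
                        c(200, -100, 5) + c(100, 50, -30),
                        events = list(c(0.25, 0.6) + 0.37))
  expect_equal(shifted$events$speed, base$events$speed, tolerance = 1e-9)
})

test_that("events with non-positive delay are excluded and flagged", {
  fr <- 1000
  t <- seq(0, 0.999, by = 1 / fr)
  src <- exp(-(t - 0.4) / 0.05) * sin(2 * pi * 15 * (t - 0.4)) * (t >= 0.4)
  lead <- c(src[11:length(src)], rep(0, 10))  # destination peaks first
  expect_error(wave_speed(src, lead, t, c(0, 0, 0), c(100, 0, 0),
                          events = list(c(0.35, 0.7))),
               "non-positive")
  # mixed: one causal event, one acausal -> acausal excluded
  dst <- c(rep(0, 10), src[1:(length(src) - 10)])
  src2 <- src + exp(-(t - 0.8) / 0.04) * sin(2 * pi * 15 * (t - 0.8)) * (t >= 0.8)
  dst2 <- dst + c(exp(-(t - 0.79) / 0.04) * sin(2 * pi * 15 * (t - 0.79)) *
                    (t >= 0.79))[1:length(t)]
  ws <- wave_speed(src2, dst2, t, c(0, 0, 0), c(100, 0, 0),
                   events = list(c(0.35, 0.7), c(0.75, 0.95)))
  expect_equal(nrow(ws$events) + nrow(attr(ws, "excluded")), 2)
})

test_that("wave-speed reports round-trip through JSON", {
  est <- wave_speed_estimate(data.frame(t_source = 1, t_dest = 1.01,
                                        delay = 0.01, distance = 200,
                                        speed = 20))
  f <- withr::local_tempfile(fileext = ".json")
  write_wave_speed(est, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$mean_speed_m_per_s, 20)
  expect_equal(back$events$speed, 20)
})
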