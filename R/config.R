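# Run configuration, validation, and the end-to-end pipeline.
#
# A run configuration ties together the input videos, the calibration
# file, the crop regions, and the analysis parameters. Frequency settings
# are validated against the camera framerate: the Nyquist frequency (half
# the framerate) is a hard upper bound on any analysis band, and bands
# above a quarter of the framerate draw a warning — the practical upper
# bound for vibration analysis from video.

#' Default run configuration
#'
#' @param videos Named list `a`, `b` of clip directories.
#' @param calibration_csv Calibration CSV (see [read_calibration_csv()]).
#' @param out_dir Output directory for artifacts.
#' @param cameras Named list `a`, `b`; each either a camera JSON path, or
#'   a list with `id`, `position_xz` (mm), `resolution`, `pixel_pitch`,
#'   and optional grid-search `center` for calibration.
#' @param crops Named list `a`, `b` of frame-0 pixel coordinates `(u, v)`
#'   of the analyzed object in each full camera frame.
#' @param levels,band,sigma Vibrometry parameters (pyramid levels,
#'   band-pass Hz, spatial blur px).
#' @param window,threshold_factor,min_separation,prominence_frac Analysis
#'   parameters: power window (s), event threshold (multiple of median
#'   power), event separation (s), peak prominence as a fraction of the
#'   event peak.
#' @param seed Integer seed recorded in the manifest and used for any
#'   stochastic step.
#' @return List of class `run_config`.
#' @export
run_config <- function(videos = NULL, calibration_csv = NULL,
                       out_dir = "stereovibro_out", cameras = NULL,
                       crops = NULL, levels = 2L, band = c(5, 100),
                       sigma = 2, window = 0.2, threshold_factor = 5,
                       min_separation = 0.5, prominence_frac = 0.25,
                       seed = 1L) {
  structure(list(videos = videos, calibration_csv = calibration_csv,
                 out_dir = out_dir, cameras = cameras, crops = crops,
                 levels = levels, band = band, sigma = sigma,
                 window = window, threshold_factor = threshold_factor,
                 min_separation = min_separation,
                 prominence_frac = prominence_frac, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- do.call(run_config, raw[intersect(names(raw),
                                           names(formals(run_config)))])
  cfg
}

#' Validate a run configuration against a framerate
#'
#' Checks the analysis band against the sampling limits: an upper edge at
#' or above the Nyquist frequency (`framerate / 2`) is a hard error; an
#' edge above the recommended quarter-rate bound (`framerate / 4`) only
#' warns. Missing parameters are filled with documented defaults.
#'
#' @param cfg A [run_config()] (or plain list).
#' @param framerate Recording framerate, Hz.
#' @return List with `config` (defaults filled), `errors` (character,
#'   field-named), `warnings` (character), `ok` (no errors),
#'   `nyquist_hz`, and `recommended_max_hz` (`framerate / 4`).
#' @export
validate_config <- function(cfg, framerate) {
  if (!inherits(cfg, "run_config")) cfg <- do.call(run_config, as.list(cfg))
  errors <- character(0)
  warnings <- character(0)
  if (framerate <= 0) errors <- c(errors, "framerate: must be positive")
  band <- cfg$band %||% c(5, 100)
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2]) {
    errors <- c(errors, "band: need 0 < low < high")
  } else {
    if (band[2] >= framerate / 2) {
      errors <- c(errors,
                  sprintf("band: upper edge %g Hz at/above Nyquist (%g Hz)",
                          band[2], framerate / 2))
    } else if (band[2] > framerate / 4) {
      warnings <- c(warnings,
                    sprintf(paste0("band: upper edge %g Hz above the ",
                                   "recommended quarter-rate bound (%g Hz)"),
                            band[2], framerate / 4))
    }
  }
  if (cfg$levels < 1) errors <- c(errors, "levels: must be >= 1")
  if (cfg$sigma <= 0) errors <- c(errors, "sigma: must be > 0")
  if (cfg$window <= 0) errors <- c(errors, "window: must be > 0")
  if (cfg$threshold_factor <= 1) {
    errors <- c(errors, "threshold_factor: must exceed 1")
  }
  list(config = cfg, errors = errors, warnings = warnings,
       ok = length(errors) == 0,
       nyquist_hz = framerate / 2, recommended_max_hz = framerate / 4)
}

#' @noRd
config_hash <- function(cfg) rlang::hash(unclass(cfg))

#' @noRd
log_stage <- function(stage, hash, t0) {
  message(sprintf("[stereovibro] stage=%s wall=%.2fs config=%s",
                  stage, as.numeric(Sys.time()) - t0, hash))
}

#' Run the full stereo vibrometry pipeline
#'
#' Stages: calibrate both cameras (or load camera JSONs) -> extract a 2D
#' motion trace per camera -> compose the 3D trace -> windowed power and
#' event detection. All intermediate artifacts (camera JSON, trace CSVs,
#' power and event tables) plus a run manifest (config hash, package
#' version, seed, artifact inventory) are written under `cfg$out_dir`.
#' Deterministic for fixed inputs and seed.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- as.numeric(Sys.time())
  hash <- config_hash(cfg)
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  add <- function(p) artifacts <<- c(artifacts, p)

  # --- inputs --------------------------------------------------------
  for (side in c("a", "b")) {
    if (is.null(cfg$videos[[side]]) || !dir.exists(cfg$videos[[side]])) {
      stop("pipeline stage 'inputs': missing video directory for camera '",
           side, "': ", cfg$videos[[side]] %||% "<unset>")
    }
  }
  clip_a <- read_clip(cfg$videos$a)
  clip_b <- read_clip(cfg$videos$b)
  chk <- validate_config(cfg, clip_a$framerate)
  if (!chk$ok) {
    stop("pipeline stage 'validate': ",
         paste(chk$errors, collapse = "; "))
  }
  for (w in chk$warnings) warning(w)
  log_stage("inputs", hash, t0)

  # --- calibrate -----------------------------------------------------
  cams <- list()
  for (side in c("a", "b")) {
    spec <- cfg$cameras[[side]]
    if (is.character(spec)) {
      cams[[side]] <- read_camera(spec)
    } else {
      if (is.null(cfg$calibration_csv) || !file.exists(cfg$calibration_csv)) {
        stop("pipeline stage 'calibrate': missing calibration file: ",
             cfg$calibration_csv %||% "<unset>")
      }
      calib <- read_calibration_csv(cfg$calibration_csv, spec$id,
                                    spec$resolution)
      gs <- grid_search_spec(spec$center,
                             steps = spec$steps %||% c(21L, 21L, 11L))
      fit <- calibrate_camera(calib, spec$position_xz, gs, spec$resolution,
                              spec$pixel_pitch)
      cams[[side]] <- fit$camera
    }
    f <- file.path(cfg$out_dir, paste0("camera_", side, ".json"))
    write_camera(cams[[side]], f); add(f)
  }
  log_stage("calibrate", hash, t0)

  # --- vibrate -------------------------------------------------------
  tr_a <- motion_trace(clip_a, cfg$levels, cfg$band, cfg$sigma)
  tr_b <- motion_trace(clip_b, cfg$levels, cfg$band, cfg$sigma)
  fa <- file.path(cfg$out_dir, "trace2d_a.csv")
  fb <- file.path(cfg$out_dir, "trace2d_b.csv")
  write_trace2d(tr_a, fa); add(fa)
  write_trace2d(tr_b, fb); add(fb)
  log_stage("vibrate", hash, t0)

  # --- stereo --------------------------------------------------------
  tr3 <- stereo_trace(cams$a, tr_a, cfg$crops$a, cams$b, tr_b, cfg$crops$b)
  f3 <- file.path(cfg$out_dir, "trace3d.csv")
  write_trace3d(tr3, f3,
                camera_files = file.path(cfg$out_dir,
                                         c("camera_a.json", "camera_b.json")),
                config_hash = hash)
  add(f3); add(paste0(f3, ".json"))
  log_stage("stereo", hash, t0)

  # --- analyze -------------------------------------------------------
  pw <- windowed_power(tr3, cfg$window)
  fp <- file.path(cfg$out_dir, "power.csv")
  utils::write.csv(as.data.frame(pw), fp, row.names = FALSE); add(fp)
  ev <- detect_events(pw, cfg$threshold_factor, cfg$min_separation)
  fe <- file.path(cfg$out_dir, "events.csv")
  utils::write.csv(ev, fe, row.names = FALSE); add(fe)
  log_stage("analyze", hash, t0)

  manifest <- list(config_hash = hash, seed = cfg$seed,
                   package_version = as.character(
                     utils::packageVersion("stereovibro")),
                   n_frames = length(tr_a$t), framerate = clip_a$framerate,
                   n_events = nrow(ev), artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
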