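# Camera calibration by epipolar-row anchoring and exhaustive grid search.
#
# The rig leaves three unknowns per camera: pan, tilt, and focal distance.
# The camera (x, z) position is tape-measured, and camera height is removed
# from the problem by the origin convention: the world origin is placed on
# the horizontal epipolar row (the image of the XZ plane through the focal
# points), so camera y = 0 by construction. The remaining parameters are
# found by discretized exhaustive search minimizing summed squared
# reconstruction error against known calibration points and known pairwise
# distances, with optional re-center-and-shrink refinement rounds.

#' Assemble a calibration set
#'
#' @param absolute_points Data frame with columns `u, v` (pixels), `x, y, z`
#'   (known world position, mm) and `plane` (the constraint plane the point
#'   lies on, e.g. `"z=0"` for the cage front face; rays are intersected
#'   with this plane before measuring the error).
#' @param distance_pairs Data frame with columns `u_i, v_i, u_j, v_j`
#'   (pixels), `distance` (known separation, mm) and `plane` (both points
#'   lie on it). May be `NULL`.
#' @param epipolar_lines Data frame of image line segments
#'   (`u0, v0, u1, v1`) whose world counterparts are parallel to the XZ
#'   plane; used by [fit_epipolar_row()]. May be `NULL`.
#' @param resolution Optional `(width, height)` used to check that all
#'   pixels fall inside the image.
#' @return Object of class `calibration_set`.
#' @export
calibration_set <- function(absolute_points, distance_pairs = NULL,
                            epipolar_lines = NULL, resolution = NULL) {
  absolute_points <- as.data.frame(absolute_points)
  n_abs <- nrow(absolute_points)
  n_pair <- if (is.null(distance_pairs)) 0L else nrow(distance_pairs)
  if (n_abs > 0) {
    stopifnot(all(c("u", "v", "x", "y", "z", "plane") %in%
                    names(absolute_points)))
  }
  if (n_pair > 0) {
    distance_pairs <- as.data.frame(distance_pairs)
    stopifnot(all(c("u_i", "v_i", "u_j", "v_j", "distance", "plane") %in%
                    names(distance_pairs)))
  }
  if (!(n_abs >= 3 || (n_abs >= 2 && n_pair >= 2))) {
    stop("under-constrained calibration set: need >= 3 absolute points, ",
         "or >= 2 absolute points plus >= 2 distance pairs")
  }
  if (!is.null(resolution)) {
    px <- rbind(
      as.matrix(absolute_points[, c("u", "v")]),
      if (n_pair > 0) as.matrix(distance_pairs[, c("u_i", "v_i")]),
      if (n_pair > 0) as.matrix(distance_pairs[, c("u_j", "v_j")])
    )
    if (any(px[, 1] < 0 | px[, 1] > resolution[1] |
            px[, 2] < 0 | px[, 2] > resolution[2])) {
      stop("calibration pixels outside image bounds")
    }
  }
  structure(list(absolute_points = absolute_points,
                 distance_pairs = distance_pairs,
                 epipolar_lines = epipolar_lines),
            class = "calibration_set")
}

#' Read calibration points from CSV
#'
#' Expected columns: `camera_id, kind, u, v, x, y, z, pair_id,
#' pair_distance_mm, plane`. Rows with `kind == "point"` become absolute
#' points; rows sharing a non-empty `pair_id` (exactly two rows per id)
#' become distance pairs with separation `pair_distance_mm`; rows with
#' `kind == "line"` are consumed in consecutive pairs of endpoints as
#' epipolar line segments.
#'
#' @param path CSV path.
#' @param camera_id Which camera's rows to keep.
#' @param resolution Optional bounds check, `(width, height)`.
#' @return A [calibration_set()].
#' @export
read_calibration_csv <- function(path, camera_id, resolution = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d <- d[d$camera_id == camera_id, , drop = FALSE]
  if (nrow(d) == 0) stop("no calibration rows for camera_id '", camera_id,
                         "' in ", path)
  pts <- d[d$kind == "point", , drop = FALSE]
  abs_pts <- data.frame(u = pts$u, v = pts$v, x = pts$x, y = pts$y,
                        z = pts$z, plane = pts$plane)
  prs <- d[d$kind == "pair" & nzchar(d$pair_id), , drop = FALSE]
  pairs <- NULL
  if (nrow(prs) > 0) {
    ids <- unique(prs$pair_id)
    pairs <- do.call(rbind, lapply(ids, function(id) {
      two <- prs[prs$pair_id == id, , drop = FALSE]
      if (nrow(two) != 2) stop("pair_id '", id, "' must have exactly 2 rows")
      data.frame(u_i = two$u[1], v_i = two$v[1], u_j = two$u[2],
                 v_j = two$v[2], distance = two$pair_distance_mm[1],
                 plane = two$plane[1])
    }))
  }
  lns <- d[d$kind == "line", , drop = FALSE]
  lines <- NULL
  if (nrow(lns) >= 2) {
    i <- seq(1, nrow(lns) - 1, by = 2)
    lines <- data.frame(u0 = lns$u[i], v0 = lns$v[i],
                        u1 = lns$u[i + 1], v1 = lns$v[i + 1])
  }
  calibration_set(abs_pts, pairs, lines, resolution)
}

#' Write calibration sets to CSV
#'
#' Inverse of [read_calibration_csv()]: one file holding the points,
#' distance pairs and epipolar line segments of one or more cameras.
#'
#' @param sets Named list of [calibration_set()]s; names are camera ids.
#' @param path Output CSV path.
#' @export
write_calibration_csv <- function(sets, path) {
  rows <- list()
  blank <- function(id, kind, u, v, x = NA, y = NA, z = NA, pair_id = "",
                    pair_distance_mm = NA, plane = "") {
    data.frame(camera_id = id, kind = kind, u = u, v = v, x = x, y = y,
               z = z, pair_id = pair_id, pair_distance_mm = pair_distance_mm,
               plane = plane)
  }
  for (id in names(sets)) {
    cs <- sets[[id]]
    ap <- cs$absolute_points
    rows[[length(rows) + 1]] <- blank(id, "point", ap$u, ap$v, ap$x, ap$y,
                                      ap$z, plane = ap$plane)
    dp <- cs$distance_pairs
    if (!is.null(dp) && nrow(dp) > 0) {
      for (i in seq_len(nrow(dp))) {
        pid <- paste0(id, "_pair", i)
        rows[[length(rows) + 1]] <- blank(
          id, "pair", c(dp$u_i[i], dp$u_j[i]), c(dp$v_i[i], dp$v_j[i]),
          pair_id = pid, pair_distance_mm = dp$distance[i],
          plane = dp$plane[i])
      }
    }
    el <- cs$epipolar_lines
    if (!is.null(el) && nrow(el) > 0) {
      for (i in seq_len(nrow(el))) {
        rows[[length(rows) + 1]] <- blank(
          id, "line", c(el$u0[i], el$u1[i]), c(el$v0[i], el$v1[i]))
      }
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Least-squares common intersection of image lines: the epipolar row
#'
#' World lines parallel to the XZ plane all image through a common
#' vanishing point whose image row is the horizontal epipolar line (for a
#' pan/tilt camera with no roll, the image of the XZ plane through the
#' focal point is a constant-`v` row). This fits the point minimizing the
#' sum of squared perpendicular distances to the extended image lines and
#' reports its `v` coordinate.
#'
#' @param lines Data frame of segments `u0, v0, u1, v1` (pixels), >= 2
#'   non-parallel lines.
#' @return List with `v` (pixels), `point` (u, v of the intersection), and
#'   `residual` (RMS point-to-line distance, pixels).
#' @export
fit_epipolar_row <- function(lines) {
  lines <- as.data.frame(lines)
  stopifnot(nrow(lines) >= 2)
  d <- cbind(lines$u1 - lines$u0, lines$v1 - lines$v0)
  len <- sqrt(rowSums(d^2))
  stopifnot(all(len > 0))
  d <- d / len
  n <- cbind(-d[, 2], d[, 1])                      # unit normals
  p <- cbind(lines$u0, lines$v0)
  # solve (sum n n^T) x = sum n n^T p
  a11 <- sum(n[, 1]^2); a12 <- sum(n[, 1] * n[, 2]); a22 <- sum(n[, 2]^2)
  amat <- matrix(c(a11, a12, a12, a22), 2, 2)
  if (abs(det(amat)) < 1e-12 * (a11 + a22)^2) {
    stop("all lines mutually parallel: no common intersection")
  }
  b <- colSums(n * rowSums(n * p))
  x <- solve(amat, b)
  res <- sqrt(mean((rowSums(n * sweep(p, 2, x)))^2))
  list(v = x[2], point = c(u = x[1], v = x[2]), residual = res)
}

#' @noRd
parse_plane <- function(plane) {
  m <- regmatches(plane, regexec("^\\s*([xyzXYZ])\\s*=\\s*(-?[0-9.eE+]+)\\s*$",
                                 plane))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("unparseable plane spec: ", plane[bad][1])
  axis <- match(tolower(vapply(m, `[`, "", 2L)), c("x", "y", "z"))
  value <- as.numeric(vapply(m, `[`, "", 3L))
  list(axis = axis, value = value)
}

# Precompute numeric arrays for fast repeated error evaluation.
#' @noRd
calib_arrays <- function(calib, position, pixel_pitch, principal_point) {
  ap <- calib$absolute_points
  dp <- calib$distance_pairs
  out <- list(position = position, pitch = pixel_pitch, pp = principal_point)
  out$n_abs <- nrow(ap)
  if (out$n_abs > 0) {
    pl <- parse_plane(ap$plane)
    out$abs <- list(
      du = (ap$u - principal_point[1]) * pixel_pitch,
      dv = (ap$v - principal_point[2]) * pixel_pitch,
      world = as.matrix(ap[, c("x", "y", "z")]),
      axis = pl$axis, value = pl$value
    )
  }
  out$n_pair <- if (is.null(dp)) 0L else nrow(dp)
  if (out$n_pair > 0) {
    pl <- parse_plane(dp$plane)
    out$pair <- list(
      du = c((dp$u_i - principal_point[1]), (dp$u_j - principal_point[1])) *
        pixel_pitch,
      dv = c((dp$v_i - principal_point[2]), (dp$v_j - principal_point[2])) *
        pixel_pitch,
      dist = dp$distance, axis = rep(pl$axis, 2), value = rep(pl$value, 2)
    )
  }
  out
}

# Intersect rays (3 x n direction matrix, common origin) with per-ray
# axis-aligned planes; returns n x 3 points.
#' @noRd
rays_to_planes <- function(origin, dirs, axis, value) {
  dk <- dirs[cbind(axis, seq_along(axis))]
  if (any(abs(dk) < 1e-14)) stop("ray parallel to its constraint plane")
  tt <- (value - origin[axis]) / dk
  cbind(origin[1] + tt * dirs[1, ],
        origin[2] + tt * dirs[2, ],
        origin[3] + tt * dirs[3, ])
}

# Summed squared error (mm^2) for one (pan, tilt, focal) candidate.
#' @noRd
reproj_core <- function(pan, tilt, focal, pre) {
  cp <- cos(pan);  sp <- sin(pan)
  ct <- cos(tilt); st <- sin(tilt)
  r <- matrix(c(cp, sp * st, sp * ct,
                0, ct, -st,
                -sp, cp * st, cp * ct), 3, 3, byrow = TRUE)
  err <- 0
  if (pre$n_abs > 0) {
    cam <- rbind(pre$abs$du, -pre$abs$dv, rep(-focal, pre$n_abs))
    pts <- rays_to_planes(pre$position, r %*% cam, pre$abs$axis,
                          pre$abs$value)
    err <- err + sum((pts - pre$abs$world)^2)
  }
  if (pre$n_pair > 0) {
    cam <- rbind(pre$pair$du, -pre$pair$dv, rep(-focal, 2L * pre$n_pair))
    pts <- rays_to_planes(pre$position, r %*% cam, pre$pair$axis,
                          pre$pair$value)
    i <- seq_len(pre$n_pair)
    sep <- sqrt(rowSums((pts[i, , drop = FALSE] -
                           pts[pre$n_pair + i, , drop = FALSE])^2))
    err <- err + sum((sep - pre$pair$dist)^2)
  }
  err
}

#' Summed squared calibration error of a camera against a calibration set
#'
#' For each absolute point the camera ray is intersected with the point's
#' known plane and the squared distance (mm^2) to the known world position
#' is accumulated; for each distance pair, the squared difference between
#' the known and reconstructed separations is added.
#'
#' @param camera A [camera_model()].
#' @param calib A [calibration_set()].
#' @return Non-negative scalar, mm^2; zero iff all constraints are met.
#' @export
reprojection_error <- function(camera, calib) {
  stopifnot(inherits(camera, "camera_model"),
            inherits(calib, "calibration_set"))
  pre <- calib_arrays(calib, camera$position, camera$pixel_pitch,
                      camera$principal_point)
  reproj_core(camera$pan, camera$tilt, camera$focal_distance, pre)
}

#' Per-constraint residuals of a camera against a calibration set
#'
#' @inheritParams reprojection_error
#' @return Data frame with `kind` ("point" or "pair"), `index`, and
#'   `residual_mm` (point position error or pair separation error).
#' @export
calibration_residuals <- function(camera, calib) {
  pre <- calib_arrays(calib, camera$position, camera$pixel_pitch,
                      camera$principal_point)
  r <- camera_rotation(camera)
  out <- list()
  if (pre$n_abs > 0) {
    cam <- rbind(pre$abs$du, -pre$abs$dv,
                 rep(-camera$focal_distance, pre$n_abs))
    pts <- rays_to_planes(pre$position, r %*% cam, pre$abs$axis,
                          pre$abs$value)
    out$pts <- data.frame(kind = "point", index = seq_len(pre$n_abs),
                          residual_mm = sqrt(rowSums((pts - pre$abs$world)^2)))
  }
  if (pre$n_pair > 0) {
    cam <- rbind(pre$pair$du, -pre$pair$dv,
                 rep(-camera$focal_distance, 2L * pre$n_pair))
    pts <- rays_to_planes(pre$position, r %*% cam, pre$pair$axis,
                          pre$pair$value)
    i <- seq_len(pre$n_pair)
    sep <- sqrt(rowSums((pts[i, , drop = FALSE] -
                           pts[pre$n_pair + i, , drop = FALSE])^2))
    out$prs <- data.frame(kind = "pair", index = i,
                          residual_mm = abs(sep - pre$pair$dist))
  }
  do.call(rbind, out)
}

#' Specify the exhaustive grid search
#'
#' @param center Numeric 3-vector `(pan, tilt, focal_distance)` initial
#'   guess (radians, radians, mm) — typically from tape-measure geometry.
#' @param half_widths Search half-widths per parameter, same units;
#'   defaults to 5 degrees for the angles and 10% of the focal guess.
#' @param steps Odd integer 3-vector of grid nodes per parameter.
#' @param refine_rounds Number of re-center-and-shrink refinement rounds
#'   after the initial pass.
#' @param shrink Factor by which half-widths contract each refinement.
#' @return Object of class `grid_search_spec`.
#' @export
grid_search_spec <- function(center,
                             half_widths = c(5 * pi / 180, 5 * pi / 180,
                                             0.10 * center[3]),
                             steps = c(41L, 41L, 21L),
                             refine_rounds = 2L, shrink = 5) {
  center <- as.numeric(center); half_widths <- as.numeric(half_widths)
  steps <- as.integer(steps)
  stopifnot(length(center) == 3, length(half_widths) == 3,
            all(half_widths > 0), length(steps) == 3, all(steps >= 3),
            all(steps %% 2L == 1L), refine_rounds >= 0, shrink > 1)
  structure(list(center = center, half_widths = half_widths, steps = steps,
                 refine_rounds = as.integer(refine_rounds), shrink = shrink),
            class = "grid_search_spec")
}

#' Calibrate a camera by exhaustive minimum-squared-error grid search
#'
#' Searches the discretized `(pan, tilt, focal_distance)` space around the
#' initial guess for the configuration minimizing [reprojection_error()].
#' The camera's `(x, z)` position is fixed to the measured value and its
#' `y` to 0 (origin-on-epipolar-row convention; see [fit_epipolar_row()]).
#' Each refinement round re-centers the grid on the current best candidate
#' and shrinks the half-widths. Grid ties break toward the candidate
#' closest to the round's search center.
#'
#' @param calib A [calibration_set()].
#' @param known_xz_position `(x, z)` of the camera focal point, mm.
#' @param spec A [grid_search_spec()].
#' @param resolution Camera `(width, height)`, pixels.
#' @param pixel_pitch mm per pixel.
#' @param principal_point Optional `(cx, cy)`; defaults to image centre.
#' @return List with `camera` (fitted [camera_model()]), `error` (mm^2),
#'   `residuals` (per-constraint data frame, mm), `evaluations` (candidate
#'   count actually evaluated), `rounds` (per-round best error), and
#'   `boundary_hit` (TRUE if any round's minimum lay on the search-region
#'   boundary — a cue to re-center the initial guess).
#' @export
calibrate_camera <- function(calib, known_xz_position, spec, resolution,
                             pixel_pitch, principal_point = NULL) {
  stopifnot(inherits(calib, "calibration_set"),
            inherits(spec, "grid_search_spec"),
            length(known_xz_position) == 2)
  if (is.null(principal_point)) principal_point <- (resolution - 1) / 2
  position <- c(known_xz_position[1], 0, known_xz_position[2])
  pre <- calib_arrays(calib, position, pixel_pitch, principal_point)

  center <- spec$center
  hw <- spec$half_widths
  best <- list(par = center, err = Inf)
  evaluations <- 0L
  round_best <- numeric(0)
  boundary_hit <- FALSE

  for (round in seq_len(1L + spec$refine_rounds)) {
    grids <- lapply(1:3, function(k)
      seq(center[k] - hw[k], center[k] + hw[k], length.out = spec$steps[k]))
    steps_sz <- vapply(1:3, function(k) grids[[k]][2] - grids[[k]][1], 0)
    round_err <- Inf
    round_par <- center
    round_tie <- Inf
    on_boundary <- FALSE
    for (fi in seq_along(grids[[3]])) {
      f <- grids[[3]][fi]
      for (ti in seq_along(grids[[2]])) {
        tl <- grids[[2]][ti]
        for (pi in seq_along(grids[[1]])) {
          pn <- grids[[1]][pi]
          e <- reproj_core(pn, tl, f, pre)
          evaluations <- evaluations + 1L
          # tie-break toward the search center, in units of grid steps
          tie <- sum(((c(pn, tl, f) - center) / steps_sz)^2)
          if (e < round_err - 1e-15 * max(1, round_err) ||
              (abs(e - round_err) <= 1e-15 * max(1, round_err) &&
                 tie < round_tie)) {
            round_err <- e
            round_par <- c(pn, tl, f)
            round_tie <- tie
            on_boundary <- any(c(pi, ti, fi) == 1L) ||
              pi == spec$steps[1] || ti == spec$steps[2] || fi == spec$steps[3]
          }
        }
      }
    }
    round_best <- c(round_best, round_err)
    boundary_hit <- boundary_hit || on_boundary
    if (on_boundary) {
      warning("grid-search minimum on the boundary of the search region ",
              "(round ", round, "); consider re-centering the initial guess")
    }
    best <- list(par = round_par, err = round_err)
    center <- round_par
    hw <- hw / spec$shrink
  }

  camera <- camera_model(position, best$par[1], best$par[2], best$par[3],
                         pixel_pitch, resolution, principal_point)
  list(camera = camera, error = best$err,
       residuals = calibration_residuals(camera, calib),
       evaluations = evaluations, rounds = round_best,
       boundary_hit = boundary_hit,
       final_step = 2 * hw * spec$shrink / (spec$steps - 1))
}
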