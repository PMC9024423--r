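# Pinhole camera geometry: camera model, ray casting, triangulation,
# axis projection, and JSON serialization.
#
# World-frame convention (right-handed): X to the right on the cage front
# face, Y up, Z toward the cameras; all lengths in millimetres.
#
# Image convention: 0-based pixel coordinates, origin at the top-left
# corner, u rightward, v downward, pixel centres at integer coordinates.
# The v-down image axis maps to world -Y; this is the single sign flip in
# cast_ray()/project_points().

#' Construct a pinhole camera model
#'
#' The camera is parameterized by its focal-point position in the world
#' frame, a pan rotation about the world Y axis followed by a tilt rotation
#' about the panned camera X axis, and intrinsics expressed as a focal
#' distance (mm) together with a pixel pitch (mm per pixel on the focal
#' plane). Only the ratio `focal_distance / pixel_pitch` (the focal length
#' in pixels) affects ray directions; keeping the two factors separate
#' mirrors how the physical rig is measured: the pitch comes from sensor
#' specifications and the focal distance is the quantity fitted during
#' calibration.
#'
#' At `pan = tilt = 0` the optical axis points along world -Z (from the
#' cameras toward the cage) and image u/v align with world +X/-Y.
#'
#' @param position Numeric 3-vector, focal point in world frame (mm).
#' @param pan Rotation about world Y, radians (positive pans the view
#'   toward +X camera positions looking back at the origin).
#' @param tilt Rotation about the panned camera X axis, radians.
#' @param focal_distance Distance from the focal point to the focal plane,
#'   mm; must be positive.
#' @param pixel_pitch Millimetres per pixel on the focal plane; positive.
#' @param resolution Integer 2-vector `(width, height)` in pixels.
#' @param principal_point Numeric 2-vector `(cx, cy)` in pixels; defaults
#'   to the image centre `((width - 1) / 2, (height - 1) / 2)`.
#' @return An object of class `camera_model`.
#' @export
#' @examples
#' cam <- camera_model(c(0, 0, 1000), pan = 0, tilt = 0,
#'                     focal_distance = 20, pixel_pitch = 0.01,
#'                     resolution = c(800, 600))
#' cast_ray(cam, cam$principal_point)$direction  # (0, 0, -1)
camera_model <- function(position, pan, tilt, focal_distance, pixel_pitch,
                         resolution, principal_point = NULL) {
  position <- as.numeric(position)
  resolution <- as.numeric(resolution)
  if (is.null(principal_point)) {
    principal_point <- (resolution - 1) / 2
  }
  principal_point <- as.numeric(principal_point)
  stopifnot(
    length(position) == 3, all(is.finite(position)),
    is.finite(pan), is.finite(tilt),
    focal_distance > 0, pixel_pitch > 0,
    length(resolution) == 2, all(resolution >= 1),
    length(principal_point) == 2,
    principal_point[1] >= 0, principal_point[1] <= resolution[1],
    principal_point[2] >= 0, principal_point[2] <= resolution[2]
  )
  structure(
    list(position = position, pan = pan, tilt = tilt,
         focal_distance = focal_distance, pixel_pitch = pixel_pitch,
         resolution = resolution, principal_point = principal_point),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat("<camera_model>\n")
  cat(sprintf("  position   : (%.2f, %.2f, %.2f) mm\n",
              x$position[1], x$position[2], x$position[3]))
  cat(sprintf("  pan / tilt : %.4f / %.4f rad\n", x$pan, x$tilt))
  cat(sprintf("  focal      : %.4f mm (pitch %.5f mm/px, %.1f px)\n",
              x$focal_distance, x$pixel_pitch,
              x$focal_distance / x$pixel_pitch))
  cat(sprintf("  resolution : %d x %d px, principal point (%.2f, %.2f)\n",
              as.integer(x$resolution[1]), as.integer(x$resolution[2]),
              x$principal_point[1], x$principal_point[2]))
  invisible(x)
}

# Rotation matrix camera -> world: R_y(pan) %*% R_x(tilt). Camera frame is
# x right, y up, z backward (optical axis = -z).
#' @noRd
camera_rotation <- function(camera) {
  cp <- cos(camera$pan);  sp <- sin(camera$pan)
  ct <- cos(camera$tilt); st <- sin(camera$tilt)
  ry <- matrix(c(cp, 0, sp,
                 0, 1, 0,
                 -sp, 0, cp), 3, 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0,
                 0, ct, -st,
                 0, st, ct), 3, 3, byrow = TRUE)
  ry %*% rx
}

#' Construct a ray
#'
#' @param origin Numeric 3-vector, mm.
#' @param direction Numeric 3-vector; normalized on construction.
#' @return Object of class `ray` with unit-norm `direction`.
#' @export
ray <- function(origin, direction) {
  origin <- as.numeric(origin)
  direction <- unitize(as.numeric(direction))
  stopifnot(length(origin) == 3, all(is.finite(origin)),
            abs(vnorm(direction) - 1) < 1e-12)
  structure(list(origin = origin, direction = direction), class = "ray")
}

# Vectorized ray directions (world frame) for an n x 2 pixel matrix.
#' @noRd
ray_directions <- function(camera, pixels) {
  pixels <- matrix(as.numeric(pixels), ncol = 2)
  du <- (pixels[, 1] - camera$principal_point[1]) * camera$pixel_pitch
  dv <- (pixels[, 2] - camera$principal_point[2]) * camera$pixel_pitch
  # camera coords: (du, -dv, -f); v-down maps to camera -y
  cam <- rbind(du, -dv, rep(-camera$focal_distance, length(du)))
  d <- camera_rotation(camera) %*% cam
  d <- t(d)
  d / sqrt(rowSums(d^2))
}

#' Cast a ray from a camera through a pixel
#'
#' Maps pixel `(u, v)` onto the focal plane using the principal point,
#' pixel pitch and focal distance, applies the camera's pan/tilt rotation
#' and translation, and returns the world-frame ray from the focal point
#' through that focal-plane position.
#'
#' @param camera A [camera_model()].
#' @param pixel Numeric 2-vector `(u, v)`, pixels (may be fractional).
#' @return A [ray()].
#' @export
cast_ray <- function(camera, pixel) {
  stopifnot(inherits(camera, "camera_model"),
            length(pixel) == 2, all(is.finite(pixel)))
  d <- ray_directions(camera, matrix(pixel, ncol = 2))
  ray(camera$position, d[1, ])
}

#' Project world points into a camera image
#'
#' Inverse of [cast_ray()] for points in front of the camera; used by the
#' calibration and synthetic-scene modules.
#'
#' @param camera A [camera_model()].
#' @param points Numeric 3-vector or n x 3 matrix of world points (mm).
#' @return n x 2 matrix of pixel coordinates `(u, v)`.
#' @export
project_points <- function(camera, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  rel <- sweep(points, 2, camera$position)      # world offsets
  q <- rel %*% camera_rotation(camera)          # = t(R) %*% rel per row
  if (any(q[, 3] >= 0)) {
    stop("point is not in front of the camera (camera-frame z >= 0)")
  }
  fpx <- camera$focal_distance / camera$pixel_pitch
  u <- camera$principal_point[1] + fpx * q[, 1] / (-q[, 3])
  v <- camera$principal_point[2] - fpx * q[, 2] / (-q[, 3])
  cbind(u = u, v = v)
}

# Closed-form midpoint of the common perpendicular between two lines,
# vectorized over n direction pairs (origins fixed). Returns list(point
# n x 3, gap n).
#' @noRd
triangulate_many <- function(origin_a, dirs_a, dirs_b, origin_b) {
  dirs_a <- matrix(dirs_a, ncol = 3)
  dirs_b <- matrix(dirs_b, ncol = 3)
  w0 <- origin_a - origin_b
  b <- rowSums(dirs_a * dirs_b)              # dot(da, db), |.|<=1
  d <- sum(w0 * w0)
  da_w <- as.numeric(dirs_a %*% w0)
  db_w <- as.numeric(dirs_b %*% w0)
  denom <- 1 - b^2
  if (any(abs(b) >= 1 - 1e-10)) {
    stop("rays are (near-)parallel: degenerate stereo geometry")
  }
  s <- (b * db_w - da_w) / denom             # parameter along ray a
  t <- (db_w - b * da_w) / denom             # parameter along ray b
  pa <- sweep(dirs_a * s, 2, origin_a, `+`)
  pb <- sweep(dirs_b * t, 2, origin_b, `+`)
  list(point = (pa + pb) / 2, gap = sqrt(rowSums((pa - pb)^2)))
}

#' Triangulate the intersection of two viewing rays
#'
#' Skew viewing rays never meet exactly; the returned point is the midpoint
#' of their common perpendicular segment, the unique point minimizing the
#' sum of squared distances to both lines. The `gap` (closest-approach
#' distance between the lines, mm) is a direct quality measure of the
#' stereo reconstruction.
#'
#' @param ray_a,ray_b [ray()] objects; must not be parallel.
#' @return List with `point` (3-vector, mm) and `gap` (mm, >= 0).
#' @export
#' @examples
#' a <- ray(c(-10, 0, 0), c(1, 0, 0))
#' b <- ray(c(0, -10, 2), c(0, 1, 0))
#' triangulate(a, b)  # point (0, 0, 1), gap 2
triangulate <- function(ray_a, ray_b) {
  stopifnot(inherits(ray_a, "ray"), inherits(ray_b, "ray"))
  r <- triangulate_many(ray_a$origin, matrix(ray_a$direction, ncol = 3),
                        matrix(ray_b$direction, ncol = 3), ray_b$origin)
  list(point = as.numeric(r$point[1, ]), gap = r$gap[1])
}

#' Project a displacement vector onto a measurement axis
#'
#' Returns the signed component of `displacement` along the unit vector
#' from `axis_from` to `axis_to` (positive toward `axis_to`). Used to
#' compare 3D stereo traces against a single-axis reference instrument
#' such as a laser vibrometer.
#'
#' @param displacement Numeric 3-vector, mm.
#' @param axis_from,axis_to Numeric 3-vectors defining the axis, mm;
#'   must differ.
#' @return Scalar displacement along the axis, mm.
#' @export
project_onto_axis <- function(displacement, axis_from, axis_to) {
  displacement <- as.numeric(displacement)
  axis <- as.numeric(axis_to) - as.numeric(axis_from)
  if (vnorm(axis) == 0) stop("axis_from and axis_to coincide: zero-length axis")
  sum(displacement * axis / vnorm(axis))
}

#' Write a camera model to JSON
#'
#' Fields mirror [camera_model()]; unit annotations are embedded so the
#' file is self-describing.
#'
#' @param camera A [camera_model()].
#' @param path Output file path.
#' @export
write_camera <- function(camera, path) {
  stopifnot(inherits(camera, "camera_model"))
  doc <- list(
    type = "camera_model",
    units = list(position = "mm", pan = "radians", tilt = "radians",
                 focal_distance = "mm", pixel_pitch = "mm_per_pixel",
                 resolution = "pixels", principal_point = "pixels"),
    position = camera$position, pan = camera$pan, tilt = camera$tilt,
    focal_distance = camera$focal_distance, pixel_pitch = camera$pixel_pitch,
    resolution = camera$resolution, principal_point = camera$principal_point
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a camera model from JSON
#'
#' @param path File written by [write_camera()].
#' @return A [camera_model()].
#' @export
read_camera <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_model(doc$position, doc$pan, doc$tilt, doc$focal_distance,
               doc$pixel_pitch, doc$resolution, doc$principal_point)
}
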