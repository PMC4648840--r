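#' Ideal pinhole camera
#'
#' World frame: X across the specimen width, Y along the load axis (up),
#' Z toward the cameras, origin at the centre of the lower clamp edge.
#' Image frame: x right, y down, pixel centres at integer coordinates
#' (1-based). The camera looks from `center_mm` toward `look_at_mm`; the
#' image y axis is aligned with decreasing world Y.
#'
#' @param f_px Focal length in pixels.
#' @param cx_px,cy_px Principal point.
#' @param width_px,height_px Sensor size.
#' @param center_mm Camera centre in world mm.
#' @param look_at_mm Point the optical axis passes through.
#' @return An object of class `pinhole_camera` with rotation `R`
#'   (world -> camera) and 3x4 projection matrix `P`.
#' @export
pinhole_camera <- function(f_px, cx_px, cy_px, width_px, height_px,
                           center_mm, look_at_mm) {
  z <- look_at_mm - center_mm
  z <- z / sqrt(sum(z^2))
  down <- c(0, -1, 0)
  x <- c(down[2] * z[3] - down[3] * z[2],
         down[3] * z[1] - down[1] * z[3],
         down[1] * z[2] - down[2] * z[1])
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  R <- rbind(x, y, z)
  K <- matrix(c(f_px, 0, 0, 0, f_px, 0, cx_px, cy_px, 1), 3, 3)
  P <- K %*% cbind(R, -R %*% center_mm)
  structure(list(f_px = f_px, cx_px = cx_px, cy_px = cy_px,
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 center_mm = center_mm, R = R, P = P),
            class = "pinhole_camera")
}

#' Project world points through a camera
#'
#' @param camera A [pinhole_camera()] or a 3x4 projection matrix.
#' @param points_mm n x 3 matrix of world coordinates.
#' @return n x 2 matrix of pixel coordinates.
#' @export
project_points <- function(camera, points_mm) {
  P <- if (inherits(camera, "pinhole_camera")) camera$P else camera
  pts <- cbind(as.matrix(points_mm), 1)
  h <- pts %*% t(P)
  cbind(x_px = h[, 1] / h[, 3], y_px = h[, 2] / h[, 3])
}

# world-space unit-free ray directions for a set of pixels
pixel_rays <- function(camera, x_px, y_px) {
  d <- rbind((x_px - camera$cx_px) / camera$f_px,
             (y_px - camera$cy_px) / camera$f_px,
             rep(1, length(x_px)))
  t(camera$R) %*% d
}

#' Default two-camera rig
#'
#' Two identical pinhole cameras symmetric about the load axis, both aimed at
#' the specimen mid-gauge point, with the focal length chosen so that the
#' magnification at the grip plane (Z = 0) equals `scale_mm_per_px`.
#'
#' @param width_px,height_px Sensor size.
#' @param scale_mm_per_px Object-space pixel size at Z = 0.
#' @param working_distance_mm Distance from the Z = 0 plane to the cameras.
#' @param baseline_mm Distance between the two camera centres.
#' @param target_y_mm Height of the aim point (typically mid gauge length).
#' @return List of two `pinhole_camera` objects (left, right).
#' @export
stereo_rig <- function(width_px, height_px, scale_mm_per_px = 0.05,
                       working_distance_mm = 500, baseline_mm = 140,
                       target_y_mm = 17.5) {
  f <- working_distance_mm / scale_mm_per_px
  cx <- (width_px + 1) / 2
  cy <- (height_px + 1) / 2
  tgt <- c(0, target_y_mm, 0)
  list(
    pinhole_camera(f, cx, cy, width_px, height_px,
                   c(-baseline_mm / 2, target_y_mm, working_distance_mm), tgt),
    pinhole_camera(f, cx, cy, width_px, height_px,
                   c(baseline_mm / 2, target_y_mm, working_distance_mm), tgt))
}
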