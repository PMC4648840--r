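#' Direct linear transform camera calibration
#'
#' Least-squares estimate of the 3x4 projection matrix from world/image
#' point correspondences (the planar calibration target is presented at two
#' or more depths so that the configuration is non-degenerate). The matrix
#' is normalized so its bottom-right entry is 1 and the root-mean-square
#' reprojection error is reported.
#'
#' @param world_points_mm n x 3 matrix of world coordinates (n >= 6, not all
#'   coplanar).
#' @param image_points_px n x 2 matrix of observed pixel coordinates.
#' @return An object of class `camera_calibration`: list with `P` (3x4) and
#'   `reprojection_rms_px`.
#' @export
calibrate_dlt <- function(world_points_mm, image_points_px) {
  Xw <- as.matrix(world_points_mm)
  xi <- as.matrix(image_points_px)
  n <- nrow(Xw)
  if (n < 6) stop("at least 6 point correspondences are required")
  if (nrow(xi) != n) stop("point lists must have equal length")
  # coplanarity check: smallest singular value of the centred cloud
  ctr <- scale(Xw, scale = FALSE)
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[3] < 1e-8 * max(sv[1], 1))
    stop("degenerate calibration: all world points are coplanar; ",
         "present the target at two or more depths")
  A <- matrix(0, 2 * n, 12)
  for (i in seq_len(n)) {
    Xh <- c(Xw[i, ], 1)
    A[2 * i - 1, 1:4] <- Xh
    A[2 * i - 1, 9:12] <- -xi[i, 1] * Xh
    A[2 * i, 5:8] <- Xh
    A[2 * i, 9:12] <- -xi[i, 2] * Xh
  }
  v <- svd(A, nu = 0)$v[, 12]
  P <- matrix(v, 3, 4, byrow = TRUE)
  if (abs(P[3, 4]) > 1e-12) P <- P / P[3, 4]
  proj <- project_points(P, Xw)
  rms <- sqrt(mean((proj - xi)^2) * 2)  # mean over points of |err|^2
  structure(list(P = P, reprojection_rms_px = rms),
            class = "camera_calibration")
}

#' Linear least-squares triangulation
#'
#' Recovers 3D points from pixel correspondences in two calibrated cameras
#' by the homogeneous DLT formulation. For exact (noise-free) input the
#' reconstruction inverts the projection to numerical precision. Pairs whose
#' viewing rays are nearly parallel are flagged low-confidence.
#'
#' @param calib_left,calib_right [calibrate_dlt()] results,
#'   [pinhole_camera()] objects or bare 3x4 matrices.
#' @param points_left_px,points_right_px n x 2 matrices of pixel coordinates.
#' @return Data frame with `X_mm`, `Y_mm`, `Z_mm`, per-camera reprojection
#'   errors (`reproj_left_px`, `reproj_right_px`) and `low_confidence`.
#' @export
triangulate <- function(calib_left, calib_right, points_left_px,
                        points_right_px) {
  getP <- function(c) {
    if (inherits(c, "camera_calibration")) return(c$P)
    if (inherits(c, "pinhole_camera")) return(c$P)
    as.matrix(c)
  }
  Pl <- getP(calib_left); Pr <- getP(calib_right)
  xl <- matrix(as.matrix(points_left_px), ncol = 2)
  xr <- matrix(as.matrix(points_right_px), ncol = 2)
  n <- nrow(xl)
  stopifnot(nrow(xr) == n)
  if (any(!is.finite(xl)) || any(!is.finite(xr)))
    stop("pixel coordinates must be finite")
  out <- matrix(NA_real_, n, 3)
  rel <- numeric(n); rer <- numeric(n); low <- logical(n)
  for (i in seq_len(n)) {
    A <- rbind(xl[i, 1] * Pl[3, ] - Pl[1, ],
               xl[i, 2] * Pl[3, ] - Pl[2, ],
               xr[i, 1] * Pr[3, ] - Pr[1, ],
               xr[i, 2] * Pr[3, ] - Pr[2, ])
    s <- svd(A)
    Xh <- s$v[, 4]
    # near-parallel rays leave the system ill-conditioned
    low[i] <- s$d[3] < 1e-8 * s$d[1] || abs(Xh[4]) < 1e-12
    X <- Xh[1:3] / Xh[4]
    out[i, ] <- X
    pl <- project_points(Pl, matrix(X, 1)); pr <- project_points(Pr, matrix(X, 1))
    rel[i] <- sqrt(sum((pl - xl[i, ])^2))
    rer[i] <- sqrt(sum((pr - xr[i, ])^2))
  }
  data.frame(X_mm = out[, 1], Y_mm = out[, 2], Z_mm = out[, 3],
             reproj_left_px = rel, reproj_right_px = rer,
             low_confidence = low)
}

# triangulate only the rows marked usable; others come back NA/invalid
triangulate_valid <- function(calib_left, calib_right, xl, xr, use) {
  use <- use & is.finite(xl[, 1]) & is.finite(xl[, 2]) &
    is.finite(xr[, 1]) & is.finite(xr[, 2])
  n <- nrow(xl)
  out <- data.frame(X_mm = rep(NA_real_, n), Y_mm = NA_real_, Z_mm = NA_real_,
                    reproj_left_px = NA_real_, reproj_right_px = NA_real_,
                    low_confidence = TRUE)
  if (any(use)) {
    tri <- triangulate(calib_left, calib_right, xl[use, , drop = FALSE],
                       xr[use, , drop = FALSE])
    out[use, ] <- tri
  }
  out
}

#' Cross-camera facet matching
#'
#' Correlates each left-camera reference facet into the right reference
#' image with the same integer-search + subpixel machinery used for temporal
#' tracking (and the same quality semantics). A per-facet initial disparity
#' may be supplied to keep the integer search small.
#'
#' @param left_ref,right_ref Reference images of the two cameras.
#' @param grid Facet grid defined on the left reference image.
#' @param config A [dic_config()]; `search_radius_px` bounds the search
#'   around the initial disparity.
#' @param init Optional n x 2 matrix of initial disparities (px).
#' @return A `displacement_field` data frame of disparities `u_px`, `v_px`.
#' @export
stereo_match <- function(left_ref, right_ref, grid, config = dic_config(),
                         init = NULL) {
  stopifnot(inherits(grid, "facet_grid"))
  half <- (config$facet_size_px - 1) %/% 2
  cx <- as.integer(grid$centers$x_px)
  cy <- as.integer(grid$centers$y_px)
  n <- length(cx)
  if (is.null(init)) init <- matrix(NA_real_, n, 2)
  m <- track_frame_cpp(left_ref, right_ref, cx, cy, half,
                       config$search_radius_px, init, config$tol,
                       config$max_iter)
  valid <- m[, "converged"] == 1 & !is.na(m[, "zncc"]) &
    m[, "zncc"] >= config$zncc_threshold
  fld <- data.frame(facet_id = grid$centers$facet_id, x_px = cx, y_px = cy,
                    u_px = m[, "u"], v_px = m[, "v"], zncc = m[, "zncc"],
                    converged = m[, "converged"] == 1, valid = valid)
  class(fld) <- c("displacement_field", "data.frame")
  fld
}

#' Reconstruct 3D surfaces and displacements from a tracked stereo sequence
#'
#' Temporal tracking is done in the left camera; stereo matching at the
#' reference frame gives the per-facet disparity. For each subsequent frame
#' the left reference facet is matched into the right-camera frame,
#' initialized by composing the reference disparity with the temporal
#' displacement, so that genuine disparity changes (out-of-plane motion) are
#' measured rather than assumed away. Each facet's reference and deformed
#' positions are triangulated; the 3D displacement is their difference.
#'
#' @param left_ref,right_ref Reference images.
#' @param left_frames,right_frames Lists of frames (matrices or file paths).
#' @param grid Facet grid on the left reference image.
#' @param calib_left,calib_right Camera calibrations (or cameras).
#' @param config A [dic_config()].
#' @param disparity_init Optional initial disparity matrix for the reference
#'   stereo match.
#' @return List with `surface_ref` (class `surface3d`: facet world
#'   coordinates at the reference state) and `frames`: per frame a list with
#'   `surface` (deformed `surface3d`) and `displacement` (class
#'   `displacement_field3d` with `dX_mm`, `dY_mm`, `dZ_mm`). Facets lacking
#'   a temporal or stereo match are invalid.
#' @export
reconstruct_displacements <- function(left_ref, right_ref, left_frames,
                                      right_frames, grid, calib_left,
                                      calib_right, config = dic_config(),
                                      disparity_init = NULL) {
  stopifnot(length(left_frames) == length(right_frames))
  disp_ref <- stereo_match(left_ref, right_ref, grid, config,
                           init = disparity_init)
  cx <- grid$centers$x_px; cy <- grid$centers$y_px
  tri_ref <- triangulate_valid(calib_left, calib_right, cbind(cx, cy),
                               cbind(cx + disp_ref$u_px,
                                     cy + disp_ref$v_px), disp_ref$valid)
  ref_valid <- disp_ref$valid & !tri_ref$low_confidence
  surface_ref <- data.frame(facet_id = grid$centers$facet_id,
                            X_mm = tri_ref$X_mm, Y_mm = tri_ref$Y_mm,
                            Z_mm = tri_ref$Z_mm, valid = ref_valid)
  class(surface_ref) <- c("surface3d", "data.frame")

  temporal <- track_sequence(left_ref, left_frames, grid, config)
  half <- (config$facet_size_px - 1) %/% 2
  frames <- vector("list", length(left_frames))
  for (k in seq_along(left_frames)) {
    tk <- temporal[[k]]
    rimg <- right_frames[[k]]
    if (is.function(rimg)) rimg <- rimg()
    if (is.character(rimg)) rimg <- read_image(rimg)
    init <- cbind(disp_ref$u_px + tk$u_px, disp_ref$v_px + tk$v_px)
    init[!(tk$valid & disp_ref$valid), ] <- NA_real_
    m <- track_frame_cpp(left_ref, rimg, as.integer(cx), as.integer(cy),
                         half, config$search_radius_px, init, config$tol,
                         config$max_iter)
    rvalid <- m[, "converged"] == 1 & !is.na(m[, "zncc"]) &
      m[, "zncc"] >= config$zncc_threshold
    ok <- ref_valid & tk$valid & rvalid
    tri <- triangulate_valid(calib_left, calib_right,
                             cbind(cx + tk$u_px, cy + tk$v_px),
                             cbind(cx + m[, "u"], cy + m[, "v"]), ok)
    ok <- ok & !tri$low_confidence
    surf <- data.frame(facet_id = grid$centers$facet_id, X_mm = tri$X_mm,
                       Y_mm = tri$Y_mm, Z_mm = tri$Z_mm, valid = ok)
    class(surf) <- c("surface3d", "data.frame")
    d3 <- data.frame(facet_id = grid$centers$facet_id,
                     dX_mm = tri$X_mm - tri_ref$X_mm,
                     dY_mm = tri$Y_mm - tri_ref$Y_mm,
                     dZ_mm = tri$Z_mm - tri_ref$Z_mm, valid = ok)
    d3[!ok, c("dX_mm", "dY_mm", "dZ_mm")] <- NA_real_
    class(d3) <- c("displacement_field3d", "data.frame")
    frames[[k]] <- list(surface = surf, displacement = d3)
  }
  list(surface_ref = surface_ref, frames = frames)
}
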