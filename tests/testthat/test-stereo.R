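# synthetic camera pair shared across stereo tests
stereo_fixture <- function(width = 300, height = 300, baseline = 100,
                           wd = 200) {
  stereo_rig(width, height, scale_mm_per_px = 0.05,
             working_distance_mm = wd, baseline_mm = baseline,
             target_y_mm = 0)
}

random_points <- function(n, seed = 1) {
  set.seed(seed)
  cbind(runif(n, -5, 5), runif(n, -5, 5), runif(n, -3, 3))
}

test_that("DLT calibration inverts exact correspondences", {
  cams <- stereo_fixture()
  pts <- random_points(24)
  px <- project_points(cams[[1]], pts)
  cal <- calibrate_dlt(pts, px)
  expect_lt(cal$reprojection_rms_px, 1e-6)
  held_out <- matrix(c(1.2, -2.3, 0.7), 1)
  expect_lt(max(abs(project_points(cal$P, held_out) -
                      project_points(cams[[1]], held_out))), 1e-6)
})

test_that("DLT reprojection RMS reflects the measurement noise level", {
  cams <- stereo_fixture()
  pts <- random_points(24)
  px <- project_points(cams[[1]], pts)
  rms <- sapply(1:20, function(s) {
    set.seed(s)
    calibrate_dlt(pts, px + matrix(rnorm(48, 0, 0.1), 24))$reprojection_rms_px
  })
  expect_gt(mean(rms), 0.05)
  expect_lt(mean(rms), 0.2)
})

test_that("DLT rejects underdetermined and coplanar configurations", {
  cams <- stereo_fixture()
  pts <- random_points(24)
  expect_error(calibrate_dlt(pts[1:5, ], project_points(cams[[1]],
                                                        pts[1:5, ])),
               "at least 6")
  flat <- pts; flat[, 3] <- 2
  expect_error(calibrate_dlt(flat, project_points(cams[[1]], flat)),
               "coplanar")
})

test_that("triangulation round trip is exact and camera-symmetric", {
  cams <- stereo_fixture()
  pts <- random_points(15, seed = 3)
  pl <- project_points(cams[[1]], pts)
  pr <- project_points(cams[[2]], pts)
  tri <- triangulate(cams[[1]], cams[[2]], pl, pr)
  expect_lt(max(abs(as.matrix(tri[, 1:3]) - pts)), 1e-6)
  expect_lt(max(tri$reproj_left_px), 1e-6)
  expect_false(any(tri$low_confidence))
  swapped <- triangulate(cams[[2]], cams[[1]], pr, pl)
  expect_equal(as.matrix(swapped[, 1:3]), as.matrix(tri[, 1:3]),
               tolerance = 1e-9)
})

test_that("triangulation depth noise follows the stereo geometry bound", {
  cams <- stereo_fixture(baseline = 100, wd = 200)
  pt <- matrix(c(0, 0, 0), 1)
  pl <- project_points(cams[[1]], pt)
  pr <- project_points(cams[[2]], pt)
  set.seed(11)
  zs <- replicate(1000, {
    tri <- triangulate(cams[[1]], cams[[2]], pl + rnorm(2, 0, 0.02),
                       pr + rnorm(2, 0, 0.02))
    tri$Z_mm
  })
  # half-angle ~14 deg; sigma_Z ~= sigma_px * scale / (2 sin(theta))
  predicted <- 0.02 * 0.05 / (2 * sin(atan(50 / 200)))
  expect_lt(abs(sd(zs) - predicted) / predicted, 0.5)
  expect_lt(sd(zs), 0.01)  # mm-scale bound: well below 10 um here
})

test_that("near-parallel rays are flagged low-confidence", {
  cams <- stereo_fixture(baseline = 1e-9)
  pt <- matrix(c(0, 0, 0), 1)
  tri <- triangulate(cams[[1]], cams[[2]], project_points(cams[[1]], pt),
                     project_points(cams[[2]], pt))
  expect_true(tri$low_confidence)
  expect_error(triangulate(cams[[1]], cams[[2]], matrix(c(NA, 1), 1),
                           matrix(c(1, 1), 1)), "finite")
})

test_that("zero-baseline identical cameras give zero disparity", {
  cam <- stereo_fixture()[[1]]
  tex <- test_speckle(400, seed = 12)
  img <- render_plane(cam, 0, tex, 0.05)
  grid <- build_facet_grid(matrix(TRUE, nrow(img), ncol(img)), 21, 25)
  dsp <- stereo_match(img, img, grid, dic_config())
  expect_true(all(dsp$valid))
  expect_lt(max(abs(dsp$u_px)), 1e-9)
})

test_that("stereo disparity matches the projected geometry", {
  cams <- stereo_fixture()
  tex <- test_speckle(500, seed = 13)
  z0 <- 1.5  # plane offset from the nominal focus plane
  left <- render_plane(cams[[1]], z0, tex, 0.05)
  right <- render_plane(cams[[2]], z0, tex, 0.05)
  grid <- build_facet_grid(matrix(TRUE, 300, 300), 21, 30)
  dsp <- stereo_match(left, right, grid, dic_config(search_radius_px = 15))
  ctr <- dsp[abs(dsp$x_px - 150) < 60 & abs(dsp$y_px - 150) < 60 &
               dsp$valid, ]
  expect_gt(nrow(ctr), 4)
  # ground truth: intersect the left-pixel ray with the plane, project into
  # the right camera
  d <- tendondic:::pixel_rays(cams[[1]], ctr$x_px, ctr$y_px)
  C <- cams[[1]]$center_mm
  tt <- (z0 - C[3]) / d[3, ]
  world <- cbind(C[1] + tt * d[1, ], C[2] + tt * d[2, ], z0)
  pr <- project_points(cams[[2]], world)
  expect_lt(max(abs(ctr$x_px + ctr$u_px - pr[, 1])), 0.05)
  expect_lt(max(abs(ctr$y_px + ctr$v_px - pr[, 2])), 0.05)
})

test_that("a rigid out-of-plane translation is recovered uniformly", {
  cams <- stereo_fixture()
  tex <- test_speckle(500, seed = 14)
  l0 <- render_plane(cams[[1]], 0, tex, 0.05)
  r0 <- render_plane(cams[[2]], 0, tex, 0.05)
  l1 <- render_plane(cams[[1]], 1.0, tex, 0.05)
  r1 <- render_plane(cams[[2]], 1.0, tex, 0.05)
  grid <- build_facet_grid(matrix(TRUE, 300, 300), 21, 25)
  rec <- reconstruct_displacements(l0, r0, list(l1), list(r1), grid,
                                   cams[[1]], cams[[2]],
                                   dic_config(search_radius_px = 15))
  d <- rec$frames[[1]]$displacement
  keep <- d$valid & abs(rec$surface_ref$X_mm) < 5 &
    abs(rec$surface_ref$Y_mm) < 5
  expect_gt(sum(keep), 20)
  expect_equal(mean(d$dZ_mm[keep]), 1.0, tolerance = 0.005)
  expect_lt(max(abs(d$dX_mm[keep])), 0.01)
  expect_lt(max(abs(d$dY_mm[keep])), 0.01)
  # uniformity: the 2D out-of-plane artifact must vanish in 3D
  expect_lt(sd(d$dZ_mm[keep]), 0.01)
  expect_lt(sd(d$dY_mm[keep]), 0.01)
  # zero deformation: zero 3D displacement
  rec0 <- reconstruct_displacements(l0, r0, list(l0), list(r0), grid,
                                    cams[[1]], cams[[2]], dic_config())
  d0 <- rec0$frames[[1]]$displacement
  # bounded by the subpixel convergence tolerance through the stereo gain
  expect_lt(max(abs(d0$dZ_mm[d0$valid])), 2e-5)
})
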