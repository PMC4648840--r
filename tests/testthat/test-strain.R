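test_that("affine displacement fields give exact, constant strain", {
  fld <- analytic_field_mm(function(x, y) 0.01 * x,
                           function(x, y) rep(0, length(x)))
  g <- local_gradient(fld, strain_config())
  expect_true(any(g$valid))
  expect_lt(max(abs(g$dudx[g$valid] - 0.01)), 1e-10)
  expect_lt(max(abs(g$dudy[g$valid])), 1e-10)
  expect_lt(max(abs(g$dvdx[g$valid])), 1e-10)
  expect_lt(max(abs(g$dvdy[g$valid])), 1e-10)
  # general affine field, exact to 1e-10
  fld2 <- analytic_field_mm(function(x, y) 0.003 * x - 0.002 * y + 0.5,
                            function(x, y) 0.004 * x + 0.011 * y - 0.2)
  s <- strain_from_gradient(local_gradient(fld2, strain_config()),
                            "engineering")
  expect_lt(max(abs(s$exx[s$valid] - 0.003)), 1e-10)
  expect_lt(max(abs(s$eyy[s$valid] - 0.011)), 1e-10)
  expect_lt(max(abs(s$exy[s$valid] - 0.001)), 1e-10)
  # rigid translation: zero gradient
  fld3 <- analytic_field_mm(function(x, y) rep(1.3, length(x)),
                            function(x, y) rep(-0.7, length(x)))
  g3 <- local_gradient(fld3, strain_config())
  expect_lt(max(abs(c(g3$dudx, g3$dudy, g3$dvdx, g3$dvdy)[
    rep(g3$valid, 4)])), 1e-10)
})

test_that("quadratic fields show the window bias predicted by direct WLS", {
  a <- 0.002
  cfg <- strain_config(window_facets = 5, gaussian_weight = TRUE)
  fld <- analytic_field_mm(function(x, y) rep(0, length(x)),
                           function(x, y) a * y^2, nx = 11, ny = 11,
                           spacing_mm = 1)
  g <- local_gradient(fld, cfg)
  ctr <- which(fld$x_mm == 6 & fld$y_mm == 6)
  # direct weighted LS on the same stencil (independent mini-oracle)
  offs <- expand.grid(dx = -2:2, dy = -2:2)
  w <- exp(-(offs$dx^2 + offs$dy^2) / (2 * 4))
  X <- cbind(1, offs$dx, offs$dy)
  vv <- a * (6 + offs$dy)^2
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * vv))
  expect_equal(g$dvdy[ctr], beta[3], tolerance = 1e-12)
  expect_equal(g$dvdy[ctr], 2 * a * 6, tolerance = abs(a))
})

test_that("strain measures reproduce their closed forms", {
  g <- data.frame(facet_id = 1, x_mm = 0, y_mm = 0, dudx = 0, dudy = 0,
                  dvdx = 0, dvdy = 0, valid = TRUE)
  z <- strain_from_gradient(g, "engineering")
  expect_equal(c(z$exx, z$eyy, z$exy), c(0, 0, 0))
  zg <- strain_from_gradient(g, "green_lagrange")
  expect_equal(c(zg$exx, zg$eyy, zg$exy), c(0, 0, 0))
  # uniaxial stretch lambda = 1.02
  g$dvdy <- 0.02
  expect_equal(strain_from_gradient(g, "engineering")$eyy, 0.02)
  expect_equal(strain_from_gradient(g, "green_lagrange")$eyy,
               0.5 * (1.02^2 - 1))
  # pure small shear gamma = 0.01 (engineering exy = gamma / 2)
  g$dvdy <- 0; g$dudy <- 0.01
  expect_equal(strain_from_gradient(g, "engineering")$exy, 0.005)
})

test_that("Green-Lagrange strain is invariant under rigid rotation", {
  th <- 5 * pi / 180
  fld <- analytic_field_mm(
    function(x, y) (cos(th) - 1) * x - sin(th) * y,
    function(x, y) sin(th) * x + (cos(th) - 1) * y)
  g <- local_gradient(fld, strain_config())
  eng <- strain_from_gradient(g, "engineering")
  gl <- strain_from_gradient(g, "green_lagrange")
  # engineering measure picks up O(theta^2) apparent strain; GL does not
  expect_lt(max(abs(gl$eyy[gl$valid])), 1e-10)
  expect_lt(max(abs(gl$exx[gl$valid])), 1e-10)
  expect_lt(max(abs(gl$exy[gl$valid])), 1e-10)
  expect_gt(max(abs(eng$eyy[eng$valid])), 1e-4)
  expect_lt(max(abs(eng$eyy[eng$valid])), 1e-2)
})

test_that("min_valid_neighbors gates the gradient, invalid windows no error", {
  fld <- analytic_field_mm(function(x, y) 0.01 * x,
                           function(x, y) 0.01 * y, nx = 9, ny = 9)
  fld$valid[] <- FALSE
  fld$valid[c(1, 2)] <- TRUE
  g <- local_gradient(fld, strain_config())
  expect_true(all(!g$valid))
})

test_that("tangent projection reduces to the 2D result on a flat surface", {
  nx <- 13; ny <- 13; sp_mm <- 0.5
  x <- rep(seq_len(nx) * sp_mm, times = ny)
  y <- rep(seq_len(ny) * sp_mm, each = nx)
  surf <- data.frame(facet_id = seq_along(x), X_mm = x, Y_mm = y, Z_mm = 0,
                     valid = TRUE)
  class(surf) <- c("surface3d", "data.frame")
  d3 <- data.frame(facet_id = seq_along(x), dX_mm = 0.002 * x,
                   dY_mm = 0.01 * y, dZ_mm = 0, valid = TRUE)
  class(d3) <- c("displacement_field3d", "data.frame")
  grid <- list(centers = data.frame(facet_id = seq_along(x),
                                    ix = rep(seq_len(nx), times = ny),
                                    iy = rep(seq_len(ny), each = nx)),
               nx = nx, ny = ny)
  class(grid) <- "facet_grid"
  sf <- surface_strain(surf, d3, grid, strain_config())
  expect_lt(max(abs(sf$eyy[sf$valid] - 0.01)), 1e-10)
  expect_lt(max(abs(sf$exx[sf$valid] - 0.002)), 1e-10)
})

test_that("a stretched cylinder reports its axial strain despite curvature", {
  # quarter-cylinder about the Y axis: Z = sqrt(R^2 - X^2), stretched 1%
  nx <- 15; ny <- 15
  R <- 12
  x <- rep(seq(-6, 6, length.out = nx), times = ny)
  y <- rep(seq(0, 14, length.out = ny), each = nx)
  z <- sqrt(R^2 - x^2)
  surf <- data.frame(facet_id = seq_along(x), X_mm = x, Y_mm = y, Z_mm = z,
                     valid = TRUE)
  class(surf) <- c("surface3d", "data.frame")
  d3 <- data.frame(facet_id = seq_along(x), dX_mm = 0, dY_mm = 0.01 * y,
                   dZ_mm = 0, valid = TRUE)
  class(d3) <- c("displacement_field3d", "data.frame")
  grid <- list(centers = data.frame(facet_id = seq_along(x),
                                    ix = rep(seq_len(nx), times = ny),
                                    iy = rep(seq_len(ny), each = nx)),
               nx = nx, ny = ny)
  class(grid) <- "facet_grid"
  sf <- surface_strain(surf, d3, grid, strain_config())
  expect_lt(max(abs(sf$eyy[sf$valid] - 0.01)), 1e-3)
})

test_that("rigid 3D rotation of a surface yields no Green-Lagrange strain", {
  th <- 5 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  nx <- 11; ny <- 11
  x <- rep(seq_len(nx), times = ny); y <- rep(seq_len(ny), each = nx)
  P <- cbind(x, y, 0.05 * x)  # mildly tilted plane
  P2 <- P %*% t(Rz)
  surf <- data.frame(facet_id = seq_along(x), X_mm = P[, 1], Y_mm = P[, 2],
                     Z_mm = P[, 3], valid = TRUE)
  class(surf) <- c("surface3d", "data.frame")
  d3 <- data.frame(facet_id = seq_along(x), dX_mm = P2[, 1] - P[, 1],
                   dY_mm = P2[, 2] - P[, 2], dZ_mm = P2[, 3] - P[, 3],
                   valid = TRUE)
  class(d3) <- c("displacement_field3d", "data.frame")
  grid <- list(centers = data.frame(facet_id = seq_along(x),
                                    ix = rep(seq_len(nx), times = ny),
                                    iy = rep(seq_len(ny), each = nx)),
               nx = nx, ny = ny)
  class(grid) <- "facet_grid"
  cfg <- strain_config(measure = "green_lagrange")
  sf <- surface_strain(surf, d3, grid, cfg)
  # tangent projection leaves a second-order residual; the engineering
  # measure shows the full theta^2/2 apparent strain
  expect_lt(max(abs(sf$eyy[sf$valid])), 1e-4)
  eng <- surface_strain(surf, d3, grid, strain_config())
  expect_gt(max(abs(eng$eyy[eng$valid])), 1e-4)
  expect_lt(max(abs(eng$eyy[eng$valid])), 1e-2)
})

test_that("region averaging is exact on uniform fields and errors when empty", {
  sf <- field_from_strains(rep(0.015, 100), 10, 10, spacing_mm = 1)
  avg <- average_over_region(sf, c(5, 5), 4)
  expect_equal(avg$eyy, 0.015)
  expect_gt(avg$n, 4)
  expect_error(average_over_region(sf, c(50, 50), 4), "no valid facet")
  # disc facet count matches direct enumeration
  d2 <- (sf$x_mm - 5)^2 + (sf$y_mm - 5)^2
  expect_equal(avg$n, sum(d2 <= 4))
  # zero-mean noise averages toward zero as the disc grows
  set.seed(2)
  big <- field_from_strains(rnorm(40 * 40, 0, 0.01), 40, 40, spacing_mm = 1)
  m_small <- replicate(20, {
    i <- sample(1:30, 2)
    average_over_region(big, c(5 + i[1], 5 + i[2]), 4)$eyy
  })
  m_large <- replicate(20, {
    i <- sample(1:10, 2)
    average_over_region(big, c(15 + i[1], 15 + i[2]), 20)$eyy
  })
  expect_gt(sd(m_small), sd(m_large))
})

test_that("end-to-end 2D pipeline recovers a 1% uniform stretch", {
  # flat, homogeneous, slip-free specimen imaged by the straight-on rig;
  # sigma/E = 1% at max load, transverse coupling 1.5
  sp <- specimen_model(ref_width_mm = 8, ref_gauge_length_mm = 12,
                       cross_section_area_mm2 = 20, modulus_E_MPa = 500,
                       transverse_coupling = 1.5,
                       convexity_amplitude_mm = 0,
                       inhomogeneity_amplitude = 0,
                       hysteresis_offset_mm = 0)
  f1 <- 0.01 * 500 * 20  # 100 N -> 1% strain
  pr <- load_protocol(preload_N = 1e-6, step1_increment_N = f1,
                      step1_limit_N = 2 * f1, max_load_N = f1,
                      frames_per_step = 1, hold_at_max = FALSE)
  pk <- speckle_params(220, 400, noise_sd = 0)
  sc <- speckle_scene(sp, pr, grip_slip_model(0, 0), pk, seed = 21,
                      plate_width_mm = 10, plate_height_mm = 3,
                      baseline_mm = 0.0)  # single straight-on view
  sim <- simulate_experiment(sc)
  i1 <- which(sim$frames$force_N == f1)[1]
  ref <- render_sim_frame(sim, 1, 1, noise = FALSE)
  def <- render_sim_frame(sim, i1, 1, noise = FALSE)
  masks <- rig_masks(sc)
  grid <- build_facet_grid(masks$mask_full, 21, 5)
  tr <- track_sequence(ref, list(def), grid, dic_config())[[1]]
  fld <- displacement_to_mm(tr, grid, 0.05)
  s <- strain_from_gradient(local_gradient(fld, strain_config()),
                            "engineering")
  expect_gt(mean(s$valid), 0.95)
  expect_equal(mean(abs(s$eyy[s$valid])), 0.01, tolerance = 0.05 / 1)
  expect_equal(mean(abs(s$exx[s$valid])), 0.015, tolerance = 0.05 / 1.5)
  expect_equal(100 * mean(abs(s$eyy[s$valid])), 1.00, tolerance = 0.05)
})
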