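make_series <- function(force, dic1, dic2, phase = rep("loading",
                                                       length(force)),
                        grip_lower = 0 * force, grip_upper = dic1,
                        band_lower = 0.1 + 0 * force,
                        band_upper = 0.1 + dic2, lvdt = NA_real_) {
  out <- data.frame(step = seq_along(force), frame = 1, force_N = force,
                    phase = phase, grip_lower_mm = grip_lower,
                    grip_upper_mm = grip_upper, band_lower_mm = band_lower,
                    band_upper_mm = band_upper, dic1_mm = dic1,
                    dic2_mm = dic2, lvdt_mm = lvdt, flagged = FALSE)
  class(out) <- c("extensometer_series", "data.frame")
  out
}

test_that("slip arithmetic reproduces the 53% / factor-2 bookkeeping", {
  # grip-to-grip elongation 2.0 mm vs on-specimen 0.94 mm
  s <- make_series(force = c(50, 300, 628),
                   dic1 = 36 + c(0, 1.0, 2.0),
                   dic2 = 34 + c(0, 0.47, 0.94))
  rep <- quantify_slip(s)
  expect_equal(rep$slip_fraction, (2.0 - 0.94) / 2.0)
  expect_equal(rep$slip_fraction, 0.53)
  expect_equal(rep$strain_overestimation_factor,
               (2.0 / 36) / (0.94 / 34), tolerance = 1e-12)
  expect_equal(rep$strain_overestimation_factor, 2.0, tolerance = 0.02)
  # zero slip: fraction 0, factor 1
  s0 <- make_series(force = c(50, 300, 628), dic1 = 36 + c(0, 0.5, 1),
                    dic2 = 36 + c(0, 0.5, 1))
  rep0 <- quantify_slip(s0)
  expect_equal(rep0$slip_fraction, 0)
  expect_equal(rep0$strain_overestimation_factor, 1)
  # degenerate: no elongation
  sflat <- make_series(force = c(50, 60), dic1 = c(36, 36),
                       dic2 = c(34, 34))
  expect_error(quantify_slip(sflat), "undefined")
})

test_that("linear agreement handles exact, scaled and degenerate input", {
  x <- seq(0, 2, length.out = 20)
  fit <- linear_agreement(x, x)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  fit2 <- linear_agreement(x, 0.982 * x)
  expect_equal(fit2$slope, 0.982, tolerance = 1e-12)
  expect_equal(fit2$r2, 1, tolerance = 1e-12)
  # noiseless linear data: r2 = 1 to 1e-12 (property)
  fit3 <- linear_agreement(x, 3.2 * x - 0.4)
  expect_lt(abs(fit3$r2 - 1), 1e-12)
  expect_error(linear_agreement(rep(1, 5), 1:5), "variance")
  # permuting a linear relationship destroys it
  set.seed(4)
  r2s <- replicate(30, linear_agreement(x, sample(x))$r2)
  expect_lt(median(r2s), 0.2)
})

test_that("modulus fitting finds the slope and skips the toe region", {
  # perfectly linear: E = 500 MPa
  eps <- seq(0.001, 0.02, length.out = 15)
  curve <- stress_strain_curve(500 * eps * 55, eps, 55)
  fit <- fit_modulus(curve)
  expect_equal(fit$E_MPa, 500, tolerance = 0.1 / 500)
  expect_equal(fit$n_points, 15)
  # toe region (soft start) followed by a linear region
  toe <- seq(0, 0.01, length.out = 6)
  stress_toe <- 100 * toe + 2000 * toe^2   # concave-up toe
  lin <- seq(0.011, 0.03, length.out = 12)
  stress_lin <- stress_toe[6] + 500 * (lin - toe[6])
  curve2 <- stress_strain_curve(c(stress_toe, stress_lin) * 55 /
                                  55, c(toe, lin), 1)
  fit2 <- fit_modulus(curve2)
  expect_gte(fit2$region[1], 6)  # window excludes the curved toe interior
  expect_equal(fit2$E_MPa, 500, tolerance = 0.02)
  expect_error(fit_modulus(stress_strain_curve(1:5, rep(0.01, 5), 1)),
               "at least")
})

test_that("cumulative distribution matches brute-force counting oracles", {
  # toy 3x3 grid with known strains (in %)
  vals <- c(0, 1, 1, 2, 2, 2, 3, 4, 5) / 100
  sf <- field_from_strains(vals, 3, 3, spacing_mm = 1)
  cd <- cumulative_distribution(sf, "eyy", grid_mm = 1, min_squares = 5)
  expect_equal(cd$n_squares, 9)
  expect_equal(area_fraction_at(cd, 2), 6 / 9)
  expect_equal(area_fraction_exceeding(cd, 2), 3 / 9)
  expect_equal(area_fraction_exceeding(cd, 5), 0)
  # brute-force sort-and-count oracle across the whole curve
  oracle <- sapply(cd$curve$strain_pct, function(x)
    sum(100 * vals <= x + 1e-12) / 9)
  expect_equal(cd$curve$area_fraction, oracle)
  # uniform field: a step function at 1.5%
  sfu <- field_from_strains(rep(0.015, 144), 12, 12)
  cdu <- cumulative_distribution(sfu)
  expect_equal(area_fraction_at(cdu, 1.4), 0)
  expect_equal(area_fraction_at(cdu, 1.5), 1)
  expect_equal(area_fraction_exceeding(cdu, 5), 0)
  # threshold 0: fraction of strictly positive squares
  expect_equal(area_fraction_exceeding(cd, 0), 8 / 9)
})

test_that("the distribution curve is a valid CDF for random fields", {
  for (seed in 1:5) {
    set.seed(seed)
    sf <- field_from_strains(abs(rnorm(400, 0.02, 0.015)), 20, 20)
    cd <- cumulative_distribution(sf)
    A <- cd$curve$area_fraction
    expect_true(all(diff(A) >= 0))
    expect_true(all(A >= 0 & A <= 1))
    expect_equal(max(A), area_fraction_at(cd, 10))
  }
  # sampling excludes squares with no facet within half a diagonal
  sf2 <- field_from_strains(rep(0.01, 9), 3, 3, spacing_mm = 4)
  expect_error(cumulative_distribution(sf2, min_squares = 200), "squares")
})

test_that("hysteresis pairs loading and unloading at matched forces", {
  # elastic series: loading and unloading displacements coincide
  f <- c(50, 200, 400, 600, 400, 200, 50)
  ph <- c(rep("loading", 4), rep("unloading", 3))
  d <- c(0, 0.3, 0.6, 0.9, 0.6, 0.3, 0)
  s <- make_series(f, 36 + d, 34 + d, phase = ph)
  h <- hysteresis(s)
  expect_lt(max(abs(h$dic2_diff_mm)), 1e-12)
  # permanent set of 0.2 mm on unloading
  s2 <- make_series(f, 36 + d + c(0, 0, 0, 0, .5, .5, .5),
                    34 + d + c(0, 0, 0, 0, .2, .2, .2), phase = ph)
  h2 <- hysteresis(s2)
  expect_equal(mean(h2$dic2_diff_mm), 0.2, tolerance = 1e-12)
  # unrecovered slip makes the DIC-1 difference exceed the DIC-2 one
  expect_true(all(h2$dic1_diff_mm >= h2$dic2_diff_mm))
  s3 <- make_series(c(50, 100), c(36, 36.2), c(34, 34.1),
                    phase = c("loading", "loading"))
  expect_error(hysteresis(s3), "phases")
})

test_that("virtual extensometers are constant without deformation", {
  n <- 24
  pos <- lapply(1:3, function(k)
    data.frame(y_mm = c(rep(-1, 8), rep(13, 8), rep(1, 4), rep(11, 4)),
               valid = TRUE))
  region <- c(rep(1, 8), rep(2, 8), rep(3, 4), rep(4, 4))
  tab <- data.frame(step = 1:3, frame = 1, force_N = 50, phase = "loading")
  s <- virtual_extensometers(pos, region, tab)
  expect_equal(unique(s$dic1_mm), 14)
  expect_equal(unique(s$dic2_mm), 10)
  expect_false(any(s$flagged))
  # a region losing all facets flags the frame
  pos[[2]]$valid[region == 3] <- FALSE
  s2 <- virtual_extensometers(pos, region, tab)
  expect_true(s2$flagged[2])
  expect_false(s2$flagged[1])
})

test_that("scatter assessment is zero for identical frames and grows with noise", {
  sf0 <- field_from_strains(rep(0, 400), 20, 20)
  rep0 <- assess_scatter(list(sf0, sf0), c(10, 10), 8)
  expect_equal(rep0$overall_range_pct, 0)
  expect_equal(rep0$central_sd_pct, 0)
  expect_error(assess_scatter(list(), c(10, 10)), "repeated")
  set.seed(6)
  sds <- sapply(c(0.0005, 0.002), function(s) {
    mean(replicate(6, {
      sf <- field_from_strains(rnorm(400, 0, s), 20, 20)
      assess_scatter(list(sf), c(10, 10), 8)$central_sd_pct
    }))
  })
  expect_gt(sds[2], sds[1])
})

test_that("tiny rig round trip recovers the scheduled slip and hysteresis", {
  sc <- tiny_scene(seed = 5)
  sim <- simulate_experiment(sc)
  res <- analyze_experiment(sim)
  f <- sim$frames
  # geometric expectation for this rig: bands sit 0.95 mm inside the clamps
  L <- sc$specimen$ref_gauge_length_mm
  i_pk <- which.max(f$force_N * (f$phase != "unloading"))
  expected_frac <- 1 - (f$dic2_true_mm[i_pk] - f$dic2_true_mm[1]) /
    (f$dic1_true_mm[i_pk] - f$dic1_true_mm[1])
  expect_lt(abs(res$slip$slip_fraction - expected_frac), 0.03)
  # measured DIC-1 - DIC-2 elongation difference matches the schedule
  meas_slip <- res$slip$slip_mm
  true_slip <- (f$dic1_true_mm[i_pk] - f$dic1_true_mm[1]) -
    (f$dic2_true_mm[i_pk] - f$dic2_true_mm[1])
  expect_lt(abs(meas_slip - true_slip), 0.02)
  # grip-to-grip displacement agrees with the rig's reference displacement
  expect_gt(res$agreement$r2, 0.999)
  expect_equal(res$agreement$slope, 1, tolerance = 0.01)
  # modulus round trip (within 5%)
  expect_lt(abs(res$modulus$E_MPa - 500) / 500, 0.05)
  # per-grip split: bone block slips more than the tissue clamp
  expect_gt(res$slip$bone_block_slip_mm, res$slip$tissue_slip_mm)
  # hysteresis visible at matched low forces
  expect_false(is.null(res$hysteresis))
  expect_gt(mean(res$hysteresis$dic1_diff_mm), mean(res$hysteresis$dic2_diff_mm) - 1e-9)
})
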