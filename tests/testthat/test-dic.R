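test_that("facet grid layout matches direct lattice enumeration", {
  mask <- matrix(TRUE, 100, 100)
  g <- build_facet_grid(mask, 21, 10)
  # centres on a step-10 lattice anchored at the bbox corner + half width:
  # 11, 21, ..., 81 in both directions -> 8 x 8
  expect_equal(nrow(g$centers), 64)
  expect_equal(sort(unique(g$centers$x_px)), seq(11, 81, by = 10))
  # dense grid: one centre per fully-interior position
  gd <- build_facet_grid(mask, 21, 1)
  expect_equal(nrow(gd$centers), (100 - 21 + 1)^2)
  expect_error(build_facet_grid(matrix(TRUE, 15, 15), 21, 5), "too small")
  expect_error(build_facet_grid(mask, 20, 5), "odd")
})

test_that("facets never straddle disjoint ROI components", {
  mask <- matrix(FALSE, 100, 60)
  mask[10:40, ] <- TRUE
  mask[47:77, ] <- TRUE   # 6-pixel gap
  g <- build_facet_grid(mask, 21, 5)
  y <- g$centers$y_px
  expect_true(all((y >= 20 & y <= 30) | (y >= 57 & y <= 67)))
})

test_that("zncc satisfies its bounds, affine invariance and NA signalling", {
  set.seed(1)
  a <- matrix(runif(49), 7, 7)
  expect_equal(zncc(a, a), 1.0)
  expect_equal(zncc(a, 2 * a + 7), 1.0)
  expect_equal(zncc(a, -a), -1.0)
  expect_true(is.na(zncc(a, matrix(0.5, 7, 7))))
  for (i in 1:25) {
    b <- matrix(runif(49), 7, 7)
    z <- zncc(a, b)
    expect_true(z >= -1 && z <= 1)
    expect_equal(zncc(a, b), zncc(b, a))
    expect_equal(zncc(1.7 * a - 0.2, b), z, tolerance = 1e-12)
  }
})

test_that("integer search recovers exact shifts and flags flat images", {
  img <- test_speckle(100, seed = 2)
  # integer shift by (+3, -2): def[y, x] = img[y+2, x-3]
  def <- matrix(img[1, 1], 100, 100)
  def[1:(100 - 2), (1 + 3):100] <- img[(1 + 2):100, 1:(100 - 3)]
  s <- integer_search(img, def, c(50, 50), 21, 5)
  expect_true(s$ok)
  expect_equal(c(s$du, s$dv), c(3, -2))
  expect_gt(s$zncc, 0.999)
  # exhaustive oracle: ZNCC map over all offsets
  half <- 10
  fa <- img[(50 - half):(50 + half), (50 - half):(50 + half)]
  cc <- sapply(-5:5, function(du) sapply(-5:5, function(dv)
    zncc(fa, def[(50 + dv - half):(50 + dv + half),
                 (50 + du - half):(50 + du + half)])))
  best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  expect_equal(unname(c(best[2] - 6, best[1] - 6)), c(3, -2))
  # zero shift
  s0 <- integer_search(img, img, c(50, 50), 21, 5)
  expect_equal(c(s0$du, s0$dv), c(0, 0))
  expect_equal(s0$zncc, 1.0)
  # featureless deformed image: no-match signal
  sf <- integer_search(img, matrix(0.4, 100, 100), c(50, 50), 21, 5)
  expect_false(sf$ok)
})

test_that("upsampled-correlation oracle convention is verified on integers", {
  img <- test_speckle(64, seed = 8)
  def <- fft_shift_image(img, 2, -1)
  pk <- xcorr_peak_upsampled(img, def, usfac = 10)
  expect_lt(max(abs(unname(pk) - c(2, -1))), 0.05)
})

test_that("subpixel refinement matches the upsampled-correlation oracle", {
  img <- test_speckle(100, seed = 3)
  for (shift in list(c(0.30, 0), c(-0.25, 0.40), c(0.07, -0.33))) {
    def <- fft_shift_image(img, shift[1], shift[2])
    r <- subpixel_refine(img, def, c(50, 50))
    expect_true(r$converged)
    expect_lt(abs(r$u - shift[1]), 0.02)
    expect_lt(abs(r$v - shift[2]), 0.02)
    # independent oracle on the same (circularly shifted) image pair
    pk <- xcorr_peak_upsampled(img, def)
    expect_lt(abs(r$u - pk["dx"]), 0.02)
    expect_lt(abs(r$v - pk["dy"]), 0.02)
  }
})

test_that("subpixel refinement is exact at zero deformation", {
  img <- test_speckle(80, seed = 4)
  r <- subpixel_refine(img, img, c(40, 40))
  expect_true(r$converged)
  expect_equal(c(r$u, r$v), c(0, 0), tolerance = 1e-10)
  expect_equal(r$zncc, 1.0, tolerance = 1e-12)
})

test_that("subpixel refinement recovers a uniform stretch about the centre", {
  img <- test_speckle(120, seed = 5)
  # def(x) = img(c + (x - c)/1.01): a 1% stretch fixing the centre
  xs <- rep(1:120, each = 120); ys <- rep(1:120, times = 120)
  v <- tendondic:::interp_bicubic_cpp(img, 60 + (xs - 60) / 1.01,
                                      60 + (ys - 60) / 1.01)
  def <- matrix(v, 120, 120)
  r <- subpixel_refine(img, def, c(60, 60))
  expect_true(r$converged)
  expect_lt(abs(r$u), 0.02)
  expect_lt(abs(r$ux - 0.01), 2e-3)
  expect_lt(abs(r$vy - 0.01), 2e-3)
  # off-centre facet: centre displacement follows the analytic warp
  r2 <- subpixel_refine(img, def, c(80, 60))
  expect_lt(abs(r2$u - 20 * 0.01), 0.02)
})

test_that("sequence tracking accumulates staircase shifts from a fixed ref", {
  img <- test_speckle(100, seed = 6)
  frames <- lapply(1:4, function(k) fft_shift_image(img, 0.5 * k, 0))
  mask <- matrix(FALSE, 100, 100)
  mask[11:90, 11:90] <- TRUE  # keep windows clear of the circular wrap
  grid <- build_facet_grid(mask, 21, 20)
  tr <- track_sequence(img, frames, grid, dic_config())
  for (k in 1:4) {
    expect_true(all(tr[[k]]$valid))
    expect_lt(max(abs(tr[[k]]$u_px - 0.5 * k)), 0.02)
    expect_lt(max(abs(tr[[k]]$v_px)), 0.02)
  }
  # identical frames: all zero, all valid
  tr0 <- track_sequence(img, list(img, img), grid, dic_config())
  expect_true(all(tr0[[2]]$valid))
  expect_equal(tr0[[2]]$u_px, rep(0, nrow(grid$centers)), tolerance = 1e-9)
})

test_that("featureless facets are marked invalid without harming the rest", {
  img <- test_speckle(100, seed = 7)
  img[35:65, 35:65] <- 0.4  # occluded flat region
  def <- img
  grid <- build_facet_grid(matrix(TRUE, 100, 100), 21, 10)
  tr <- track_sequence(img, list(def), grid, dic_config())[[1]]
  cx <- grid$centers$x_px; cy <- grid$centers$y_px
  inside <- cx >= 46 & cx <= 54 & cy >= 46 & cy <= 54   # window all flat
  clear <- (cx <= 24 | cx >= 76) & (cy <= 24 | cy >= 76) # window untouched
  expect_true(any(inside) && any(clear))
  expect_true(all(!tr$valid[inside]))
  expect_true(all(tr$valid[clear]))
  expect_error(track_sequence(img, list(matrix(0.5, 50, 50)), grid,
                              dic_config()), "dimensions")
})

test_that("added noise never increases the mean ZNCC", {
  img <- test_speckle(100, seed = 9)
  grid <- build_facet_grid(matrix(TRUE, 100, 100), 21, 15)
  mean_zncc <- function(sd_noise, seed) {
    set.seed(seed)
    def <- img + matrix(rnorm(length(img), 0, sd_noise), nrow(img))
    tr <- track_sequence(img, list(def), grid, dic_config())[[1]]
    mean(tr$zncc, na.rm = TRUE)
  }
  for (seed in 1:4) {
    z0 <- mean_zncc(0.005, seed)
    z1 <- mean_zncc(0.03, seed + 100)
    expect_gt(z0, z1)
  }
})
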