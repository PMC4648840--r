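# Shared fixtures and independent oracles, all built in code at test time.

# small smooth speckle image for correlation tests
test_speckle <- function(n = 100, seed = 1, density = 0.03, blur = 1.2) {
  p <- speckle_params(n, n, speckle_density = density, blur_sigma_px = blur,
                      noise_sd = 0)
  generate_speckle(p, seed)
}

# exact subpixel translation of a (quasi-periodic) image via FFT phase shift;
# independent of the package's bicubic interpolation
fft_shift_image <- function(img, dx, dy) {
  H <- nrow(img); W <- ncol(img)
  kx <- c(0:(W %/% 2), -((W - W %/% 2 - 1):1)) / W
  ky <- c(0:(H %/% 2), -((H - H %/% 2 - 1):1)) / H
  Fm <- stats::fft(img)
  ph <- exp(-2i * pi * (outer(ky * dy, rep(1, W)) +
                          outer(rep(1, H), kx * dx)))
  Re(stats::fft(Fm * ph, inverse = TRUE)) / (H * W)
}

# upsampled cross-correlation peak (sinc-interpolated correlation surface
# evaluated on a 1/usfac grid by local matrix-multiply DFT); returns the
# (dx, dy) shift of img_b relative to img_a at the correlation maximum.
# Orientation is fixed by construction and verified in a test against
# integer shifts.
xcorr_peak_upsampled <- function(img_a, img_b, usfac = 100, halfwin = 1.5) {
  a <- img_a - mean(img_a); b <- img_b - mean(img_b)
  H <- nrow(a); W <- ncol(a)
  Cs <- stats::fft(a) * Conj(stats::fft(b))
  cc <- Re(stats::fft(Cs, inverse = TRUE)) / (H * W)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  dy0 <- wrap(pk[1], H); dx0 <- wrap(pk[2], W)
  fy <- c(0:(H %/% 2), -((H - H %/% 2 - 1):1)) / H
  fx <- c(0:(W %/% 2), -((W - W %/% 2 - 1):1)) / W
  ys <- dy0 + seq(-halfwin, halfwin, by = 1 / usfac)
  xs <- dx0 + seq(-halfwin, halfwin, by = 1 / usfac)
  # sign must match fft(..., inverse = TRUE) = sum C * exp(+2i pi f x)
  My <- exp(2i * pi * outer(ys, fy))       # n_ys x H
  Mx <- exp(2i * pi * outer(fx, xs))       # W x n_xs
  fine <- Re(My %*% Cs %*% Mx)
  ij <- which(fine == max(fine), arr.ind = TRUE)[1, ]
  # the image shifted by (dx, dy) correlates maximally at -(dx, dy) in this
  # convention; negate so the return value is the shift applied to img_b
  c(dx = -xs[ij[2]], dy = -ys[ij[1]])
}

# render a textured fronto-parallel plane at depth z (world mm) through a
# camera: an independent mini-renderer used for stereo reconstruction tests
render_plane <- function(camera, z_mm, tex, scale_mm_per_px,
                         origin_mm = c(0, 0)) {
  W <- camera$width_px; H <- camera$height_px
  xs <- rep(seq_len(W), each = H)
  ys <- rep(seq_len(H), times = W)
  d <- tendondic:::pixel_rays(camera, xs, ys)
  C <- camera$center_mm
  tt <- (z_mm - C[3]) / d[3, ]
  xw <- C[1] + tt * d[1, ]
  yw <- C[2] + tt * d[2, ]
  tx <- (xw - origin_mm[1]) / scale_mm_per_px + ncol(tex) / 2
  ty <- (yw - origin_mm[2]) / scale_mm_per_px + nrow(tex) / 2
  tx <- pmin(pmax(tx, 1), ncol(tex))
  ty <- pmin(pmax(ty, 1), nrow(tex))
  matrix(tendondic:::interp_bicubic_cpp(tex, tx, ty), H, W)
}

# compact synthetic rig for pipeline-level tests (fast to render)
tiny_scene <- function(seed = 5, slip = grip_slip_model(0.33, 0.20),
                       noise_sd = 0.01, inhom_amp = 0.2,
                       hysteresis = 0.1, frames_per_step = 2,
                       max_load = 300, convexity = 0.5) {
  sp <- specimen_model(ref_width_mm = 8, ref_gauge_length_mm = 12,
                       cross_section_area_mm2 = 20, modulus_E_MPa = 500,
                       convexity_amplitude_mm = convexity,
                       inhomogeneity_amplitude = inhom_amp,
                       inhomogeneity_corr_length_mm = 2,
                       hysteresis_offset_mm = hysteresis)
  pr <- load_protocol(preload_N = 48.9, step1_increment_N = 20,
                      step1_limit_N = 100, step2_increment_N = 50,
                      max_load_N = max_load, unload_increment_N = 100,
                      frames_per_step = frames_per_step)
  pk <- speckle_params(220, 400, noise_sd = noise_sd)
  speckle_scene(sp, pr, slip, pk, seed = seed, plate_width_mm = 10,
                plate_height_mm = 3)
}

# regular-lattice displacement field in mm (for strain-module unit tests):
# u and v are functions of (x, y) in mm
analytic_field_mm <- function(ufun, vfun, nx = 15, ny = 15,
                              spacing_mm = 0.5) {
  xs <- seq_len(nx) * spacing_mm
  ys <- seq_len(ny) * spacing_mm
  x <- rep(xs, times = ny); y <- rep(ys, each = nx)
  out <- data.frame(facet_id = seq_along(x), x_mm = x, y_mm = y,
                    u_mm = ufun(x, y), v_mm = vfun(x, y), valid = TRUE)
  attr(out, "lattice") <- list(ix = rep(seq_len(nx), times = ny),
                               iy = rep(seq_len(ny), each = nx),
                               nx = nx, ny = ny)
  class(out) <- c("displacement_field_mm", "data.frame")
  out
}

# strain field on a lattice from explicit eyy values
field_from_strains <- function(eyy, nx, ny, spacing_mm = 1, exx = 0,
                               exy = 0) {
  x <- rep(seq_len(nx) * spacing_mm, times = ny)
  y <- rep(seq_len(ny) * spacing_mm, each = nx)
  out <- data.frame(facet_id = seq_along(x), x_mm = x, y_mm = y,
                    exx = exx, eyy = eyy, exy = exy, valid = TRUE)
  attr(out, "lattice") <- list(ix = rep(seq_len(nx), times = ny),
                               iy = rep(seq_len(ny), each = nx),
                               nx = nx, ny = ny)
  class(out) <- c("strain_field", "data.frame")
  out
}
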