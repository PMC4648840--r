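#' Build a synthetic speckle scene
#'
#' Assembles the textured geometry of the uniaxial rig: the speckled
#' specimen surface (white dots on a dark, dyed background), two rigid grip
#' plates carrying an inverted speckle (black dots on white paint), the
#' stereo cameras, the seeded strain-inhomogeneity field, and the reference
#' regions used by the analysis layer (grip strips for the grip-to-grip
#' extensometer, on-specimen bands adjacent to the clamps, and the central
#' disc).
#'
#' @param specimen A [specimen_model()].
#' @param protocol A [load_protocol()].
#' @param slip A [grip_slip_model()].
#' @param params A [speckle_params()]; its image dimensions set the camera
#'   sensor size.
#' @param seed Integer seed controlling textures and the inhomogeneity field.
#' @param scale_mm_per_px Object-space pixel size at the grip plane.
#' @param working_distance_mm,baseline_mm Stereo rig geometry.
#' @param plate_width_mm,plate_height_mm Grip plate dimensions.
#' @return An object of class `speckle_scene`.
#' @export
speckle_scene <- function(specimen, protocol, slip, params, seed,
                          scale_mm_per_px = 0.05, working_distance_mm = 500,
                          baseline_mm = 140, plate_width_mm = 24,
                          plate_height_mm = 6) {
  stopifnot(inherits(specimen, "specimen_model"),
            inherits(protocol, "load_protocol"),
            inherits(slip, "grip_slip_model"),
            inherits(params, "speckle_params"))
  L <- specimen$ref_gauge_length_mm
  Wsp <- specimen$ref_width_mm
  margin <- 1.5
  sc <- scale_mm_per_px
  tex_dim <- function(w_mm, h_mm) c(ceiling(w_mm / sc), ceiling(h_mm / sc))

  sp_dim <- tex_dim(Wsp + 2 * margin, L + 2 * margin)
  p_sp <- params
  p_sp$image_width_px <- as.integer(sp_dim[1])
  p_sp$image_height_px <- as.integer(sp_dim[2])
  spec_tex <- generate_speckle(p_sp, seed + 11L)

  pl_dim <- tex_dim(plate_width_mm, plate_height_mm)
  p_pl <- params
  p_pl$image_width_px <- as.integer(pl_dim[1])
  p_pl$image_height_px <- as.integer(pl_dim[2])
  # plates are painted white with a black speckle: invert the contrast
  p_pl$background_level <- 0.1
  p_pl$dot_level <- 0.88
  plate_lo <- 1 - generate_speckle(p_pl, seed + 21L)
  plate_up <- 1 - generate_speckle(p_pl, seed + 31L)

  inhom <- if (specimen$inhomogeneity_amplitude > 0)
    inhomogeneity_field(specimen, seed + 41L) else NULL

  cams <- stereo_rig(params$image_width_px, params$image_height_px,
                     scale_mm_per_px = sc,
                     working_distance_mm = working_distance_mm,
                     baseline_mm = baseline_mm, target_y_mm = L / 2)

  # virtual extensometer regions: grip strips just outside the clamp edges
  # (on the plates) and on-specimen bands immediately adjacent to the
  # clamps. Each region is tall enough for one row of default-size facets
  # and stands 0.3 mm off the clamp edge so that no correlation window can
  # straddle the plate/tendon boundary (where grip slip opens a gap).
  region_gap <- 0.3
  region_h <- 1.3
  g0 <- region_gap; g1 <- region_gap + region_h
  regions <- list(
    grip_lower = c(xmin = -plate_width_mm / 2 + 1,
                   xmax = plate_width_mm / 2 - 1, ymin = -g1, ymax = -g0),
    grip_upper = c(xmin = -plate_width_mm / 2 + 1,
                   xmax = plate_width_mm / 2 - 1, ymin = L + g0,
                   ymax = L + g1),
    band_lower = c(xmin = -Wsp / 2 + 1, xmax = Wsp / 2 - 1, ymin = g0,
                   ymax = g1),
    band_upper = c(xmin = -Wsp / 2 + 1, xmax = Wsp / 2 - 1,
                   ymin = L - g1, ymax = L - g0),
    central_disc = c(x = 0, y = L / 2, diameter = 4))

  structure(list(specimen = specimen, protocol = protocol, slip = slip,
                 params = params, seed = as.integer(seed),
                 scale_mm_per_px = sc,
                 spec_tex = spec_tex,
                 spec_x0 = -Wsp / 2 - margin, spec_y0 = -margin,
                 plate_lo = plate_lo, plate_up = plate_up,
                 plate_width_mm = plate_width_mm,
                 plate_height_mm = plate_height_mm,
                 ext_offset_mm = region_gap + region_h / 2,
                 inhom = inhom, cameras = cams,
                 regions = regions),
            class = "speckle_scene")
}

# ---------------------------------------------------------------------------
# Per-frame rig state: nominal strain, permanent offset, slip split and
# commanded grip travel, all relative to the unloaded configuration.

rig_state <- function(scene, force_N, phase = "loading") {
  sp <- scene$specimen
  pr <- scene$protocol
  sl <- scene$slip
  L <- sp$ref_gauge_length_mm
  eps <- function(f) (f / sp$cross_section_area_mm2) / sp$modulus_E_MPa
  e_rel <- eps(force_N) - eps(pr$preload_N)
  h <- sp$hysteresis_offset_mm
  # the permanent set accrues during the constant-force hold at maximum
  # load, so the loading branch stays purely elastic
  permanent <- if (phase == "loading") 0 else h
  elong_spec <- e_rel * L + permanent
  s_tot <- sl$bone_block_slip_fraction + sl$tissue_slip_fraction
  slip_now <- if (phase == "loading") {
    if (s_tot > 0) s_tot / (1 - s_tot) * elong_spec else 0
  } else {
    # slip is not recovered after the peak
    e_max <- eps(pr$max_load_N) - eps(pr$preload_N)
    if (s_tot > 0) s_tot / (1 - s_tot) * (e_max * L + h) else 0
  }
  frac_bb <- if (s_tot > 0) sl$bone_block_slip_fraction / s_tot else 0
  slip_lower <- slip_now * frac_bb      # bone block clamped below
  slip_upper <- slip_now - slip_lower   # tissue clamp above
  grip_travel <- elong_spec + slip_now
  list(force_N = force_N, phase = phase, eps_rel = e_rel,
       eps_abs = eps(force_N), permanent_mm = permanent,
       elong_spec_mm = elong_spec, slip_mm = slip_now,
       slip_lower_mm = slip_lower, slip_upper_mm = slip_upper,
       grip_travel_mm = grip_travel)
}

#' Render one frame of the synthetic rig
#'
#' Inverse-mapped rendering: for every sensor pixel the pre-image on the
#' deformed specimen surface (or on a rigid grip plate) is found by a short
#' fixed-point iteration on the ray/surface intersection, and the reference
#' texture is sampled there with bicubic interpolation. Pixels that hit
#' neither specimen nor plate show the white screen mounted behind the
#' specimen. Additive Gaussian sensor noise is applied last.
#'
#' @param scene A [speckle_scene()].
#' @param force_N Applied force.
#' @param cam Camera index (1 = left, 2 = right).
#' @param noise_seed Seed for the sensor noise; `NULL` renders noise-free.
#' @param phase Protocol phase (`"loading"`, `"hold"` or `"unloading"`),
#'   which determines the hysteresis and slip state.
#' @return Intensity matrix (height x width) in `[0, 1]`.
#' @export
render_frame <- function(scene, force_N, cam = 1, noise_seed = NULL,
                         phase = "loading") {
  st <- rig_state(scene, force_N, phase)
  render_frame_state(scene, st, cam, noise_seed)
}

render_frame_state <- function(scene, st, cam = 1, noise_seed = NULL) {
  sp <- scene$specimen
  camera <- scene$cameras[[cam]]
  W <- camera$width_px; H <- camera$height_px
  L <- sp$ref_gauge_length_mm
  Fmax <- scene$protocol$max_load_N
  C <- camera$center_mm
  g <- st$force_N / Fmax
  sc <- scale_of(scene)
  img <- rep(1.0, W * H)  # white screen background

  # image-space bounding box of a world rectangle (at a set of depths),
  # padded generously; pixels outside can only ever show the screen
  bbox_px <- function(xr, yr, zr, pad = 25) {
    corners <- as.matrix(expand.grid(X = xr, Y = yr, Z = zr))
    px <- project_points(camera, corners)
    c(max(1, floor(min(px[, 1])) - pad), min(W, ceiling(max(px[, 1])) + pad),
      max(1, floor(min(px[, 2])) - pad), min(H, ceiling(max(px[, 2])) + pad))
  }
  pix_subset <- function(bb) {
    xs <- rep(bb[1]:bb[2], each = bb[4] - bb[3] + 1)
    ys <- rep(bb[3]:bb[4], times = bb[2] - bb[1] + 1)
    list(xs = xs, ys = ys, idx = (xs - 1) * H + ys)
  }

  # --- pass A: specimen pre-image by fixed point on material coordinates
  grow <- 1 + 0.1  # widening allowance
  bbA <- bbox_px(c(-1, 1) * (sp$ref_width_mm / 2 * grow + 1),
                 c(-1, L + st$grip_travel_mm + 1),
                 c(0, sp$convexity_amplitude_mm))
  pA <- pix_subset(bbA)
  d <- pixel_rays(camera, pA$xs, pA$ys)
  n <- length(pA$xs)
  Xm <- numeric(n); Ym <- numeric(n)
  zs <- rep(0, n)
  xw <- yw <- NULL
  for (it in 1:4) {
    tt <- (zs - C[3]) / d[3, ]
    xw <- C[1] + tt * d[1, ]
    yw <- C[2] + tt * d[2, ]
    if (it == 1) { Xm <- xw; Ym <- yw }
    # affine part only: the smooth micrometre-scale inhomogeneity term is
    # applied once after convergence (its spatial gradient is far too small
    # to affect the fixed point)
    disp <- deformation_at(sp, st$force_N, cbind(Xm, Ym), NULL,
                           max_force_N = Fmax,
                           permanent_mm = st$permanent_mm,
                           rigid_y_mm = st$slip_lower_mm)
    Xm <- xw - disp[, 1]
    Ym <- yw - disp[, 2]
    # deformed surface height of the current material guess
    zs <- bow_shape(sp, Xm) * (1 - g)
  }
  if (!is.null(scene$inhom) && sp$inhomogeneity_amplitude > 0) {
    eyy0 <- (st$force_N / sp$cross_section_area_mm2) / sp$modulus_E_MPa
    a <- sp$inhomogeneity_amplitude * eyy0 * sp$inhomogeneity_corr_length_mm
    env <- inhom_envelope(sp, Ym)$val
    Xm <- Xm - a * env * eval_inhom(scene$inhom, "gu", Xm, Ym)$val
    Ym <- Ym - a * env * eval_inhom(scene$inhom, "gv", Xm, Ym)$val
  }
  in_spec <- Xm >= -sp$ref_width_mm / 2 & Xm <= sp$ref_width_mm / 2 &
    Ym >= 0 & Ym <= L
  tx <- (Xm - scene$spec_x0) / sc + 1
  ty <- (Ym - scene$spec_y0) / sc + 1
  if (any(in_spec & (tx < 1 | tx > ncol(scene$spec_tex) |
                     ty < 1 | ty > nrow(scene$spec_tex))))
    stop("deformation maps a pixel outside the specimen texture")
  spec_idx <- pA$idx[in_spec]
  img[spec_idx] <- interp_bicubic_cpp(scene$spec_tex, tx[in_spec],
                                      ty[in_spec])

  # --- pass B: rigid grip plates at Z = 0
  pw <- scene$plate_width_mm; ph <- scene$plate_height_mm
  covered <- logical(W * H)
  covered[spec_idx] <- TRUE
  plate_pass <- function(yr_world, travel, tex, tex_y0) {
    bb <- bbox_px(c(-pw / 2, pw / 2), yr_world + travel, 0)
    pB <- pix_subset(bb)
    keep <- !covered[pB$idx]
    if (!any(keep)) return(invisible())
    d <- pixel_rays(camera, pB$xs[keep], pB$ys[keep])
    tt <- (0 - C[3]) / d[3, ]
    xw <- C[1] + tt * d[1, ]
    yw <- C[2] + tt * d[2, ] - travel
    inp <- xw >= -pw / 2 & xw <= pw / 2 & yw >= yr_world[1] &
      yw <= yr_world[2]
    if (any(inp)) {
      ptx <- (xw[inp] + pw / 2) / sc + 1
      pty <- (yw[inp] - tex_y0) / sc + 1
      img[pB$idx[keep][inp]] <<- interp_bicubic_cpp(tex, ptx, pty)
    }
    invisible()
  }
  # lower plate (bone block side) is fixed; upper plate (tissue clamp)
  # translates with the commanded grip travel
  plate_pass(c(-ph, 0), 0, scene$plate_lo, -ph)
  plate_pass(c(L, L + ph), st$grip_travel_mm, scene$plate_up, L)
  out <- matrix(img, nrow = H, ncol = W)
  if (!is.null(noise_seed) && scene$params$noise_sd > 0) {
    out <- out + withr_seed(noise_seed,
                            matrix(stats::rnorm(H * W, 0,
                                                scene$params$noise_sd), H, W))
    out[out < 0] <- 0
    out[out > 1] <- 1
  }
  out
}

scale_of <- function(scene) scene$scale_mm_per_px

# ---------------------------------------------------------------------------

#' Simulate a complete loading experiment
#'
#' Expands the loading protocol into the per-frame force table, computes the
#' exact per-frame ground truth (specimen elongation, slip split, grip
#' travel, virtual gauge distances) and returns a simulation object from
#' which any frame of either camera can be rendered deterministically.
#' Repeated frames at one load position differ only in sensor noise. At
#' every frame the commanded grip-to-grip elongation equals the specimen
#' elongation plus the cumulative slip, exactly.
#'
#' @param scene A [speckle_scene()].
#' @param dir Optional output directory; when given, all frames are written
#'   as 16-bit grayscale TIFF files `cam{0,1}_step{SSS}_frame{F}.tiff`
#'   together with `forces.csv`, `ground_truth.json` and per-frame
#'   ground-truth displacement CSVs.
#' @param cams Camera indices to render when writing to `dir`.
#' @param gt_grid_mm Grid spacing of the written ground-truth maps.
#' @return An object of class `dic_simulation` with elements `scene`,
#'   `frames` (force table plus ground-truth columns) and, when `dir` was
#'   given, `paths`.
#' @export
simulate_experiment <- function(scene, dir = NULL, cams = c(1, 2),
                                gt_grid_mm = 1) {
  stopifnot(inherits(scene, "speckle_scene"))
  tab <- protocol_forces(scene$protocol)
  c0 <- scene$ext_offset_mm
  Lg <- scene$specimen$ref_gauge_length_mm
  L1 <- Lg + 2 * c0  # distance between grip-strip centres (on the plates)
  L2 <- Lg - 2 * c0  # distance between on-specimen band centres
  gt <- lapply(seq_len(nrow(tab)), function(i)
    rig_state(scene, tab$force_N[i], tab$phase[i]))
  tab$eps_rel <- vapply(gt, `[[`, 0, "eps_rel")
  tab$permanent_mm <- vapply(gt, `[[`, 0, "permanent_mm")
  tab$elong_spec_mm <- vapply(gt, `[[`, 0, "elong_spec_mm")
  tab$slip_mm <- vapply(gt, `[[`, 0, "slip_mm")
  tab$slip_lower_mm <- vapply(gt, `[[`, 0, "slip_lower_mm")
  tab$slip_upper_mm <- vapply(gt, `[[`, 0, "slip_upper_mm")
  tab$grip_travel_mm <- vapply(gt, `[[`, 0, "grip_travel_mm")
  tab$dic1_true_mm <- L1 + tab$grip_travel_mm
  tab$dic2_true_mm <- L2 * (1 + tab$eps_rel + tab$permanent_mm / Lg)
  tab$lvdt_mm <- tab$grip_travel_mm
  sim <- structure(list(scene = scene, frames = tab), class = "dic_simulation")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- character(0)
    for (i in seq_len(nrow(tab))) {
      for (cam in cams) {
        img <- render_sim_frame(sim, i, cam)
        fn <- sprintf("cam%d_step%03d_frame%d.tiff", cam - 1, tab$step[i],
                      tab$frame[i])
        write_image(img, file.path(dir, fn))
        paths <- c(paths, file.path(dir, fn))
      }
      gtm <- ground_truth_maps(sim, i, grid_mm = gt_grid_mm)
      utils::write.csv(gtm, file.path(dir, sprintf("gt_step%03d_frame%d.csv",
                                                   tab$step[i], tab$frame[i])),
                       row.names = FALSE)
    }
    utils::write.csv(tab[, c("step", "frame", "force_N", "phase")],
                     file.path(dir, "forces.csv"), row.names = FALSE)
    jsonlite::write_json(tab, file.path(dir, "ground_truth.json"),
                         digits = NA, auto_unbox = TRUE)
    sim$paths <- paths
    sim$dir <- dir
  }
  sim
}

#' Render one frame of a simulation
#'
#' Deterministic for a fixed scene seed: the per-frame noise seed is derived
#' from the scene seed, the frame index and the camera.
#'
#' @param sim A [simulate_experiment()] result.
#' @param i Row index into `sim$frames`.
#' @param cam Camera index (1 or 2).
#' @param noise Set `FALSE` to render without sensor noise.
#' @return Intensity matrix.
#' @export
render_sim_frame <- function(sim, i, cam = 1, noise = TRUE) {
  stopifnot(inherits(sim, "dic_simulation"))
  tab <- sim$frames
  st <- rig_state(sim$scene, tab$force_N[i], tab$phase[i])
  ns <- if (noise) frame_noise_seed(sim$scene$seed, i, cam) else NULL
  render_frame_state(sim$scene, st, cam, ns)
}

frame_noise_seed <- function(seed, i, cam) {
  (abs(seed) %% 1000000L) * 1000L + i * 2L + cam
}

#' Ground-truth displacement and strain map for one frame
#'
#' Analytic displacement (relative to the preload reference frame) and the
#' matching strain tensor, sampled on a regular grid over the specimen. The
#' strain columns are the spatial derivative of the displacement field to
#' numerical precision.
#'
#' @param sim A [simulate_experiment()] result.
#' @param i Row index into `sim$frames`.
#' @param grid_mm Grid spacing.
#' @return Data frame with columns `x_mm`, `y_mm`, `u_mm`, `v_mm`, `w_mm`,
#'   `exx`, `eyy`, `exy`.
#' @export
ground_truth_maps <- function(sim, i, grid_mm = 1) {
  scene <- sim$scene
  sp <- scene$specimen
  tab <- sim$frames
  st <- rig_state(scene, tab$force_N[i], tab$phase[i])
  pre <- rig_state(scene, scene$protocol$preload_N, "loading")
  xs <- seq(-sp$ref_width_mm / 2 + grid_mm / 2, sp$ref_width_mm / 2,
            by = grid_mm)
  ys <- seq(grid_mm / 2, sp$ref_gauge_length_mm, by = grid_mm)
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  Fmax <- scene$protocol$max_load_N
  d1 <- deformation_at(sp, st$force_N, pts, scene$inhom, Fmax,
                       st$permanent_mm, st$slip_lower_mm)
  d0 <- deformation_at(sp, pre$force_N, pts, scene$inhom, Fmax,
                       pre$permanent_mm, pre$slip_lower_mm)
  s1 <- strain_at(sp, st$force_N, pts, scene$inhom, Fmax, st$permanent_mm)
  s0 <- strain_at(sp, pre$force_N, pts, scene$inhom, Fmax, pre$permanent_mm)
  data.frame(x_mm = pts[, 1], y_mm = pts[, 2],
             u_mm = d1[, 1] - d0[, 1], v_mm = d1[, 2] - d0[, 2],
             w_mm = d1[, 3] - d0[, 3],
             exx = s1[, 1] - s0[, 1], eyy = s1[, 2] - s0[, 2],
             exy = s1[, 3] - s0[, 3])
}
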