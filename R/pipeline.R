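#' Region-of-interest masks and facet region labels for a scene
#'
#' Projects the scene's analysis regions (grip strips, on-specimen bands,
#' central disc, full specimen interior) into the left reference image and
#' returns pixel masks plus a labelling function for facet centres.
#'
#' @param scene A [speckle_scene()].
#' @param cam Camera index used for the projection.
#' @return List with `mask_regions` (union of extensometer regions and
#'   central disc), `mask_full` (specimen interior, 1 mm shrunk),
#'   `region_id(x_px, y_px)` returning 1/2 lower/upper grip, 3/4 lower/upper
#'   band, 5 central disc, 0 otherwise, and the projected rectangles.
#' @export
rig_masks <- function(scene, cam = 1) {
  camera <- scene$cameras[[cam]]
  sp <- scene$specimen
  g_pre <- scene$protocol$preload_N / scene$protocol$max_load_N
  zspec <- function(X) bow_shape(sp, X) * (1 - g_pre)
  proj_rect <- function(r, on_specimen) {
    xs <- c(r["xmin"], r["xmax"])
    ys <- c(r["ymin"], r["ymax"])
    corners <- expand.grid(X = xs, Y = ys)
    z <- if (on_specimen) zspec(corners$X) else rep(0, 4)
    px <- project_points(camera, cbind(corners$X, corners$Y, z))
    c(xmin = min(px[, 1]), xmax = max(px[, 1]),
      ymin = min(px[, 2]), ymax = max(px[, 2]))
  }
  rg <- scene$regions
  rects <- list(grip_lower = proj_rect(rg$grip_lower, FALSE),
                grip_upper = proj_rect(rg$grip_upper, FALSE),
                band_lower = proj_rect(rg$band_lower, TRUE),
                band_upper = proj_rect(rg$band_upper, TRUE))
  disc <- rg$central_disc
  dc <- project_points(camera, cbind(disc["x"], disc["y"],
                                     zspec(disc["x"])))
  disc_r_px <- disc["diameter"] / 2 / scene$scale_mm_per_px
  W <- camera$width_px; H <- camera$height_px
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), times = W), H, W)
  in_rect <- function(r) xs >= r["xmin"] & xs <= r["xmax"] &
    ys >= r["ymin"] & ys <= r["ymax"]
  mask_regions <- in_rect(rects$grip_lower) | in_rect(rects$grip_upper) |
    in_rect(rects$band_lower) | in_rect(rects$band_upper) |
    ((xs - dc[1])^2 + (ys - dc[2])^2 <= disc_r_px^2)
  shrink <- 1  # mm kept clear of the specimen boundary
  full <- proj_rect(c(xmin = -sp$ref_width_mm / 2 + shrink,
                      xmax = sp$ref_width_mm / 2 - shrink,
                      ymin = shrink, ymax = sp$ref_gauge_length_mm - shrink),
                    TRUE)
  mask_full <- in_rect(full)
  region_id <- function(x_px, y_px) {
    out <- integer(length(x_px))
    test <- function(r) x_px >= r["xmin"] & x_px <= r["xmax"] &
      y_px >= r["ymin"] & y_px <= r["ymax"]
    out[test(rects$grip_lower)] <- 1L
    out[test(rects$grip_upper)] <- 2L
    out[test(rects$band_lower)] <- 3L
    out[test(rects$band_upper)] <- 4L
    indisc <- (x_px - dc[1])^2 + (y_px - dc[2])^2 <= disc_r_px^2
    out[indisc] <- 5L
    out
  }
  list(mask_regions = mask_regions, mask_full = mask_full,
       region_id = region_id, rects = rects, disc_center_px = dc,
       disc_radius_px = disc_r_px)
}

#' Calibrate the rig cameras from a synthetic target
#'
#' Emulates the calibration step: a small planar dot target is presented at
#' several positions and depths across the measurement volume; the known
#' target coordinates and their (noisy) image projections feed the DLT
#' estimator for each camera.
#'
#' @param scene A [speckle_scene()].
#' @param noise_px Gaussian noise added to the detected target image
#'   coordinates.
#' @param seed Seed for the detection noise.
#' @param target_w_mm,target_h_mm Target dimensions.
#' @return List of two [calibrate_dlt()] results (left, right).
#' @export
rig_calibration <- function(scene, noise_px = 0.02, seed = 1,
                            target_w_mm = 12, target_h_mm = 9) {
  L <- scene$specimen$ref_gauge_length_mm
  gx <- seq(-target_w_mm / 2, target_w_mm / 2, length.out = 5)
  gy <- seq(-target_h_mm / 2, target_h_mm / 2, length.out = 4)
  base <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  poses <- rbind(c(0, L * 0.2, -4), c(0, L * 0.2, 4),
                 c(-4, L * 0.5, 0), c(4, L * 0.8, -4),
                 c(0, L * 0.8, 4))
  world <- do.call(rbind, lapply(seq_len(nrow(poses)), function(i)
    cbind(base[, 1] + poses[i, 1], base[, 2] + poses[i, 2], poses[i, 3])))
  lapply(1:2, function(cam) {
    px <- project_points(scene$cameras[[cam]], world)
    px <- px + withr_seed(seed + cam,
                          matrix(stats::rnorm(length(px), 0, noise_px),
                                 nrow(px)))
    calibrate_dlt(world, px)
  })
}

# lazy per-frame renderers for a simulation
sim_frame_list <- function(sim, cam, idx = seq_len(nrow(sim$frames))) {
  lapply(idx, function(i) {
    force(i)
    function() render_sim_frame(sim, i, cam)
  })
}

#' Full-protocol stereo analysis of a simulated experiment
#'
#' Runs the complete measurement chain on a [simulate_experiment()] result:
#' DLT calibration from a synthetic target, facet tracking of the grip
#' strips, on-specimen bands and central disc through every frame of both
#' cameras, stereo reconstruction, virtual extensometers, grip-slip
#' quantification, agreement of the DIC-1 extensometer with the reference
#' (LVDT-like) displacement, the stress-strain curve from the central-disc
#' strain, the fitted Young's modulus and the loading/unloading hysteresis.
#'
#' @param sim A [simulate_experiment()] result.
#' @param dic A [dic_config()].
#' @param strain A [strain_config()].
#' @param calib Optional list of two calibrations (defaults to
#'   [rig_calibration()] with the scene seed).
#' @param frame_idx Frames to analyse (default: all).
#' @return List with `series` (extensometer series), `slip`, `agreement`,
#'   `curve`, `modulus`, `hysteresis`, `grid`, `region_id`, `recon`.
#' @export
analyze_experiment <- function(sim, dic = dic_config(),
                               strain = strain_config(), calib = NULL,
                               frame_idx = seq_len(nrow(sim$frames))) {
  stopifnot(inherits(sim, "dic_simulation"))
  scene <- sim$scene
  masks <- rig_masks(scene)
  if (is.null(calib)) calib <- rig_calibration(scene, seed = scene$seed)
  grid <- build_facet_grid(masks$mask_regions, dic$facet_size_px,
                           dic$step_px)
  region <- masks$region_id(grid$centers$x_px, grid$centers$y_px)
  left_ref <- render_sim_frame(sim, frame_idx[1], 1)
  right_ref <- render_sim_frame(sim, frame_idx[1], 2)
  recon <- reconstruct_displacements(
    left_ref, right_ref,
    sim_frame_list(sim, 1, frame_idx), sim_frame_list(sim, 2, frame_idx),
    grid, calib[[1]], calib[[2]], dic)
  tab <- sim$frames[frame_idx, ]
  positions <- extensometer_positions_3d(recon)
  series <- virtual_extensometers(positions, region, tab)
  slip <- quantify_slip(series)
  ld <- series$phase %in% c("loading", "hold") & !series$flagged
  agreement <- linear_agreement(series$lvdt_mm[ld] - series$lvdt_mm[ld][1],
                                series$dic1_mm[ld] - series$dic1_mm[ld][1])
  # central-disc strain per loading step (first frame of each step)
  steps <- tab$frame == 1 & tab$phase == "loading"
  disc_sel <- which(steps)
  disc_eyy <- vapply(disc_sel, function(k) {
    sf <- surface_strain(recon$surface_ref, recon$frames[[k]]$displacement,
                         grid, strain)
    ctr <- c(scene$regions$central_disc["x"],
             scene$regions$central_disc["y"])
    average_over_region(sf, ctr,
                        scene$regions$central_disc["diameter"])$eyy
  }, 0)
  curve <- stress_strain_curve(tab$force_N[disc_sel] -
                                 scene$protocol$preload_N,
                               disc_eyy,
                               scene$specimen$cross_section_area_mm2)
  modulus <- fit_modulus(curve)
  hyst <- tryCatch(hysteresis(series), error = function(e) NULL)
  list(series = series, slip = slip, agreement = agreement, curve = curve,
       modulus = modulus, hysteresis = hyst, grid = grid,
       region_id = region, recon = recon, calib = calib)
}

#' Static-accuracy (scatter) analysis of repeated preload frames
#'
#' Tracks the full specimen field between repeated static frames at the
#' preload (identical geometry, independent sensor noise), reconstructs the
#' surfaces, computes the strain fields (whose true value is zero) and
#' summarizes the measurement scatter.
#'
#' @param sim A [simulate_experiment()] result; its first protocol step
#'   must have at least 2 frames.
#' @param dic A [dic_config()].
#' @param strain A [strain_config()].
#' @param calib Optional calibrations.
#' @return List with `report` (an [assess_scatter()] result), the strain
#'   `fields` and the `grid`.
#' @export
scatter_analysis <- function(sim, dic = dic_config(),
                             strain = strain_config(), calib = NULL) {
  scene <- sim$scene
  tab <- sim$frames
  idx <- which(tab$step == tab$step[1])
  if (length(idx) < 2) stop("need at least 2 repeated frames at the preload")
  masks <- rig_masks(scene)
  if (is.null(calib)) calib <- rig_calibration(scene, seed = scene$seed)
  grid <- build_facet_grid(masks$mask_full, dic$facet_size_px, dic$step_px)
  left_ref <- render_sim_frame(sim, idx[1], 1)
  right_ref <- render_sim_frame(sim, idx[1], 2)
  rest <- idx[-1]
  recon <- reconstruct_displacements(
    left_ref, right_ref,
    sim_frame_list(sim, 1, rest), sim_frame_list(sim, 2, rest),
    grid, calib[[1]], calib[[2]], dic)
  fields <- lapply(recon$frames, function(fr)
    surface_strain(recon$surface_ref, fr$displacement, grid, strain))
  ctr <- c(scene$regions$central_disc["x"], scene$regions$central_disc["y"])
  report <- assess_scatter(fields, ctr,
                           scene$regions$central_disc["diameter"])
  list(report = report, fields = fields, grid = grid, recon = recon)
}

#' Full-field strain at maximum load and its cumulative distribution
#'
#' Tracks the whole specimen field through the first frame of every
#' loading step (so facet initialization can follow the deformation),
#' reconstructs the surface at maximum load, computes the strain field and
#' tiles it on the millimetre grid.
#'
#' @param sim A [simulate_experiment()] result.
#' @param dic A [dic_config()].
#' @param strain A [strain_config()].
#' @param calib Optional calibrations.
#' @param grid_mm Square size of the distribution grid.
#' @return List with `field` (the max-load `strain_field`) and
#'   `distribution` (a [cumulative_distribution()] result).
#' @export
max_load_distribution <- function(sim, dic = dic_config(),
                                  strain = strain_config(), calib = NULL,
                                  grid_mm = 1.0) {
  scene <- sim$scene
  tab <- sim$frames
  masks <- rig_masks(scene)
  if (is.null(calib)) calib <- rig_calibration(scene, seed = scene$seed)
  grid <- build_facet_grid(masks$mask_full, dic$facet_size_px, dic$step_px)
  idx <- which(tab$phase == "loading" & tab$frame == 1)
  left_ref <- render_sim_frame(sim, idx[1], 1)
  right_ref <- render_sim_frame(sim, idx[1], 2)
  recon <- reconstruct_displacements(
    left_ref, right_ref,
    sim_frame_list(sim, 1, idx), sim_frame_list(sim, 2, idx),
    grid, calib[[1]], calib[[2]], dic)
  last <- recon$frames[[length(idx)]]
  field <- surface_strain(recon$surface_ref, last$displacement, grid,
                          strain)
  list(field = field,
       distribution = cumulative_distribution(field, "eyy",
                                              grid_mm = grid_mm))
}

#' Constructed inhomogeneous strain field with a calibrated quantile
#'
#' Builds a smooth positive synthetic strain field over a specimen-shaped
#' region whose true area fraction at or below `at_pct` equals
#' `target_fraction` exactly (by monotone rescaling against the field's
#' quantile on a fine evaluation grid). Used to exercise the cumulative
#' strain distribution against a known ground truth.
#'
#' @param width_mm,length_mm Region dimensions.
#' @param spacing_mm Facet spacing of the returned field.
#' @param corr_mm Correlation length of the smooth field.
#' @param seed Seed.
#' @param target_fraction Desired true `A(at_pct)`.
#' @param at_pct Strain level (in %) at which the fraction is calibrated.
#' @return A `strain_field` data frame (with lattice attribute); the
#'   calibrated true quantile is stored in attribute `true_fraction`.
#' @export
synthetic_strain_field <- function(width_mm = 16, length_mm = 33,
                                   spacing_mm = 0.25, corr_mm = 4, seed = 7,
                                   target_fraction = 0.80, at_pct = 2.0) {
  n_cells_x <- max(8L, ceiling(width_mm / corr_mm) + 3L)
  n_cells_y <- max(8L, ceiling(length_mm / corr_mm) + 3L)
  raw <- withr_seed(seed, matrix(stats::rnorm(n_cells_x * n_cells_y),
                                 n_cells_y, n_cells_x))
  sm <- gaussian_blur_cpp(raw, 1.0)
  sm <- sm - min(sm)  # non-negative base field
  eval_at <- function(x_mm, y_mm) {
    gx <- x_mm / corr_mm + 2
    gy <- y_mm / corr_mm + 2
    interp_bicubic_cpp(sm, gx, gy)
  }
  # calibrate the scale on a fine grid so that A(at_pct) = target_fraction
  fx <- seq(0, width_mm, by = 0.1)
  fy <- seq(0, length_mm, by = 0.1)
  fine <- eval_at(rep(fx, times = length(fy)), rep(fy, each = length(fx)))
  q <- stats::quantile(fine, target_fraction, names = FALSE)
  scale_fac <- (at_pct / 100) / q
  xs <- seq(spacing_mm / 2, width_mm, by = spacing_mm)
  ys <- seq(spacing_mm / 2, length_mm, by = spacing_mm)
  X <- rep(xs, times = length(ys))
  Y <- rep(ys, each = length(xs))
  eyy <- scale_fac * eval_at(X, Y)
  out <- data.frame(facet_id = seq_along(X), x_mm = X, y_mm = Y,
                    exx = 0, eyy = eyy, exy = 0, valid = TRUE)
  attr(out, "lattice") <- list(ix = rep(seq_along(xs), times = length(ys)),
                               iy = rep(seq_along(ys), each = length(xs)),
                               nx = length(xs), ny = length(ys))
  attr(out, "true_fraction") <- mean(fine * scale_fac <= at_pct / 100)
  class(out) <- c("strain_field", "data.frame")
  out
}
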