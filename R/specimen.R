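#' Specimen model for the synthetic tensile rig
#'
#' Geometry and constitutive parameters of the simulated tendon specimen.
#' The load axis is Y (mm, upward from the lower clamp edge), X runs across
#' the specimen width (centred at 0) and Z points toward the cameras.
#'
#' @param ref_width_mm Reference specimen width.
#' @param ref_gauge_length_mm Free (clamp-to-clamp) length.
#' @param cross_section_area_mm2 Cross-sectional area used to convert force
#'   to stress.
#' @param modulus_E_MPa Young's modulus of the homogeneous response,
#'   `eps_yy = sigma / E`.
#' @param transverse_coupling Ratio `eps_xx / eps_yy`. Positive values mean
#'   the specimen widens under load, as a slightly convex specimen does when
#'   it flattens.
#' @param convexity_amplitude_mm Out-of-plane bow depth at the specimen
#'   centre in the unloaded state; the bow flattens in proportion to the load
#'   fraction.
#' @param inhomogeneity_amplitude Dimensionless amplitude of the smooth
#'   zero-mean strain inhomogeneity field, relative to the nominal strain
#'   (0.3 means local strains vary by roughly +/-30% of the mean).
#' @param inhomogeneity_corr_length_mm Correlation length of that field.
#' @param hysteresis_offset_mm Permanent elongation remaining after a full
#'   load/unload cycle; it ramps in once the load exceeds half the maximum.
#' @return An object of class `specimen_model`.
#' @export
specimen_model <- function(ref_width_mm = 20, ref_gauge_length_mm = 35,
                           cross_section_area_mm2 = 55,
                           modulus_E_MPa = 500, transverse_coupling = 1.5,
                           convexity_amplitude_mm = 1.0,
                           inhomogeneity_amplitude = 0.3,
                           inhomogeneity_corr_length_mm = 2,
                           hysteresis_offset_mm = 0.3) {
  stopifnot(ref_width_mm > 0, ref_gauge_length_mm > 0,
            cross_section_area_mm2 > 0, modulus_E_MPa > 0,
            inhomogeneity_amplitude >= 0, inhomogeneity_corr_length_mm > 0,
            hysteresis_offset_mm >= 0)
  structure(list(ref_width_mm = ref_width_mm,
                 ref_gauge_length_mm = ref_gauge_length_mm,
                 cross_section_area_mm2 = cross_section_area_mm2,
                 modulus_E_MPa = modulus_E_MPa,
                 transverse_coupling = transverse_coupling,
                 convexity_amplitude_mm = convexity_amplitude_mm,
                 inhomogeneity_amplitude = inhomogeneity_amplitude,
                 inhomogeneity_corr_length_mm = inhomogeneity_corr_length_mm,
                 hysteresis_offset_mm = hysteresis_offset_mm),
            class = "specimen_model")
}

#' Loading protocol of the uniaxial rig
#'
#' Static load steps from a preload up to a maximum, an optional hold at the
#' maximum, and stepwise unloading; several frames are captured at each step
#' so that repeated frames at one load differ only in sensor noise.
#'
#' @param preload_N Preload force.
#' @param step1_increment_N,step1_limit_N Increment used while the force is
#'   below `step1_limit_N`.
#' @param step2_increment_N Increment used above `step1_limit_N`.
#' @param max_load_N Maximum force (the final loading step lands on it
#'   exactly).
#' @param unload_increment_N Unloading decrement; unloading ends back at the
#'   preload.
#' @param frames_per_step Images captured at each load position.
#' @param hold_at_max Whether to repeat the maximum-load step once more,
#'   representing the constant-force hold before unloading.
#' @return An object of class `load_protocol`.
#' @export
load_protocol <- function(preload_N = 48.9, step1_increment_N = 10,
                          step1_limit_N = 100, step2_increment_N = 25,
                          max_load_N = 628.3, unload_increment_N = 50,
                          frames_per_step = 3L, hold_at_max = TRUE) {
  stopifnot(preload_N > 0, step1_increment_N > 0, step2_increment_N > 0,
            max_load_N > preload_N, unload_increment_N > 0,
            frames_per_step >= 1)
  structure(list(preload_N = preload_N, step1_increment_N = step1_increment_N,
                 step1_limit_N = step1_limit_N,
                 step2_increment_N = step2_increment_N,
                 max_load_N = max_load_N,
                 unload_increment_N = unload_increment_N,
                 frames_per_step = as.integer(frames_per_step),
                 hold_at_max = isTRUE(hold_at_max)),
            class = "load_protocol")
}

#' Expand a protocol into the per-frame force table
#'
#' @param protocol A [load_protocol()] object.
#' @return A data frame with columns `step`, `frame`, `force_N`, `phase`
#'   (`loading`, `hold` or `unloading`). Loading forces are strictly
#'   increasing across steps; unloading forces strictly decreasing.
#' @export
protocol_forces <- function(protocol) {
  stopifnot(inherits(protocol, "load_protocol"))
  f <- protocol$preload_N
  loading <- f
  while (f + protocol$step1_increment_N <= protocol$step1_limit_N + 1e-9 &&
         f + protocol$step1_increment_N < protocol$max_load_N - 1e-9) {
    f <- f + protocol$step1_increment_N
    loading <- c(loading, f)
  }
  while (f + protocol$step2_increment_N < protocol$max_load_N - 1e-9) {
    f <- f + protocol$step2_increment_N
    loading <- c(loading, f)
  }
  loading <- c(loading, protocol$max_load_N)
  hold <- if (protocol$hold_at_max) protocol$max_load_N else numeric(0)
  unloading <- numeric(0)
  f <- protocol$max_load_N
  while (f - protocol$unload_increment_N > protocol$preload_N + 1e-9) {
    f <- f - protocol$unload_increment_N
    unloading <- c(unloading, f)
  }
  unloading <- c(unloading, protocol$preload_N)
  forces <- c(loading, hold, unloading)
  phase <- c(rep("loading", length(loading)), rep("hold", length(hold)),
             rep("unloading", length(unloading)))
  k <- protocol$frames_per_step
  data.frame(step = rep(seq_along(forces), each = k),
             frame = rep(seq_len(k), times = length(forces)),
             force_N = rep(forces, each = k),
             phase = rep(phase, each = k),
             stringsAsFactors = FALSE)
}

#' Grip slip model
#'
#' Fractions of the commanded grip travel lost at the bone-block clamp and at
#' the tissue clamp. The bone block is expected to slip at least as much as
#' the tissue clamp.
#'
#' @param bone_block_slip_fraction,tissue_slip_fraction Fractions in
#'   `[0, 1)`; their sum is the total slip fraction of grip-to-grip travel.
#' @return An object of class `grip_slip_model`.
#' @export
grip_slip_model <- function(bone_block_slip_fraction = 0.33,
                            tissue_slip_fraction = 0.20) {
  stopifnot(bone_block_slip_fraction >= 0, bone_block_slip_fraction < 1,
            tissue_slip_fraction >= 0, tissue_slip_fraction < 1,
            bone_block_slip_fraction + tissue_slip_fraction < 1)
  if (bone_block_slip_fraction < tissue_slip_fraction)
    stop("bone_block_slip_fraction must be >= tissue_slip_fraction")
  structure(list(bone_block_slip_fraction = bone_block_slip_fraction,
                 tissue_slip_fraction = tissue_slip_fraction),
            class = "grip_slip_model")
}

# ---------------------------------------------------------------------------
# Smooth seeded inhomogeneity field: Gaussian-filtered white noise on a
# coarse grid (one cell per correlation length), evaluated by bicubic
# interpolation so that analytic spatial derivatives are available.

inhomogeneity_field <- function(specimen, seed,
                                margin_mm = 2 * specimen$inhomogeneity_corr_length_mm) {
  l <- specimen$inhomogeneity_corr_length_mm
  x0 <- -specimen$ref_width_mm / 2 - margin_mm
  x1 <- specimen$ref_width_mm / 2 + margin_mm
  y0 <- -margin_mm
  y1 <- specimen$ref_gauge_length_mm + margin_mm
  nx <- max(8L, ceiling((x1 - x0) / l) + 1L)
  ny <- max(8L, ceiling((y1 - y0) / l) + 1L)
  make1 <- function(sub, center_rows) {
    raw <- withr_seed(seed + sub, matrix(stats::rnorm(nx * ny), ny, nx))
    sm <- gaussian_blur_cpp(raw, 1.0)
    # equilibrium of a uniaxial test keeps the cross-section-averaged
    # longitudinal displacement close to nominal: remove the per-row
    # (constant-Y) mean from the longitudinal perturbation
    if (center_rows) sm <- sm - rowMeans(sm) else sm <- sm - mean(sm)
    sdv <- stats::sd(as.vector(sm))
    if (sdv > 0) sm <- sm / sdv
    sm
  }
  structure(list(gu = make1(101L, FALSE), gv = make1(202L, TRUE),
                 x0 = x0, y0 = y0, cell_mm = l, nx = nx, ny = ny),
            class = "inhomogeneity_field")
}

# Evaluate field component ("gu"/"gv") and its spatial derivatives at
# (X, Y) mm. Returns list(val, dX, dY); derivatives are of the bicubic
# interpolant, i.e. exact for the field as defined.
eval_inhom <- function(field, which, X, Y) {
  g <- field[[which]]
  gx <- (X - field$x0) / field$cell_mm + 1
  gy <- (Y - field$y0) / field$cell_mm + 1
  m <- interp_bicubic_grad_cpp(g, gx, gy)
  list(val = m[, 1], dX = m[, 2] / field$cell_mm, dY = m[, 3] / field$cell_mm)
}

# Amplitude envelope of the inhomogeneity along the gauge length: strongest
# adjacent to the clamps (where real tests show elevated, irregular strain)
# and decaying smoothly to a mid-substance floor. Analytic derivative
# available for the ground-truth strain.
inhom_envelope <- function(specimen, Y) {
  L <- specimen$ref_gauge_length_mm
  tau <- L / 8
  f <- 0.15
  e1 <- exp(-Y / tau)
  e2 <- exp(-(L - Y) / tau)
  list(val = f + (1 - f) * (e1 + e2),
       dY = (1 - f) * (-e1 / tau + e2 / tau))
}

# bow shape B(X): out-of-plane height of the unloaded convex specimen
bow_shape <- function(specimen, X) {
  w <- specimen$ref_width_mm
  specimen$convexity_amplitude_mm * pmax(0, 1 - (2 * X / w)^2)
}

#' Analytic displacement field of the loaded specimen
#'
#' Closed-form displacement of a reference surface point under a static
#' force: uniform longitudinal stretch `eps_yy = sigma / E` (stress = force /
#' area), transverse stretch `eps_xx = transverse_coupling * eps_yy`,
#' out-of-plane flattening of the convex bow in proportion to the load
#' fraction of `max_force_N`, plus a smooth seeded zero-mean inhomogeneity
#' perturbation scaling with the nominal strain. Optional rigid and permanent
#' contributions (used by the rig simulation for grip slip and hysteresis)
#' are added on top.
#'
#' @param specimen A [specimen_model()].
#' @param force_N Applied force (N), `0 <= force_N <= max_force_N`.
#' @param points Two-column matrix (or data frame) of reference coordinates
#'   `(X_mm, Y_mm)` on the specimen surface.
#' @param inhom Optional inhomogeneity field from an internal generator run;
#'   `NULL` disables the perturbation.
#' @param max_force_N Protocol maximum, used for the bow-flattening fraction.
#' @param permanent_mm Permanent (hysteresis) elongation already accumulated,
#'   distributed uniformly along the gauge length.
#' @param rigid_y_mm Rigid longitudinal offset (slip at the lower clamp).
#' @return A matrix with columns `u_mm`, `v_mm`, `w_mm` (displacement along
#'   X, Y, Z).
#' @export
deformation_at <- function(specimen, force_N, points, inhom = NULL,
                           max_force_N = 628.3, permanent_mm = 0,
                           rigid_y_mm = 0) {
  stopifnot(inherits(specimen, "specimen_model"))
  if (force_N < 0) stop("force must be >= 0")
  if (force_N > max_force_N + 1e-9) stop("force exceeds the protocol maximum")
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  X <- pts[, 1]; Y <- pts[, 2]
  eyy <- (force_N / specimen$cross_section_area_mm2) / specimen$modulus_E_MPa
  exx <- specimen$transverse_coupling * eyy
  u <- exx * X
  v <- eyy * Y + permanent_mm * Y / specimen$ref_gauge_length_mm + rigid_y_mm
  w <- -bow_shape(specimen, X) * (force_N / max_force_N)
  if (!is.null(inhom) && specimen$inhomogeneity_amplitude > 0) {
    a <- specimen$inhomogeneity_amplitude * eyy *
      specimen$inhomogeneity_corr_length_mm
    env <- inhom_envelope(specimen, Y)$val
    u <- u + a * env * eval_inhom(inhom, "gu", X, Y)$val
    v <- v + a * env * eval_inhom(inhom, "gv", X, Y)$val
  }
  cbind(u_mm = u, v_mm = v, w_mm = w)
}

#' Analytic in-plane strain field of the loaded specimen
#'
#' Spatial derivative of [deformation_at()]: the engineering strain tensor of
#' the in-plane displacement components, exact for the field as defined
#' (the inhomogeneity term is differentiated through its interpolant).
#'
#' @inheritParams deformation_at
#' @return A matrix with columns `exx`, `eyy`, `exy` (dimensionless).
#' @export
strain_at <- function(specimen, force_N, points, inhom = NULL,
                      max_force_N = 628.3, permanent_mm = 0) {
  stopifnot(inherits(specimen, "specimen_model"))
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  X <- pts[, 1]; Y <- pts[, 2]
  eyy0 <- (force_N / specimen$cross_section_area_mm2) / specimen$modulus_E_MPa
  exx <- rep(specimen$transverse_coupling * eyy0, length(X))
  eyy <- rep(eyy0 + permanent_mm / specimen$ref_gauge_length_mm, length(X))
  exy <- rep(0, length(X))
  if (!is.null(inhom) && specimen$inhomogeneity_amplitude > 0) {
    a <- specimen$inhomogeneity_amplitude * eyy0 *
      specimen$inhomogeneity_corr_length_mm
    env <- inhom_envelope(specimen, Y)
    du <- eval_inhom(inhom, "gu", X, Y)
    dv <- eval_inhom(inhom, "gv", X, Y)
    exx <- exx + a * env$val * du$dX
    eyy <- eyy + a * (env$val * dv$dY + env$dY * dv$val)
    exy <- exy + 0.5 * a * (env$val * du$dY + env$dY * du$val +
                              env$val * dv$dX)
  }
  cbind(exx = exx, eyy = eyy, exy = exy)
}
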