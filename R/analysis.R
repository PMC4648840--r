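#' Virtual extensometers: grip-to-grip (DIC-1) and on-specimen (DIC-2)
#'
#' DIC-1 is the distance between the mean tracked positions of the two grip
#' regions (the speckled clamp plates, used as a virtual LVDT); DIC-2 is the
#' distance between the mean positions of two facet bands on the specimen
#' itself, adjacent to the grips. Their difference quantifies grip slip.
#'
#' Works on either a 2D tracked sequence (positions in mm via the image
#' scale) or a stereo reconstruction (3D facet positions); distances are
#' measured along the load axis.
#'
#' @param positions List, one element per frame, of data frames with columns
#'   `y_mm` (current longitudinal position) and `valid`, aligned with the
#'   facet grid. Use [extensometer_positions_2d()] or
#'   [extensometer_positions_3d()] to build it.
#' @param region_id Integer vector aligned with facets: 1/2 = lower/upper
#'   grip region, 3/4 = lower/upper specimen band, 0 = other.
#' @param force_table Data frame with `step`, `frame`, `force_N`, `phase`
#'   (one row per frame) and optionally `lvdt_mm`.
#' @return An `extensometer_series` data frame with per-frame `dic1_mm`,
#'   `dic2_mm`, `grip_lower_mm`, `grip_upper_mm`, `band_lower_mm`,
#'   `band_upper_mm`, `lvdt_mm` and a `flagged` column marking frames where
#'   some region had no valid facet.
#' @export
virtual_extensometers <- function(positions, region_id, force_table) {
  stopifnot(length(positions) == nrow(force_table))
  ref <- positions[[1]]
  # fixed reference position per region, plus the mean displacement of the
  # facets valid in both the reference and the current frame: immune to
  # mean-position jumps when the valid set changes between frames
  mean_pos <- function(df, sel) {
    base <- sel & ref$valid
    if (!any(base)) return(NA_real_)
    s <- base & df$valid
    if (!any(s)) return(NA_real_)
    mean(ref$y_mm[base]) + mean(df$y_mm[s] - ref$y_mm[s])
  }
  n <- length(positions)
  out <- force_table
  g1 <- region_id == 1; g2 <- region_id == 2
  b1 <- region_id == 3; b2 <- region_id == 4
  out$grip_lower_mm <- vapply(positions, mean_pos, 0, sel = g1)
  out$grip_upper_mm <- vapply(positions, mean_pos, 0, sel = g2)
  out$band_lower_mm <- vapply(positions, mean_pos, 0, sel = b1)
  out$band_upper_mm <- vapply(positions, mean_pos, 0, sel = b2)
  out$dic1_mm <- abs(out$grip_upper_mm - out$grip_lower_mm)
  out$dic2_mm <- abs(out$band_upper_mm - out$band_lower_mm)
  out$flagged <- !is.finite(out$dic1_mm) | !is.finite(out$dic2_mm)
  if (is.null(out$lvdt_mm)) out$lvdt_mm <- NA_real_
  class(out) <- c("extensometer_series", "data.frame")
  out
}

#' Per-frame longitudinal positions from a 2D tracked sequence
#'
#' @param tracked List of `displacement_field`s from [track_sequence()].
#' @param grid The facet grid.
#' @param scale_mm_per_px Image scale. The image y axis points opposite to
#'   the load axis, so positions are negated to increase with load height.
#' @return List of per-frame position data frames for
#'   [virtual_extensometers()].
#' @export
extensometer_positions_2d <- function(tracked, grid, scale_mm_per_px) {
  lapply(tracked, function(f)
    data.frame(y_mm = -(f$y_px + f$v_px) * scale_mm_per_px, valid = f$valid))
}

#' Per-frame longitudinal positions from a stereo reconstruction
#'
#' @param recon A [reconstruct_displacements()] result.
#' @return List of per-frame position data frames for
#'   [virtual_extensometers()].
#' @export
extensometer_positions_3d <- function(recon) {
  lapply(recon$frames, function(fr)
    data.frame(y_mm = fr$surface$Y_mm, valid = fr$surface$valid))
}

#' Quantify grip slip from an extensometer series
#'
#' Slip is the difference between the grip-to-grip (DIC-1) and on-specimen
#' (DIC-2) elongations; the slip fraction is total slip over total DIC-1
#' elongation at maximum load, and the strain-overestimation factor is the
#' grip-to-grip strain divided by the on-specimen strain there. A per-grip
#' breakdown (bone-block clamp = lower, tissue clamp = upper) is derived
#' from the relative motion of each grip region and its adjacent band.
#'
#' @param series An `extensometer_series`.
#' @return An object of class `slip_report`: list with `per_step` (data
#'   frame of loading-phase slip), `slip_mm`, `slip_fraction`,
#'   `strain_overestimation_factor`, `bone_block_slip_mm`,
#'   `tissue_slip_mm`.
#' @export
quantify_slip <- function(series) {
  s <- series[series$phase %in% c("loading", "hold") & !series$flagged, ]
  if (nrow(s) < 2) stop("need at least two loading-phase frames")
  ref <- s[1, ]
  el1 <- s$dic1_mm - ref$dic1_mm
  el2 <- s$dic2_mm - ref$dic2_mm
  imax <- which.max(s$force_N)
  tot1 <- el1[imax]; tot2 <- el2[imax]
  if (abs(tot1) < 1e-12)
    stop("total grip-to-grip elongation is zero; slip fraction undefined")
  strain1 <- tot1 / ref$dic1_mm
  strain2 <- tot2 / ref$dic2_mm
  # per-grip slip: relative motion of each grip plate and its adjacent band
  lower_slip <- (s$band_lower_mm - ref$band_lower_mm) -
    (s$grip_lower_mm - ref$grip_lower_mm)
  upper_slip <- (s$grip_upper_mm - ref$grip_upper_mm) -
    (s$band_upper_mm - ref$band_upper_mm)
  per_step <- data.frame(step = s$step, frame = s$frame, force_N = s$force_N,
                         slip_mm = el1 - el2,
                         bone_block_slip_mm = abs(lower_slip),
                         tissue_slip_mm = abs(upper_slip))
  structure(list(per_step = per_step,
                 slip_mm = tot1 - tot2,
                 slip_fraction = (tot1 - tot2) / tot1,
                 strain_overestimation_factor =
                   if (abs(strain2) > 1e-12) strain1 / strain2 else NA_real_,
                 bone_block_slip_mm = abs(lower_slip[imax]),
                 tissue_slip_mm = abs(upper_slip[imax])),
            class = "slip_report")
}

#' Accuracy assessment from repeated static frames
#'
#' With no change in load between repeated frames the true strain is zero,
#' so everything the strain pipeline reports is measurement scatter. The
#' overall scatter is the maximum-minus-minimum longitudinal strain over all
#' valid facets pooled across frame pairs; the central scatter is the
#' standard deviation over a small central disc, averaged over frame pairs.
#'
#' @param strain_fields List (one per repeated frame beyond the reference,
#'   at least 1 field from at least 2 frames) of `strain_field`s computed
#'   against the first repeated frame.
#' @param center_mm Centre of the specimen disc.
#' @param diameter_mm Disc diameter (4.0 mm by convention).
#' @return An object of class `scatter_report`: `overall_range_pct`,
#'   `central_mean_pct`, `central_sd_pct`, and a `per_frame` data frame.
#' @export
assess_scatter <- function(strain_fields, center_mm, diameter_mm = 4.0) {
  if (length(strain_fields) < 1)
    stop("need at least 2 repeated frames (1 strain field)")
  r2 <- (diameter_mm / 2)^2
  per <- lapply(strain_fields, function(sf) {
    e <- sf$eyy[sf$valid]
    d2 <- (sf$x_mm - center_mm[1])^2 + (sf$y_mm - center_mm[2])^2
    ec <- sf$eyy[sf$valid & d2 <= r2]
    data.frame(range_pct = 100 * (max(e) - min(e)),
               central_mean_pct = 100 * mean(ec),
               central_sd_pct = 100 * stats::sd(ec),
               n_central = length(ec))
  })
  per <- do.call(rbind, per)
  all_e <- unlist(lapply(strain_fields, function(sf) sf$eyy[sf$valid]))
  structure(list(overall_range_pct = 100 * (max(all_e) - min(all_e)),
                 central_mean_pct = mean(per$central_mean_pct),
                 central_sd_pct = mean(per$central_sd_pct),
                 per_frame = per),
            class = "scatter_report")
}

#' Linear agreement between two displacement series
#'
#' Ordinary least squares `y = a + b x` with the squared Pearson correlation
#' as R^2 (used to compare the DIC grip-to-grip extensometer against the
#' reference LVDT displacement).
#'
#' @param x,y Paired numeric series (at least 3 points).
#' @return List with `r2`, `slope`, `intercept`, `n`.
#' @export
linear_agreement <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired points")
  if (stats::sd(x) == 0) stop("zero variance in x; fit undefined")
  b <- stats::cov(x, y) / stats::var(x)
  a <- mean(y) - b * mean(x)
  r <- stats::cor(x, y)
  list(r2 = r^2, slope = b, intercept = a, n = length(x))
}

#' Stress-strain curve from forces and central-region strain
#'
#' @param force_N Per-step force.
#' @param strain Per-step longitudinal strain (dimensionless).
#' @param cross_section_area_mm2 Specimen cross-section used for stress.
#' @param phase Optional phase labels (default all `"loading"`).
#' @return A `stress_strain_curve` data frame with `stress_MPa`, `strain`,
#'   `phase`.
#' @export
stress_strain_curve <- function(force_N, strain, cross_section_area_mm2,
                                phase = rep("loading", length(force_N))) {
  stopifnot(length(force_N) == length(strain), cross_section_area_mm2 > 0)
  out <- data.frame(stress_MPa = force_N / cross_section_area_mm2,
                    strain = strain, phase = phase)
  class(out) <- c("stress_strain_curve", "data.frame")
  out
}

#' Fit the Young's modulus on the linear part of a stress-strain curve
#'
#' The linear region is selected automatically: among all contiguous
#' windows of loading-phase points with at least `min_points` points, the
#' window whose least-squares fit has the highest r-squared is chosen
#' (ties, within 1e-9, broken toward the longer window and then toward
#' higher stress). The modulus is the slope of stress versus strain over
#' that window.
#'
#' @param curve A [stress_strain_curve()].
#' @param min_points Minimum window length (>= 8).
#' @return An object of class `modulus_fit`: `E_MPa`, `region` (index
#'   range), `r2_fit`.
#' @export
fit_modulus <- function(curve, min_points = 8L) {
  ld <- which(curve$phase == "loading")
  x <- curve$strain[ld]; y <- curve$stress_MPa[ld]
  n <- length(x)
  if (n < min_points) stop("need at least ", min_points, " loading points")
  best <- NULL
  for (len in min_points:n) {
    for (s in 1:(n - len + 1)) {
      xi <- x[s:(s + len - 1)]; yi <- y[s:(s + len - 1)]
      if (stats::sd(xi) == 0) next
      r2 <- stats::cor(xi, yi)^2
      cand <- list(s = s, len = len, r2 = r2)
      if (is.null(best) || r2 > best$r2 + 1e-9 ||
          (abs(r2 - best$r2) <= 1e-9 &&
           (len > best$len || (len == best$len && s > best$s))))
        best <- cand
    }
  }
  if (is.null(best)) stop("no window with non-constant strain found")
  sel <- ld[best$s:(best$s + best$len - 1)]
  xi <- curve$strain[sel]; yi <- curve$stress_MPa[sel]
  E <- stats::cov(xi, yi) / stats::var(xi)
  structure(list(E_MPa = E, region = range(sel), r2_fit = best$r2,
                 n_points = best$len),
            class = "modulus_fit")
}

#' Cumulative strain distribution on a millimetre grid
#'
#' The analysed area is tiled with `grid_mm` x `grid_mm` squares; the strain
#' at each square centre is taken from the nearest valid facet within half a
#' square diagonal (squares with no such facet are excluded). The curve
#' `A(x)` is the fraction of sampled squares with strain at or below `x`,
#' evaluated on a fixed grid 0-10% in steps of 0.1%.
#'
#' @param strain_field A `strain_field`.
#' @param component `"eyy"`, `"exx"` or `"exy"`.
#' @param grid_mm Square edge length (1.0 mm by convention).
#' @param min_squares Minimum number of sampled squares.
#' @return An object of class `cumulative_strain_distribution`: `samples`
#'   (per-square strain, %), `curve` (data frame `strain_pct`,
#'   `area_fraction`), `n_squares`, `n_excluded`.
#' @export
cumulative_distribution <- function(strain_field, component = "eyy",
                                    grid_mm = 1.0, min_squares = 10L) {
  component <- match.arg(component, c("eyy", "exx", "exy"))
  sf <- strain_field[strain_field$valid, ]
  if (!nrow(sf)) stop("strain field has no valid facets")
  xs <- seq(min(sf$x_mm), max(sf$x_mm) + 1e-9, by = grid_mm)
  ys <- seq(min(sf$y_mm), max(sf$y_mm) + 1e-9, by = grid_mm)
  cx <- rep(xs, times = length(ys))
  cy <- rep(ys, each = length(xs))
  maxd2 <- (grid_mm * sqrt(2) / 2)^2
  # nearest valid facet per square centre
  val <- numeric(length(cx)); found <- logical(length(cx))
  for (i in seq_along(cx)) {
    d2 <- (sf$x_mm - cx[i])^2 + (sf$y_mm - cy[i])^2
    j <- which.min(d2)
    if (d2[j] <= maxd2) { val[i] <- sf[[component]][j]; found[i] <- TRUE }
  }
  if (sum(found) < min_squares)
    stop("fewer than ", min_squares, " grid squares with a valid strain")
  samples_pct <- 100 * val[found]
  grid_pct <- seq(0, 10, by = 0.1)
  A <- vapply(grid_pct, function(x) mean(samples_pct <= x), 0)
  structure(list(samples = samples_pct,
                 curve = data.frame(strain_pct = grid_pct, area_fraction = A),
                 n_squares = sum(found), n_excluded = sum(!found),
                 grid_mm = grid_mm, component = component),
            class = "cumulative_strain_distribution")
}

#' Evaluate the cumulative distribution at a strain level
#'
#' @param dist A [cumulative_distribution()] result.
#' @param strain_pct Strain level in %.
#' @return Fraction of the sampled area with strain at or below
#'   `strain_pct`.
#' @export
area_fraction_at <- function(dist, strain_pct) {
  mean(dist$samples <= strain_pct)
}

#' Area fraction exceeding a strain threshold
#'
#' `1 - A(threshold)`: the fraction of the sampled surface whose strain is
#' strictly above the threshold (e.g. the 5% assumed damage threshold).
#'
#' @param dist A [cumulative_distribution()] result.
#' @param threshold_pct Threshold in % strain.
#' @return Fraction in `[0, 1]`.
#' @export
area_fraction_exceeding <- function(dist, threshold_pct) {
  1 - area_fraction_at(dist, threshold_pct)
}

#' Loading/unloading hysteresis at matched forces
#'
#' For each unloading step the nearest loading-phase force is found; the
#' difference of the DIC-2 (and DIC-1) elongations at the matched forces is
#' the hysteresis (for DIC-1 it also contains the unrecovered grip slip).
#'
#' @param series An `extensometer_series`.
#' @return Data frame with `force_N`, `dic2_diff_mm`, `dic1_diff_mm`.
#' @export
hysteresis <- function(series) {
  ld <- series[series$phase == "loading" & !series$flagged, ]
  ul <- series[series$phase == "unloading" & !series$flagged, ]
  if (!nrow(ld) || !nrow(ul)) stop("need both loading and unloading phases")
  if (min(ul$force_N) > max(ld$force_N) || max(ul$force_N) < min(ld$force_N))
    stop("loading and unloading force ranges do not overlap")
  ref1 <- ld$dic1_mm[1]; ref2 <- ld$dic2_mm[1]
  # one matched pair per distinct unloading force
  uf <- unique(ul$force_N)
  rows <- lapply(uf, function(f) {
    iu <- which(ul$force_N == f)
    il <- which.min(abs(ld$force_N - f))
    data.frame(force_N = f,
               dic2_diff_mm = mean(ul$dic2_mm[iu]) - ld$dic2_mm[il],
               dic1_diff_mm = mean(ul$dic1_mm[iu]) - ld$dic1_mm[il])
  })
  do.call(rbind, rows)
}
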