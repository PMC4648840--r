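#' DIC configuration
#'
#' Tracking parameters for facet-based correlation.
#'
#' @param facet_size_px Odd facet (subset) edge length in pixels, at least 5.
#'   The default (21 px) sits just above the classical 5-20 px range, which
#'   favours stability at the default speckle scale.
#' @param step_px Facet grid spacing.
#' @param search_radius_px Half-width of the integer ZNCC search window.
#' @param zncc_threshold Quality threshold; facets below it are invalid.
#' @param tol Convergence tolerance on the displacement update norm (px).
#' @param max_iter Maximum Gauss-Newton iterations.
#' @return An object of class `dic_config`.
#' @export
dic_config <- function(facet_size_px = 21L, step_px = 5L,
                       search_radius_px = 10L, zncc_threshold = 0.8,
                       tol = 1e-4, max_iter = 50L) {
  facet_size_px <- as.integer(facet_size_px)
  if (facet_size_px < 5 || facet_size_px %% 2 == 0)
    stop("facet_size_px must be an odd integer >= 5")
  stopifnot(step_px >= 1, search_radius_px >= 1, max_iter >= 1, tol > 0)
  structure(list(facet_size_px = facet_size_px,
                 step_px = as.integer(step_px),
                 search_radius_px = as.integer(search_radius_px),
                 zncc_threshold = zncc_threshold, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "dic_config")
}

#' Build a regular facet grid inside a region of interest
#'
#' Facet centres are laid out on a regular lattice anchored at the ROI
#' bounding-box corner (offset by the facet half-width); only centres whose
#' whole facet window lies inside the ROI are kept.
#'
#' @param roi_mask Logical matrix (height x width), `TRUE` inside the ROI.
#' @param facet_size_px Odd facet edge length, at least 5.
#' @param step_px Lattice spacing, at least 1.
#' @return An object of class `facet_grid`: data frame `centers` with
#'   columns `facet_id`, `x_px`, `y_px`, `ix`, `iy` (lattice indices), plus
#'   the grid geometry.
#' @export
build_facet_grid <- function(roi_mask, facet_size_px = 21L, step_px = 5L) {
  facet_size_px <- as.integer(facet_size_px)
  step_px <- as.integer(step_px)
  if (facet_size_px < 5 || facet_size_px %% 2 == 0)
    stop("facet_size_px must be an odd integer >= 5")
  if (step_px < 1) stop("step_px must be >= 1")
  stopifnot(is.matrix(roi_mask))
  mode(roi_mask) <- "logical"
  half <- (facet_size_px - 1) %/% 2
  rows <- which(apply(roi_mask, 1, any))
  cols <- which(apply(roi_mask, 2, any))
  if (!length(rows) || !length(cols))
    stop("ROI is empty")
  if (length(rows) < facet_size_px || length(cols) < facet_size_px)
    stop("ROI is too small to hold a single facet")
  xs <- seq(min(cols) + half, max(cols) - half, by = step_px)
  ys <- seq(min(rows) + half, max(rows) - half, by = step_px)
  if (!length(xs) || !length(ys))
    stop("ROI is too small to hold a single facet")
  # summed-area table (zero border) for a fast all-inside test
  m <- matrix(as.numeric(roi_mask), nrow(roi_mask))
  sat <- matrix(0, nrow(m) + 1, ncol(m) + 1)
  sat[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  win_sum <- function(cx, cy) {
    x0 <- cx - half; x1 <- cx + half; y0 <- cy - half; y1 <- cy + half
    sat[y1 + 1, x1 + 1] - sat[y0, x1 + 1] - sat[y1 + 1, x0] + sat[y0, x0]
  }
  grid <- expand.grid(ix = seq_along(xs), iy = seq_along(ys))
  cx <- xs[grid$ix]; cy <- ys[grid$iy]
  full <- facet_size_px^2
  keep <- vapply(seq_along(cx), function(k) win_sum(cx[k], cy[k]) == full,
                 logical(1))
  if (!any(keep)) stop("ROI is too small to hold a single facet")
  centers <- data.frame(facet_id = seq_len(sum(keep)),
                        x_px = cx[keep], y_px = cy[keep],
                        ix = grid$ix[keep], iy = grid$iy[keep])
  structure(list(centers = centers, facet_size_px = facet_size_px,
                 step_px = step_px, half_px = half,
                 nx = length(xs), ny = length(ys),
                 image_dim = dim(roi_mask)),
            class = "facet_grid")
}

#' Zero-mean normalized cross-correlation of two patches
#'
#' Invariant to affine intensity transforms of either patch; lies in
#' `[-1, 1]`. A patch with zero intensity variance makes the coefficient
#' undefined, signalled by `NA`.
#'
#' @param patch_a,patch_b Numeric matrices or vectors of equal size.
#' @return A single number in `[-1, 1]`, or `NA` if undefined.
#' @export
zncc <- function(patch_a, patch_b) {
  a <- as.numeric(patch_a); b <- as.numeric(patch_b)
  if (length(a) != length(b)) stop("patches must have equal size")
  zncc_cpp(a, b)
}

#' Integer-pixel ZNCC search for one facet
#'
#' Exhaustive zero-mean normalized cross-correlation over all integer
#' offsets within the search radius; ties are broken toward the smaller
#' offset magnitude, then row-major order.
#'
#' @param ref_img,def_img Reference and deformed images.
#' @param center_px Facet centre `c(x, y)` in the reference image.
#' @param facet_size_px Odd facet edge length.
#' @param search_radius_px Search radius r; the `(2r+1)^2` offsets are tried.
#' @return List with `du`, `dv`, `zncc`, `ok`. `ok = FALSE` signals that no
#'   candidate window had intensity variance (no match possible).
#' @export
integer_search <- function(ref_img, def_img, center_px, facet_size_px = 21L,
                           search_radius_px = 10L) {
  half <- (as.integer(facet_size_px) - 1) %/% 2
  r <- integer_search_cpp(ref_img, def_img, as.integer(center_px[1]),
                          as.integer(center_px[2]), half,
                          as.integer(search_radius_px))
  list(du = as.integer(r[["du"]]), dv = as.integer(r[["dv"]]),
       zncc = r[["zncc"]], ok = r[["ok"]] == 1)
}

#' Subpixel facet refinement
#'
#' Inverse-compositional Gauss-Newton optimization of the ZNSSD criterion
#' with a first-order (affine) facet shape function and bicubic image
#' interpolation. Convergence is declared when the norm of the displacement
#' update drops below `tol`; the equivalent ZNCC of the final match is
#' reported.
#'
#' @inheritParams integer_search
#' @param init Initial integer offset `c(du, dv)`.
#' @param tol,max_iter Convergence controls.
#' @return List with subpixel `u`, `v`, affine gradient terms, `zncc`,
#'   `converged` and `iterations`.
#' @export
subpixel_refine <- function(ref_img, def_img, center_px, init = c(0, 0),
                            facet_size_px = 21L, tol = 1e-4, max_iter = 50L) {
  half <- (as.integer(facet_size_px) - 1) %/% 2
  p0 <- c(init[1], 0, 0, init[2], 0, 0)
  r <- icgn_refine_cpp(ref_img, def_img, as.integer(center_px[1]),
                       as.integer(center_px[2]), half, p0, tol,
                       as.integer(max_iter))
  list(u = r[["u"]], v = r[["v"]], ux = r[["ux"]], uy = r[["uy"]],
       vx = r[["vx"]], vy = r[["vy"]], zncc = r[["zncc"]],
       converged = r[["converged"]] == 1,
       iterations = as.integer(r[["iterations"]]))
}

#' Track a facet grid through an image sequence
#'
#' Every frame is correlated against the fixed reference image (no
#' incremental drift); facet i in frame k is initialized from its converged
#' result in frame k-1, with an integer ZNCC search used for the first frame
#' and after any failure. Facets are valid when converged with a ZNCC at or
#' above the quality threshold.
#'
#' @param ref_img Reference image (matrix).
#' @param frames List of images (matrices) or character vector of image file
#'   paths, all the same size as `ref_img`.
#' @param grid A [build_facet_grid()] result.
#' @param config A [dic_config()].
#' @return List of per-frame displacement fields (class
#'   `displacement_field`): data frames with columns `facet_id`, `x_px`,
#'   `y_px`, `u_px`, `v_px`, `zncc`, `converged`, `valid`.
#' @export
track_sequence <- function(ref_img, frames, grid, config = dic_config()) {
  stopifnot(inherits(grid, "facet_grid"), inherits(config, "dic_config"))
  half <- (config$facet_size_px - 1) %/% 2
  cx <- as.integer(grid$centers$x_px)
  cy <- as.integer(grid$centers$y_px)
  n <- length(cx)
  init <- matrix(NA_real_, n, 2)
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    def <- frames[[k]]
    if (is.function(def)) def <- def()  # lazily rendered / loaded frame
    if (is.character(def)) def <- read_image(def)
    if (!all(dim(def) == dim(ref_img)))
      stop("frame ", k, " does not match the reference image dimensions")
    m <- track_frame_cpp(ref_img, def, cx, cy, half, config$search_radius_px,
                         init, config$tol, config$max_iter)
    valid <- m[, "converged"] == 1 & !is.na(m[, "zncc"]) &
      m[, "zncc"] >= config$zncc_threshold
    fld <- data.frame(facet_id = grid$centers$facet_id, x_px = cx, y_px = cy,
                      u_px = m[, "u"], v_px = m[, "v"], zncc = m[, "zncc"],
                      converged = m[, "converged"] == 1, valid = valid)
    class(fld) <- c("displacement_field", "data.frame")
    out[[k]] <- fld
    init <- cbind(ifelse(valid, m[, "u"], NA_real_),
                  ifelse(valid, m[, "v"], NA_real_))
  }
  out
}
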