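#' Strain computation configuration
#'
#' @param window_facets Odd edge length (in facets) of the least-squares
#'   neighbourhood used for the displacement gradient; at least 3.
#' @param measure `"engineering"` (default) or `"green_lagrange"`.
#' @param min_valid_neighbors Minimum number of valid facets in the window
#'   for the gradient to be defined; at least 6.
#' @param gaussian_weight Use Gaussian distance weighting over the window
#'   (sigma = half the window) instead of uniform weights.
#' @return An object of class `strain_config`.
#' @export
strain_config <- function(window_facets = 5L, measure = "engineering",
                          min_valid_neighbors = 6L, gaussian_weight = TRUE) {
  window_facets <- as.integer(window_facets)
  if (window_facets < 3 || window_facets %% 2 == 0)
    stop("window_facets must be an odd integer >= 3")
  if (min_valid_neighbors < 6) stop("min_valid_neighbors must be >= 6")
  measure <- match.arg(measure, c("engineering", "green_lagrange"))
  structure(list(window_facets = window_facets, measure = measure,
                 min_valid_neighbors = as.integer(min_valid_neighbors),
                 gaussian_weight = isTRUE(gaussian_weight)),
            class = "strain_config")
}

#' Convert a tracked displacement field to physical units
#'
#' @param field A `displacement_field` from [track_sequence()].
#' @param grid The [build_facet_grid()] the field was tracked on.
#' @param scale_mm_per_px Object-space pixel size.
#' @return A `displacement_field_mm` data frame with facet coordinates and
#'   displacements in mm, carrying the grid lattice as an attribute.
#' @export
displacement_to_mm <- function(field, grid, scale_mm_per_px) {
  out <- data.frame(facet_id = field$facet_id,
                    x_mm = field$x_px * scale_mm_per_px,
                    y_mm = field$y_px * scale_mm_per_px,
                    u_mm = field$u_px * scale_mm_per_px,
                    v_mm = field$v_px * scale_mm_per_px,
                    valid = field$valid)
  attr(out, "lattice") <- grid_lattice(grid)
  class(out) <- c("displacement_field_mm", "data.frame")
  out
}

grid_lattice <- function(grid) {
  list(ix = grid$centers$ix, iy = grid$centers$iy, nx = grid$nx, ny = grid$ny)
}

# neighbour row-index matrix: n_facets x window^2 (NA where no facet)
neighbor_index <- function(lattice, window) {
  hw <- (window - 1) %/% 2
  idx <- matrix(NA_integer_, lattice$ny, lattice$nx)
  idx[cbind(lattice$iy, lattice$ix)] <- seq_along(lattice$ix)
  offs <- expand.grid(di = -hw:hw, dj = -hw:hw)
  n <- length(lattice$ix)
  nb <- matrix(NA_integer_, n, nrow(offs))
  for (j in seq_len(nrow(offs))) {
    ix2 <- lattice$ix + offs$di[j]
    iy2 <- lattice$iy + offs$dj[j]
    ok <- ix2 >= 1 & ix2 <= lattice$nx & iy2 >= 1 & iy2 <= lattice$ny
    nb[ok, j] <- idx[cbind(iy2[ok], ix2[ok])]
  }
  list(nb = nb, offs = offs, hw = hw)
}

offset_weights <- function(offs, hw, gaussian) {
  if (!gaussian) return(rep(1, nrow(offs)))
  s2 <- max(hw, 1)^2
  exp(-(offs$di^2 + offs$dj^2) / (2 * s2))
}

#' Local displacement-gradient tensor
#'
#' At each facet, a linear function is fitted to each displacement component
#' over the surrounding window by weighted least squares; the gradient is
#' the fitted slope pair. Exact for affine displacement fields. Facets whose
#' window holds fewer than `min_valid_neighbors` valid facets are invalid
#' (not an error).
#'
#' @param field A `displacement_field_mm` (see [displacement_to_mm()]) or a
#'   `tangent_field` from [tangent_project()].
#' @param config A [strain_config()].
#' @return A `gradient_field` data frame with columns `dudx`, `dudy`,
#'   `dvdx`, `dvdy` and `valid`.
#' @export
local_gradient <- function(field, config = strain_config()) {
  UseMethod("local_gradient")
}

#' @export
local_gradient.displacement_field_mm <- function(field,
                                                 config = strain_config()) {
  lat <- attr(field, "lattice")
  if (is.null(lat)) stop("field carries no lattice attribute")
  nb <- neighbor_index(lat, config$window_facets)
  w <- offset_weights(nb$offs, nb$hw, config$gaussian_weight)
  n <- nrow(field)
  # relative coordinates of each neighbour
  dx <- matrix(NA_real_, n, ncol(nb$nb))
  dy <- matrix(NA_real_, n, ncol(nb$nb))
  for (j in seq_len(ncol(nb$nb))) {
    id <- nb$nb[, j]
    ok <- !is.na(id)
    dx[ok, j] <- field$x_mm[id[ok]] - field$x_mm[ok]
    dy[ok, j] <- field$y_mm[id[ok]] - field$y_mm[ok]
  }
  vals <- list(u = umat_by_id(field$u_mm, nb$nb),
               v = umat_by_id(field$v_mm, nb$nb))
  res <- wls_gradient_mats(nb, w, dx, dy, vals, field$valid,
                           config$min_valid_neighbors)
  out <- data.frame(facet_id = field$facet_id, x_mm = field$x_mm,
                    y_mm = field$y_mm,
                    dudx = res$grad[[1]]$dx, dudy = res$grad[[1]]$dy,
                    dvdx = res$grad[[2]]$dx, dvdy = res$grad[[2]]$dy,
                    valid = res$valid)
  class(out) <- c("gradient_field", "data.frame")
  out
}

# value matrix aligned with the neighbour index matrix
umat_by_id <- function(x, nbmat) {
  m <- matrix(NA_real_, nrow(nbmat), ncol(nbmat))
  ok <- !is.na(nbmat)
  m[ok] <- x[nbmat[ok]]
  m
}

#' Strain tensor from a displacement gradient
#'
#' Engineering measure: `exx = du/dx`, `eyy = dv/dy`,
#' `exy = (du/dy + dv/dx) / 2`. Green-Lagrange measure:
#' `E = (F'F - I) / 2` with `F = I + grad(u)`; rigid rotations then produce
#' exactly zero strain.
#'
#' @param gradient A `gradient_field` from [local_gradient()].
#' @param measure `"engineering"` or `"green_lagrange"`.
#' @return A `strain_field` data frame with `exx`, `eyy`, `exy`
#'   (dimensionless) and `valid`.
#' @export
strain_from_gradient <- function(gradient, measure = "engineering") {
  measure <- match.arg(measure, c("engineering", "green_lagrange"))
  g <- gradient
  if (measure == "engineering") {
    exx <- g$dudx
    eyy <- g$dvdy
    exy <- 0.5 * (g$dudy + g$dvdx)
  } else {
    exx <- g$dudx + 0.5 * (g$dudx^2 + g$dvdx^2)
    eyy <- g$dvdy + 0.5 * (g$dudy^2 + g$dvdy^2)
    exy <- 0.5 * (g$dudy + g$dvdx + g$dudx * g$dudy + g$dvdx * g$dvdy)
  }
  out <- data.frame(facet_id = g$facet_id, x_mm = g$x_mm, y_mm = g$y_mm,
                    exx = exx, eyy = eyy, exy = exy, valid = g$valid)
  out$valid <- out$valid & is.finite(exx) & is.finite(eyy) & is.finite(exy)
  class(out) <- c("strain_field", "data.frame")
  out
}

#' Project 3D surface displacements into local tangent planes
#'
#' Per facet, a plane is fitted to the reconstructed reference surface over
#' the strain window; an orthonormal in-plane basis is built with its first
#' axis along the projection of the global load axis (Y) and the second
#' completing a right-handed frame (approximately the transverse X
#' direction). Neighbour positions and 3D displacements are expressed in
#' that basis, giving an in-plane displacement field ready for
#' [local_gradient()]. Facets with a degenerate plane fit are invalid.
#'
#' @param surface_ref A `surface3d` (reference state).
#' @param displacement A `displacement_field3d`.
#' @param grid The facet grid the surfaces were computed on.
#' @param config A [strain_config()].
#' @return An object of class `tangent_field`.
#' @export
tangent_project <- function(surface_ref, displacement, grid,
                            config = strain_config()) {
  lat <- grid_lattice(grid)
  nb <- neighbor_index(lat, config$window_facets)
  w <- offset_weights(nb$offs, nb$hw, config$gaussian_weight)
  n <- nrow(surface_ref)
  valid_in <- surface_ref$valid & displacement$valid
  P <- cbind(surface_ref$X_mm, surface_ref$Y_mm, surface_ref$Z_mm)
  D <- cbind(displacement$dX_mm, displacement$dY_mm, displacement$dZ_mm)

  # --- weighted plane fit Z ~ a + b X + c Y over the window
  Sw <- Sx <- Sy <- Sxx <- Sxy <- Syy <- Sz <- Szx <- Szy <- numeric(n)
  nr <- numeric(n)
  for (j in seq_len(ncol(nb$nb))) {
    id <- nb$nb[, j]
    ok <- which(!is.na(id))
    ok <- ok[valid_in[id[ok]]]
    if (!length(ok)) next
    idd <- id[ok]
    wj <- w[j]
    dxi <- P[idd, 1] - P[ok, 1]
    dyi <- P[idd, 2] - P[ok, 2]
    dzi <- P[idd, 3] - P[ok, 3]
    Sw[ok] <- Sw[ok] + wj; nr[ok] <- nr[ok] + 1
    Sx[ok] <- Sx[ok] + wj * dxi; Sy[ok] <- Sy[ok] + wj * dyi
    Sxx[ok] <- Sxx[ok] + wj * dxi^2; Sxy[ok] <- Sxy[ok] + wj * dxi * dyi
    Syy[ok] <- Syy[ok] + wj * dyi^2
    Sz[ok] <- Sz[ok] + wj * dzi; Szx[ok] <- Szx[ok] + wj * dzi * dxi
    Szy[ok] <- Szy[ok] + wj * dzi * dyi
  }
  det <- Sw * (Sxx * Syy - Sxy^2) - Sx * (Sx * Syy - Sxy * Sy) +
    Sy * (Sx * Sxy - Sxx * Sy)
  okp <- nr >= config$min_valid_neighbors & abs(det) > 1e-300
  inv12 <- -(Sx * Syy - Sxy * Sy)
  inv13 <- Sx * Sxy - Sxx * Sy
  inv22 <- Sw * Syy - Sy^2
  inv23 <- -(Sw * Sxy - Sx * Sy)
  inv33 <- Sw * Sxx - Sx^2
  b <- (inv12 * Sz + inv22 * Szx + inv23 * Szy) / det
  c_ <- (inv13 * Sz + inv23 * Szx + inv33 * Szy) / det
  # unit normal of the fitted plane (pointing toward +Z / the cameras)
  nv <- cbind(-b, -c_, 1)
  nn <- sqrt(rowSums(nv^2))
  nv <- nv / nn
  # in-plane basis: e_long = projected load axis, e_trans = n x e_long
  yhat <- matrix(rep(c(0, 1, 0), each = n), n, 3)
  e1 <- yhat - nv * nv[, 2]
  e1n <- sqrt(rowSums(e1^2))
  okp <- okp & e1n > 1e-6
  e1 <- e1 / e1n
  e2 <- cbind(nv[, 2] * e1[, 3] - nv[, 3] * e1[, 2],
              nv[, 3] * e1[, 1] - nv[, 1] * e1[, 3],
              nv[, 1] * e1[, 2] - nv[, 2] * e1[, 1])

  structure(list(P = P, D = D, e_long = e1, e_trans = e2, normal = nv,
                 valid = valid_in, center_ok = okp, nb = nb, w = w,
                 facet_id = surface_ref$facet_id,
                 min_valid_neighbors = config$min_valid_neighbors),
            class = "tangent_field")
}

#' @export
local_gradient.tangent_field <- function(field, config = strain_config()) {
  nb <- field$nb
  n <- nrow(field$P)
  ncol_nb <- ncol(nb$nb)
  dx <- dy <- umat <- vmat <- matrix(NA_real_, n, ncol_nb)
  for (j in seq_len(ncol_nb)) {
    id <- nb$nb[, j]
    ok <- which(!is.na(id))
    if (!length(ok)) next
    idd <- id[ok]
    rel <- field$P[idd, , drop = FALSE] - field$P[ok, , drop = FALSE]
    dx[ok, j] <- rowSums(rel * field$e_trans[ok, , drop = FALSE])
    dy[ok, j] <- rowSums(rel * field$e_long[ok, , drop = FALSE])
    umat[ok, j] <- rowSums(field$D[idd, , drop = FALSE] *
                             field$e_trans[ok, , drop = FALSE])
    vmat[ok, j] <- rowSums(field$D[idd, , drop = FALSE] *
                             field$e_long[ok, , drop = FALSE])
  }
  # reuse the WLS solver with value matrices already aligned to neighbours
  res <- wls_gradient_mats(nb, field$w, dx, dy, list(umat, vmat),
                           field$valid, field$min_valid_neighbors)
  out <- data.frame(facet_id = field$facet_id,
                    x_mm = field$P[, 1], y_mm = field$P[, 2],
                    dudx = res$grad[[1]]$dx, dudy = res$grad[[1]]$dy,
                    dvdx = res$grad[[2]]$dx, dvdy = res$grad[[2]]$dy,
                    valid = res$valid & field$center_ok)
  class(out) <- c("gradient_field", "data.frame")
  out
}

# WLS gradient where the value matrices are pre-gathered (n x window^2)
wls_gradient_mats <- function(nb, w, dx, dy, vals, valid, min_nb) {
  n <- nrow(nb$nb)
  Sw <- Sx <- Sy <- Sxx <- Sxy <- Syy <- numeric(n)
  nr <- numeric(n)
  nc <- length(vals)
  Sv <- Svx <- Svy <- replicate(nc, numeric(n), simplify = FALSE)
  for (j in seq_len(ncol(nb$nb))) {
    id <- nb$nb[, j]
    ok <- which(!is.na(id))
    ok <- ok[valid[id[ok]] & is.finite(dx[ok, j])]
    if (!length(ok)) next
    wj <- w[j]
    dxi <- dx[ok, j]; dyi <- dy[ok, j]
    Sw[ok] <- Sw[ok] + wj; nr[ok] <- nr[ok] + 1
    Sx[ok] <- Sx[ok] + wj * dxi; Sy[ok] <- Sy[ok] + wj * dyi
    Sxx[ok] <- Sxx[ok] + wj * dxi^2; Sxy[ok] <- Sxy[ok] + wj * dxi * dyi
    Syy[ok] <- Syy[ok] + wj * dyi^2
    for (c in seq_len(nc)) {
      vv <- vals[[c]][ok, j]
      Sv[[c]][ok] <- Sv[[c]][ok] + wj * vv
      Svx[[c]][ok] <- Svx[[c]][ok] + wj * vv * dxi
      Svy[[c]][ok] <- Svy[[c]][ok] + wj * vv * dyi
    }
  }
  det <- Sw * (Sxx * Syy - Sxy^2) - Sx * (Sx * Syy - Sxy * Sy) +
    Sy * (Sx * Sxy - Sxx * Sy)
  ok <- nr >= min_nb & abs(det) > 1e-300
  inv12 <- -(Sx * Syy - Sxy * Sy)
  inv13 <- Sx * Sxy - Sxx * Sy
  inv22 <- Sw * Syy - Sy^2
  inv23 <- -(Sw * Sxy - Sx * Sy)
  inv33 <- Sw * Sxx - Sx^2
  out <- vector("list", nc)
  for (c in seq_len(nc)) {
    bx <- (inv12 * Sv[[c]] + inv22 * Svx[[c]] + inv23 * Svy[[c]]) / det
    by <- (inv13 * Sv[[c]] + inv23 * Svx[[c]] + inv33 * Svy[[c]]) / det
    bx[!ok] <- NA_real_; by[!ok] <- NA_real_
    out[[c]] <- list(dx = bx, dy = by)
  }
  list(grad = out, valid = ok)
}

#' Full-field surface strain from a stereo reconstruction
#'
#' Convenience wrapper: [tangent_project()] followed by [local_gradient()]
#' and [strain_from_gradient()].
#'
#' @inheritParams tangent_project
#' @return A `strain_field` data frame.
#' @export
surface_strain <- function(surface_ref, displacement, grid,
                           config = strain_config()) {
  tf <- tangent_project(surface_ref, displacement, grid, config)
  g <- local_gradient(tf, config)
  strain_from_gradient(g, config$measure)
}

#' Average strain over a circular region
#'
#' Unweighted mean of each tensor component over the valid facets inside a
#' disc, as used for the central-area strain history.
#'
#' @param strain_field A `strain_field`.
#' @param center_mm Disc centre `c(x, y)` in mm.
#' @param diameter_mm Disc diameter in mm.
#' @return List with `exx`, `eyy`, `exy` and the facet count `n`.
#' @export
average_over_region <- function(strain_field, center_mm, diameter_mm = 4.0) {
  r2 <- (diameter_mm / 2)^2
  d2 <- (strain_field$x_mm - center_mm[1])^2 +
    (strain_field$y_mm - center_mm[2])^2
  sel <- strain_field$valid & d2 <= r2
  if (!any(sel)) stop("no valid facet inside the region")
  list(exx = mean(strain_field$exx[sel]), eyy = mean(strain_field$eyy[sel]),
       exy = mean(strain_field$exy[sel]), n = sum(sel))
}
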