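#' Speckle pattern parameters
#'
#' Parameters of the synthetic airbrush speckle texture: white dots on a dark
#' (methylene-blue-like) background. Intensities are fractions of the sensor
#' dynamic range.
#'
#' @param image_width_px,image_height_px Image dimensions in pixels.
#' @param speckle_density Expected number of dots per square pixel.
#' @param dot_radius_mean_px,dot_radius_sd_px Mean and standard deviation of
#'   the dot radius in pixels (radii are truncated below at 0.3 px).
#' @param background_level,dot_level Background and dot intensity, both in
#'   `[0, 1]`; `dot_level` must exceed `background_level` (white-on-dark).
#' @param blur_sigma_px Standard deviation of the Gaussian optical blur.
#' @param noise_sd Standard deviation of the additive Gaussian sensor noise,
#'   as a fraction of the dynamic range. Applied at render time, not here.
#' @return An object of class `speckle_params`.
#' @export
speckle_params <- function(image_width_px = 1243L, image_height_px = 993L,
                           speckle_density = 0.03, dot_radius_mean_px = 2,
                           dot_radius_sd_px = 0.5, background_level = 0.15,
                           dot_level = 0.9, blur_sigma_px = 1.0,
                           noise_sd = 0.01) {
  stopifnot(image_width_px >= 8, image_height_px >= 8, speckle_density > 0 ||
              speckle_density == 0)
  if (speckle_density < 0) stop("speckle_density must be >= 0")
  if (background_level < 0 || background_level > 1 ||
      dot_level < 0 || dot_level > 1)
    stop("intensity levels must lie in [0, 1]")
  if (dot_level <= background_level)
    stop("dot_level must exceed background_level (white-on-dark contrast)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(image_width_px = as.integer(image_width_px),
                 image_height_px = as.integer(image_height_px),
                 speckle_density = speckle_density,
                 dot_radius_mean_px = dot_radius_mean_px,
                 dot_radius_sd_px = dot_radius_sd_px,
                 background_level = background_level,
                 dot_level = dot_level,
                 blur_sigma_px = blur_sigma_px,
                 noise_sd = noise_sd),
            class = "speckle_params")
}

#' Generate a synthetic speckle texture
#'
#' Rasterizes a Poisson number of hard-edged circular dots at uniform random
#' positions, then applies Gaussian optical blur. Before blur the intensity
#' histogram is bimodal at `background_level` and `dot_level`. Reproducible
#' for a fixed seed. Sensor noise is *not* added here (it belongs to each
#' rendered frame, not to the physical paint pattern).
#'
#' @param params A [speckle_params()] object.
#' @param seed Integer seed.
#' @return A `height x width` intensity matrix in `[0, 1]`.
#' @export
generate_speckle <- function(params, seed) {
  stopifnot(inherits(params, "speckle_params"))
  W <- params$image_width_px
  H <- params$image_height_px
  # expected covered-area fraction; an overdense pattern cannot be correlated
  exp_cover <- params$speckle_density * pi *
    (params$dot_radius_mean_px^2 + params$dot_radius_sd_px^2)
  if (exp_cover > 0.9)
    stop("speckle_density too high: expected dot coverage exceeds 90% of the area")
  withr_seed(seed, {
    n <- stats::rpois(1, params$speckle_density * W * H)
    if (n == 0) {
      img <- matrix(params$background_level, H, W)
    } else {
      x <- stats::runif(n, 0.5, W + 0.5)
      y <- stats::runif(n, 0.5, H + 0.5)
      r <- pmax(0.3, stats::rnorm(n, params$dot_radius_mean_px,
                                  params$dot_radius_sd_px))
      img <- draw_dots_cpp(W, H, x, y, r, params$background_level,
                           params$dot_level)
    }
    gaussian_blur_cpp(img, params$blur_sigma_px)
  })
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps the generators deterministic
# without clobbering user code.
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
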