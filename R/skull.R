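#' Hounsfield-unit volume
#'
#' A CT-style volume in Hounsfield units (water ~ 0 HU by convention) on a
#' [voxel_grid()], the input to [map_hu_to_properties()].
#'
#' @param grid a [voxel_grid()].
#' @param hu 3D array (or scalar) of Hounsfield units, finite.
#' @return an object of class `hu_volume`.
#' @export
hu_volume <- function(grid, hu) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (length(hu) == 1L) hu <- array(hu, grid$dims)
  if (!identical(dim(hu), as.integer(grid$dims)))
    stop("`hu` does not match the grid dimensions", call. = FALSE)
  if (any(!is.finite(hu))) stop("HU values must be finite", call. = FALSE)
  structure(list(grid = grid, hu = hu), class = "hu_volume")
}

#' @export
print.hu_volume <- function(x, ...) {
  cat("<hu_volume>\n"); print(x$grid)
  cat(sprintf("  HU range %.4g - %.4g\n", min(x$hu), max(x$hu)))
  invisible(x)
}

#' Configuration of the HU-to-acoustic-property mapping
#'
#' Density follows an affine map of HU; sound speed and attenuation follow
#' monotone piecewise-linear curves over the bone HU range, linearly
#' interpolated between knots and clamped at the end knots.  Voxels below
#' `hu_threshold` receive the homogeneous background (water/soft-tissue)
#' properties.  The default knots are the package's own documented
#' stand-in for externally published optimized curves (the curve family is
#' configuration, not a fixed constant): water at 0 HU maps to
#' 1000 kg/m^3 / 1500 m/s / 0 dB/(cm MHz), and the top cortical-bone knot
#' reaches 2740 m/s.  All knots are user-configurable.
#'
#' @param density_intercept,density_slope affine density map
#'   `rho = intercept + slope * HU` (kg/m^3); slope must be > 0.
#' @param speed_knots,attenuation_knots data frames (or 2-column matrices)
#'   of `hu` and `value` knots, sorted and monotone non-decreasing.
#' @param background list of background `speed`, `attenuation`, `density`.
#' @param hu_threshold HU separating soft tissue from bone.
#' @return an object of class `hu_mapping_config`.
#' @export
hu_mapping_config <- function(density_intercept = 1000, density_slope = 0.9,
                              speed_knots = data.frame(
                                hu = c(300, 1000, 1700, 2200),
                                value = c(1550, 2100, 2500, 2740)),
                              attenuation_knots = data.frame(
                                hu = c(300, 1000, 1700, 2200),
                                value = c(1, 4, 7, 9)),
                              background = list(speed = 1500, attenuation = 0,
                                                density = 1000),
                              hu_threshold = 300) {
  chk_curve <- function(k, what) {
    k <- as.data.frame(k)
    names(k)[1:2] <- c("hu", "value")
    if (nrow(k) < 2L) stop(sprintf("%s needs >= 2 knots", what), call. = FALSE)
    if (is.unsorted(k$hu, strictly = TRUE))
      stop(sprintf("%s knots must be strictly increasing in HU", what), call. = FALSE)
    if (is.unsorted(k$value))
      stop(sprintf("%s curve must be monotone non-decreasing", what), call. = FALSE)
    k
  }
  if (density_slope <= 0) stop("density slope must be > 0", call. = FALSE)
  structure(list(density_intercept = density_intercept,
                 density_slope = density_slope,
                 speed_knots = chk_curve(speed_knots, "speed"),
                 attenuation_knots = chk_curve(attenuation_knots, "attenuation"),
                 background = background,
                 hu_threshold = hu_threshold),
            class = "hu_mapping_config")
}

#' Map a Hounsfield-unit volume to an acoustic model
#'
#' Voxels below the bone threshold get background (water/soft-tissue)
#' properties exactly; bone voxels get density from the affine map and
#' speed/attenuation from the piecewise-linear curves, clamped at the end
#' knots.  HU beyond the top knot is clamped with a warning, never an
#' error.
#'
#' @param hu an [hu_volume()].
#' @param cfg an [hu_mapping_config()].
#' @return an [acoustic_model()] on the same grid.
#' @export
map_hu_to_properties <- function(hu, cfg = hu_mapping_config()) {
  stopifnot(inherits(hu, "hu_volume"), inherits(cfg, "hu_mapping_config"))
  h <- hu$hu
  bone <- h >= cfg$hu_threshold
  if (any(bone & (h > max(cfg$speed_knots$hu) | h > max(cfg$attenuation_knots$hu))))
    warning("HU above the top curve knot; values clamped", call. = FALSE)
  bg <- cfg$background
  speed <- array(bg$speed, hu$grid$dims)
  atten <- array(bg$attenuation, hu$grid$dims)
  dens <- array(bg$density, hu$grid$dims)
  if (any(bone)) {
    hb <- h[bone]
    speed[bone] <- stats::approx(cfg$speed_knots$hu, cfg$speed_knots$value,
                                 xout = hb, rule = 2)$y
    atten[bone] <- stats::approx(cfg$attenuation_knots$hu,
                                 cfg$attenuation_knots$value,
                                 xout = hb, rule = 2)$y
    dens[bone] <- cfg$density_intercept + cfg$density_slope * hb
  }
  acoustic_model(hu$grid, speed, atten, dens, background = bg)
}

#' Generate a synthetic skull-like HU volume
#'
#' A curved bone slab with smoothly varying thickness (long lateral
#' correlation length, unlike the random aberrator plate) and seeded
#' internal HU texture, intended as a reproducible stand-in for a CT scan
#' of a skull flap.  Deterministic per seed.
#'
#' @param seed integer seed.
#' @param grid a [voxel_grid()].
#' @param mean_thickness,thickness_variation mean slab thickness and the
#'   half-range of its smooth lateral variation, m.
#' @param thickness_scale lateral correlation scale (FWHM) of the
#'   thickness variation, m (long compared to the aberrator's relief
#'   features).
#' @param curvature_radius radius of the slab's spherical curvature, m
#'   (`Inf` gives a flat slab).
#' @param hu_mean mean bone HU inside the slab.
#' @param texture_amplitude half-range of the internal HU texture (0 gives
#'   a homogeneous slab).
#' @param texture_scale lateral correlation scale of the texture, m.
#' @param slab_z z coordinate (m) of the shallowest point of the slab's
#'   entry surface; default centers the slab along z.
#' @return an [hu_volume()]; the lateral thickness map (m) is attached as
#'   attribute `"thickness"`.
#' @export
generate_synthetic_skull <- function(seed, grid,
                                     mean_thickness = 6e-3,
                                     thickness_variation = 1.5e-3,
                                     thickness_scale = 25e-3,
                                     curvature_radius = 90e-3,
                                     hu_mean = 1400,
                                     texture_amplitude = 300,
                                     texture_scale = 2e-3,
                                     slab_z = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (mean_thickness + thickness_variation >= grid$dims[3] * grid$spacing[3])
    stop("slab thicker than the grid z extent", call. = FALSE)
  nx <- grid$dims[1]; ny <- grid$dims[2]
  dx <- grid$spacing[1]
  fwhm_px <- function(s) s / (2 * sqrt(2 * log(2))) / dx

  fields <- with_seed(seed, {
    n1 <- matrix(stats::runif(nx * ny), nx, ny)
    n2 <- matrix(stats::runif(nx * ny * grid$dims[3]), nx, ny * grid$dims[3])
    list(n1 = n1, n2 = n2)
  })
  tvar <- gauss_smooth2(fields$n1, fwhm_px(thickness_scale))
  rng <- range(tvar)
  tvar <- if (rng[2] - rng[1] < .Machine$double.eps) 0 * tvar else
    (tvar - mean(tvar)) / (rng[2] - rng[1]) * 2
  thickness <- mean_thickness + thickness_variation * tvar

  x <- grid_coords(grid, 1); y <- grid_coords(grid, 2)
  sag <- if (is.finite(curvature_radius))
    outer(x^2, y^2, `+`) / (2 * curvature_radius) else matrix(0, nx, ny)
  zext <- grid$dims[3] * grid$spacing[3]
  if (is.null(slab_z))
    slab_z <- grid$origin[3] +
      (zext - mean_thickness - max(sag)) / 2
  z_top <- slab_z + sag

  hu <- array(0, grid$dims)
  z <- grid_coords(grid, 3)
  # internal texture: per-slice smoothed noise, reused lazily
  tex_sigma <- fwhm_px(texture_scale)
  for (k in seq_len(grid$dims[3])) {
    inside <- (z[k] >= z_top) & (z[k] < z_top + thickness)
    if (!any(inside)) next
    sl <- matrix(0, nx, ny)
    if (texture_amplitude > 0) {
      noise <- matrix(fields$n2[, (k - 1L) * ny + seq_len(ny)], nx, ny)
      tx <- gauss_smooth2(noise, tex_sigma)
      trng <- range(tx)
      if (trng[2] - trng[1] > .Machine$double.eps)
        sl <- (tx - mean(tx)) / (trng[2] - trng[1]) * 2 * texture_amplitude
    }
    slice <- matrix(0, nx, ny)
    slice[inside] <- hu_mean + sl[inside]
    hu[, , k] <- slice
  }
  out <- hu_volume(grid, hu)
  attr(out, "thickness") <- thickness
  out
}
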