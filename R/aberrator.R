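#' Generate the random-relief aberrator plate
#'
#' Builds a water-immersed plastic plate that mimics skull-like phase
#' aberrations: flat on the entry (transducer-facing) side, with randomly
#' varying relief on the exit side.  The relief is seeded uniform white
#' noise smoothed to a configurable lateral feature scale and min-max
#' rescaled so it spans exactly `[0, max_relief]`; the defaults (7.5 mm
#' base + up to 4 mm relief, plate speed 2492 m/s, attenuation
#' 4.72 dB/(cm MHz)) give a through-plate phase span slightly above 2*pi at
#' 1 MHz, the design rule for a full-strength aberrator.
#'
#' A voxel belongs to the plate when its center lies inside the plate
#' surface.  The construction is bitwise deterministic for a fixed seed.
#'
#' @param seed integer seed for the relief noise.
#' @param grid a [voxel_grid()]; its z extent must cover the plate.
#' @param base_thickness flat base thickness, m (> 0).
#' @param max_relief maximum relief height on top of the base, m (>= 0).
#' @param feature_scale lateral size (FWHM of the smoothing kernel) of the
#'   relief features, m.
#' @param plate_speed,plate_attenuation,plate_density plate material
#'   properties (m/s, dB/(cm MHz), kg/m^3).  The density default is a
#'   nominal rigid-photopolymer value; it only matters when the solver's
#'   reflection flag is on.
#' @param plate_z z coordinate (m) of the flat entry face; default centers
#'   the plate in the grid's z extent.
#' @param c_water,a_water,rho_water immersion-water properties.
#' @return a list with elements `model` (an [acoustic_model()]) and
#'   `heightmap` (a `height_map`: relief matrix in meters plus metadata).
#' @export
generate_aberrator <- function(seed, grid,
                               base_thickness = 7.5e-3, max_relief = 4e-3,
                               feature_scale = 5e-3,
                               plate_speed = 2492, plate_attenuation = 4.72,
                               plate_density = 1180,
                               plate_z = NULL,
                               c_water = 1500, a_water = 0, rho_water = 1000) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (base_thickness <= 0) stop("base_thickness must be > 0", call. = FALSE)
  if (max_relief < 0) stop("max_relief must be >= 0", call. = FALSE)
  zext <- grid$dims[3] * grid$spacing[3]
  thick <- base_thickness + max_relief
  if (thick > zext)
    stop("grid z extent too thin for the plate", call. = FALSE)
  if (is.null(plate_z))
    plate_z <- grid$origin[3] + (zext - thick) / 2
  z <- grid_coords(grid, 3)
  if (plate_z < z[1] - grid$spacing[3] / 2 ||
      plate_z + thick > z[grid$dims[3]] + grid$spacing[3] / 2)
    stop("plate does not fit inside the grid along z", call. = FALSE)

  relief <- relief_map(seed, grid$dims[1], grid$dims[2],
                       grid$spacing[1], max_relief, feature_scale)
  hm <- structure(list(heights = relief, base = base_thickness,
                       spacing = grid$spacing[1:2],
                       extent = grid$dims[1:2] * grid$spacing[1:2],
                       feature_scale = feature_scale, seed = seed),
                  class = "height_map")

  speed <- array(c_water, grid$dims)
  atten <- array(a_water, grid$dims)
  dens <- array(rho_water, grid$dims)
  for (k in seq_len(grid$dims[3])) {
    inside <- (z[k] >= plate_z) & (z[k] < plate_z + base_thickness + relief)
    if (any(inside)) {
      sl <- speed[, , k]; sl[inside] <- plate_speed; speed[, , k] <- sl
      sl <- atten[, , k]; sl[inside] <- plate_attenuation; atten[, , k] <- sl
      sl <- dens[, , k]; sl[inside] <- plate_density; dens[, , k] <- sl
    }
  }
  model <- acoustic_model(grid, speed, atten, dens,
                          background = list(speed = c_water,
                                            attenuation = a_water,
                                            density = rho_water))
  list(model = model, heightmap = hm)
}

# Seeded white noise, periodically Gaussian-smoothed to `feature_scale`
# (FWHM), min-max rescaled to [0, max_relief].
relief_map <- function(seed, nx, ny, dx, max_relief, feature_scale) {
  if (max_relief == 0) return(matrix(0, nx, ny))
  noise <- with_seed(seed, matrix(stats::runif(nx * ny), nx, ny))
  sigma_px <- feature_scale / (2 * sqrt(2 * log(2))) / dx
  sm <- gauss_smooth2(noise, sigma_px)
  rng <- range(sm)
  if (rng[2] - rng[1] < .Machine$double.eps)
    return(matrix(max_relief / 2, nx, ny))
  (sm - rng[1]) / (rng[2] - rng[1]) * max_relief
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d, base %.3g mm, relief 0 - %.3g mm, feature scale %.3g mm\n",
              nrow(x$heights), ncol(x$heights), 1e3 * x$base,
              1e3 * max(x$heights), 1e3 * x$feature_scale))
  invisible(x)
}

#' Total plate thickness of a height map
#'
#' @param hm a `height_map` from [generate_aberrator()].
#' @return matrix of total thickness (base + relief) in meters.
#' @export
total_thickness <- function(hm) {
  stopifnot(inherits(hm, "height_map"))
  hm$base + hm$heights
}
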