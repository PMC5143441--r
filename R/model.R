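#' Voxelized acoustic model
#'
#' Container for per-voxel medium properties on a [voxel_grid()]: sound
#' speed (m/s), attenuation (frequency-normalized, dB/(cm MHz)) and density
#' (kg/m^3).  Attenuation is stored frequency-normalized and converted to
#' Np/m at run time with [attenuation_to_neper()].  The `background` field
#' records the immersion-medium properties used to fill vacated voxels when
#' the model is translated.
#'
#' @param grid a [voxel_grid()].
#' @param speed,attenuation,density 3D arrays matching `grid$dims`, or
#'   scalars (recycled).
#' @param background named list with elements `speed`, `attenuation`,
#'   `density` describing the immersion medium.
#' @return an object of class `acoustic_model`.
#' @export
acoustic_model <- function(grid, speed, attenuation, density,
                           background = list(speed = 1500, attenuation = 0,
                                             density = 1000)) {
  stopifnot(inherits(grid, "voxel_grid"))
  expand <- function(v, what) {
    if (length(v) == 1L) v <- array(v, grid$dims)
    if (!identical(dim(v), as.integer(grid$dims)))
      stop(sprintf("`%s` does not match the grid dimensions", what), call. = FALSE)
    v
  }
  speed <- expand(speed, "speed")
  attenuation <- expand(attenuation, "attenuation")
  density <- expand(density, "density")
  if (any(!is.finite(speed)) || any(speed <= 0))
    stop("speed must be positive and finite everywhere", call. = FALSE)
  if (any(!is.finite(attenuation)) || any(attenuation < 0))
    stop("attenuation must be non-negative and finite", call. = FALSE)
  if (any(!is.finite(density)) || any(density <= 0))
    stop("density must be positive and finite everywhere", call. = FALSE)
  structure(list(grid = grid, speed = speed, attenuation = attenuation,
                 density = density, background = background),
            class = "acoustic_model")
}

#' @export
print.acoustic_model <- function(x, ...) {
  cat("<acoustic_model>\n")
  print(x$grid)
  cat(sprintf("  speed       %.4g - %.4g m/s\n", min(x$speed), max(x$speed)))
  cat(sprintf("  attenuation %.4g - %.4g dB/(cm MHz)\n",
              min(x$attenuation), max(x$attenuation)))
  cat(sprintf("  density     %.4g - %.4g kg/m^3\n", min(x$density), max(x$density)))
  invisible(x)
}

#' Homogeneous water (or soft-tissue) model
#'
#' @param dims,spacing,origin grid specification, see [voxel_grid()].
#' @param c_water sound speed, m/s (> 0).
#' @param a_water attenuation, dB/(cm MHz) (>= 0).
#' @param rho_water density, kg/m^3 (> 0).
#' @return an `acoustic_model` with every voxel carrying the given
#'   properties.
#' @export
make_water_model <- function(dims, spacing, c_water = 1500, a_water = 0,
                             rho_water = 1000, origin = NULL) {
  if (c_water <= 0 || rho_water <= 0)
    stop("speed and density must be positive", call. = FALSE)
  if (a_water < 0)
    stop("attenuation must be non-negative", call. = FALSE)
  g <- voxel_grid(dims, spacing, origin)
  acoustic_model(g, c_water, a_water, rho_water,
                 background = list(speed = c_water, attenuation = a_water,
                                   density = rho_water))
}

#' Per-voxel propagation constant
#'
#' `b = 2*pi*f / c` in rad/m for every voxel of the model at the given
#' frequency.
#'
#' @param model an [acoustic_model()].
#' @param frequency Hz.
#' @return 3D array of propagation constants (rad/m).
#' @export
propagation_constant <- function(model, frequency) {
  stopifnot(inherits(model, "acoustic_model"), frequency > 0)
  2 * pi * frequency / model$speed
}

#' Translate a model laterally (misregistration emulation)
#'
#' Shifts all property maps in the (x, y) plane by the nearest whole-voxel
#' amount (shifts are quantized to the grid; property maps are never
#' interpolated, which would smear binary material boundaries).  Vacated
#' voxels are filled with the model's background (immersion) properties.
#'
#' @param model an [acoustic_model()].
#' @param shift numeric `(dx, dy)` in meters.
#' @return the translated `acoustic_model`.
#' @export
translate_model <- function(model, shift) {
  stopifnot(inherits(model, "acoustic_model"), length(shift) == 2L)
  g <- model$grid
  sv <- as.integer(round(as.numeric(shift) / g$spacing[1:2]))
  if (any(abs(sv) >= g$dims[1:2]))
    stop("shift exceeds the lateral extent of the model", call. = FALSE)
  if (all(sv == 0L)) return(model)
  shift_one <- function(vol, fill) {
    out <- array(fill, dim(vol))
    src_x <- seq_len(g$dims[1]) - sv[1]
    src_y <- seq_len(g$dims[2]) - sv[2]
    okx <- src_x >= 1L & src_x <= g$dims[1]
    oky <- src_y >= 1L & src_y <= g$dims[2]
    out[okx, oky, ] <- vol[src_x[okx], src_y[oky], , drop = FALSE]
    out
  }
  bg <- model$background
  model$speed <- shift_one(model$speed, bg$speed)
  model$attenuation <- shift_one(model$attenuation, bg$attenuation)
  model$density <- shift_one(model$density, bg$density)
  model
}
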