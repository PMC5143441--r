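#' Ratio map over a lattice of shifts or steering targets
#'
#' @param values numeric matrix of ratios (>= 0).
#' @param x,y lattice coordinates (m) along each axis.
#' @param kind `"steering"` or `"misregistration"`.
#' @param reference description of the normalization.
#' @return an object of class `ratio_map`.
#' @export
ratio_map <- function(values, x, y, kind, reference) {
  stopifnot(is.matrix(values), nrow(values) == length(x),
            ncol(values) == length(y), all(values >= 0))
  structure(list(values = values, x = x, y = y, kind = kind,
                 reference = reference),
            class = "ratio_map")
}

#' @export
print.ratio_map <- function(x, ...) {
  cat(sprintf("<ratio_map> %s, %d x %d lattice, values %.3f - %.3f\n",
              x$kind, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  cat(sprintf("  reference: %s\n", x$reference))
  invisible(x)
}

#' Steering-improvement map
#'
#' For each target on a lateral lattice in the focal plane, runs one
#' full-array simulation with uncorrected (water-path geometric steering)
#' phases and one with conjugate-phase corrections from the element field
#' bank, and records the ratio of the maximum pressure magnitudes in the
#' focal plane (corrected / uncorrected).  In homogeneous water the
#' correction reduces to geometric steering and the map is flat at 1.
#'
#' @param array a [build_spherical_array()].
#' @param model an [acoustic_model()].
#' @param cfg a [solver_config()].
#' @param offsets_x,offsets_y lateral target offsets (m) from the beam
#'   axis; the target lattice is their outer product.
#' @param z_focus z coordinate (m) of the focal plane; default the
#'   geometric focus.
#' @param bank optional precomputed [simulate_element_bank()] covering the
#'   lattice; computed (over the focal-plane slab) when missing.
#' @param c_ref water speed for the geometric steering baseline.
#' @param window lateral half-width (m) of the focal-plane search window
#'   centered on each target, emulating a hydrophone raster scan around
#'   the treatment location (default 5 mm, i.e. a 10 x 10 mm scan);
#'   `Inf` searches the whole plane.
#' @return a `ratio_map` (kind `"steering"`).
#' @export
steering_improvement_map <- function(array, model, cfg = solver_config(),
                                     offsets_x, offsets_y,
                                     z_focus = NULL, bank = NULL,
                                     c_ref = NULL, window = 5e-3) {
  g <- model$grid
  if (is.null(z_focus)) z_focus <- array$focal_length
  if (is.null(c_ref)) c_ref <- model$background$speed
  kz <- nearest_voxel(g, c(0, 0, z_focus))[3]
  if (is.null(bank)) {
    zr <- c(max(1L, kz - 2L), min(g$dims[3], kz + 2L))
    bank <- simulate_element_bank(array, model, cfg,
                                  region = list(x = c(1L, g$dims[1]),
                                                y = c(1L, g$dims[2]),
                                                z = zr))
  }
  vals <- matrix(NA_real_, length(offsets_x), length(offsets_y))
  for (i in seq_along(offsets_x)) {
    for (j in seq_along(offsets_y)) {
      target <- c(offsets_x[i], offsets_y[j], z_focus)
      sol <- correction_phases(bank, target)
      corr <- corrected_field(array, model, cfg, sol, planes = bank$planes)
      unc_drives <- exp(1i * geometric_phases(array, target, c_ref))
      src <- full_source_plane(array, g, drives = unc_drives,
                               planes = bank$planes)
      unc <- propagate(src, model, cfg)
      vals[i, j] <- plane_peak(corr, kz, target, window) /
        plane_peak(unc, kz, target, window)
    }
  }
  ratio_map(vals, offsets_x, offsets_y, "steering",
            "max |p| in focal plane, corrected / uncorrected (geometric)")
}

# Max |p| in z slice kz within a lateral window around the target
# (hydrophone-raster emulation); window = Inf gives the whole plane.
plane_peak <- function(vol, kz, target, window = Inf) {
  mag <- Mod(vol$field[, , kz])
  if (is.finite(window)) {
    x <- grid_coords(vol$grid, 1); y <- grid_coords(vol$grid, 2)
    selx <- abs(x - target[1]) <= window
    sely <- abs(y - target[2]) <= window
    if (!any(selx) || !any(sely))
      stop("search window falls outside the grid", call. = FALSE)
    mag <- mag[selx, sely, drop = FALSE]
  }
  max(mag)
}

#' Translational misregistration sensitivity map
#'
#' Keeps the phase solution computed for the unshifted model fixed,
#' translates the model by each lattice shift in the plane perpendicular
#' to the beam ([translate_model()], whole-voxel quantization), re-runs
#' the full-array simulation, and records the maximum focal-plane pressure
#' normalized by the zero-shift value (so the origin cell is exactly 1).
#'
#' @param array,model,cfg as in [steering_improvement_map()].
#' @param solution the [correction_phases()] solution for the unshifted
#'   model.
#' @param shifts_x,shifts_y lattice shifts (m); must include 0 in each.
#' @param planes optional unit-drive entry planes (the water path does not
#'   depend on the model, so bank planes can be reused).
#' @param window lateral half-width (m) of the focal-plane search window
#'   centered on the solution's target (hydrophone-raster emulation,
#'   default 5 mm); `Inf` searches the whole plane.
#' @return a `ratio_map` (kind `"misregistration"`).
#' @export
misregistration_map <- function(array, model, cfg = solver_config(),
                                solution, shifts_x, shifts_y,
                                planes = NULL, window = 5e-3) {
  stopifnot(inherits(solution, "phase_solution"))
  if (!any(shifts_x == 0) || !any(shifts_y == 0))
    stop("shift lattices must include 0 (the normalization cell)",
         call. = FALSE)
  g <- model$grid
  kz <- nearest_voxel(g, solution$target)[3]
  drives <- exp(1i * solution$phases)
  if (is.null(planes)) {
    subs <- array_subsources(array, c_medium = model$background$speed)
    arr_unit <- array; arr_unit$drive <- rep(1 + 0i, nrow(array$centers))
    planes <- lapply(seq_len(nrow(array$centers)), function(i)
      element_source_plane(arr_unit, i, g,
                           c_medium = model$background$speed,
                           a_medium = model$background$attenuation,
                           rho_medium = model$background$density,
                           subsources = subs))
  }
  src <- full_source_plane(array, g, drives = drives, planes = planes)
  vals <- matrix(NA_real_, length(shifts_x), length(shifts_y))
  for (i in seq_along(shifts_x)) {
    for (j in seq_along(shifts_y)) {
      m <- translate_model(model, c(shifts_x[i], shifts_y[j]))
      vol <- propagate(src, m, cfg)
      vals[i, j] <- plane_peak(vol, kz, solution$target, window)
    }
  }
  ref <- vals[which(shifts_x == 0)[1], which(shifts_y == 0)[1]]
  ratio_map(vals / ref, shifts_x, shifts_y, "misregistration",
            "max |p| in focal plane, normalized to zero shift")
}

#' Accumulated phase-length map
#'
#' Accumulates the propagation phase along straight paths parallel to the
#' beam axis, `phi(x, y) = sum_z b(x, y, z) * dz` (no refraction), then
#' optionally Gaussian-smooths the map (`sigma` in pixels, e.g. to absorb
#' CT measurement noise) and forms the unit-modulus phasor `e^{j phi}`,
#' which best represents the potential for interference.
#'
#' @param model an [acoustic_model()].
#' @param frequency Hz.
#' @param sigma Gaussian smoothing standard deviation in pixels (0 = none).
#' @return an object of class `phase_length_map` with fields `phi` (rad),
#'   `phasor`, `spacing` (m) and `sigma`.
#' @export
phase_length_map <- function(model, frequency, sigma = 0) {
  stopifnot(inherits(model, "acoustic_model"), frequency > 0, sigma >= 0)
  b <- propagation_constant(model, frequency)
  phi <- apply(b, c(1, 2), sum) * model$grid$spacing[3]
  if (sigma > 0) phi <- gauss_smooth2(phi, sigma)
  structure(list(phi = phi, phasor = exp(1i * phi),
                 spacing = model$grid$spacing[1:2], sigma = sigma,
                 frequency = frequency),
            class = "phase_length_map")
}

#' @export
print.phase_length_map <- function(x, ...) {
  cat(sprintf("<phase_length_map> %d x %d, phi %.2f - %.2f rad (span %.2f), sigma %.1f px\n",
              nrow(x$phi), ncol(x$phi), min(x$phi), max(x$phi),
              max(x$phi) - min(x$phi), x$sigma))
  invisible(x)
}

#' Normalized phasor autocorrelation of a phase-length map
#'
#' A circular patch of the phasor map, centered on the beam axis and equal
#' in size to the beam footprint where it enters the model, is
#' cross-correlated (complex, circularly) with the untruncated phasor map.
#' The magnitude is normalized so the global maximum is 1 (which occurs at
#' zero lag), and contour areas at the requested fractions of the maximum
#' are reported in mm^2.  Broad correlation areas predict tolerance to
#' transducer/model misregistration; narrow ones predict sensitivity.
#'
#' @param map a [phase_length_map()].
#' @param aperture_radius radius (m) of the circular patch (the beam
#'   radius at the model entry plane, see [beam_radius_at()]).
#' @param fractions contour fractions of the maximum (default 25/50/75%).
#' @return an object of class `correlation_result`: `corr` (magnitude
#'   map, zero lag at the center cell), `lag_x`/`lag_y` (m), and
#'   `areas_mm2` (named, non-increasing in the fraction).
#' @export
phasor_autocorrelation <- function(map, aperture_radius,
                                   fractions = c(0.25, 0.5, 0.75)) {
  stopifnot(inherits(map, "phase_length_map"), aperture_radius > 0)
  nx <- nrow(map$phi); ny <- ncol(map$phi)
  dx <- map$spacing[1]; dy <- map$spacing[2]
  if (aperture_radius >= min(nx * dx, ny * dy) / 2)
    stop("aperture radius too large for the map", call. = FALSE)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  rr2 <- outer(((seq_len(nx) - cx) * dx)^2, ((seq_len(ny) - cy) * dy)^2, `+`)
  patch <- map$phasor * (rr2 <= aperture_radius^2)
  # circular complex cross-correlation via FFT
  C <- stats::fft(Conj(stats::fft(patch)) * stats::fft(map$phasor),
                  inverse = TRUE) / (nx * ny)
  mag <- Mod(C)
  mag <- mag / max(mag)
  magc <- fft_shift2(mag)
  lag_x <- sort(fft_lags(nx)) * dx
  lag_y <- sort(fft_lags(ny)) * dy
  cell_mm2 <- dx * dy * 1e6
  areas <- vapply(fractions, function(fr) sum(magc >= fr) * cell_mm2,
                  numeric(1))
  names(areas) <- sprintf("%g%%", 100 * fractions)
  structure(list(corr = magc, lag_x = lag_x, lag_y = lag_y,
                 fractions = fractions, areas_mm2 = areas,
                 aperture_radius = aperture_radius),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %d x %d lags, aperture radius %.3g mm\n",
              nrow(x$corr), ncol(x$corr), 1e3 * x$aperture_radius))
  for (i in seq_along(x$areas_mm2))
    cat(sprintf("  %s contour area: %.1f mm^2\n",
                names(x$areas_mm2)[i], x$areas_mm2[i]))
  invisible(x)
}

#' Beam radius where the converging cone meets the model
#'
#' Cone geometry for a focused spherical-cap array: the beam footprint
#' radius at a plane `d` meters in front of the focus is
#' `aperture_radius * d / focal_length`.
#'
#' @param array a [build_spherical_array()].
#' @param entry_z z coordinate (m, transducer frame) of the model entry
#'   plane.
#' @return radius in meters.
#' @export
beam_radius_at <- function(array, entry_z) {
  d <- array$focal_length - entry_z
  if (d <= 0) stop("entry plane must lie before the focus", call. = FALSE)
  (array$aperture_diameter / 2) * d / array$focal_length
}
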