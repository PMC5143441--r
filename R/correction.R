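#' Simulate the per-element field bank
#'
#' Runs a zero-phase, unit-amplitude simulation for every element of the
#' array ([element_source_plane()] + [propagate()]) and stores the complex
#' pressure over a declared treatment region (default: the full volume).
#' The bank is the precomputation behind conjugate-phase correction: once
#' it exists, phase solutions at any location inside the region are pure
#' lookups, so multiple treatment sites cost essentially nothing extra.
#'
#' Elements are independent; with `checkpoint_dir` set, each element's
#' region field is written to disk as it completes and later calls resume
#' from the checkpoints without recomputation.
#'
#' @param array a [build_spherical_array()].
#' @param model an [acoustic_model()] registered in the transducer frame.
#' @param cfg a [solver_config()].
#' @param region optional list with integer index ranges `x`, `y`, `z`
#'   (each `c(first, last)`) declaring the stored treatment region.
#' @param c_medium,a_medium,rho_medium coupling-water properties for the
#'   entry-plane computation.
#' @param checkpoint_dir optional directory for per-element checkpoints.
#' @param verbose print per-element progress.
#' @return an object of class `element_field_bank`: per-element complex
#'   region fields, unit-drive entry planes, grid/region/frequency
#'   metadata.  The number of elements actually simulated in this call
#'   (as opposed to restored from checkpoints) is in field `n_computed`.
#' @export
simulate_element_bank <- function(array, model, cfg = solver_config(),
                                  region = NULL,
                                  c_medium = NULL, a_medium = NULL,
                                  rho_medium = NULL,
                                  checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(array, "transducer_array"), inherits(model, "acoustic_model"))
  g <- model$grid
  if (is.null(c_medium)) c_medium <- model$background$speed
  if (is.null(a_medium)) a_medium <- model$background$attenuation
  if (is.null(rho_medium)) rho_medium <- model$background$density
  region <- normalize_region(region, g)
  n <- nrow(array$centers)
  arr_unit <- array
  arr_unit$drive <- rep(1 + 0i, n)  # bank contract: unit amplitude, zero phase
  subs <- array_subsources(arr_unit, c_medium = c_medium)
  rx <- region$x[1]:region$x[2]; ry <- region$y[1]:region$y[2]
  rz <- region$z[1]:region$z[2]
  fields <- vector("list", n)
  planes <- vector("list", n)
  n_computed <- 0L
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE)
  for (i in seq_len(n)) {
    ck <- if (!is.null(checkpoint_dir))
      file.path(checkpoint_dir, sprintf("element_%04d.rds", i)) else NULL
    if (!is.null(ck) && file.exists(ck)) {
      rec <- readRDS(ck)
      fields[[i]] <- rec$field
      planes[[i]] <- rec$plane
      next
    }
    plane <- element_source_plane(arr_unit, i, g, c_medium = c_medium,
                                  a_medium = a_medium,
                                  rho_medium = rho_medium,
                                  subsources = subs)
    vol <- tryCatch(propagate(plane, model, cfg), error = function(e)
      stop(sprintf("propagation failed for element %d: %s", i,
                   conditionMessage(e)), call. = FALSE))
    fields[[i]] <- vol$field[rx, ry, rz, drop = FALSE]
    planes[[i]] <- plane
    n_computed <- n_computed + 1L
    if (!is.null(ck)) saveRDS(list(field = fields[[i]], plane = plane), ck)
    if (verbose) message(sprintf("element %d/%d done", i, n))
  }
  structure(list(fields = fields, planes = planes, region = region,
                 grid = g, frequency = array$frequency,
                 n_elements = n, n_computed = n_computed,
                 medium = list(speed = c_medium, attenuation = a_medium,
                               density = rho_medium)),
            class = "element_field_bank")
}

normalize_region <- function(region, grid) {
  if (is.null(region))
    return(list(x = c(1L, grid$dims[1]), y = c(1L, grid$dims[2]),
                z = c(1L, grid$dims[3])))
  chk <- function(r, n, ax) {
    r <- as.integer(r)
    if (length(r) != 2L || r[1] < 1L || r[2] > n || r[1] > r[2])
      stop(sprintf("invalid region along %s", ax), call. = FALSE)
    r
  }
  list(x = chk(region$x, grid$dims[1], "x"),
       y = chk(region$y, grid$dims[2], "y"),
       z = chk(region$z, grid$dims[3], "z"))
}

#' @export
print.element_field_bank <- function(x, ...) {
  r <- x$region
  cat(sprintf("<element_field_bank> %d elements, %.3g MHz\n",
              x$n_elements, x$frequency / 1e6))
  cat(sprintf("  region x %d:%d, y %d:%d, z %d:%d of %d x %d x %d grid\n",
              r$x[1], r$x[2], r$y[1], r$y[2], r$z[1], r$z[2],
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3]))
  invisible(x)
}

#' Conjugate-phase solution at a treatment location
#'
#' The aberration-correction rule: each element's drive phase is the
#' negative of the phase its unit-drive field accrues to the target,
#' `phi_i = -arg p_i(target)`, wrapped to `(-pi, pi]`.  Driving the
#' elements with `e^{j phi_i}` aligns every contribution at the target
#' (zero phase there), giving maximum constructive interference.  Element
#' amplitudes are never altered.  Off-grid targets are evaluated by
#' trilinear interpolation of the complex field (the phasor, never the
#' wrapped angle).
#'
#' @param bank an [simulate_element_bank()] result covering the target.
#' @param target numeric `(x, y, z)` in meters (transducer/model frame).
#' @return an object of class `phase_solution`: per-element `phases`
#'   (rad, principal value), `target` coordinates and nearest voxel,
#'   per-element complex `p_target`, and provenance metadata.
#' @export
correction_phases <- function(bank, target) {
  stopifnot(inherits(bank, "element_field_bank"), length(target) == 3L)
  start <- c(bank$region$x[1], bank$region$y[1], bank$region$z[1])
  p <- vapply(bank$fields, function(fld)
    interp_complex3(fld, bank$grid, target, start = start), complex(1))
  phases <- numeric(length(p))
  nz <- Mod(p) > 0
  phases[nz] <- wrap_phase(-Arg(p[nz]))
  if (any(!nz))
    warning(sprintf("%d element(s) with zero amplitude at the target; phase set to 0",
                    sum(!nz)), call. = FALSE)
  structure(list(phases = phases, target = as.numeric(target),
                 target_voxel = nearest_voxel(bank$grid, target),
                 p_target = p,
                 frequency = bank$frequency,
                 n_elements = bank$n_elements),
            class = "phase_solution")
}

#' @export
print.phase_solution <- function(x, ...) {
  cat(sprintf("<phase_solution> %d elements, target (%.2f, %.2f, %.2f) mm\n",
              x$n_elements, 1e3 * x$target[1], 1e3 * x$target[2],
              1e3 * x$target[3]))
  cat(sprintf("  phase range %.3f .. %.3f rad; coherent |sum| = %.4g\n",
              min(x$phases), max(x$phases), sum(Mod(x$p_target))))
  invisible(x)
}

#' Phase solutions for multiple treatment locations
#'
#' Pure lookups into an existing bank (no new propagation); cost is
#' O(targets x elements).
#'
#' @param bank an element field bank.
#' @param targets list of `(x, y, z)` coordinate vectors (m).
#' @return list of [correction_phases()] solutions, one per target.
#' @export
multi_target_solutions <- function(bank, targets) {
  lapply(targets, function(t) correction_phases(bank, t))
}

#' Full-array field under a phase solution
#'
#' Propagates the full array with drives `e^{j phi_i}` (unit amplitudes)
#' through the model and reports the peak location, peak magnitude and
#' the peak-to-target distance in the volume metadata.
#'
#' @param array a [build_spherical_array()].
#' @param model an [acoustic_model()].
#' @param cfg a [solver_config()].
#' @param solution a [correction_phases()] solution (element count must
#'   match the array).
#' @param planes optional list of unit-drive entry planes (e.g.
#'   `bank$planes`) to skip the Rayleigh-Sommerfeld recomputation.
#' @return a [pressure_volume()]; `meta` holds `peak`, `target` and
#'   `peak_target_distance_mm`.
#' @export
corrected_field <- function(array, model, cfg = solver_config(), solution,
                            planes = NULL) {
  stopifnot(inherits(solution, "phase_solution"))
  if (solution$n_elements != nrow(array$centers))
    stop("solution element count does not match the array", call. = FALSE)
  drives <- exp(1i * solution$phases)
  src <- full_source_plane(array, model$grid, drives = drives, planes = planes,
                           c_medium = model$background$speed,
                           a_medium = model$background$attenuation,
                           rho_medium = model$background$density)
  vol <- propagate(src, model, cfg)
  kz <- nearest_voxel(model$grid, solution$target)[3]
  pk_plane <- peak_info(vol, slice = kz)
  vol$meta$peak <- peak_info(vol)
  vol$meta$peak_focal_plane <- pk_plane
  vol$meta$target <- solution$target
  # lateral distance in the target's transverse plane (hydrophone-scan
  # convention; the free-field axial peak sits upstream of the focus)
  vol$meta$peak_target_distance_mm <-
    1e3 * sqrt(sum((pk_plane$position[1:2] - solution$target[1:2])^2))
  vol
}
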