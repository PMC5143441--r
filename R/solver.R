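#' Solver configuration for the hybrid angular spectrum march
#'
#' The solver alternates a space-domain step (per-voxel phase offset and
#' attenuation over one slice) with a spectral-domain step (plane-wave
#' diffraction transfer function) for every slice along +z.  Sign
#' convention project-wide: time dependence `e^{-j omega t}`, forward
#' propagation multiplies by `e^{+j k z}`; the spectral transfer function
#' is `e^{+j b' sqrt(1 - alpha^2 - beta^2) dz}`.
#'
#' Radiating (non-reflecting) lateral boundaries are emulated by
#' `pad_factor`-fold zero padding of the field plus a raised-cosine
#' amplitude taper `taper` voxels wide applied each slice.  Spectral
#' components with `alpha^2 + beta^2 > 1` are evanescent; policy `"zero"`
#' removes them (default, prevents spurious growth), `"decay"` applies the
#' real exponential decay.  Under the paraxial policy both the oblique and
#' perpendicular space-step distances are taken as `dz`.
#'
#' @param dz marching step, m; default the grid's z spacing.
#' @param evanescent `"zero"` or `"decay"`.
#' @param pad_factor lateral padding factor (>= 1; 1 disables padding).
#' @param taper raised-cosine edge taper width in voxels (0 disables).
#' @param reflection logical; when `TRUE` the space step additionally
#'   applies the plane-wave pressure-transmission factor
#'   `2 Z2 / (Z1 + Z2)` at voxels whose impedance changed from the
#'   previous slice (forward losses only, no backward-travelling field).
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(dz = NULL, evanescent = c("zero", "decay"),
                          pad_factor = 2, taper = 10, reflection = FALSE) {
  evanescent <- match.arg(evanescent)
  if (!is.null(dz) && dz <= 0) stop("dz must be > 0", call. = FALSE)
  if (pad_factor < 1) stop("pad_factor must be >= 1", call. = FALSE)
  if (taper < 0) stop("taper must be >= 0", call. = FALSE)
  structure(list(dz = dz, evanescent = evanescent, pad_factor = pad_factor,
                 taper = as.integer(taper), reflection = isTRUE(reflection)),
            class = "solver_config")
}

#' Slice-average propagation constant
#'
#' Area-weighted arithmetic mean of the per-voxel propagation constant
#' `b = 2*pi*f/c` over one transverse slice; used by the spectral
#' diffraction step, while the space step carries each voxel's difference
#' from this average.
#'
#' @param speed_slice matrix of sound speeds (m/s) for the slice.
#' @param frequency Hz.
#' @return scalar `b'` in rad/m (always between the min and max voxel `b`).
#' @export
slice_average_b <- function(speed_slice, frequency) {
  stopifnot(frequency > 0)
  mean(2 * pi * frequency / speed_slice)
}

#' Space-domain step
#'
#' Pointwise multiplies the incoming slice field by
#' `e^{j (b - b') dz} e^{-a dz}` where `b` is the voxel propagation
#' constant, `b'` the slice average, and `a` the attenuation in Np/m
#' (converted from the model's dB/(cm MHz) at the run frequency).  A voxel
#' slower than the slice average (`c < c_bar`, so `b > b'`) therefore
#' accrues extra positive phase relative to its neighbours.
#'
#' @param p_in complex matrix, field at the slice entrance.
#' @param speed_slice,atten_slice property maps for the slice (m/s,
#'   dB/(cm MHz)), same shape as `p_in`.
#' @param b_bar slice-average propagation constant, rad/m.
#' @param frequency Hz.
#' @param dz step distance, m.
#' @param transmission optional matrix of pressure-transmission factors
#'   (reflection mode), applied multiplicatively.
#' @return complex matrix `p'`.
#' @export
space_domain_step <- function(p_in, speed_slice, atten_slice, b_bar,
                              frequency, dz, transmission = NULL) {
  if (!all(dim(p_in) == dim(speed_slice)) ||
      !all(dim(p_in) == dim(atten_slice)))
    stop("field and slice property maps must have identical shapes",
         call. = FALSE)
  b <- 2 * pi * frequency / speed_slice
  a_np <- attenuation_to_neper(atten_slice, frequency)
  out <- p_in * exp(1i * (b - b_bar) * dz - a_np * dz)
  if (!is.null(transmission)) out <- out * transmission
  out
}

#' Spectral-domain diffraction step
#'
#' Multiplies each plane-wave component by the angular-spectrum transfer
#' function `e^{j b' sqrt(1 - alpha^2 - beta^2) dz}` where
#' `alpha = lambda f_x`, `beta = lambda f_y` are the directional cosines
#' and `lambda = 2*pi/b'` the slice-average wavelength.  Components with
#' `alpha^2 + beta^2 > 1` are evanescent and are zeroed or exponentially
#' decayed according to the policy.
#'
#' @param A complex matrix, FFT of the slice field (native FFT ordering).
#' @param b_bar slice-average propagation constant, rad/m.
#' @param dz step distance, m.
#' @param dx,dy lateral sample spacings of the FFT lattice, m.
#' @param evanescent `"zero"` or `"decay"`.
#' @return complex matrix, the propagated spectrum.
#' @export
spectral_step <- function(A, b_bar, dz, dx, dy, evanescent = "zero") {
  lambda <- 2 * pi / b_bar
  alpha <- lambda * fft_freq(nrow(A), dx)
  beta <- lambda * fft_freq(ncol(A), dy)
  s2 <- outer(alpha^2, beta^2, `+`)
  H <- matrix(0 + 0i, nrow(A), ncol(A))
  prop <- s2 <= 1
  H[prop] <- exp(1i * b_bar * sqrt(1 - s2[prop]) * dz)
  if (evanescent == "decay")
    H[!prop] <- exp(-b_bar * sqrt(s2[!prop] - 1) * dz)
  A * H
}

#' 3D complex steady-state pressure volume
#'
#' @param field complex 3D array of pressure (arbitrary linear,
#'   Pa-proportional units).
#' @param grid the (unpadded) model [voxel_grid()].
#' @param frequency Hz.
#' @param meta optional list of drive metadata.
#' @return an object of class `pressure_volume`.
#' @export
pressure_volume <- function(field, grid, frequency, meta = list()) {
  stopifnot(identical(dim(field), as.integer(grid$dims)))
  structure(list(field = field, grid = grid, frequency = frequency,
                 meta = meta),
            class = "pressure_volume")
}

#' @export
print.pressure_volume <- function(x, ...) {
  pk <- peak_info(x)
  cat(sprintf("<pressure_volume> %d x %d x %d, %.3g MHz\n",
              dim(x$field)[1], dim(x$field)[2], dim(x$field)[3],
              x$frequency / 1e6))
  cat(sprintf("  peak |p| = %.4g at voxel (%d, %d, %d), (%.2f, %.2f, %.2f) mm\n",
              pk$magnitude, pk$voxel[1], pk$voxel[2], pk$voxel[3],
              1e3 * pk$position[1], 1e3 * pk$position[2], 1e3 * pk$position[3]))
  invisible(x)
}

#' Location and magnitude of the pressure peak
#'
#' @param p a [pressure_volume()].
#' @param slice optional z slice index restricting the search (e.g. the
#'   focal plane).
#' @return list with `magnitude`, `voxel` (i, j, k) and `position` (m).
#' @export
peak_info <- function(p, slice = NULL) {
  stopifnot(inherits(p, "pressure_volume"))
  mag <- Mod(p$field)
  if (!is.null(slice)) {
    m2 <- mag[, , slice, drop = FALSE]
    w <- which.max(m2)
    idx <- arrayInd(w, dim(m2))
    idx[3] <- slice
  } else {
    idx <- arrayInd(which.max(mag), dim(mag))
  }
  idx <- as.integer(idx)
  list(magnitude = mag[idx[1], idx[2], idx[3]], voxel = idx,
       position = voxel_center(p$grid, idx))
}

#' Complex pressure at a physical point
#'
#' Trilinear interpolation of the complex field (phasor interpolation;
#' the wrapped angle is never interpolated directly).
#'
#' @param p a [pressure_volume()].
#' @param point numeric `(x, y, z)` in meters.
#' @return a complex scalar.
#' @export
pressure_at <- function(p, point) {
  stopifnot(inherits(p, "pressure_volume"))
  interp_complex3(p$field, p$grid, point)
}

#' March a source plane through a model (hybrid angular spectrum)
#'
#' Propagates the steady-state field slice by slice through all `nz`
#' slices of the model: space-domain step, forward 2D FFT, spectral
#' diffraction step, inverse FFT.  The recorded volume holds the unpadded
#' field at the exit of every slice, so slice `k` corresponds to a
#' propagated distance of `k * dz` from the source plane.  Output is
#' linear in the source.
#'
#' @param source a `source_plane` (first model slice).
#' @param model an [acoustic_model()] whose lateral grid matches the
#'   source.
#' @param cfg a [solver_config()].
#' @return a [pressure_volume()] on the model grid.
#' @export
propagate <- function(source, model, cfg = solver_config()) {
  stopifnot(inherits(source, "source_plane"), inherits(model, "acoustic_model"),
            inherits(cfg, "solver_config"))
  g <- model$grid
  if (!all(dim(source$field) == g$dims[1:2]))
    stop("source plane does not match the model's lateral grid", call. = FALSE)
  f <- source$frequency
  dz <- cfg$dz %||% g$spacing[3]
  nx <- g$dims[1]; ny <- g$dims[2]; nz <- g$dims[3]
  npx <- max(nx, as.integer(round(nx * cfg$pad_factor)))
  npy <- max(ny, as.integer(round(ny * cfg$pad_factor)))
  i0 <- (npx - nx) %/% 2L; j0 <- (npy - ny) %/% 2L
  sel_x <- i0 + seq_len(nx); sel_y <- j0 + seq_len(ny)

  P <- pad_zero(source$field, npx, npy, i0, j0)
  w <- if (cfg$taper > 0) taper_window(npx, npy, cfg$taper) else NULL
  out <- array(0 + 0i, g$dims)
  Zprev <- NULL
  for (n in seq_len(nz)) {
    cs <- model$speed[, , n]
    as_ <- model$attenuation[, , n]
    b_bar <- slice_average_b(cs, f)
    cs_p <- pad_replicate(cs, npx, npy, i0, j0)
    as_p <- pad_replicate(as_, npx, npy, i0, j0)
    trans <- NULL
    if (cfg$reflection) {
      Z <- pad_replicate(model$density[, , n] * cs, npx, npy, i0, j0)
      if (!is.null(Zprev)) {
        trans <- 2 * Z / (Zprev + Z)
      }
      Zprev <- Z
    }
    P <- space_domain_step(P, cs_p, as_p, b_bar, f, dz, trans)
    if (!is.null(w)) P <- P * w
    A <- stats::fft(P)
    A <- spectral_step(A, b_bar, dz, g$spacing[1], g$spacing[2],
                       cfg$evanescent)
    P <- stats::fft(A, inverse = TRUE) / (npx * npy)
    if (anyNA(P) || any(!is.finite(Re(P))))
      stop(sprintf("non-finite field at slice %d", n), call. = FALSE)
    out[, , n] <- P[sel_x, sel_y]
  }
  pressure_volume(out, g, f, meta = list(dz = dz, source_z = source$z))
}
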