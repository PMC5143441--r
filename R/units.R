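#' Convert a frequency-normalized attenuation coefficient to Np/m
#'
#' Acoustic models store attenuation frequency-normalized in dB/(cm MHz),
#' the unit in which tissue and plastic attenuation are usually tabulated.
#' The solver needs the amplitude decay rate in nepers per meter at the
#' run frequency:
#' \deqn{a_{Np/m} = a_{dB/(cm\,MHz)} \cdot (f / 10^6) \cdot 100 / (20 \log_{10} e).}
#'
#' @param a attenuation in dB/(cm MHz), >= 0 (scalar, vector or array).
#' @param f acoustic frequency in Hz, > 0.
#' @return attenuation in Np/m, same shape as `a`.
#' @examples
#' attenuation_to_neper(4.72, 1e6)  # ~54.34 Np/m
#' @export
attenuation_to_neper <- function(a, f) {
  if (any(a < 0, na.rm = TRUE))
    stop("attenuation must be non-negative", call. = FALSE)
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0)
    stop("frequency must be a positive scalar (Hz)", call. = FALSE)
  a * (f / 1e6) * 100 / (20 * log10(exp(1)))
}

#' Through-plate phase span of a relief step
#'
#' Closed-form accumulated phase difference at frequency `f` between a ray
#' crossing `d` meters of plate material and one crossing the same distance
#' of water:
#' \deqn{\Delta\phi = 2\pi f\, d\, (1/c_{water} - 1/c_{plate}).}
#' Used to check that an aberrator's relief span covers a full 2*pi of
#' phase aberration (the design rule for the random-relief plate).
#'
#' @param d path-length difference in meters (e.g. the relief span).
#' @param f frequency in Hz.
#' @param c_plate plate sound speed, m/s.
#' @param c_water immersion-medium sound speed, m/s.
#' @return phase difference in radians (positive when the plate is faster).
#' @examples
#' relief_phase_span(4e-3, 1e6, 2492, 1500)  # ~6.67 rad, > 2*pi
#' @export
relief_phase_span <- function(d, f, c_plate, c_water = 1500) {
  stopifnot(d >= 0, f > 0, c_plate > 0, c_water > 0)
  2 * pi * f * d * (1 / c_water - 1 / c_plate)
}

#' Percentage of hydrophone time-reversal pressure recovered
#'
#' Benchmarking convention for simulation-based phase correction: both the
#' simulation-based and the hydrophone (gold-standard time-reversal)
#' corrections are reported as peak-pressure gain factors over the
#' uncorrected case, measured at the same spot.  The recovery percentage is
#' their ratio:
#' \deqn{recovery = 100 \cdot g_{sim} / g_{hydrophone}.}
#'
#' @param simulation_gain corrected/uncorrected peak-pressure factor for
#'   the simulation-based phases.
#' @param hydrophone_gain the same factor for hydrophone time-reversal
#'   phases.
#' @return recovery in percent.
#' @examples
#' pressure_recovery(1.41, 1.50)  # plastic-aberrator benchmark, ~94%
#' @export
pressure_recovery <- function(simulation_gain, hydrophone_gain) {
  stopifnot(simulation_gain > 0, hydrophone_gain > 0)
  100 * simulation_gain / hydrophone_gain
}

#' Parse a length that may carry a unit suffix
#'
#' The command-line interface accepts lengths in meters (bare numbers) or
#' with explicit `mm`, `cm` or `m` suffixes; mixing units silently is a
#' correction-destroying bug class, so suffixes are explicit.
#'
#' @param x character or numeric scalar/vector, e.g. `"5mm"`, `"0.13m"`, `0.02`.
#' @return numeric length(s) in meters.
#' @export
parse_length <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(as.character(x), function(s) {
    s <- trimws(s)
    if (grepl("mm$", s)) as.numeric(sub("mm$", "", s)) * 1e-3
    else if (grepl("cm$", s)) as.numeric(sub("cm$", "", s)) * 1e-2
    else if (grepl("m$", s)) as.numeric(sub("m$", "", s))
    else as.numeric(s)
  }, numeric(1), USE.NAMES = FALSE)
}
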