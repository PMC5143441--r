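#' Build a spherical-cap phased-array transducer
#'
#' The transducer frame has the cap apex at the origin and the beam axis
#' along +z, so the geometric focus (center of curvature) sits at
#' `(0, 0, focal_length)`.  Element centers are placed deterministically on
#' the cap: the default `"spiral"` layout is a Fermat (sunflower) spiral in
#' cap-area coordinates, which packs near-uniformly and assigns every
#' element an equal nominal area `cap_area / n`; `"ring"` places all
#' elements on a single ring at half the aperture angle (useful for exact
#' symmetry).  Alternatively a hardware layout is loaded verbatim from a
#' CSV file with columns `x,y,z,nx,ny,nz,area` (SI units, header required).
#'
#' @param n_elements number of elements (>= 1).
#' @param aperture_diameter circular aperture diameter, m (must be
#'   < 2 * focal_length).
#' @param focal_length radius of curvature, m.
#' @param frequency drive frequency, Hz.
#' @param layout_kind `"spiral"` or `"ring"`.
#' @param seed unused by the deterministic layouts; accepted so callers can
#'   treat layout generation like the other seeded generators.
#' @param layout_file optional CSV path overriding the generated layout.
#' @return an object of class `transducer_array` with element `centers`
#'   (n x 3, m), `normals` (n x 3, unit, towards the focus), `areas` (m^2),
#'   and complex `drive` (unit amplitude, zero phase by default).
#' @export
build_spherical_array <- function(n_elements = 256,
                                  aperture_diameter = 0.145,
                                  focal_length = 0.13,
                                  frequency = 1e6,
                                  layout_kind = c("spiral", "ring"),
                                  seed = NULL, layout_file = NULL) {
  layout_kind <- match.arg(layout_kind)
  if (aperture_diameter >= 2 * focal_length)
    stop("aperture too large for the focal length", call. = FALSE)
  if (frequency <= 0) stop("frequency must be > 0", call. = FALSE)
  a <- aperture_diameter / 2
  R <- focal_length
  theta_max <- asin(a / R)
  cap_area <- 2 * pi * R^2 * (1 - cos(theta_max))

  if (!is.null(layout_file)) {
    lay <- read_layout_csv(layout_file)
    centers <- as.matrix(lay[, c("x", "y", "z")])
    normals <- as.matrix(lay[, c("nx", "ny", "nz")])
    areas <- lay$area
    n_elements <- nrow(centers)
  } else if (n_elements == 1L) {
    centers <- matrix(c(0, 0, 0), 1, 3)
    normals <- matrix(c(0, 0, 1), 1, 3)
    areas <- cap_area
  } else if (layout_kind == "spiral") {
    pts <- cap_spiral_points(n_elements, R, theta_max)
    centers <- pts
    normals <- normals_to_focus(pts, R)
    areas <- rep(cap_area / n_elements, n_elements)
  } else {
    th <- theta_max / 2
    phi <- 2 * pi * (seq_len(n_elements) - 1) / n_elements
    centers <- cbind(R * sin(th) * cos(phi), R * sin(th) * sin(phi),
                     R - R * cos(th))
    normals <- normals_to_focus(centers, R)
    areas <- rep(cap_area / n_elements, n_elements)
  }
  structure(list(frequency = frequency, focal_length = focal_length,
                 aperture_diameter = aperture_diameter,
                 centers = centers, normals = normals, areas = areas,
                 drive = rep(1 + 0i, n_elements),
                 cap_area = cap_area, theta_max = theta_max),
            class = "transducer_array")
}

# Fermat spiral in cap-area coordinates: point i sits at the polar angle
# enclosing area fraction (i - 0.5)/n of the cap, azimuth stepped by the
# golden angle.  Near-uniform equal-area packing.
cap_spiral_points <- function(n, R, theta_max) {
  i <- seq_len(n)
  t <- (i - 0.5) / n
  costh <- 1 - t * (1 - cos(theta_max))
  theta <- acos(pmin(1, pmax(-1, costh)))
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  cbind(R * sin(theta) * cos(phi), R * sin(theta) * sin(phi),
        R - R * cos(theta))
}

normals_to_focus <- function(centers, R) {
  focus <- c(0, 0, R)
  d <- sweep(-centers, 2, focus, `+`)  # focus - center
  d / sqrt(rowSums(d^2))
}

#' @export
print.transducer_array <- function(x, ...) {
  cat(sprintf("<transducer_array> %d elements, %.3g MHz\n",
              nrow(x$centers), x$frequency / 1e6))
  cat(sprintf("  aperture %.3g cm, focal length %.3g cm, cap area %.4g cm^2\n",
              1e2 * x$aperture_diameter, 1e2 * x$focal_length, 1e4 * x$cap_area))
  invisible(x)
}

#' Geometric (water-path) steering phases
#'
#' The uncorrected steering baseline: per-element drive phases that
#' compensate the homogeneous-water path-length differences so all
#' contributions arrive in phase at the target,
#' `phi_i = -k_ref * (|center_i - target| - focal_length)`, referenced to
#' the geometric focus (where all path lengths equal the focal length and
#' all phases are zero).  Under the project's `e^{-j omega t}` convention
#' forward propagation accrues phase `+k r`, so the compensating drive
#' phase is the negative path-length phase.
#'
#' @param array a [build_spherical_array()].
#' @param target numeric `(x, y, z)` in the transducer frame, m.
#' @param c_ref reference (water) sound speed, m/s.
#' @return numeric vector of per-element phases, wrapped to `(-pi, pi]`.
#' @export
geometric_phases <- function(array, target, c_ref = 1500) {
  stopifnot(inherits(array, "transducer_array"), length(target) == 3L)
  k <- 2 * pi * array$frequency / c_ref
  d <- sqrt(colSums((t(array$centers) - as.numeric(target))^2))
  wrap_phase(-k * (d - array$focal_length))
}

#' Sub-source discretization of the transducer cap
#'
#' Flat-piston sub-sources at spacing `<= ds` (default half a wavelength
#' in the coupling medium, the standard Rayleigh-Sommerfeld accuracy
#' bound), placed by an equal-area spiral over the cap and assigned to the
#' nearest element center.  Compute once and pass to
#' [element_source_plane()] when looping over elements.
#'
#' @param array a [build_spherical_array()].
#' @param ds sub-source spacing, m (`NULL` = half wavelength).
#' @param c_medium coupling-medium sound speed used for the default `ds`.
#' @return list with `points` (ns x 3, m), `element` (index per
#'   sub-source) and `area` (m^2 per sub-source).
#' @export
array_subsources <- function(array, ds = NULL, c_medium = 1500) {
  if (is.null(ds)) ds <- (c_medium / array$frequency) / 2
  ns <- max(nrow(array$centers), ceiling(array$cap_area / ds^2))
  pts <- cap_spiral_points(ns, array$focal_length, array$theta_max)
  # nearest element center (chunked to bound memory)
  n <- nrow(array$centers)
  elem <- integer(ns)
  step <- 20000L
  cn <- array$centers
  for (s in seq(1L, ns, by = step)) {
    e <- min(s + step - 1L, ns)
    blk <- pts[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rep(1, n)) +
      outer(rep(1, e - s + 1L), rowSums(cn^2)) - 2 * blk %*% t(cn)
    elem[s:e] <- max.col(-d2)
  }
  list(points = pts, element = elem, area = array$cap_area / ns)
}

#' Complex pressure of one element on the simulation entry plane
#'
#' Rayleigh-Sommerfeld summation over flat-piston sub-sources discretizing
#' the element surface (spacing <= half a wavelength by default),
#' propagated through homogeneous water to the grid's entry plane
#' (`z = grid origin z` by default).  The result is linear in the
#' element's complex drive.  Pressure units are Pa-proportional with unit
#' normal velocity: `p = -j rho c k / (2 pi) * sum(e^{(jk - a) r} / r * dS)`.
#'
#' @param array a [build_spherical_array()].
#' @param element_index which element (1-based).
#' @param grid the simulation [voxel_grid()]; the entry plane is its first
#'   slice.
#' @param c_medium,a_medium,rho_medium homogeneous coupling-water
#'   properties (m/s, dB/(cm MHz), kg/m^3).
#' @param subsources optional precomputed [array_subsources()] result
#'   (compute once when looping over elements).
#' @param plane_z optional entry-plane z (m); defaults to the grid origin.
#' @return an object of class `source_plane`: complex `field`
#'   (nx x ny), `z`, `frequency`, `grid`.
#' @export
element_source_plane <- function(array, element_index, grid,
                                 c_medium = 1500, a_medium = 0,
                                 rho_medium = 1000,
                                 subsources = NULL, plane_z = NULL) {
  stopifnot(inherits(array, "transducer_array"), inherits(grid, "voxel_grid"))
  n <- nrow(array$centers)
  if (element_index < 1L || element_index > n)
    stop("element index out of range", call. = FALSE)
  if (is.null(subsources))
    subsources <- array_subsources(array, c_medium = c_medium)
  if (is.null(plane_z)) plane_z <- grid$origin[3]
  sel <- subsources$element == element_index
  S <- subsources$points[sel, , drop = FALSE]
  if (plane_z <= max(S[, 3]))
    stop("entry plane lies behind the element surface", call. = FALSE)
  f <- array$frequency
  k <- 2 * pi * f / c_medium
  a_np <- attenuation_to_neper(a_medium, f)
  x <- grid_coords(grid, 1); y <- grid_coords(grid, 2)
  P <- cbind(rep(x, times = length(y)), rep(y, each = length(x)), plane_z)
  pref <- -1i * rho_medium * c_medium * k / (2 * pi) *
    array$drive[element_index] * subsources$area
  acc <- complex(length.out = nrow(P))
  step <- 512L
  nsub <- nrow(S)
  for (s in seq(1L, nsub, by = step)) {
    e <- min(s + step - 1L, nsub)
    blk <- S[s:e, , drop = FALSE]
    d2 <- outer(rowSums(P^2), rep(1, e - s + 1L)) +
      outer(rep(1, nrow(P)), rowSums(blk^2)) - 2 * P %*% t(blk)
    r <- sqrt(pmax(d2, 1e-300))
    acc <- acc + rowSums(exp((1i * k - a_np) * r) / r)
  }
  field <- matrix(pref * acc, length(x), length(y))
  structure(list(field = field, z = plane_z, frequency = f, grid = grid),
            class = "source_plane")
}

#' Full-array entry-plane field for a set of complex drives
#'
#' Drive-weighted superposition of per-element source planes.  When the
#' per-element planes were computed at unit drive (as in an element field
#' bank), pass them via `planes` to avoid recomputation.
#'
#' @param array a [build_spherical_array()].
#' @param grid the simulation grid.
#' @param drives complex vector, one per element.
#' @param planes optional list of unit-drive `source_plane`s.
#' @param c_medium,a_medium,rho_medium,plane_z as in [element_source_plane()].
#' @return a `source_plane`.
#' @export
full_source_plane <- function(array, grid, drives = NULL, planes = NULL,
                              c_medium = 1500, a_medium = 0,
                              rho_medium = 1000, plane_z = NULL) {
  n <- nrow(array$centers)
  if (is.null(drives)) drives <- array$drive
  if (length(drives) != n) stop("one drive per element required", call. = FALSE)
  if (is.null(planes)) {
    subs <- array_subsources(array, c_medium = c_medium)
    arr_unit <- array; arr_unit$drive <- rep(1 + 0i, n)
    planes <- lapply(seq_len(n), function(i)
      element_source_plane(arr_unit, i, grid, c_medium = c_medium,
                           a_medium = a_medium, rho_medium = rho_medium,
                           subsources = subs, plane_z = plane_z))
  }
  field <- Reduce(`+`, Map(function(p, d) p$field * d, planes, as.complex(drives)))
  structure(list(field = field, z = planes[[1]]$z,
                 frequency = planes[[1]]$frequency, grid = grid),
            class = "source_plane")
}

#' @export
print.source_plane <- function(x, ...) {
  cat(sprintf("<source_plane> %d x %d at z = %.4g mm, %.3g MHz, max |p| = %.4g\n",
              nrow(x$field), ncol(x$field), 1e3 * x$z, x$frequency / 1e6,
              max(Mod(x$field))))
  invisible(x)
}
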