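# Shared desk-scale fixtures.  All fields are generated in code at test
# time; expensive objects (element field banks) are memoised per session.

WATER_C <- 1500
FREQ <- 1e6
LAM <- WATER_C / FREQ  # 1.5 mm

# 64 x 64 x 80 grid at half-wavelength spacing, entry plane at z = 5 mm,
# laterally centered on the beam axis (axis falls between voxels).
test_grid <- function(nz = 80L, dz = LAM / 2) {
  voxel_grid(c(64L, 64L, nz), c(LAM / 2, LAM / 2, dz),
             origin = c(-31.5 * LAM / 2, -31.5 * LAM / 2, 0.005))
}

# Desk-scale focused array: 4 cm aperture, 6 cm focal length.
test_array <- function(n = 16L, layout = "spiral") {
  build_spherical_array(n_elements = n, aperture_diameter = 0.04,
                        focal_length = 0.06, frequency = FREQ,
                        layout_kind = layout)
}

test_water_model <- function(g = test_grid()) {
  make_water_model(g$dims, g$spacing, origin = g$origin)
}

# Uniform or arbitrary source plane on a grid's entry plane.
make_source <- function(g, field = matrix(1 + 0i, g$dims[1], g$dims[2]),
                        frequency = FREQ) {
  structure(list(field = field, z = g$origin[3], frequency = frequency,
                 grid = g),
            class = "source_plane")
}

# Raw solver configuration for analytic oracles (no padding, no taper).
bare_cfg <- function() solver_config(pad_factor = 1, taper = 0)

# Session-level fixture cache for expensive banks.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Default seeded aberrator on the test grid, plate entry at z = 20 mm.
test_aberrator <- function(seed = 42, g = test_grid(), plate_z = 0.02, ...) {
  generate_aberrator(seed, g, plate_z = plate_z, ...)
}

# Seeded RNG scope that restores the caller's state.
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

focus_region <- function(g, kz = NULL) {
  if (is.null(kz)) kz <- nearest_voxel(g, c(0, 0, 0.06))[3]
  list(x = c(1L, g$dims[1]), y = c(1L, g$dims[2]),
       z = c(max(1L, kz - 4L), min(g$dims[3], kz + 4L)))
}

# Two aberrators differing only in relief feature scale: 50% contour area
# of the phasor autocorrelation, and the misregistration response over a
# 5 x 5 shift lattice spanning +/- 3 mm (shifts comparable to the finer
# feature scale, where decoherence dominates).  "Flatter" = off-origin
# ratios closer to 1: higher mean retained pressure, smaller RMS deviation.
feature_scale_linkage <- function() {
  g <- test_grid()
  arr <- test_array(16)
  cfg <- solver_config()
  models <- list(fine = test_aberrator(seed = 21, feature_scale = 3e-3),
                 broad = test_aberrator(seed = 21, feature_scale = 10e-3))
  area50 <- vapply(models, function(ab) {
    plm <- phase_length_map(ab$model, FREQ)
    unname(phasor_autocorrelation(plm, aperture_radius = 8e-3)$areas_mm2["50%"])
  }, numeric(1))
  sh <- c(-4L, -2L, 0L, 2L, 4L) * g$spacing[1]
  stats <- vapply(models, function(ab) {
    bank <- simulate_element_bank(arr, ab$model, cfg, region = focus_region(g))
    sol <- correction_phases(bank, c(0, 0, 0.06))
    rm_ <- misregistration_map(arr, ab$model, cfg, sol, sh, sh,
                               planes = bank$planes)
    off_origin <- row(rm_$values) != 3L | col(rm_$values) != 3L
    c(mean = mean(rm_$values[off_origin]),
      rms = sqrt(mean((rm_$values[off_origin] - 1)^2)))
  }, c(mean = 0, rms = 0))
  list(area50 = area50, mean_retained = stats["mean", ],
       rms_dev = stats["rms", ])
}
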