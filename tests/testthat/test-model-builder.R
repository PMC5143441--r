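test_that("water model fills constant properties and propagation constant", {
  m <- make_water_model(c(8, 8, 8), rep(1e-3, 3), c_water = 1500, a_water = 0)
  expect_true(all(m$speed == 1500))
  expect_true(all(m$attenuation == 0))
  expect_true(all(m$density == 1000))
  b <- propagation_constant(m, 1e6)
  expect_equal(unname(b[1, 1, 1]), 2 * pi * 1e6 / 1500, tolerance = 1e-12)
  expect_equal(max(abs(b - 4188.7902)), 0, tolerance = 1e-4)
  expect_true(all(attenuation_to_neper(m$attenuation, 1e6) == 0))
  expect_error(make_water_model(c(8, 8, 8), rep(1e-3, 3), c_water = -1),
               "positive")
  expect_error(make_water_model(c(8, 8, 8), rep(1e-3, 3), rho_water = 0),
               "positive")
})

test_that("attenuation unit conversion is exact and linear in frequency", {
  expect_equal(attenuation_to_neper(4.72, 1e6), 4.72 * 100 / 8.685889638,
               tolerance = 1e-9)
  expect_equal(attenuation_to_neper(4.72, 1e6), 54.34, tolerance = 1e-4)
  expect_equal(attenuation_to_neper(0, 3.7e6), 0)
  expect_equal(attenuation_to_neper(1.3, 2e6), 2 * attenuation_to_neper(1.3, 1e6))
  expect_error(attenuation_to_neper(-1, 1e6), "non-negative")
})

test_that("aberrator is deterministic, spans the design thickness range, and is water-immersed", {
  g <- test_grid()
  ab1 <- test_aberrator(seed = 7)
  ab2 <- test_aberrator(seed = 7)
  expect_identical(ab1$heightmap$heights, ab2$heightmap$heights)
  expect_identical(ab1$model$speed, ab2$model$speed)
  ab3 <- test_aberrator(seed = 8)
  expect_false(identical(ab1$heightmap$heights, ab3$heightmap$heights))

  tt <- total_thickness(ab1$heightmap)
  expect_true(all(tt >= 7.5e-3 - 1e-12))
  expect_true(all(tt <= 11.5e-3 + 1e-12))
  expect_equal(range(ab1$heightmap$heights), c(0, 4e-3), tolerance = 1e-12)

  # first and last slices are water (immersion)
  expect_true(all(ab1$model$speed[, , 1] == 1500))
  expect_true(all(ab1$model$speed[, , g$dims[3]] == 1500))
  # plate voxels carry plate properties
  expect_true(any(ab1$model$speed == 2492))
  expect_identical(ab1$model$speed == 2492, ab1$model$attenuation == 4.72)
})

test_that("degenerate relief gives a uniform flat plate", {
  ab <- test_aberrator(seed = 1, max_relief = 0)
  expect_true(all(ab$heightmap$heights == 0))
  nplate <- apply(ab$model$speed == 2492, c(1, 2), sum)
  expect_true(all(nplate == nplate[1, 1]))
})

test_that("default relief span covers a full 2*pi of phase at 1 MHz", {
  span <- relief_phase_span(4e-3, 1e6, 2492, 1500)
  expect_equal(span, 2 * pi * 1e6 * 4e-3 * (1 / 1500 - 1 / 2492),
               tolerance = 1e-12)
  expect_equal(span, 6.67, tolerance = 1e-2)
  expect_gte(span, 2 * pi)
})

test_that("aberrator geometry errors are raised for too-thin grids", {
  g <- voxel_grid(c(16, 16, 8), rep(1e-3, 3))
  expect_error(generate_aberrator(1, g, base_thickness = 7.5e-3,
                                  max_relief = 4e-3), "too thin|does not fit")
  expect_error(generate_aberrator(1, test_grid(), base_thickness = -1),
               "base_thickness")
})

test_that("HU mapping: background exact, clamped endpoints, monotone curves", {
  cfg <- hu_mapping_config()
  g <- voxel_grid(c(4, 4, 4), rep(1e-3, 3))
  hu <- hu_volume(g, 0)
  m <- map_hu_to_properties(hu, cfg)
  expect_true(all(m$speed == cfg$background$speed))
  expect_true(all(m$attenuation == cfg$background$attenuation))
  expect_true(all(m$density == cfg$background$density))

  top <- max(cfg$speed_knots$hu)
  hu2 <- hu_volume(g, top)
  m2 <- map_hu_to_properties(hu2, cfg)
  expect_true(all(m2$speed == max(cfg$speed_knots$value)))
  expect_warning(map_hu_to_properties(hu_volume(g, top + 5000), cfg),
                 "clamped")
  m3 <- suppressWarnings(map_hu_to_properties(hu_volume(g, top + 5000), cfg))
  expect_identical(m3$speed, m2$speed)

  # monotone over a random HU sample in the bone range
  hus <- sort(with_seed_test(99, runif(50, cfg$hu_threshold, top + 200)))
  vol <- hu_volume(voxel_grid(c(50, 1, 1), rep(1e-3, 3)),
                   array(hus, c(50, 1, 1)))
  mm <- suppressWarnings(map_hu_to_properties(vol, cfg))
  expect_true(all(diff(mm$speed[, 1, 1]) >= 0))
  expect_true(all(diff(mm$attenuation[, 1, 1]) >= 0))
  expect_true(all(diff(mm$density[, 1, 1]) >= 0))
  # distinct HU map to distinct speeds between knots
  expect_gt(length(unique(mm$speed[, 1, 1])), 40)
})

test_that("HU mapping config rejects invalid curves", {
  expect_error(hu_mapping_config(density_slope = -1), "slope")
  expect_error(hu_mapping_config(speed_knots = data.frame(
    hu = c(300, 200), value = c(1500, 1600))), "increasing")
  expect_error(hu_mapping_config(attenuation_knots = data.frame(
    hu = c(300, 400), value = c(5, 1))), "monotone")
})

test_that("synthetic skull phantom is deterministic with controllable texture", {
  g <- test_grid(nz = 48L)
  s1 <- generate_synthetic_skull(11, g, thickness_scale = 10e-3)
  s2 <- generate_synthetic_skull(11, g, thickness_scale = 10e-3)
  expect_identical(s1$hu, s2$hu)
  s3 <- generate_synthetic_skull(12, g, thickness_scale = 10e-3)
  expect_false(identical(s1$hu, s3$hu))

  # zero texture amplitude -> homogeneous HU inside the slab
  s0 <- generate_synthetic_skull(11, g, texture_amplitude = 0)
  inside <- s0$hu != 0
  expect_true(any(inside))
  expect_equal(length(unique(s0$hu[inside])), 1L)

  # lateral autocorrelation length of the thickness map is long
  th <- attr(s1, "thickness")
  d <- th - mean(th)
  ac <- Re(stats::fft(Mod(stats::fft(d))^2, inverse = TRUE))
  ac <- ac / ac[1, 1]
  # half-height lag along x (periodic autocorrelation, lags 0..nx-1)
  lag_half <- which(ac[, 1] < 0.5)[1] - 1L
  expect_gte(lag_half, 4L)
})

test_that("model translation is voxel-quantized with exact inverses", {
  ab <- test_aberrator(seed = 3)
  m <- ab$model
  dx <- m$grid$spacing[1]
  expect_identical(translate_model(m, c(0, 0)), m)
  fwd <- translate_model(m, c(3 * dx, -2 * dx))
  back <- translate_model(fwd, c(-3 * dx, 2 * dx))
  # interior voxels restored exactly; vacated border came back as water
  expect_equal(back$speed[4:61, 4:61, ], m$speed[4:61, 4:61, ])
  # sub-voxel shifts quantize to the nearest voxel
  expect_identical(translate_model(m, c(0.4 * dx, 0)), m)
  expect_identical(translate_model(m, c(0.6 * dx, 0))$speed,
                   translate_model(m, c(dx, 0))$speed)
  # vacated voxels are background water
  shifted <- translate_model(m, c(5 * dx, 0))
  expect_true(all(shifted$speed[1:5, , ] == m$background$speed))
  # homogeneous model is translation invariant
  w <- test_water_model()
  expect_identical(translate_model(w, c(4 * dx, 2 * dx))$speed, w$speed)
  expect_error(translate_model(m, c(100 * dx * 64, 0)), "exceeds")
})
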