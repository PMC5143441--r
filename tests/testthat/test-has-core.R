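test_that("slice-average propagation constant is the arithmetic mean", {
  sl <- matrix(1500, 8, 8)
  expect_equal(slice_average_b(sl, 1e6), 2 * pi * 1e6 / 1500, tolerance = 1e-12)
  expect_equal(slice_average_b(sl, 1e6), 4188.79, tolerance = 1e-5)
  sl[1:4, ] <- 2492
  b1 <- 2 * pi * 1e6 / 1500; b2 <- 2 * pi * 1e6 / 2492
  expect_equal(slice_average_b(sl, 1e6), (b1 + b2) / 2, tolerance = 1e-12)
  expect_gte(slice_average_b(sl, 1e6), b2)
  expect_lte(slice_average_b(sl, 1e6), b1)
})

test_that("space-domain step: identity, attenuation decay, sign convention", {
  p <- matrix(complex(modulus = 1, argument = seq(0, 1, length.out = 64)), 8, 8)
  sl <- matrix(1500, 8, 8)
  a0 <- matrix(0, 8, 8)
  b_bar <- slice_average_b(sl, 1e6)
  expect_equal(space_domain_step(p, sl, a0, b_bar, 1e6, 1e-3), p,
               tolerance = 1e-14)

  av <- matrix(4.72, 8, 8)  # 54.34 Np/m at 1 MHz
  out <- space_domain_step(p, sl, av, b_bar, 1e6, 1e-3)
  expect_equal(Mod(out) / Mod(p), matrix(exp(-0.0543410), 8, 8),
               tolerance = 1e-6)

  # a voxel slower than the slice average accrues extra positive phase
  sl2 <- sl; sl2[3, 3] <- 1400
  b_bar2 <- slice_average_b(sl2, 1e6)
  out2 <- space_domain_step(p, sl2, a0, b_bar2, 1e6, 1e-3)
  dphi <- Arg(out2 / p)
  expect_gt(dphi[3, 3], dphi[1, 1])
  expect_equal(dphi[3, 3] - dphi[1, 1],
               (2 * pi * 1e6 / 1400 - 2 * pi * 1e6 / 1500) * 1e-3,
               tolerance = 1e-9)
  expect_error(space_domain_step(p, matrix(1500, 4, 4), a0, b_bar, 1e6, 1e-3),
               "shape")
})

test_that("spectral step endpoint identities and evanescent policies", {
  # lattice chosen so alpha = 0.25 * m exactly: n = 16, dx = lambda/4
  n <- 16L
  lam <- 1.5e-3
  dx <- lam / 4
  b_bar <- 2 * pi / lam
  dz <- 1e-3
  A <- matrix(0 + 0i, n, n)
  A[1, 1] <- 1   # alpha = beta = 0
  out <- spectral_step(A, b_bar, dz, dx, dx)
  expect_equal(out[1, 1], exp(1i * b_bar * dz), tolerance = 1e-12)

  A2 <- matrix(0 + 0i, n, n); A2[5, 1] <- 1  # alpha = 1, beta = 0 (grazing)
  out2 <- spectral_step(A2, b_bar, dz, dx, dx)
  expect_equal(out2[5, 1], 1 + 0i, tolerance = 1e-12)

  # alpha = 1, beta = 0.5: alpha^2 + beta^2 = 1.25, sqrt(0.25) = 0.5 decay
  A3 <- matrix(0 + 0i, n, n); A3[5, 3] <- 1
  expect_equal(spectral_step(A3, b_bar, dz, dx, dx, "zero")[5, 3], 0 + 0i)
  out3 <- spectral_step(A3, b_bar, dz, dx, dx, "decay")
  expect_equal(Mod(out3[5, 3]), exp(-0.5 * b_bar * dz), tolerance = 1e-12)
})

test_that("plane wave in lossless water propagates as e^{jkz} exactly", {
  g <- test_grid(nz = 40L, dz = LAM / 4)
  m <- test_water_model(g)
  v <- propagate(make_source(g), m, bare_cfg())
  k <- 2 * pi * FREQ / WATER_C
  for (nstep in c(1L, 13L, 40L)) {
    expect_lt(max(Mod(v$field[, , nstep] - exp(1i * k * nstep * g$spacing[3]))),
              1e-6)
  }
})

test_that("uniform lossy medium reproduces e^{-az} exactly for a plane wave", {
  g <- test_grid(nz = 40L, dz = LAM / 4)
  m <- make_water_model(g$dims, g$spacing, a_water = 4.72, origin = g$origin)
  v <- propagate(make_source(g), m, bare_cfg())
  a_np <- attenuation_to_neper(4.72, FREQ)
  z <- seq_len(40) * g$spacing[3]
  decay <- vapply(seq_len(40), function(n) max(Mod(v$field[, , n])), numeric(1))
  expect_equal(decay, exp(-a_np * z), tolerance = 1e-9)
})

test_that("propagation is linear in the source", {
  g <- test_grid(nz = 16L)
  m <- test_aberrator(seed = 5, g = g, plate_z = 0.008,
                      base_thickness = 3e-3, max_relief = 2e-3)$model
  s1 <- with_seed_test(1, matrix(complex(real = rnorm(64 * 64),
                                         imaginary = rnorm(64 * 64)), 64, 64))
  s2 <- with_seed_test(2, matrix(complex(real = rnorm(64 * 64),
                                         imaginary = rnorm(64 * 64)), 64, 64))
  cfg <- solver_config()
  v1 <- propagate(make_source(g, s1), m, cfg)
  v2 <- propagate(make_source(g, s2), m, cfg)
  v12 <- propagate(make_source(g, s1 + s2), m, cfg)
  expect_equal(v12$field, v1$field + v2$field, tolerance = 1e-10)
})

test_that("energy over propagating components is conserved in lossless water", {
  g <- test_grid(nz = 24L)
  m <- test_water_model(g)
  # smooth apodized source with negligible evanescent content
  x <- grid_coords(g, 1); y <- grid_coords(g, 2)
  field <- exp(-(outer(x^2, y^2, `+`)) / (2 * (4e-3)^2)) *
    exp(1i * 2 * pi * x / 30e-3)
  v <- propagate(make_source(g, field), m, bare_cfg())
  lam_w <- WATER_C / FREQ
  fx <- hasim:::fft_freq(64, g$spacing[1])
  s2 <- outer((lam_w * fx)^2, (lam_w * fx)^2, `+`)
  prop <- s2 <= 1
  energy <- vapply(seq_len(24), function(n) {
    A <- stats::fft(v$field[, , n])
    sum(Mod(A[prop])^2)
  }, numeric(1))
  expect_lt(max(abs(energy - energy[1])) / energy[1], 1e-9)
})

test_that("point-to-point transmission through a uniform slab is reciprocal", {
  g <- test_grid(nz = 30L)
  # laterally uniform slab: plate layers across the full aperture
  speed <- array(WATER_C, g$dims)
  speed[, , 10:16] <- 2492
  m <- acoustic_model(g, speed, 0, 1000)
  cfg <- bare_cfg()
  src_at <- function(i, j) {
    f <- matrix(0 + 0i, 64, 64); f[i, j] <- 1
    make_source(g, f)
  }
  fwd <- propagate(src_at(22, 32), m, cfg)$field[45, 35, 30]
  rev <- propagate(src_at(45, 35), m, cfg)$field[22, 32, 30]
  expect_lt(Mod(fwd - rev) / Mod(fwd), 1e-2)
})

test_that("focused bowl on-axis pressure matches the O'Neil solution within 5%", {
  f <- FREQ; c0 <- WATER_C; rho <- 1000
  A <- 0.06; ap <- 0.03; a <- ap / 2
  arr <- build_spherical_array(1, ap, A, f)
  g <- voxel_grid(c(128L, 128L, 200L), c(3.5e-4, 3.5e-4, LAM / 4),
                  origin = c(-63.5 * 3.5e-4, -63.5 * 3.5e-4, 0.02))
  sp <- cached("oneil_source", element_source_plane(arr, 1, g))
  v <- cached("oneil_volume", propagate(sp, test_water_model(g), solver_config()))
  z <- 0.02 + seq_len(200) * g$spacing[3]
  h <- A - sqrt(A^2 - a^2)
  oneil <- function(z) {
    rb <- sqrt((z - h)^2 + a^2)
    2 * rho * c0 * abs(sin(2 * pi * f / c0 * (rb - z) / 2)) / abs(1 - z / A)
  }
  # the beam axis falls between voxels: bilinear value at (0,0) is the
  # mean of the four central voxels
  p_axis <- vapply(seq_len(200), function(n) Mod(mean(v$field[64:65, 64:65, n])),
                   numeric(1))
  sel <- z >= 0.050 & z <= 0.070
  expect_lt(max(abs(p_axis[sel] - oneil(z[sel]))) / max(oneil(z[sel])), 0.05)
})

test_that("halving the marching step changes the focal pressure by < 1%", {
  f <- FREQ
  arr <- build_spherical_array(1, 0.03, 0.06, f)
  mk <- function(dz, nz) {
    g <- voxel_grid(c(64L, 64L, nz), c(7e-4, 7e-4, dz),
                    origin = c(-31.5 * 7e-4, -31.5 * 7e-4, 0.0225))
    sp <- element_source_plane(arr, 1, g)
    v <- propagate(sp, test_water_model(g), solver_config())
    # focus z = 60 mm is slice (0.06 - 0.0225)/dz
    kz <- as.integer(round((0.06 - 0.0225) / dz))
    mean(v$field[32:33, 32:33, kz])
  }
  p_coarse <- mk(LAM / 4, 110L)
  p_fine <- mk(LAM / 8, 220L)
  expect_lt(Mod(p_coarse - p_fine) / Mod(p_fine), 0.01)
})

test_that("reflection mode applies the plane-wave transmission factor", {
  g <- test_grid(nz = 20L)
  speed <- array(WATER_C, g$dims); dens <- array(1000, g$dims)
  speed[, , 8:20] <- 2492; dens[, , 8:20] <- 1180
  m <- acoustic_model(g, speed, 0, dens)
  cfg_off <- bare_cfg()
  cfg_on <- solver_config(pad_factor = 1, taper = 0, reflection = TRUE)
  v_off <- propagate(make_source(g), m, cfg_off)
  v_on <- propagate(make_source(g), m, cfg_on)
  Z1 <- 1000 * WATER_C; Z2 <- 1180 * 2492
  Tp <- 2 * Z2 / (Z1 + Z2)
  expect_equal(Mod(v_on$field[32, 32, 20]) / Mod(v_off$field[32, 32, 20]),
               Tp, tolerance = 1e-9)
})

test_that("non-finite fields abort with the slice index named", {
  g <- test_grid(nz = 6L)
  m <- test_water_model(g)
  bad <- matrix(1 + 0i, 64, 64); bad[1, 1] <- NaN
  expect_error(propagate(make_source(g, bad), m, bare_cfg()), "slice 1")
})
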