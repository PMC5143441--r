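test_that("single-element bank equals a direct propagation", {
  g <- test_grid()
  m <- test_water_model(g)
  arr <- test_array(1)
  cfg <- solver_config()
  bank <- simulate_element_bank(arr, m, cfg, region = focus_region(g))
  sp <- element_source_plane(arr, 1, g)
  direct <- propagate(sp, m, cfg)
  r <- bank$region
  expect_equal(bank$fields[[1]],
               direct$field[r$x[1]:r$x[2], r$y[1]:r$y[2], r$z[1]:r$z[2]],
               tolerance = 1e-12)
})

test_that("drive-weighted bank sum equals the full-array simulation", {
  g <- test_grid()
  ab <- cached("aberrator42", test_aberrator(seed = 42))
  arr <- test_array(16)
  cfg <- solver_config()
  bank <- cached("bank_ab42", {
    simulate_element_bank(arr, ab$model, cfg, region = focus_region(g))
  })
  drives <- with_seed_test(4, exp(1i * runif(16, -pi, pi)))
  src <- full_source_plane(arr, g, drives = drives, planes = bank$planes)
  full <- propagate(src, ab$model, cfg)
  r <- bank$region
  manual <- Reduce(`+`, Map(function(f, d) f * d, bank$fields, drives))
  expect_equal(manual,
               full$field[r$x[1]:r$x[2], r$y[1]:r$y[2], r$z[1]:r$z[2]],
               tolerance = 1e-9)
})

test_that("symmetric elements see equal phases at the geometric focus", {
  g <- test_grid()
  m <- test_water_model(g)
  arr <- build_spherical_array(4, 0.04, 0.06, FREQ, layout_kind = "ring")
  subs <- array_subsources(arr, ds = LAM / 4)
  p <- vapply(1:4, function(i) {
    pl <- element_source_plane(arr, i, g, subsources = subs)
    pressure_at(propagate(pl, m, solver_config()), c(0, 0, 0.06))
  }, complex(1))
  expect_lt(diff(range(Arg(p))), 1e-3)
})

test_that("conjugate phases reproduce the recorded phases and align phasors", {
  g <- test_grid()
  bank <- cached("bank_ab42", {
    simulate_element_bank(test_array(16), cached("aberrator42", test_aberrator(seed = 42))$model,
                          solver_config(), region = focus_region(g))
  })
  target <- c(0, 0, 0.06)
  sol <- correction_phases(bank, target)
  expect_true(all(sol$phases > -pi & sol$phases <= pi))
  expect_equal(sol$phases, hasim:::wrap_phase(-Arg(sol$p_target)),
               tolerance = 1e-12)
  # phasor alignment: coherent magnitude is exactly the sum of moduli
  expect_equal(Mod(sum(sol$p_target * exp(1i * sol$phases))),
               sum(Mod(sol$p_target)), tolerance = 1e-12)
})

test_that("conjugate solution matches an exhaustive phase search (3 elements)", {
  g <- test_grid()
  m <- test_water_model(g)
  arr <- test_array(3)
  bank <- simulate_element_bank(arr, m, solver_config(),
                                region = focus_region(g))
  target <- c(2e-3, -1e-3, 0.06)
  p <- correction_phases(bank, target)$p_target
  conj_val <- sum(Mod(p))
  # brute force over a 64^3 phase lattice (element 1 fixed by global
  # rotation invariance: rotate so its phase is the conjugate one)
  ph <- seq(-pi, pi, length.out = 65L)[-65L]
  grid2 <- expand.grid(ph2 = ph, ph3 = ph)
  vals <- Mod(p[1] * exp(1i * (-Arg(p[1]))) +
              p[2] * exp(1i * grid2$ph2) + p[3] * exp(1i * grid2$ph3))
  best <- which.max(vals)
  # exhaustive maximum never beats the conjugate solution and approaches
  # it within the lattice resolution
  expect_lte(max(vals), conj_val + 1e-9)
  expect_gt(max(vals), conj_val * (1 - 2 * (2 * pi / 64)^2))
  dphi2 <- hasim:::wrap_phase(grid2$ph2[best] - (-Arg(p[2])))
  dphi3 <- hasim:::wrap_phase(grid2$ph3[best] - (-Arg(p[3])))
  expect_lt(abs(dphi2), 2 * pi / 64)
  expect_lt(abs(dphi3), 2 * pi / 64)
})

test_that("multi-target solutions are pure lookups with duplicate stability", {
  g <- test_grid()
  bank <- cached("bank_ab42", {
    simulate_element_bank(test_array(16), cached("aberrator42", test_aberrator(seed = 42))$model,
                          solver_config(), region = focus_region(g))
  })
  kz <- nearest_voxel(g, c(0, 0, 0.06))[3]
  zf <- grid_coords(g, 3)[kz]
  targets <- c(list(c(0, 0, zf), c(0, 0, zf)),
               lapply(1:100, function(i)
                 c((i %% 10 - 5) * 1e-3, (i %/% 10 - 5) * 1e-3, zf)))
  t0 <- Sys.time()
  sols <- multi_target_solutions(bank, targets)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  expect_identical(sols[[1]]$phases, sols[[2]]$phases)
  expect_length(sols, 102L)
  expect_lt(elapsed, 5)  # lookups, not simulations
  expect_error(correction_phases(bank, c(0, 0, 0.09)), "outside")
})

test_that("water-path correction at the focus has near-zero phase spread", {
  g <- test_grid()
  bank <- cached("bank_water12", {
    simulate_element_bank(test_array(12), test_water_model(g), solver_config(),
                          region = focus_region(g))
  })
  sol <- correction_phases(bank, c(0, 0, 0.06))
  expect_lt(diff(range(sol$phases)), 1e-1)
})

test_that("zero amplitude at the target yields phase 0 with a warning", {
  g <- test_grid()
  bank <- simulate_element_bank(test_array(2), test_water_model(g),
                                solver_config(), region = focus_region(g))
  bank$fields[[2]][] <- 0 + 0i
  expect_warning(sol <- correction_phases(bank, c(0, 0, 0.06)), "zero amplitude")
  expect_identical(sol$phases[2], 0)
})

test_that("corrected field beats zero phases through the aberrator and is self-consistent", {
  g <- test_grid()
  ab <- cached("aberrator42", test_aberrator(seed = 42))
  arr <- test_array(16)
  cfg <- solver_config()
  bank <- cached("bank_ab42", {
    simulate_element_bank(arr, ab$model, cfg, region = focus_region(g))
  })
  target <- c(0, 0, 0.06)
  sol <- correction_phases(bank, target)
  corr <- cached("corr_ab42", corrected_field(arr, ab$model, cfg, sol,
                                              planes = bank$planes))
  unc <- cached("unc_ab42", {
    propagate(full_source_plane(arr, g, drives = rep(1 + 0i, 16),
                                planes = bank$planes), ab$model, cfg)
  })
  expect_gt(Mod(pressure_at(corr, target)), Mod(pressure_at(unc, target)))
  # full corrected simulation at the target equals the aligned bank sum
  expect_equal(Mod(pressure_at(corr, target)), sum(Mod(sol$p_target)),
               tolerance = 1e-6)
  # phase at the target is zero (all contributions aligned)
  expect_lt(abs(Arg(pressure_at(corr, target))), 1e-6)

  # in-silico time reversal: re-running each element and reading the
  # phase at the target reproduces the bank phases exactly
  subs <- array_subsources(arr)
  virt <- vapply(c(3L, 11L), function(i) {
    pl <- element_source_plane(arr, i, g, subsources = subs)
    Arg(pressure_at(propagate(pl, ab$model, cfg), target))
  }, numeric(1))
  expect_equal(hasim:::wrap_phase(-virt), sol$phases[c(3L, 11L)],
               tolerance = 1e-9)
})

test_that("water correction to the focus peaks within one voxel of the target", {
  g <- test_grid()
  m <- test_water_model(g)
  arr <- test_array(16)
  cfg <- solver_config()
  bank <- cached("bank_water16", {
    simulate_element_bank(arr, m, cfg, region = focus_region(g))
  })
  sol <- correction_phases(bank, c(0, 0, 0.06))
  corr <- corrected_field(arr, m, cfg, sol, planes = bank$planes)
  expect_lte(corr$meta$peak_target_distance_mm, 1e3 * sqrt(2) * g$spacing[1])
})

test_that("bank checkpointing resumes without recomputation", {
  g <- test_grid(nz = 24L)
  m <- test_aberrator(seed = 9, g = g, plate_z = 0.008,
                      base_thickness = 3e-3, max_relief = 2e-3)$model
  arr <- test_array(6)
  cfg <- solver_config()
  ck <- file.path(tempdir(), "bank_ckpt_test")
  unlink(ck, recursive = TRUE)
  region <- list(x = c(1L, 64L), y = c(1L, 64L), z = c(20L, 24L))
  b1 <- simulate_element_bank(arr, m, cfg, region = region,
                              checkpoint_dir = ck)
  expect_identical(b1$n_computed, 6L)
  # resume: nothing recomputed, identical results
  b2 <- simulate_element_bank(arr, m, cfg, region = region,
                              checkpoint_dir = ck)
  expect_identical(b2$n_computed, 0L)
  expect_identical(b2$fields, b1$fields)
  # partial checkpoint loss: only the missing elements are recomputed
  unlink(file.path(ck, c("element_0002.rds", "element_0005.rds")))
  b3 <- simulate_element_bank(arr, m, cfg, region = region,
                              checkpoint_dir = ck)
  expect_identical(b3$n_computed, 2L)
  expect_equal(b3$fields, b1$fields, tolerance = 1e-14)
  unlink(ck, recursive = TRUE)
})
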