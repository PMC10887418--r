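test_that("curve generator records truth and is deterministic", {
  s <- cell_setup()
  cu <- simulate_curve(7000, s$settings, s$tip, s$cal, contact_index = 700,
                       seed = 9)
  expect_equal(cu$labels$truth$contact_index, 700)
  expect_equal(cu$labels$truth$true_modulus_pa, 7000)
  cu2 <- simulate_curve(7000, s$settings, s$tip, s$cal, contact_index = 700,
                        seed = 9)
  expect_identical(cu$deflection, cu2$deflection)
  cu3 <- simulate_curve(7000, s$settings, s$tip, s$cal, contact_index = 700,
                        seed = 10)
  expect_false(identical(cu$deflection, cu3$deflection))
  expect_error(simulate_curve(7000, s$settings, s$tip, s$cal,
                              noise_force_frac = -0.1), ">= 0")
})

test_that("generator/fitter inversion holds for any modulus", {
  s <- cryo_setup()
  for (E in c(800, 12e6)) {
    cu <- simulate_curve(E, s$settings, s$tip, s$cal, noise_force_frac = 0)
    expect_lt(abs(fit_modulus(cu, s$settings)$modulus_pa - E) / E, 1e-6)
  }
})

test_that("volume generator writes an exact truth map", {
  s <- cell_setup()
  sc <- two_region_scene(4, 4, c(5000, 15000), noise_force_frac = 0,
                         seed = 3, n_samples = 256, contact_index = 90)
  vol <- simulate_volume(sc, s$settings, s$tip, s$cal)
  expect_length(vol$curves, 16)
  expect_equal(sort(unique(as.vector(vol$labels$truth_map_pa))),
               c(5000, 15000))
  expect_equal(vol$labels$truth_map_pa[1, 1], 5000)   # lesion = left half
  expect_equal(vol$labels$truth_map_pa[1, 4], 15000)
  truths <- vapply(vol$curves, function(cu) cu$labels$truth$true_modulus_pa,
                   numeric(1))
  expect_equal(matrix(truths, 4, 4, byrow = TRUE), vol$labels$truth_map_pa)

  # same scene, different seed: same truth, different noise
  sc2 <- two_region_scene(4, 4, c(5000, 15000), noise_force_frac = 0.02,
                          seed = 4, n_samples = 256, contact_index = 90)
  sc3 <- two_region_scene(4, 4, c(5000, 15000), noise_force_frac = 0.02,
                          seed = 5, n_samples = 256, contact_index = 90)
  v2 <- simulate_volume(sc2, s$settings, s$tip, s$cal)
  v3 <- simulate_volume(sc3, s$settings, s$tip, s$cal)
  expect_equal(v2$labels$truth_map_pa, v3$labels$truth_map_pa)
  expect_false(identical(v2$curves[[1]]$deflection,
                         v3$curves[[1]]$deflection))
})

test_that("scene masks must partition the grid", {
  m1 <- matrix(FALSE, 2, 2); m1[1, ] <- TRUE
  expect_error(scene_spec(2, 2, list(list(mask = m1, modulus_pa = 1000,
                                          label = "a"))), "partition")
  expect_error(scene_spec(2, 2, list(list(mask = matrix(TRUE, 2, 2),
                                          modulus_pa = -5, label = "a"))),
               "positive")
})

test_that("thermal trace generator hits the equipartition variance", {
  kB <- 1.380649e-23
  tr <- simulate_thermal_trace(0.4, 298, 65536, seed = 2)
  target <- 0.971 * kB * 298 / 0.4
  expect_lt(abs(var(tr$deflection_m) - target) / target, 0.03)
  tr2 <- simulate_thermal_trace(0.4, 298, 65536, seed = 2)
  expect_identical(tr$deflection_m, tr2$deflection_m)
  # doubling T doubles the variance (same draws, rescaled)
  trT <- simulate_thermal_trace(0.4, 298 * 1.1, 65536, seed = 2)
  expect_equal(var(trT$deflection_m) / var(tr$deflection_m), 1.1,
               tolerance = 1e-10)
})

test_that("cell image generator is reproducible and overlap-safe", {
  spec <- cell_population_spec(5, image_size_px = 256, seed = 8)
  s1 <- simulate_cell_image(spec)
  s2 <- simulate_cell_image(spec)
  expect_identical(s1$image, s2$image)
  expect_equal(nrow(s1$truth), 5)
  expect_true(all(s1$truth$aspect_ratio >= 1))
  # impossible packing errors out with advice
  expect_error(simulate_cell_image(cell_population_spec(
    60, area_mean_um2 = 900, image_size_px = 128, seed = 1)), "larger")
})

test_that("two-group generator is reproducible and validated", {
  g1 <- simulate_two_groups(list("normal", mean = 1, sd = 2),
                            list("exponential", rate = 0.5), 10, 12,
                            seed = 3)
  g2 <- simulate_two_groups(list("normal", mean = 1, sd = 2),
                            list("exponential", rate = 0.5), 10, 12,
                            seed = 3)
  expect_identical(g1$a, g2$a)
  expect_identical(g1$b, g2$b)
  expect_length(g1$b, 12)
  expect_error(simulate_two_groups(list("normal"), list("normal"), 2, 5),
               ">= 3")
  expect_error(simulate_two_groups(list("beta"), list("normal"), 5, 5),
               "unknown distribution")
})

test_that("reference moduli fixture carries the seeded study values", {
  ref <- reference_moduli()
  expect_equal(ref$nhm_2d, 4)
  expect_equal(ref$ic8_hsr_section, 16000)
  expect_equal(ref$t1c3_hsr_section, 12000)
  expect_equal(ref$ic8_t1c3_2d_ratio, 2)
})
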