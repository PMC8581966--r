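test_that("generators are deterministic under a fixed seed", {
  cfg <- generator_config(seed = 77, noise_frac = 0.05)
  bands <- carboxylate_bands()
  a <- gen_action_scans(bands, fingerprint_grid(), cfg = cfg)
  b <- gen_action_scans(bands, fingerprint_grid(), cfg = cfg)
  expect_identical(a, b)
  t <- seq(0, 20, length.out = 8)
  ta <- gen_kinetic_trace(2.5e-10, 2.4e8, t, cfg = cfg)
  tb <- gen_kinetic_trace(2.5e-10, 2.4e8, t, cfg = cfg)
  expect_identical(ta, tb)
})

test_that("zero-amplitude bands give fragment-free scans and an all-zero spectrum", {
  bands <- data.frame(center_cm1 = 1600, fwhm_cm1 = 30, peak_f = 0)
  scans <- gen_action_scans(bands, fingerprint_grid(),
                            cfg = generator_config(noise_frac = 0))
  sp <- build_action_spectrum(scans, precursor_mz = 649.8,
                              fragment_mz = c(632.7, 448.9, 126.9))
  expect_true(all(sp$yield == 0))
  too_much <- data.frame(center_cm1 = 1600, fwhm_cm1 = 30, peak_f = 1.0)
  expect_error(gen_action_scans(too_much, fingerprint_grid()), ">= 1")
})

test_that("kinetic traces follow the closed-form exponential and branching rules", {
  tr <- gen_kinetic_trace(2.53e-10, 2.414e8, c(0, 2),
                          cfg = generator_config(noise_frac = 0))
  expect_equal(tr$fractions$parent[2], exp(-2.53e-10 * 2.414e8 * 2),
               tolerance = 1e-12)
  expect_equal(tr$fractions$parent[2], 0.885, tolerance = 1e-3)
  still <- gen_kinetic_trace(0, 2.414e8, 0:5,
                             cfg = generator_config(noise_frac = 0))
  expect_true(all(still$fractions$parent == 1))
  expect_error(gen_kinetic_trace(1e-10, 1e8, 0:3,
                                 branching = c(a = 0.5, b = 0.2)),
               "sum to 1")
})

test_that("mobility generator round-trips exactly without noise", {
  truth <- list(A = 350, B = 0.55, edc = 1.41)
  analytes <- data.frame(mz = 649.8, z = -1, ccs_A2 = c(209, 215))
  ds <- gen_mobility_dataset(truth, polyala_ladder(), analytes,
                             cfg = generator_config(noise_frac = 0))
  cal <- fit_tw_calibration(ds$calibrants, edc = 1.41)
  expect_equal(cal$A, 350, tolerance = 1e-8)
  expect_equal(cal$B, 0.55, tolerance = 1e-8)
  back <- drift_to_ccs(ds$truth$analyte_td_ms, 649.8, -1, cal)
  expect_equal(back, c(209, 215), tolerance = 1e-6 / 209)
  # the later mobilogram peak belongs to the larger CCS
  expect_true(all(diff(ds$truth$analyte_td_ms) > 0))
  fit <- deconvolve_mobilogram(ds$mobilogram, 2)
  expect_equal(fit$components$center_ms, sort(ds$truth$analyte_td_ms),
               tolerance = 1e-3)
})

test_that("single-analyte mobilograms have one peak", {
  truth <- list(A = 350, B = 0.55, edc = 1.41)
  ds <- gen_mobility_dataset(truth, polyala_ladder(),
                             data.frame(mz = 649.8, z = -1, ccs_A2 = 209),
                             cfg = generator_config(noise_frac = 0))
  fit <- deconvolve_mobilogram(ds$mobilogram, 1)
  expect_equal(length(fit$apparent_maxima_ms), 1)
  expect_error(gen_mobility_dataset(truth, polyala_ladder(),
                                    data.frame(mz = 649.8, z = -1, ccs_A2 = -5)))
})

test_that("toy geometries have the stated deterministic layout", {
  chain <- gen_toy_geometry("chain", n_atoms = 5, spacing = 1.5)
  expect_equal(max(chain$atoms$x) - min(chain$atoms$x), 6.0)
  pair0 <- gen_toy_geometry("sphere_pair", separation = 0)
  expect_equal(nrow(pair0$atoms), 2)
  expect_equal(dist(pair0$atoms[, c("x", "y", "z")])[1], 0)
  ring <- gen_toy_geometry("ring", n_atoms = 6, spacing = 1.5)
  d <- as.matrix(dist(ring$atoms[, c("x", "y", "z")]))
  expect_equal(d[1, 2], 1.5, tolerance = 1e-12)
  expect_error(gen_toy_geometry("helix"))
})

test_that("generator output survives the CSV formats the readers consume", {
  scans <- gen_action_scans(carboxylate_bands(), seq(1500, 1700, 10),
                            cfg = generator_config(seed = 5))
  p <- withr::local_tempfile(fileext = ".csv")
  write_scans_csv(scans, p)
  back <- read_scans_csv(p)
  sp1 <- build_action_spectrum(scans, 649.8, c(632.7, 448.9, 126.9))
  sp2 <- build_action_spectrum(back, 649.8, c(632.7, 448.9, 126.9))
  expect_equal(sp2$yield, sp1$yield, tolerance = 1e-12)
  tr <- gen_kinetic_trace(2.5e-10, 2.4e8, seq(0, 20, 4),
                          cfg = generator_config(seed = 5))
  pt <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, pt)
  tr2 <- read_trace_csv(pt)
  expect_equal(fit_pseudo_first_order(tr2)$k_prime,
               fit_pseudo_first_order(tr)$k_prime, tolerance = 1e-9)
})
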