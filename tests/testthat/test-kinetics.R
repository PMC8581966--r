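# Independent cgs oracle for the Langevin capture rate, coded from the
# closed form k_L = 2 pi e sqrt(alpha / mu) with its own constants.
langevin_oracle <- function(m_ion, m_neutral, alpha_A3) {
  mu <- m_ion * m_neutral / (m_ion + m_neutral) * 1.66054e-24
  2 * pi * 4.80320e-10 * sqrt(alpha_A3 * 1e-24 / mu)
}

test_that("semilog fit recovers exact exponential decay to machine precision", {
  t <- seq(0, 5, by = 1)
  tr <- kinetic_trace(t, data.frame(parent = exp(-0.5 * t),
                                    product = 1 - exp(-0.5 * t)))
  fit <- fit_pseudo_first_order(tr)
  expect_equal(fit$k_prime, 0.5, tolerance = 1e-10)
  expect_lt(fit$stderr, 1e-10)
  const <- kinetic_trace(t, data.frame(parent = rep(1, 6), product = rep(0, 6)))
  expect_equal(fit_pseudo_first_order(const)$k_prime, 0)
})

test_that("nonpositive parent points are excluded with a warning", {
  t <- 0:5
  p <- c(exp(-0.5 * t[1:5]), 0)
  tr <- kinetic_trace(t, data.frame(parent = p, product = 1 - p))
  expect_warning(fit <- fit_pseudo_first_order(tr), "excluded")
  expect_equal(fit$k_prime, 0.5, tolerance = 1e-10)
  short <- kinetic_trace(0:2, data.frame(parent = c(1, 0, 0), product = c(0, 1, 1)))
  expect_warning(expect_error(fit_pseudo_first_order(short), ">= 3"))
})

test_that("seeded noisy decays are recovered within a few percent in median", {
  t <- seq(0, 6, length.out = 10)
  ks <- vapply(1:50, function(s) {
    tr <- gen_kinetic_trace(0.5, 1, t, cfg = generator_config(seed = s,
                                                              noise_frac = 0.02))
    fit_pseudo_first_order(tr)$k_prime
  }, numeric(1))
  expect_lt(abs(stats::median(ks) - 0.5) / 0.5, 0.05)
})

test_that("number density follows the ideal-gas law with linear factors", {
  expect_equal(number_density(1e-8, 300), 2.414e8, tolerance = 1e-3)
  expect_equal(number_density(1e-8, 300, calibration_factor = 2),
               2 * number_density(1e-8, 300))
  expect_error(number_density(-1, 300), "positive")
  # reference-reaction calibration: a gauge reading under-reporting by 1/f
  # yields factor f back from the measured pseudo-first-order rate
  n_true <- number_density(3e-8, 300)
  k_prime_ref <- 1.1e-9 * n_true
  expect_equal(gauge_factor_from_reference(k_prime_ref, 1e-8, 300), 3,
               tolerance = 1e-12)
})

test_that("channel rates divide k' by density and split flux by abundance ratio", {
  cr <- channel_rates(0.0611, 2.414e8)
  expect_equal(cr$k_exp, 2.53e-10, tolerance = 5e-3)
  expect_equal(cr$channels$k, cr$k_exp)
  two <- channel_rates(0.0611, 2.414e8,
                       product_abundances = c(proton_transfer = 22, adduct = 7))
  expect_equal(sum(two$channels$k), two$k_exp)
  expect_equal(two$channels$k[1] / two$channels$k[2], 22 / 7)
  expect_equal(sum(two$channels$branching), 1)
  expect_warning(channel_rates(0.1, 1e8, product_abundances = c(a = 0, b = 0)),
                 "zero total product")
})

test_that("capture rates reduce to the Langevin closed form for nonpolar neutrals", {
  k <- collision_rate_ado(16.031, 16.031, alpha_A3 = 2.59, dipole_D = 0)
  expect_equal(k, langevin_oracle(16.031, 16.031, 2.59), tolerance = 1e-4)
  expect_warning(k0 <- collision_rate_ado(100, 50, alpha_A3 = 0, dipole_D = 0),
                 "no long-range capture")
  expect_equal(k0, 0)
})

test_that("dipole enhancement behaves as parametrized trajectory theory requires", {
  kl <- collision_rate_ado(649.78, 114.02, 5.3, 0)
  kado <- collision_rate_ado(649.78, 114.02, 5.3, 2.28)
  expect_gt(kado, kl)
  # the published magnitude for TFA capture by a m/z ~650 anion
  expect_equal(kado, 1.14e-9, tolerance = 0.10)
  # k_ADO -> k_L as the dipole vanishes
  expect_equal(collision_rate_ado(649.78, 114.02, 5.3, 1e-8), kl,
               tolerance = 1e-5)
  # decreasing in temperature for polar neutrals
  k250 <- collision_rate_ado(649.78, 114.02, 5.3, 2.28, temperature_k = 250)
  k400 <- collision_rate_ado(649.78, 114.02, 5.3, 2.28, temperature_k = 400)
  expect_gt(k250, kado)
  expect_lt(k400, kado)
  # the two fit branches join continuously at x = 2
  a <- 5.3e-24; kb <- 1.380649e-16
  t_star <- (2.28e-18 / 2)^2 / (2 * a * kb)  # temperature where x = 2
  lo <- collision_rate_ado(649.78, 114.02, 5.3, 2.28, temperature_k = t_star * 0.999)
  hi <- collision_rate_ado(649.78, 114.02, 5.3, 2.28, temperature_k = t_star * 1.001)
  expect_equal(lo, hi, tolerance = 1e-3)
  # langevin variant ignores the dipole
  expect_equal(collision_rate_ado(649.78, 114.02, 5.3, 2.28,
                                  variant = "langevin"), kl)
})

test_that("efficiencies reproduce the tabulated percentages", {
  expect_equal(round(efficiency(2.53e-10, 1.14e-9)), 22)
  expect_equal(round(efficiency(1.12e-10, 1.14e-9)), 10)
  expect_equal(efficiency(1.14e-9, 1.14e-9), 100)
  expect_error(efficiency(1e-10, 0), "positive")
})

test_that("the full kinetics chain recovers generator truth at realistic noise", {
  n <- 2.414e8
  t <- seq(0, 30, length.out = 12)
  tr <- gen_kinetic_trace(2.53e-10, n, t,
                          branching = c(proton_transfer = 0.76, adduct = 0.24),
                          cfg = generator_config(seed = 21, noise_frac = 0.02))
  fit <- fit_pseudo_first_order(tr)
  last <- nrow(tr$fractions)
  cr <- channel_rates(fit$k_prime, n,
                      product_abundances = unlist(tr$fractions[last, -1]),
                      k_ado = 1.14e-9)
  expect_equal(cr$k_exp, 2.53e-10, tolerance = 0.30)
  expect_equal(sum(cr$channels$k), cr$k_exp)
  expect_equal(cr$efficiency_pct, 22, tolerance = 0.35)
})
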