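#!/usr/bin/env Rscript
# Ion-molecule kinetics with trifluoroacetic acid (TFA). Synthetic FT-ICR
# traces are generated at the tabulated magnitudes (k_exp 2.53e-10 and
# 1.12e-10 cm^3 s^-1 for the T3 and rT3 anions, neutral density from a
# 1e-8 mbar reading at 300 K) with proton-transfer and TFA-addition
# channels, then fitted back: semilog k', division by density, competitive
# branching, Su-Chesnavich capture rate and efficiency.
suppressPackageStartupMessages(library(ionchem))

n <- number_density(1e-8, 300)
cat(sprintf("neutral number density at 1e-8 mbar, 300 K: %.3e cm^-3\n", n))
k_ado <- collision_rate_ado(649.78, 114.02, alpha_A3 = 5.3, dipole_D = 2.28,
                            temperature_k = 300)
cat(sprintf("k_ADO (TFA + m/z 650 anion, Su-Chesnavich): %.3e cm^3 s^-1\n", k_ado))

scenarios <- list(
  T3  = list(k_exp = 2.53e-10, branching = c(proton_transfer = 0.76, adduct = 0.24)),
  rT3 = list(k_exp = 1.12e-10, branching = c(proton_transfer = 0.71, adduct = 0.29)))

dir.create("results", showWarnings = FALSE)
rows <- NULL
for (nm in names(scenarios)) {
  sc <- scenarios[[nm]]
  times <- seq(0, 30, length.out = 12)
  tr <- gen_kinetic_trace(sc$k_exp, n, times, branching = sc$branching,
                          cfg = generator_config(seed = 11, noise_frac = 0.02))
  fit <- fit_pseudo_first_order(tr)
  cr <- channel_rates(fit$k_prime, n,
                      product_abundances = unlist(tr$fractions[12, -1]),
                      k_prime_stderr = fit$stderr, k_ado = k_ado)
  cat(sprintf("\n%s + TFA: k' = %.4f s^-1, k_exp = %.3e cm^3 s^-1, eff = %.0f%%\n",
              nm, fit$k_prime, cr$k_exp, cr$efficiency_pct))
  print(cr$channels, digits = 3)
  rows <- rbind(rows, data.frame(isomer = nm, k_prime = fit$k_prime,
                                 k_exp = cr$k_exp, k_ado = k_ado,
                                 efficiency_pct = cr$efficiency_pct))
}
write.csv(rows, "results/kinetics_summary.csv", row.names = FALSE)
cat("\nwrote results/kinetics_summary.csv: the T3 anion reacts ~2x faster.\n")
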