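# Shared fixtures: band templates for the carboxylate-vs-phenolate
# deprotomer problem (diagnostic fingerprint bands: carboxylate asymmetric
# stretch ~1600/1625 cm^-1; carboxylic-acid C=O ~1790 plus phenolate ring
# mode ~1528 cm^-1), and small helpers used across test files.

carboxylate_stick <- function() {
  stick_spectrum("carboxylate", freq_cm1 = c(1636, 1661) / 0.978,
                 intensity = c(1.0, 0.8))
}

phenolate_stick <- function() {
  stick_spectrum("phenolate", freq_cm1 = c(1528, 1790) / 0.978,
                 intensity = c(0.9, 1.0))
}

carboxylate_bands <- function(peak_f = 0.25) {
  data.frame(center_cm1 = c(1636, 1661), fwhm_cm1 = c(30, 30),
             peak_f = peak_f * c(1, 0.8))
}

phenolate_bands <- function(peak_f = 0.25) {
  data.frame(center_cm1 = c(1528, 1790), fwhm_cm1 = c(30, 30),
             peak_f = peak_f * c(0.9, 1))
}

fingerprint_grid <- function() seq(1450, 1850, by = 2)

# Nine-point polyalanine-like calibrant ladder (singly deprotonated n-mers).
polyala_ladder <- function() {
  n <- 3:11
  data.frame(mz = 71.03711 * n + 18.01056 + 1.00728, z = -1,
             ccs_A2 = 150 + 18 * (n - 3))
}
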