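# Seeded synthetic-data generators. Each generator emulates the statistical
# structure one analysis stage assumes (band-shaped photofragmentation
# probability, exponential parent decay with competitive channels, power-law
# mobility calibration with Gaussian mobilogram peaks, toy geometries), so
# the full chain can be exercised without experimental data. Noiseless output
# is exactly inverted by the corresponding analysis stage.

# Run fn under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  fn()
}

#' Default synthetic-noise configuration
#'
#' Multiplicative Gaussian noise (fraction of signal) plus a small additive
#' floor, qualitatively reflecting ion-count statistics.
#'
#' @param seed Integer RNG seed.
#' @param noise_frac Multiplicative Gaussian noise fraction (default 0.02).
#' @param noise_floor Additive noise floor in intensity units (default 0).
#' @return Configuration list.
#' @export
generator_config <- function(seed = 1, noise_frac = 0.02, noise_floor = 0) {
  stopifnot(noise_frac >= 0, noise_floor >= 0)
  list(seed = seed, noise_frac = noise_frac, noise_floor = noise_floor)
}

apply_noise <- function(x, cfg) {
  if (cfg$noise_frac == 0 && cfg$noise_floor == 0) return(x)
  y <- x * (1 + cfg$noise_frac * stats::rnorm(length(x))) +
    cfg$noise_floor * abs(stats::rnorm(length(x)))
  pmax(y, 0)
}

#' Generate synthetic IRMPD fragmentation scans
#'
#' Per photon energy, the fragmented fraction is a sum of Gaussian bands
#' f(E) = sum A_b exp(-4 ln 2 (E - c_b)^2 / w_b^2) (must stay < 1); the
#' precursor carries N (1 - f) counts and the fragment intensity N f is
#' split evenly over the configured fragment m/z values, then noise is
#' applied. With zero noise the downstream yield R = -ln(1 - f) inverts f
#' exactly.
#'
#' @param bands Data frame with columns `center_cm1`, `fwhm_cm1`, `peak_f`
#'   (peak fragmented fraction, in \[0, 1)).
#' @param energies_cm1 Photon-energy grid.
#' @param precursor_mz Precursor m/z (default 649.8).
#' @param fragment_mz Fragment m/z values (default c(632.7, 448.9, 126.9)).
#' @param n_ions Total ion count per scan (default 1000).
#' @param cfg A [generator_config()].
#' @return List of [fragmentation_scan()] objects, one per energy.
#' @export
gen_action_scans <- function(bands, energies_cm1, precursor_mz = 649.8,
                             fragment_mz = c(632.7, 448.9, 126.9),
                             n_ions = 1000, cfg = generator_config()) {
  stopifnot(is.data.frame(bands),
            all(c("center_cm1", "fwhm_cm1", "peak_f") %in% names(bands)))
  f <- rep(0, length(energies_cm1))
  for (b in seq_len(nrow(bands))) {
    f <- f + bands$peak_f[b] *
      exp(-4 * log(2) * (energies_cm1 - bands$center_cm1[b])^2 /
            bands$fwhm_cm1[b]^2)
  }
  if (any(f >= 1)) stop("configured bands give fragmented fraction >= 1")
  with_seed(cfg$seed, function() {
    lapply(seq_along(energies_cm1), function(i) {
      ip <- n_ions * (1 - f[i])
      ifr <- rep(n_ions * f[i] / length(fragment_mz), length(fragment_mz))
      peaks <- data.frame(mz = c(precursor_mz, fragment_mz),
                          intensity = apply_noise(c(ip, ifr), cfg))
      fragmentation_scan(energies_cm1[i], peaks, precursor_mz)
    })
  })
}

#' Generate a synthetic kinetic trace
#'
#' Parent fraction exp(-k_exp n t); products split by the branching vector;
#' noise applied and rows renormalized.
#'
#' @param k_exp True second-order rate constant (cm^3 s^-1).
#' @param n_cm3 Neutral number density (cm^-3).
#' @param times_s Increasing sampling times (s).
#' @param branching Named branching fractions summing to 1.
#' @param cfg A [generator_config()].
#' @return A [kinetic_trace()] with parent column `"parent"`.
#' @export
gen_kinetic_trace <- function(k_exp, n_cm3, times_s,
                              branching = c(product = 1),
                              cfg = generator_config()) {
  stopifnot(k_exp >= 0, n_cm3 > 0, !is.unsorted(times_s))
  if (abs(sum(branching) - 1) > 1e-9) stop("branching must sum to 1")
  parent <- exp(-k_exp * n_cm3 * times_s)
  ab <- data.frame(parent = parent)
  for (nm in names(branching)) ab[[nm]] <- (1 - parent) * branching[[nm]]
  with_seed(cfg$seed, function() {
    noisy <- as.data.frame(lapply(ab, apply_noise, cfg = cfg))
    kinetic_trace(times_s, noisy, parent = "parent")
  })
}

#' Generate a synthetic mobility dataset
#'
#' Builds a calibrant ladder whose drift times follow the inverse of a known
#' power-law calibration (ground truth A, B, EDC), and a mobilogram with one
#' Gaussian peak per analyte at its inverse-mapped drift time. The noiseless
#' round trip through [fit_tw_calibration()] / [drift_to_ccs()] is exact.
#'
#' @param cal_truth List with `A`, `B`, `edc` (and optionally `gas_mass_da`).
#' @param calibrants Data frame `mz`, `z`, `ccs_A2` (reference ladder).
#' @param analytes Data frame `mz`, `z`, `ccs_A2` (and optionally
#'   `amplitude`).
#' @param peak_fwhm_ms Mobilogram peak FWHM in ms (default 0.30).
#' @param grid_step_ms Mobilogram grid step (default 0.01).
#' @param cfg A [generator_config()]; noise perturbs calibrant drift times
#'   (multiplicative) and the mobilogram trace.
#' @return List: `calibrants` (with `td_ms` added), `mobilogram` (data frame
#'   `td_ms`, `intensity`), `truth` (cal_truth plus analyte drift times).
#' @export
gen_mobility_dataset <- function(cal_truth, calibrants, analytes,
                                 peak_fwhm_ms = 0.30, grid_step_ms = 0.01,
                                 cfg = generator_config()) {
  stopifnot(cal_truth$A > 0, cal_truth$B > 0, all(calibrants$ccs_A2 > 0),
            all(analytes$ccs_A2 > 0))
  gas <- cal_truth$gas_mass_da %||% 28.006
  cal <- structure(list(A = cal_truth$A, B = cal_truth$B, edc = cal_truth$edc,
                        gas_mass_da = gas, r_squared = 1, residuals = numeric(0),
                        n = 0L),
                   class = "tw_calibration")
  td_cal <- ccs_to_drift(calibrants$ccs_A2, calibrants$mz, calibrants$z, cal)
  td_ana <- ccs_to_drift(analytes$ccs_A2, analytes$mz, analytes$z, cal)
  amp <- analytes$amplitude %||% rep(1, nrow(analytes))
  sigma <- peak_fwhm_ms / (2 * sqrt(2 * log(2)))
  grid <- seq(max(0.05, min(td_ana) - 6 * sigma), max(td_ana) + 6 * sigma,
              by = grid_step_ms)
  intensity <- rep(0, length(grid))
  for (i in seq_along(td_ana)) {
    intensity <- intensity + gaussian_peak(grid, td_ana[i], sigma, amp[i])
  }
  with_seed(cfg$seed, function() {
    out_cal <- calibrants
    out_cal$td_ms <- td_cal * (1 + cfg$noise_frac * stats::rnorm(length(td_cal)))
    mob <- data.frame(td_ms = grid, intensity = apply_noise(intensity, cfg))
    list(calibrants = out_cal, mobilogram = mob,
         truth = c(cal_truth, list(analyte_td_ms = td_ana)))
  })
}

#' Generate a toy geometry
#'
#' Deterministic toy geometries for projection-CCS testing: a pair of atoms
#' at a given separation, a linear chain, a planar ring, or matched
#' compact/extended variants sharing one composition.
#'
#' @param spec One of `"sphere_pair"`, `"chain"`, `"ring"`.
#' @param n_atoms Number of atoms (chain/ring; >= 2).
#' @param spacing Nearest-neighbour spacing in A (chain/ring; default 1.5).
#' @param separation Pair separation in A (sphere_pair; default 2).
#' @param element Element symbol for all atoms (default "C").
#' @param extended For `"chain"`: `TRUE` gives the straight chain, `FALSE`
#'   folds the same atoms into a compact zigzag ball.
#' @return A [geometry()].
#' @export
gen_toy_geometry <- function(spec = c("sphere_pair", "chain", "ring"),
                             n_atoms = 5, spacing = 1.5, separation = 2,
                             element = "C", extended = TRUE) {
  spec <- match.arg(spec)
  if (spec == "sphere_pair") {
    return(geometry(rep(element, 2), c(0, separation), c(0, 0), c(0, 0),
                    label = sprintf("sphere_pair_d%.2f", separation)))
  }
  if (spec == "ring") {
    stopifnot(n_atoms >= 3)
    r <- spacing / (2 * sin(pi / n_atoms))
    th <- 2 * pi * (seq_len(n_atoms) - 1) / n_atoms
    return(geometry(rep(element, n_atoms), r * cos(th), r * sin(th),
                    rep(0, n_atoms), label = sprintf("ring_%d", n_atoms)))
  }
  stopifnot(n_atoms >= 2)
  if (extended) {
    geometry(rep(element, n_atoms), spacing * (seq_len(n_atoms) - 1),
             rep(0, n_atoms), rep(0, n_atoms),
             label = sprintf("chain_%d_extended", n_atoms))
  } else {
    # compact variant: same composition packed on a small cubic lattice
    side <- ceiling(n_atoms^(1 / 3))
    idx <- seq_len(n_atoms) - 1
    geometry(rep(element, n_atoms),
             spacing * (idx %% side),
             spacing * ((idx %/% side) %% side),
             spacing * (idx %/% (side^2)),
             label = sprintf("chain_%d_compact", n_atoms))
  }
}
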