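# FT-ICR ion-molecule kinetics: pseudo-first-order decay fits on the semilog
# parent trace, pressure-gauge calibration against a reference reaction,
# second-order rate constants with competitive branching, capture rates from
# Langevin / Su-Chesnavich parametrized trajectory theory, and efficiencies.

#' Construct a kinetic trace
#'
#' @param time_s Reaction times in s (>= 0, increasing).
#' @param abundances Data frame (one column per species, parent first) of
#'   nonnegative abundances, one row per time point. Rows are normalized to
#'   sum to one.
#' @param parent Name of the parent-ion column (default: first column).
#' @param neutral Identity of the neutral reagent (metadata).
#' @return Object of class `"kinetic_trace"`.
#' @export
kinetic_trace <- function(time_s, abundances, parent = names(abundances)[1],
                          neutral = NA_character_) {
  stopifnot(is.numeric(time_s), all(time_s >= 0), !is.unsorted(time_s),
            is.data.frame(abundances), nrow(abundances) == length(time_s),
            parent %in% names(abundances))
  if (any(as.matrix(abundances) < 0)) stop("abundances must be >= 0")
  tot <- rowSums(abundances)
  if (any(tot <= 0)) stop("each time point needs positive total abundance")
  structure(list(time_s = time_s,
                 fractions = abundances / tot,
                 parent = parent, neutral = neutral),
            class = "kinetic_trace")
}

#' Pseudo-first-order rate constant from a semilog fit
#'
#' Least-squares line through ln(parent fraction) versus time; k' is the
#' negated slope. Points with nonpositive parent fraction are excluded with
#' a warning.
#'
#' @param trace A [kinetic_trace()].
#' @return List: `k_prime` (s^-1), `stderr`, `n_points`.
#' @export
fit_pseudo_first_order <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  p <- trace$fractions[[trace$parent]]
  t <- trace$time_s
  usable <- p > 0
  if (any(!usable)) {
    warning(sprintf("%d point(s) with nonpositive parent fraction excluded",
                    sum(!usable)))
  }
  if (sum(usable) < 3) stop("need >= 3 usable points for the semilog fit")
  fit <- stats::lm(log(p[usable]) ~ t[usable])
  k <- -unname(stats::coef(fit)[2])
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  list(k_prime = k, stderr = unname(se), n_points = sum(usable))
}

#' Neutral number density from a pressure reading
#'
#' Ideal-gas number density n = P / (k_B T) after correcting the gauge
#' reading by a calibration factor and a species response factor.
#'
#' @param pressure_mbar Gauge reading in mbar (> 0).
#' @param temperature_k Temperature in K (> 0).
#' @param calibration_factor Gauge calibration factor (default 1).
#' @param response_factor Species-specific response factor (default 1).
#' @return Number density in cm^-3.
#' @examples
#' number_density(1e-8, 300)
#' @export
number_density <- function(pressure_mbar, temperature_k,
                           calibration_factor = 1, response_factor = 1) {
  if (pressure_mbar <= 0 || temperature_k <= 0 ||
      calibration_factor <= 0 || response_factor <= 0) {
    stop("pressure, temperature and factors must be positive")
  }
  p_pa <- pressure_mbar * 100 * calibration_factor * response_factor
  (p_pa / (.const$kB_SI * temperature_k)) * 1e-6
}

#' Gauge calibration factor from a reference reaction
#'
#' Infers the gauge calibration factor from a measured pseudo-first-order
#' rate constant for a reference reaction of known second-order rate
#' constant (e.g. CH4+. + CH4 -> CH5+ + CH3., k = 1.1e-9 cm^3 s^-1):
#' factor = k' / (k_ref * n_gauge), where n_gauge is the density implied by
#' the uncorrected reading.
#'
#' @param k_prime_ref Measured pseudo-first-order rate (s^-1).
#' @param pressure_mbar Uncorrected gauge reading during the measurement.
#' @param temperature_k Temperature in K.
#' @param k_ref Reference second-order rate constant in cm^3 s^-1
#'   (default 1.1e-9).
#' @return Calibration factor (dimensionless).
#' @export
gauge_factor_from_reference <- function(k_prime_ref, pressure_mbar,
                                        temperature_k, k_ref = 1.1e-9) {
  stopifnot(k_prime_ref > 0, k_ref > 0)
  n_gauge <- number_density(pressure_mbar, temperature_k)
  k_prime_ref / (k_ref * n_gauge)
}

#' Second-order rate constants with competitive branching
#'
#' k_exp = k' / n; for competitive reactions each channel rate is k_exp
#' multiplied by that product's share of the summed product abundances, so
#' channel rates conserve k_exp exactly.
#'
#' @param k_prime Pseudo-first-order rate (s^-1).
#' @param n_cm3 Neutral number density (cm^-3).
#' @param product_abundances Named nonnegative channel abundances (optional;
#'   a single unnamed channel means all flux in one channel).
#' @param k_prime_stderr Fit standard error on k' (optional).
#' @param k_ado Capture rate constant (cm^3 s^-1, optional); when given,
#'   efficiencies are attached.
#' @param systematic_fraction Relative systematic uncertainty on k_exp
#'   (default 0.30, the conventional absolute-rate error bar).
#' @return Object of class `"channel_rates"`: `k_exp`, `k_exp_uncertainty`,
#'   `channels` (data frame `channel`, `branching`, `k`), and when `k_ado`
#'   is given `k_ado`, `efficiency_pct` (total) and per-channel
#'   `channels$efficiency_pct`.
#' @export
channel_rates <- function(k_prime, n_cm3, product_abundances = c(total = 1),
                          k_prime_stderr = NA_real_, k_ado = NULL,
                          systematic_fraction = 0.30) {
  stopifnot(n_cm3 > 0, k_prime >= 0, all(product_abundances >= 0))
  k_exp <- k_prime / n_cm3
  tot <- sum(product_abundances)
  if (tot == 0) {
    if (k_prime > 0) {
      warning("zero total product abundance with nonzero k'; branching undefined")
    }
    branching <- rep(NA_real_, length(product_abundances))
  } else {
    branching <- product_abundances / tot
  }
  channels <- data.frame(
    channel = names(product_abundances) %||%
      paste0("ch", seq_along(product_abundances)),
    branching = as.numeric(branching),
    k = k_exp * as.numeric(branching))
  stat <- if (is.na(k_prime_stderr) || k_prime == 0) 0 else k_prime_stderr / k_prime
  out <- list(k_exp = k_exp,
              k_exp_uncertainty = k_exp * sqrt(systematic_fraction^2 + stat^2),
              channels = channels)
  if (!is.null(k_ado)) {
    out$k_ado <- k_ado
    out$efficiency_pct <- efficiency(k_exp, k_ado)
    out$channels$efficiency_pct <- efficiency(out$channels$k, k_ado)
  }
  structure(out, class = "channel_rates")
}

#' @export
print.channel_rates <- function(x, ...) {
  cat(sprintf("<channel_rates> k_exp = %.3g cm^3 s^-1 (+/- %.2g)\n",
              x$k_exp, x$k_exp_uncertainty))
  if (!is.null(x$k_ado)) {
    cat(sprintf("  k_ADO = %.3g cm^3 s^-1, efficiency = %.1f%%\n",
                x$k_ado, x$efficiency_pct))
  }
  print(x$channels)
  invisible(x)
}

#' Capture rate constant: Langevin / Su-Chesnavich parametrized trajectory
#'
#' Ion-molecule capture rate in cm^3 s^-1. The Langevin rate
#' k_L = 2 pi q sqrt(alpha / mu) (cgs) applies to nonpolar neutrals; for a
#' polar neutral the Su-Chesnavich parametrized fit to trajectory
#' calculations scales k_L by K(x) with x = mu_D / sqrt(2 alpha k_B T):
#' K = (x + 0.5090)^2 / 10.526 + 0.9754 for x < 2, and
#' K = 0.4767 x + 0.6200 for x >= 2. K(0) = 1 to 1e-5, so the dipole-free
#' limit is Langevin.
#'
#' @param ion_mass_da Ion mass in Da.
#' @param neutral_mass_da Neutral mass in Da.
#' @param alpha_A3 Neutral polarizability in A^3 (>= 0).
#' @param dipole_D Neutral dipole moment in Debye (>= 0).
#' @param temperature_k Temperature in K (default 300).
#' @param variant `"su_chesnavich"` (default) or `"langevin"` (ignores the
#'   dipole).
#' @return Capture rate constant in cm^3 s^-1.
#' @examples
#' collision_rate_ado(649.78, 114.02, alpha_A3 = 5.3, dipole_D = 2.28)
#' @export
collision_rate_ado <- function(ion_mass_da, neutral_mass_da, alpha_A3,
                               dipole_D = 0, temperature_k = 300,
                               variant = c("su_chesnavich", "langevin")) {
  variant <- match.arg(variant)
  stopifnot(ion_mass_da > 0, neutral_mass_da > 0, alpha_A3 >= 0,
            dipole_D >= 0, temperature_k > 0)
  if (alpha_A3 == 0 && dipole_D == 0) {
    warning("alpha = 0 and dipole = 0: no long-range capture, returning 0")
    return(0)
  }
  mu_g <- ion_mass_da * neutral_mass_da / (ion_mass_da + neutral_mass_da) *
    .const$amu_g
  alpha_cgs <- alpha_A3 * 1e-24
  k_l <- 2 * pi * .const$e_cgs * sqrt(alpha_cgs / mu_g)
  if (variant == "langevin" || dipole_D == 0) return(k_l)
  mud <- dipole_D * .const$debye_cgs
  kbt2a <- sqrt(2 * alpha_cgs * .const$kB_cgs * temperature_k)
  x <- if (alpha_cgs > 0) mud / kbt2a else Inf
  if (x < 2) {
    k_l * ((x + 0.5090)^2 / 10.526 + 0.9754)
  } else {
    # written so the alpha -> 0 limit stays finite: k_L * x has no alpha
    pref <- 2 * pi * .const$e_cgs / sqrt(mu_g)
    pref * (0.4767 * mud / sqrt(2 * .const$kB_cgs * temperature_k) +
              0.6200 * sqrt(alpha_cgs))
  }
}

#' Reaction efficiency
#'
#' Percentage of capture collisions that are reactive:
#' phi = 100 * k_exp / k_ADO. Rounding to an integer is left to the report
#' layer.
#'
#' @param k_exp Second-order rate constant (cm^3 s^-1).
#' @param k_ado Capture rate constant (cm^3 s^-1, > 0).
#' @return Efficiency in percent.
#' @examples
#' efficiency(2.53e-10, 1.14e-9)
#' @export
efficiency <- function(k_exp, k_ado) {
  if (any(k_ado <= 0)) stop("k_ADO must be positive")
  100 * k_exp / k_ado
}
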