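# Traveling-wave ion mobility: power-law calibration of EDC-corrected drift
# times against reference CCS values, drift-time -> CCS conversion, and
# Gaussian-mixture deconvolution of overlapping mobilogram peaks.

# Reduced mass (Da) of ion (from m/z and charge) and drift gas.
tw_reduced_mass <- function(mz, z, gas_mass_da) {
  m_ion <- mz * abs(z)
  m_ion * gas_mass_da / (m_ion + gas_mass_da)
}

# Enhanced-duty-cycle (EDC) corrected drift time (ms).
tw_corrected_time <- function(td_ms, mz, edc) td_ms - edc * sqrt(mz) / 1000

#' Fit a traveling-wave CCS calibration
#'
#' Standard TWIMS power-law calibration: drift times are corrected for the
#' m/z-dependent transfer delay (EDC coefficient), reference CCS values are
#' reduced by charge and reduced mass with the drift gas,
#' CCS' = CCS * sqrt(mu) / |z|, and ln CCS' is regressed on ln t_d' to give
#' CCS' = A * t_d'^B.
#'
#' @param calibrants Data frame with columns `mz`, `z`, `ccs_A2` (reference
#'   CCS in A^2) and `td_ms` (measured drift time in ms); >= 2 rows.
#' @param edc EDC delay coefficient (default 1.41).
#' @param gas_mass_da Drift-gas mass in Da (default 28.006, N2).
#' @return Object of class `"tw_calibration"`: `A`, `B`, `edc`,
#'   `gas_mass_da`, `r_squared`, `residuals` (in ln CCS'), `n`.
#' @export
fit_tw_calibration <- function(calibrants, edc = 1.41, gas_mass_da = 28.006) {
  stopifnot(is.data.frame(calibrants),
            all(c("mz", "z", "ccs_A2", "td_ms") %in% names(calibrants)))
  if (nrow(calibrants) < 2) stop("need >= 2 calibration points")
  tdp <- tw_corrected_time(calibrants$td_ms, calibrants$mz, edc)
  bad <- which(tdp <= 0)
  if (length(bad)) {
    stop(sprintf("nonpositive corrected drift time for calibrant row(s) %s",
                 paste(bad, collapse = ", ")))
  }
  mu <- tw_reduced_mass(calibrants$mz, calibrants$z, gas_mass_da)
  ccs_red <- calibrants$ccs_A2 * sqrt(mu) / abs(calibrants$z)
  fit <- stats::lm(log(ccs_red) ~ log(tdp))
  r2 <- if (nrow(calibrants) > 2) suppressWarnings(summary(fit)$r.squared) else 1
  structure(list(A = exp(unname(stats::coef(fit)[1])),
                 B = unname(stats::coef(fit)[2]),
                 edc = edc, gas_mass_da = gas_mass_da,
                 r_squared = r2,
                 residuals = unname(stats::residuals(fit)),
                 n = nrow(calibrants)),
            class = "tw_calibration")
}

#' @export
print.tw_calibration <- function(x, ...) {
  cat(sprintf("<tw_calibration> CCS' = %.4g * td'^%.4g (n = %d, R^2 = %.6f)\n",
              x$A, x$B, x$n, x$r_squared))
  invisible(x)
}

#' Convert a drift time to CCS
#'
#' @param td_ms Drift time in ms.
#' @param mz Ion m/z.
#' @param z Signed charge.
#' @param cal A [fit_tw_calibration()] result.
#' @return CCS in A^2.
#' @export
drift_to_ccs <- function(td_ms, mz, z, cal) {
  stopifnot(inherits(cal, "tw_calibration"))
  tdp <- tw_corrected_time(td_ms, mz, cal$edc)
  if (any(tdp <= 0)) stop("nonpositive corrected drift time")
  mu <- tw_reduced_mass(mz, z, cal$gas_mass_da)
  cal$A * tdp^cal$B * abs(z) / sqrt(mu)
}

#' Invert a calibration: CCS to drift time
#'
#' @param ccs_A2 CCS in A^2.
#' @inheritParams drift_to_ccs
#' @return Drift time in ms.
#' @export
ccs_to_drift <- function(ccs_A2, mz, z, cal) {
  stopifnot(inherits(cal, "tw_calibration"), all(ccs_A2 > 0))
  mu <- tw_reduced_mass(mz, z, cal$gas_mass_da)
  tdp <- (ccs_A2 * sqrt(mu) / (abs(z) * cal$A))^(1 / cal$B)
  tdp + cal$edc * sqrt(mz) / 1000
}

gaussian_peak <- function(t, center, sigma, amp) {
  amp * exp(-(t - center)^2 / (2 * sigma^2))
}

#' Deconvolve a mobilogram into Gaussian components
#'
#' Nonlinear least-squares fit (Levenberg-Marquardt) of a one- or
#' two-Gaussian mixture to a drift-time trace. The two components share one
#' width: for isomers at the same m/z the peak width is instrumental, and the
#' shared width keeps the strongly overlapped fit well conditioned. Starting
#' values come from intensity moments of the baseline-thresholded trace, the
#' fit is restricted to the signal window, and centers are box-constrained to
#' it. For two components the apparent maxima of the fitted sum are reported
#' alongside the fitted centers: overlapping peaks pull the observable maxima
#' toward each other, so apparent maxima and true component centers differ.
#'
#' @param mobilogram Data frame with columns `td_ms` (increasing) and
#'   `intensity` (>= 0), >= 10 points.
#' @param n_components 1 or 2.
#' @return List of class `"mobilogram_fit"`: `components` (data frame
#'   `center_ms`, `fwhm_ms`, `area`, sorted by center), `apparent_maxima_ms`,
#'   `fit` (the `nls` object).
#' @export
deconvolve_mobilogram <- function(mobilogram, n_components = 1) {
  stopifnot(is.data.frame(mobilogram),
            all(c("td_ms", "intensity") %in% names(mobilogram)))
  if (!n_components %in% c(1, 2)) stop("n_components > 2 unsupported")
  t_all <- mobilogram$td_ms
  y_all <- mobilogram$intensity
  if (sum(y_all > max(y_all) * 0.01) < 10) stop("need >= 10 points above baseline")
  w <- pmax(y_all - 0.1 * max(y_all), 0)
  mu0 <- sum(t_all * w) / sum(w)
  sd0 <- sqrt(sum((t_all - mu0)^2 * w) / sum(w))
  keep <- abs(t_all - mu0) < 5 * sd0
  t <- t_all[keep]
  y <- y_all[keep]
  fwhm_of <- function(s) 2 * sqrt(2 * log(2)) * abs(s)
  if (n_components == 1) {
    fit <- minpack.lm::nlsLM(
      y ~ gaussian_peak(t, c1, s1, a1),
      start = list(c1 = mu0, s1 = sd0, a1 = max(y)),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    p <- stats::coef(fit)
    comps <- data.frame(center_ms = p[["c1"]],
                        fwhm_ms = fwhm_of(p[["s1"]]),
                        area = abs(p[["a1"]] * p[["s1"]]) * sqrt(2 * pi))
  } else {
    fit <- minpack.lm::nlsLM(
      y ~ gaussian_peak(t, c1, s1, a1) + gaussian_peak(t, c2, s1, a2),
      start = list(c1 = mu0 - 0.55 * sd0, c2 = mu0 + 0.55 * sd0,
                   s1 = 0.75 * sd0, a1 = max(y), a2 = max(y)),
      lower = c(mu0 - 3 * sd0, mu0 - 3 * sd0, 1e-4, 0, 0),
      upper = c(mu0 + 3 * sd0, mu0 + 3 * sd0, 3 * sd0, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    p <- stats::coef(fit)
    comps <- data.frame(
      center_ms = c(p[["c1"]], p[["c2"]]),
      fwhm_ms = fwhm_of(c(p[["s1"]], p[["s1"]])),
      area = abs(c(p[["a1"]], p[["a2"]]) * p[["s1"]]) * sqrt(2 * pi))
    comps <- comps[order(comps$center_ms), , drop = FALSE]
    rownames(comps) <- NULL
  }
  if (!fit$convInfo$isConv) stop("mobilogram fit did not converge")
  # apparent maxima of the fitted sum on a fine grid, parabolic-refined
  fine <- seq(min(t), max(t), length.out = 4000)
  yhat <- stats::predict(fit, newdata = list(t = fine))
  apex <- numeric(0)
  for (i in 2:(length(fine) - 1L)) {
    if (yhat[i] > yhat[i - 1L] && yhat[i] >= yhat[i + 1L] &&
        yhat[i] > 0.05 * max(yhat)) {
      denom <- yhat[i - 1L] - 2 * yhat[i] + yhat[i + 1L]
      delta <- if (denom < 0) 0.5 * (yhat[i - 1L] - yhat[i + 1L]) / denom else 0
      apex <- c(apex, fine[i] + delta * (fine[2] - fine[1]))
    }
  }
  structure(list(components = comps, apparent_maxima_ms = sort(apex), fit = fit),
            class = "mobilogram_fit")
}
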