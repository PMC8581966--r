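# Theoretical IR spectra: harmonic stick spectra are frequency-scaled and
# convolved with a lineshape, candidate isomers are Boltzmann-weighted by
# relative free energy, and candidates are ranked against an experimental
# action spectrum by profile similarity.

#' Construct a stick spectrum
#'
#' @param label Candidate label (e.g. conformer name).
#' @param freq_cm1 Harmonic frequencies in cm^-1 (> 0).
#' @param intensity IR intensities in km mol^-1 (>= 0).
#' @param delta_g_kjmol Relative Gibbs free energy in kJ mol^-1 (optional).
#' @return Object of class `"stick_spectrum"`.
#' @export
stick_spectrum <- function(label, freq_cm1, intensity,
                           delta_g_kjmol = NA_real_) {
  stopifnot(length(freq_cm1) == length(intensity),
            all(freq_cm1 > 0), all(intensity >= 0))
  structure(list(label = label,
                 lines = data.frame(freq_cm1 = freq_cm1, intensity = intensity),
                 delta_g_kjmol = delta_g_kjmol),
            class = "stick_spectrum")
}

lineshape_profile <- function(grid, center, fwhm, lineshape) {
  switch(lineshape,
    gaussian  = exp(-4 * log(2) * (grid - center)^2 / fwhm^2),
    lorentzian = 1 / (1 + (2 * (grid - center) / fwhm)^2),
    stop("unknown lineshape: ", lineshape)
  )
}

#' Scale and broaden a stick spectrum
#'
#' Multiplies all harmonic frequencies by an empirical scale factor
#' (default 0.978, compensating the systematic overestimation of harmonic
#' frequencies by hybrid DFT functionals) and convolves the scaled lines with
#' a unit-peak-height Gaussian or Lorentzian of fixed FWHM on a uniform grid.
#'
#' @param stick A [stick_spectrum()].
#' @param scale Frequency scale factor, in (0.5, 1.5); default 0.978.
#' @param fwhm Full width at half maximum of the lineshape in cm^-1
#'   (default 25, typical for free-electron-laser fingerprint comparisons).
#' @param lineshape `"gaussian"` (default) or `"lorentzian"`.
#' @param grid Uniform energy grid in cm^-1; default 800-1850 step 1.
#' @return Data frame (`energy_cm1`, `absorbance`) of class
#'   `"broadened_spectrum"` with attributes `label`, `scale`, `fwhm`,
#'   `lineshape`.
#' @export
scale_and_broaden <- function(stick, scale = 0.978, fwhm = 25,
                              lineshape = c("gaussian", "lorentzian"),
                              grid = seq(800, 1850, by = 1)) {
  lineshape <- match.arg(lineshape)
  stopifnot(inherits(stick, "stick_spectrum"), fwhm > 0)
  if (scale <= 0.5 || scale >= 1.5) stop("scale factor outside (0.5, 1.5)")
  if (nrow(stick$lines) == 0) stop("empty stick spectrum")
  step <- grid[2] - grid[1]
  if (step > fwhm) {
    warning(sprintf("grid step (%.3g) exceeds fwhm (%.3g): undersampled profile",
                    step, fwhm))
  }
  prof <- rep(0, length(grid))
  for (k in seq_len(nrow(stick$lines))) {
    prof <- prof + stick$lines$intensity[k] *
      lineshape_profile(grid, scale * stick$lines$freq_cm1[k], fwhm, lineshape)
  }
  structure(data.frame(energy_cm1 = grid, absorbance = prof),
            class = c("broadened_spectrum", "data.frame"),
            label = stick$label, scale = scale, fwhm = fwhm,
            lineshape = lineshape)
}

#' Boltzmann population weights from relative free energies
#'
#' w_i proportional to exp(-dG_i / RT), normalized to sum to one; invariant
#' to adding a constant to all free energies.
#'
#' @param delta_g_kjmol Relative Gibbs free energies in kJ mol^-1.
#' @param temperature_k Temperature in K (default 298.15).
#' @return Numeric weights summing to 1.
#' @examples
#' boltzmann_weights(c(0, 24.2))
#' @export
boltzmann_weights <- function(delta_g_kjmol, temperature_k = 298.15) {
  stopifnot(length(delta_g_kjmol) >= 1)
  if (temperature_k <= 0) stop("temperature must be positive")
  g <- delta_g_kjmol - min(delta_g_kjmol)
  w <- exp(-g / (.const$R_kJ * temperature_k))
  w / sum(w)
}

resample_profile <- function(spec, grid) {
  stats::approx(spec$energy_cm1, spec$absorbance, xout = grid)$y
}

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Rank candidate theoretical spectra against an experimental spectrum
#'
#' Resamples each broadened candidate onto the overlap of its grid with the
#' experimental one (linear interpolation), max-normalizes both profiles and
#' scores their similarity (cosine by default, Pearson optionally). When
#' Boltzmann weights are supplied, a population-weighted composite of all
#' candidates is scored as well under the label `"weighted_composite"`.
#'
#' @param experimental An `"action_spectrum"` or data frame with
#'   `energy_cm1` and `yield` (or `absorbance`) columns.
#' @param candidates List of `"broadened_spectrum"` objects.
#' @param weights Optional population weights (same length as `candidates`).
#' @param method `"cosine"` (default) or `"pearson"`.
#' @return Data frame (`label`, `score`) sorted by decreasing score.
#' @export
match_and_rank <- function(experimental, candidates, weights = NULL,
                           method = c("cosine", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(candidates) >= 1)
  ycol <- if ("yield" %in% names(experimental)) "yield" else "absorbance"
  e_grid <- experimental$energy_cm1
  e_prof <- experimental[[ycol]]
  score_one <- function(cand) {
    lo <- max(min(e_grid), min(cand$energy_cm1))
    hi <- min(max(e_grid), max(cand$energy_cm1))
    if (lo >= hi) stop("empty overlap between experimental and candidate grids")
    keep <- e_grid >= lo & e_grid <= hi
    a <- e_prof[keep]
    b <- resample_profile(cand, e_grid[keep])
    if (max(a) > 0) a <- a / max(a)
    if (max(b) > 0) b <- b / max(b)
    if (method == "cosine") cosine_similarity(a, b) else stats::cor(a, b)
  }
  labels <- vapply(candidates, function(cc) attr(cc, "label"), character(1))
  scores <- vapply(candidates, score_one, numeric(1))
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(candidates))
    grid <- candidates[[1]]$energy_cm1
    comp <- rep(0, length(grid))
    for (k in seq_along(candidates)) {
      comp <- comp + weights[k] * resample_profile(candidates[[k]], grid)
    }
    comp_spec <- data.frame(energy_cm1 = grid, absorbance = comp)
    labels <- c(labels, "weighted_composite")
    scores <- c(scores, score_one(comp_spec))
  }
  out <- data.frame(label = labels, score = scores)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}
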