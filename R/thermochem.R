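# Gas-phase acidity bookkeeping: DG_acid of HA -> A- + H+ from component
# Gibbs free energies, conformer free-energy ladders, and qualitative
# proton-transfer reactivity prediction.

#' Construct a species thermochemistry record
#'
#' @param label Species label.
#' @param g Gibbs free energy value.
#' @param unit `"hartree"` or `"kJ/mol"`.
#' @param temperature_k Temperature in K (default 298.15).
#' @return Object of class `"species_thermo"` with `g_kjmol` converted to
#'   kJ mol^-1 (1 hartree = 2625.4996 kJ mol^-1).
#' @export
species_thermo <- function(label, g, unit = c("hartree", "kJ/mol"),
                           temperature_k = 298.15) {
  unit <- match.arg(unit)
  stopifnot(temperature_k > 0, is.finite(g))
  g_kj <- if (unit == "hartree") g * .const$hartree_kJ else g
  structure(list(label = label, g_kjmol = g_kj, unit = unit,
                 temperature_k = temperature_k),
            class = "species_thermo")
}

#' Gas-phase acidity from component free energies
#'
#' DG_acid(HA) for HA -> A- + H+ is the free energy of the anion plus that
#' of the proton minus that of the neutral:
#' DG_acid = G(anion) + G(H+) - G(neutral). The proton's standard gas-phase
#' Gibbs free energy defaults to -26.28 kJ mol^-1 at 298.15 K
#' (Sackur-Tetrode translational entropy convention).
#'
#' @param neutral,anion [species_thermo()] records.
#' @param proton_g_kjmol Proton Gibbs free energy in kJ mol^-1
#'   (default -26.28).
#' @return Object of class `"acidity_result"`: `dg_acid_kjmol`, `neutral`,
#'   `anion`, `proton_g_kjmol`, `temperature_k`.
#' @export
gas_phase_acidity <- function(neutral, anion, proton_g_kjmol = -26.28) {
  stopifnot(inherits(neutral, "species_thermo"), inherits(anion, "species_thermo"))
  if (neutral$temperature_k != anion$temperature_k) {
    warning("neutral and anion temperatures differ")
  }
  structure(list(dg_acid_kjmol = anion$g_kjmol + proton_g_kjmol - neutral$g_kjmol,
                 neutral = neutral$label, anion = anion$label,
                 proton_g_kjmol = proton_g_kjmol,
                 temperature_k = neutral$temperature_k),
            class = "acidity_result")
}

#' Relative free energies of a conformer set
#'
#' @param species List of [species_thermo()] records with common temperature.
#' @return Named numeric vector of DG_i = G_i - min(G) in kJ mol^-1 (at
#'   least one zero entry).
#' @export
relative_free_energies <- function(species) {
  stopifnot(length(species) >= 1)
  temps <- vapply(species, function(s) s$temperature_k, numeric(1))
  if (length(unique(temps)) > 1) warning("mixed temperatures across species")
  g <- vapply(species, function(s) s$g_kjmol, numeric(1))
  names(g) <- vapply(species, function(s) s$label, character(1))
  g - min(g)
}

#' Predict proton-transfer reactivity from acidities
#'
#' For the proton transfer [X-H]- + HA -> XH + A- (the deprotonated analyte
#' abstracting a proton from reference acid HA), the reaction free energy is
#' DG_rxn = DG_acid(HA) - DG_acid(XH): transfer is exergonic when the
#' reference acid is the stronger one (lower DG_acid).
#'
#' @param dg_acid_donor_kjmol DG_acid of the neutral reference acid HA.
#' @param dg_acid_acceptor_kjmol DG_acid of the analyte conjugate acid XH.
#' @param thermoneutral_band_kjmol Half-width of the ~thermoneutral verdict
#'   band in kJ mol^-1 (default 5).
#' @return List: `dg_rxn_kjmol` and `verdict` in
#'   `c("exergonic", "~thermoneutral", "endergonic")`.
#' @examples
#' predict_proton_transfer(1328, 1345)  # TFA vs T3: exergonic
#' @export
predict_proton_transfer <- function(dg_acid_donor_kjmol,
                                    dg_acid_acceptor_kjmol,
                                    thermoneutral_band_kjmol = 5) {
  dg <- dg_acid_donor_kjmol - dg_acid_acceptor_kjmol
  verdict <- if (abs(dg) <= thermoneutral_band_kjmol) {
    "~thermoneutral"
  } else if (dg < 0) "exergonic" else "endergonic"
  list(dg_rxn_kjmol = dg, verdict = verdict)
}
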