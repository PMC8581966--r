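---
title: "Methods: discriminating isomeric anions by spectroscopy, mobility and kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discriminating isomeric anions by spectroscopy, mobility and kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionchem)
```

## The problem

Deprotonated triiodothyronine, [T3-H]⁻, and reverse triiodothyronine,
[rT3-H]⁻, are isomers with the same elemental composition
(C₁₅H₁₁NO₄I₃, m/z 649.78 as anions), so accurate mass cannot distinguish
them. What does distinguish them is *where* the charge sits: one isomer
prefers deprotonation at the carboxylic acid (a carboxylate anion), the
other at the phenol (a phenolate). `ionchem` implements the measurement
chain that turns that structural difference into observables: IR action
spectra, ion-mobility collision cross sections (CCS), ion–molecule reaction
kinetics, and gas-phase acidity bookkeeping, plus seeded generators that
emulate each data type so the whole chain is testable end to end.

## IRMPD action spectra

A trapped ion irradiated with tunable IR light fragments when the photon
energy is resonant with a vibrational mode. Each fragmentation scan is
reduced to the photofragmentation yield

$$R = -\log\!\left[\frac{I_p}{I_p + \sum I_f}\right],$$

where $I_p$ and $\sum I_f$ are integrated precursor and fragment
abundances. Plotting $R$ against photon energy gives the action spectrum.

Choices that matter:

* **Log base.** "−log" is written both ways in the action-spectroscopy
  literature. The default is the natural log, with `log_base = "10"`
  available; the base is recorded in the spectrum's provenance and the two
  conventions differ by the exact factor $\ln 10$, so nothing downstream
  depends on the choice (similarity scoring normalizes amplitudes away).
* **Peak windows.** Peaks are assigned to precursor/fragment windows of
  half-width `tol = 0.5` m/z, matching unit-resolution quadrupole
  isolation. Configurable.
* **No laser-power normalization** by default; spectra here are used for
  band positions and relative profiles, not absolute cross sections.
* **Degenerate scans.** $I_p = \sum I_f = 0$ is an error; $I_p = 0$ with
  fragments present ("total depletion") returns `Inf` with a warning rather
  than silently saturating.

`detect_bands()` reports local maxima above a prominence threshold with
three-point parabolic refinement; `min_separation_cm1` merges noise ripples
on a band flank into the taller maximum. Heavily overlapped bands (closer
than their width) genuinely merge into one maximum — that is physics, not a
detection failure.

## Theory spectra and candidate ranking

Harmonic stick spectra are scaled by 0.978 (the standard empirical
correction for hybrid-DFT harmonic frequencies in this frequency range) and
convolved with a unit-height Gaussian of FWHM 25 cm⁻¹, typical for
free-electron-laser fingerprint comparisons; a Lorentzian is available.
Candidates are ranked against the experimental spectrum by cosine
similarity of max-normalized profiles on the common grid (linear
interpolation for resampling). Cosine was chosen over peak matching because
it is parameter-free, bounded in [0, 1], and invariant to uniform intensity
rescaling — the property the yield spectrum actually guarantees. Pearson
correlation is offered as an alternative. Because it is unknown whether
plotted theory spectra should be population-weighted, `match_and_rank()`
scores pure candidates and, when Boltzmann weights are supplied
(`boltzmann_weights()`, $w_i \propto e^{-\Delta G_i/RT}$), a weighted
composite as well.

## Traveling-wave mobility calibration

TWIMS drift times have no closed-form CCS relation, so reference calibrants
(polyalanine-like ladders) anchor an empirical power law. Following the
standard protocol: drift times are corrected for the m/z-dependent transfer
delay, $t_d' = t_d - \mathrm{EDC}\sqrt{m/z}/1000$ (EDC default 1.41);
reference CCS values are reduced, $\Omega' = \Omega\sqrt{\mu}/|z|$ with
$\mu$ the ion–gas reduced mass (N₂, 28.006 Da default); and
$\ln\Omega'$ is regressed on $\ln t_d'$ to give $\Omega' = A\,t_d'^B$.
Reference CCS values are user-supplied tables, not bundled constants.
Because the exact calibrant set behind any given experiment is rarely
recoverable, experimental CCS values are treated as an *ordering*
observable (larger CCS ↔ longer drift time), which the calibration
preserves exactly.

`deconvolve_mobilogram()` fits a one- or two-Gaussian mixture by
Levenberg–Marquardt. The two components share one width: isomers at the
same m/z have instrument-determined peak widths, and the shared width keeps
the strongly overlapped fit well conditioned. Starts come from intensity
moments of the baseline-thresholded trace, the fit is windowed to ±5 SD of
the signal, and centers are box-constrained. The fit reports both the
component centers and the apparent maxima of the summed curve — for
overlapping peaks the observable maxima are pulled toward each other, which
is exactly the mixture-versus-pure-compound drift-time discrepancy the
two-isomer experiment shows.

## Projection-approximation CCS

`pa_ccs()` estimates the orientation-averaged projected area of the union
of hard spheres (atom radius + probe radius): uniform random rotations from
quaternion sampling, and within each orientation a uniform Monte-Carlo area
estimate over the bounding box of the projected disks. The standard error
comes from the spread across orientations and shrinks as
$1/\sqrt{n_{\text{orient}}}$; the seed is recorded in the result.
`projection_area_grid()` is the deterministic brute-force counterpart
(0.01 Å rasterization) used for cross-checks. The shipped radii table is
explicitly configuration, not ground truth — absolute projection CCS values
depend on it, but the *ordering* used in the analysis (elongated
charge-extended structures project larger than compact charge-folded ones)
is robust to any sane radii choice, and that ordering is what links the
carboxylate/phenolate assignment to the mobility separation. Trajectory-
method and EHSS cross sections are out of scope.

## Ion–molecule kinetics

The chain is: (1) pseudo-first-order rate $k'$ from the slope of
$\ln(\text{parent fraction})$ vs time (unweighted least squares, matching
semilog-plot practice; nonpositive fractions are excluded with a warning);
(2) neutral number density $n = P/(k_BT)$ with the gauge reading corrected
by a calibration factor — derivable from a reference reaction of known rate
constant (default 1.1 × 10⁻⁹ cm³ s⁻¹ for CH₄⁺· + CH₄) via
`gauge_factor_from_reference()` — and a per-neutral response factor;
(3) $k_{\text{exp}} = k'/n$, split over competitive channels by final
product-abundance ratios so channel rates conserve $k_{\text{exp}}$
exactly; (4) the capture rate $k_{\text{ADO}}$ and efficiency
$\phi = 100\,k_{\text{exp}}/k_{\text{ADO}}$.

For the capture rate the Su–Chesnavich parametrized-trajectory fit is used:
the Langevin rate $k_L = 2\pi q\sqrt{\alpha/\mu}$ (cgs) scaled by $K(x)$
with $x = \mu_D/\sqrt{2\alpha k_BT}$,
$K = (x+0.509)^2/10.526 + 0.9754$ for $x<2$ and $K = 0.4767x + 0.62$ for
$x \ge 2$; the two branches join continuously and $K(0)=1$ recovers
Langevin. Neutral dipole moments and polarizabilities are configuration
inputs. For trifluoroacetic acid we default to the experimental dipole
2.28 D and a computed-monomer-scale polarizability 5.3 Å³, which give
$k_{\text{ADO}} = 1.24 \times 10^{-9}$ cm³ s⁻¹ for capture by a m/z ≈ 650
anion at 300 K — within the ~10% spread that different literature
($\alpha$, $\mu_D$) pairs produce for this quantity. Reported rate
uncertainties combine the fit standard error with a ±30% systematic error,
the conventional absolute-rate error bar for FT-ICR pressure calibration.

Efficiency conventions: when the measured decay feeds several channels,
"efficiency" can mean total $k_{\text{exp}}/k_{\text{ADO}}$ or the
proton-transfer channel alone; `channel_rates()` reports both the total and
per-channel values so either convention can be read off.

## Gas-phase acidity

$\Delta G_{\text{acid}} = G(\text{A}^-) + G(\text{H}^+) - G(\text{HA})$,
with hartree → kJ mol⁻¹ conversion 2625.4996 and the proton's standard
Gibbs free energy defaulting to −26.28 kJ mol⁻¹ at 298.15 K (the
Sackur–Tetrode-based convention); the proton value is configuration since
conventions differ by a few tenths of kJ mol⁻¹. Proton transfer
[X−H]⁻ + HA → XH + A⁻ has
$\Delta G_{\text{rxn}} = \Delta G_{\text{acid}}(\text{HA}) -
\Delta G_{\text{acid}}(\text{XH})$; verdicts use a ±5 kJ mol⁻¹
thermoneutral band, chosen so that a transfer sitting ~2 kJ mol⁻¹ uphill is
classified "~thermoneutral" (slow but observable) rather than forbidden,
while ~60 kJ mol⁻¹ uphill is cleanly endergonic. Computing the component
free energies themselves (DFT/MP2) is out of scope; the package does the
bookkeeping.

## Synthetic data: what it emulates, and what it does not

The generators produce, under a fixed seed, byte-identical data with the
statistical structure each stage assumes:

* `gen_action_scans()` — band-shaped fragmentation probability
  $f(E)$ (Gaussian bands, must stay < 1), precursor $N(1-f)$, fragments
  $Nf$ split over the configured m/z list. Noiseless output inverts the
  yield formula exactly: $R = -\ln(1-f)$.
* `gen_kinetic_trace()` — exponential parent decay with branching-split
  products, renormalized rows.
* `gen_mobility_dataset()` — calibrant drift times from the *inverse* of a
  known power law and Gaussian mobilogram peaks at inverse-mapped analyte
  drift times; the noiseless round trip through the calibration fit is the
  identity.
* `gen_toy_geometry()` — deterministic sphere pairs, chains, rings and
  matched compact/extended pairs for projection-CCS properties.

Noise is 2% multiplicative Gaussian plus an optional additive floor by
default — a deliberately simple stand-in for ion-count statistics. The
generators do not emulate multi-photon absorption dynamics, TWIMS field
physics, space-charge effects, baseline drift, or correlated noise; passing
tests demonstrate that the *analysis chain* inverts its own model classes
at realistic noise, not that it is robust to every artifact of real
instruments. Generators write the same CSV formats the readers consume, so
fixtures take no privileged in-memory path.

## Problem sizes and numerical choices

Test and script workloads were sized to be comfortable on a single CPU:
action-spectrum trials use a 1450–1850 cm⁻¹ grid at 2 cm⁻¹ (200 ranking
trials at SNR 10); mobility checks use a 9-point ladder and 100 noisy
seeds; kinetics recovery uses 12-point traces over 50 seeds; Monte-Carlo
CCS uses 300–3000 orientations × 2000 samples. Other numerics: Hill-order
canonicalization for formulas; only |z| = 1 in neutral-loss arithmetic
(multiply charged fragments are out of scope); one-decimal m/z labels are a
formatting layer, never an internal representation — where a computed value
(632.76 for ammonia loss) disagrees in the last displayed digit with a
nominal instrument readout (632.7), the computed value is reported;
monoisotopic masses are NIST values with iodine 126.904473 Da and explicit
electron-mass handling, $(M - z\,m_e)/|z|$.

## Known limitations

* Absolute experimental CCS values depend on the calibrant reference set;
  only orderings and round-trip consistency are claimed.
* Projection approximation systematically underestimates CCS for concave
  surfaces versus trajectory methods; used here for orderings on toy and
  candidate structures, not for absolute comparison to drift-tube data.
* The two-Gaussian mobilogram fit assumes a common instrumental width;
  strongly asymmetric or >2-component mixtures are unsupported.
* Capture-rate accuracy is limited by the neutral ($\alpha$, $\mu_D$)
  inputs, typically known to ~10%.
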