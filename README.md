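# ionchem

Gas-phase ion-chemistry workflows for discriminating isomeric anions.

Deprotonated triiodothyronine ([T3-H]⁻) and reverse triiodothyronine
([rT3-H]⁻) are isomeric thyroid-hormone anions (C₁₅H₁₁NO₄I₃, m/z 649.78):
accurate mass cannot tell them apart, but their preferred deprotonation
sites — carboxylate vs phenolate — can, through four independent gas-phase
observables. `ionchem` implements that measurement chain for analytical
mass spectrometrists and gas-phase ion chemists:

* **Exact-mass arithmetic** — formula parsing, monoisotopic ion m/z with
  electron-mass handling, ppm errors, neutral-loss fragment bookkeeping.
* **IRMPD action spectroscopy** — photofragmentation yield
  R = −log[I_p/(I_p + ΣI_f)] per scan, yield-vs-energy spectra, band
  detection, and ranking of scaled/broadened harmonic candidate spectra by
  cosine similarity (with Boltzmann population weighting).
* **Ion mobility** — traveling-wave power-law calibration
  Ω′ = A·t_d′^B on EDC-corrected drift times with reduced-mass/charge
  reduction, drift-time → CCS conversion, Gaussian-mixture mobilogram
  deconvolution, and projection-approximation CCS from XYZ structures with
  a Monte-Carlo orientation average.
* **Ion–molecule kinetics** — pseudo-first-order semilog fits, pressure →
  number-density conversion with reference-reaction gauge calibration,
  competitive channel branching, Langevin/Su–Chesnavich capture rates and
  reaction efficiencies φ = 100·k_exp/k_ADO.
* **Gas-phase acidity** — ΔG_acid = G(A⁻) + G(H⁺) − G(HA) bookkeeping and
  proton-transfer reactivity verdicts.
* **Seeded synthetic-data generators** for every stage, so the full chain
  runs end to end without instrument data.

## Worked example

```r
library(ionchem)

# 1. Composition check: both isomers share one exact mass
mz <- ion_mz("C15H11NO4I3", charge = -1)
mz                                  #> 649.7828 (printed 649.78278 at 5 dp)
ppm_error(649.78319, mz)            #> 0.638 ppm
mz_label(neutral_loss_mz(mz, c("HI", "C2H3NO2")))  #> "448.9"
mz_label(ion_mz("I", -1))           #> "126.9"

# 2. Kinetics: synthetic trace at the tabulated magnitudes, fitted back
n <- number_density(1e-8, 300)      #> 2.414e8 cm^-3
tr <- gen_kinetic_trace(2.53e-10, n, seq(0, 30, length.out = 12),
                        branching = c(proton_transfer = 0.76, adduct = 0.24),
                        cfg = generator_config(seed = 11, noise_frac = 0.02))
fit <- fit_pseudo_first_order(tr)
k_ado <- collision_rate_ado(649.78, 114.02, alpha_A3 = 5.3, dipole_D = 2.28)
channel_rates(fit$k_prime, n, unlist(tr$fractions[12, -1]),
              k_prime_stderr = fit$stderr, k_ado = k_ado)
#> <channel_rates> k_exp = 2.54e-10 cm^3 s^-1 (+/- 7.6e-11)
#>   k_ADO = 1.24e-09 cm^3 s^-1, efficiency = 20.5%
#>           channel branching            k efficiency_pct
#> 1 proton_transfer 0.7615369 1.931220e-10      15.607165
#> 2          adduct 0.2384631 6.047307e-11       4.887135
```

The k_exp recovered from the noisy trace reproduces the generating value
2.53 × 10⁻¹⁰ cm³ s⁻¹ well inside the ±30% systematic error bar, and the
efficiency (~20% here; 22% when the tabulated k_ADO = 1.14 × 10⁻⁹ is used)
says roughly one capture collision in five transfers a proton — about twice
the rT3 value, consistent with T3 being the weaker gas-phase acid.

## Analysis scripts

The `analysis/` directory walks the full discrimination argument on
synthetic data, writing tables under `results/`:

1. `01_mass_bookkeeping.R` — exact mass, ppm error, fragment assignments.
2. `02_irmpd_assignment.R` — action spectra from both band templates;
   the generating template wins both candidate rankings.
3. `03_mobility.R` — calibration, mixture deconvolution (fitted centers vs
   displaced apparent maxima), CCS 209/215 Å², compact-vs-extended
   projection CCS.
4. `04_kinetics.R` — the full kinetics chain for both isomers.
5. `05_acidity_crosscheck.R` — proton-transfer verdicts and the merged
   multi-technique discrimination report.

Run them in order with `Rscript analysis/01_mass_bookkeeping.R`, etc.

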