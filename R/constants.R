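# Physical constants. SI unless suffixed; cgs values used by collision-rate
# theory carry a _cgs suffix.

.const <- list(
  kB_SI        = 1.380649e-23,      # J K^-1
  kB_cgs       = 1.380649e-16,      # erg K^-1
  e_cgs        = 4.80320471e-10,    # statC (esu)
  amu_g        = 1.66053906660e-24, # g
  debye_cgs    = 1e-18,             # esu cm
  electron_da  = 5.48579909065e-4,  # Da
  R_kJ         = 8.31446261815e-3,  # kJ mol^-1 K^-1
  hartree_kJ   = 2625.4996          # kJ mol^-1 per hartree
)

#' Monoisotopic atomic masses
#'
#' Monoisotopic masses (Da) of the most abundant isotope of each supported
#' element, plus the electron mass, as used for exact ion m/z arithmetic.
#'
#' @return Named numeric vector of monoisotopic masses in Da. The electron
#'   mass is available separately via `electron_mass()`.
#' @examples
#' isotope_masses()[["I"]]
#' @export
isotope_masses <- function() {
  c(
    H  = 1.00782503207,
    C  = 12.0,
    N  = 14.0030740048,
    O  = 15.9949146196,
    F  = 18.99840322,
    Na = 22.9897692809,
    P  = 30.97376163,
    S  = 31.97207100,
    Cl = 34.96885268,
    K  = 38.96370668,
    Br = 78.9183371,
    I  = 126.904473,
    B  = 11.0093054,
    Si = 27.9769265325
  )
}

#' @rdname isotope_masses
#' @export
electron_mass <- function() .const$electron_da
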