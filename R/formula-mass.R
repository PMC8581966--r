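# Molecular-formula parsing and exact-mass arithmetic for singly charged
# ions: monoisotopic m/z with electron-mass handling, ppm error, and
# neutral-loss bookkeeping for fragment assignment.

#' Parse a molecular formula
#'
#' Parses a Hill-notation formula string ("C15H11NO4I3") into named element
#' counts. Only elements present in [isotope_masses()] are accepted; an
#' unknown symbol or an explicit zero/negative count is an error.
#'
#' @param text Formula string, e.g. `"C15H11NO4I3"` or `"H2O"`.
#' @return Named integer vector of element counts, class `"mol_formula"`,
#'   ordered canonically (C, H, then alphabetical).
#' @examples
#' parse_formula("C15H11NO4I3")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula string")
  tokens <- gregexpr("[A-Z][a-z]?|[0-9]+|.", text)[[1L]]
  parts <- regmatches(text, list(tokens))[[1L]]
  known <- names(isotope_masses())
  counts <- integer(0)
  i <- 1L
  while (i <= length(parts)) {
    sym <- parts[i]
    if (!grepl("^[A-Z][a-z]?$", sym)) {
      stop(sprintf("formula parse error at token '%s' in '%s'", sym, text))
    }
    if (!sym %in% known) {
      stop(sprintf("unknown element symbol '%s' in '%s'", sym, text))
    }
    n <- 1L
    if (i < length(parts) && grepl("^[0-9]+$", parts[i + 1L])) {
      n <- as.integer(parts[i + 1L])
      i <- i + 1L
    }
    if (n <= 0L) stop(sprintf("nonpositive count for element '%s'", sym))
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + n else n
    i <- i + 1L
  }
  if (length(counts) == 0L) stop("formula contains no elements")
  structure(counts[hill_order(names(counts))], class = "mol_formula")
}

hill_order <- function(symbols) {
  rest <- sort(setdiff(symbols, c("C", "H")))
  c(intersect(c("C", "H"), symbols), rest)
}

#' Format a formula in canonical Hill notation
#'
#' @param formula Named counts as returned by [parse_formula()].
#' @return Hill-notation string (C first, then H, then alphabetical; unit
#'   counts omitted).
#' @examples
#' format_formula(parse_formula("H2O"))
#' @export
format_formula <- function(formula) {
  formula <- as_formula(formula)
  syms <- hill_order(names(formula))
  paste0(vapply(syms, function(s) {
    n <- formula[[s]]
    if (n == 1L) s else paste0(s, n)
  }, character(1)), collapse = "")
}

as_formula <- function(x) {
  if (is.character(x)) return(parse_formula(x))
  stopifnot(is.numeric(x), !is.null(names(x)), all(x >= 1))
  unknown <- setdiff(names(x), names(isotope_masses()))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  structure(stats::setNames(as.integer(x), names(x)), class = "mol_formula")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula>", format_formula(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of a neutral formula
#'
#' @param formula Formula string or parsed counts.
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass("HI")
#' @export
formula_mass <- function(formula) {
  formula <- as_formula(formula)
  sum(isotope_masses()[names(formula)] * as.numeric(formula))
}

#' Exact m/z of an ion
#'
#' Monoisotopic m/z of an ion given its elemental composition and charge,
#' accounting for the electron mass:
#' m/z = (M_neutral - z * m_e) / |z|, so an anion gains electron mass and a
#' cation loses it.
#'
#' @param formula Formula string or parsed counts (composition of the ion,
#'   e.g. `"C15H11NO4I3"` for the deprotonated anion).
#' @param charge Signed integer charge in elementary units; must be nonzero.
#' @return m/z in Da per elementary charge.
#' @examples
#' ion_mz("C15H11NO4I3", charge = -1)
#' @export
ion_mz <- function(formula, charge) {
  stopifnot(length(charge) == 1L, is.finite(charge))
  if (charge == 0) {
    stop("charge must be nonzero; use formula_mass() for neutrals")
  }
  (formula_mass(formula) - charge * electron_mass()) / abs(charge)
}

#' Mass error in parts per million
#'
#' @param measured Measured m/z.
#' @param reference Reference (exact) m/z; must be positive.
#' @return Signed ppm error `1e6 * (measured - reference) / reference`.
#' @examples
#' ppm_error(649.78319, 649.78276)
#' @export
ppm_error <- function(measured, reference) {
  if (any(reference <= 0)) stop("reference m/z must be positive")
  1e6 * (measured - reference) / reference
}

#' Fragment m/z after neutral losses
#'
#' Subtracts the monoisotopic masses of one or more neutral-loss formulas
#' from a singly charged precursor m/z. The charge is assumed to stay on the
#' fragment (|z| = 1), so the m/z arithmetic is plain mass subtraction.
#'
#' @param precursor_mz Precursor m/z (> 0).
#' @param losses List (or character vector) of neutral-loss formulas.
#' @return Fragment m/z.
#' @examples
#' neutral_loss_mz(649.78278, c("HI", "C2H3NO2"))
#' @export
neutral_loss_mz <- function(precursor_mz, losses = list()) {
  stopifnot(precursor_mz > 0)
  lost <- if (length(losses)) {
    sum(vapply(losses, formula_mass, numeric(1)))
  } else 0
  out <- precursor_mz - lost
  if (out <= 0) {
    stop(sprintf("neutral losses (%.4f Da) exceed precursor m/z %.4f",
                 lost, precursor_mz))
  }
  out
}

#' One-decimal m/z label
#'
#' Formats an m/z at the single-decimal (nominal instrument-readout)
#' precision used when labelling fragment peaks.
#'
#' @param mz Numeric m/z.
#' @return Character label, e.g. `"448.9"`.
#' @export
mz_label <- function(mz) formatC(round(mz, 1), format = "f", digits = 1)
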