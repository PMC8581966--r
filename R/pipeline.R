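# Stage dispatch and report assembly: a validated configuration (R list or
# YAML file) names one analysis stage and its inputs; stage results are
# wrapped in a provenance-carrying report, and per-stage reports are merged
# into a multi-technique discrimination verdict.

stage_keys <- list(
  irmpd    = c("scans_csv", "precursor_mz", "fragment_mz", "tol", "log_base"),
  assign   = c("spectrum", "candidates", "weights", "method"),
  mobility = c("calibrants_csv", "mobilogram_csv", "edc", "gas_mass_da",
               "n_components", "analyte_mz", "analyte_z"),
  ccs      = c("xyz", "radii", "n_orientations", "n_samples", "seed"),
  kinetics = c("trace_csv", "pressure_mbar", "temperature_k",
               "calibration_factor", "response_factor", "ion_mass_da",
               "neutral_mass_da", "alpha_A3", "dipole_D"),
  acidity  = c("species", "proton_g_kjmol", "donor_dg", "acceptor_dg")
)

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$stage)) stop("config validation: missing 'stage'")
  if (!config$stage %in% names(stage_keys)) {
    stop("config validation: unknown stage '", config$stage, "'")
  }
  extra <- setdiff(names(config), c("stage", "output_dir", stage_keys[[config$stage]]))
  if (length(extra)) {
    stop("config validation: unknown key(s): ", paste(extra, collapse = ", "))
  }
  for (key in grep("_csv$|^xyz$", names(config), value = TRUE)) {
    if (!file.exists(config[[key]])) {
      stop("config validation: path does not exist: ", config[[key]])
    }
  }
  config
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

make_report <- function(stage, results, config) {
  structure(list(stage = stage, results = results,
                 provenance = list(
                   config_hash = config_hash(config),
                   package_version = as.character(utils::packageVersion("ionchem")),
                   seed = config$seed %||% NA)),
            class = "ion_report")
}

#' Run one analysis stage from a configuration
#'
#' Dispatches a validated configuration (an R list, or the path of a YAML
#' file) to the named stage and returns a report with provenance (config
#' hash, package version, seed). Stages: `irmpd` (scans -> action spectrum),
#' `assign` (spectrum vs candidate ranking), `mobility` (calibration + CCS +
#' mobilogram deconvolution), `ccs` (XYZ -> projection CCS), `kinetics`
#' (trace -> channel rates and efficiency), `acidity` (free energies ->
#' DG_acid and proton-transfer verdicts). Unknown stages or config keys are
#' validation errors.
#'
#' @param config Named list or YAML path; must contain `stage`.
#' @return Object of class `"ion_report"`.
#' @export
run_stage <- function(config) {
  config <- validate_config(config)
  results <- switch(config$stage,
    irmpd = {
      scans <- read_scans_csv(config$scans_csv)
      spec <- build_action_spectrum(
        scans, precursor_mz = config$precursor_mz,
        fragment_mz = config$fragment_mz, tol = config$tol %||% 0.5,
        log_base = config$log_base %||% "e")
      list(spectrum = as.data.frame(spec),
           log_base = attr(spec, "log_base"),
           bands = detect_bands(spec))
    },
    assign = {
      list(ranking = match_and_rank(config$spectrum, config$candidates,
                                    weights = config$weights,
                                    method = config$method %||% "cosine"))
    },
    mobility = {
      cal <- fit_tw_calibration(read_calibrants_csv(config$calibrants_csv),
                                edc = config$edc %||% 1.41,
                                gas_mass_da = config$gas_mass_da %||% 28.006)
      mob <- read_mobilogram_csv(config$mobilogram_csv)
      dec <- deconvolve_mobilogram(mob, n_components = config$n_components %||% 1)
      ccs <- drift_to_ccs(dec$components$center_ms, config$analyte_mz,
                          config$analyte_z, cal)
      list(calibration = unclass(cal)[c("A", "B", "r_squared")],
           components = cbind(dec$components, ccs_A2 = ccs),
           apparent_maxima_ms = dec$apparent_maxima_ms)
    },
    ccs = {
      res <- pa_ccs(read_xyz(config$xyz),
                    radii = config$radii %||% default_collision_radii(),
                    n_orientations = config$n_orientations %||% 300,
                    n_samples = config$n_samples %||% 2000,
                    seed = config$seed %||% 1)
      unclass(res)
    },
    kinetics = {
      trace <- read_trace_csv(config$trace_csv)
      fit <- fit_pseudo_first_order(trace)
      n <- number_density(config$pressure_mbar, config$temperature_k,
                          calibration_factor = config$calibration_factor %||% 1,
                          response_factor = config$response_factor %||% 1)
      kado <- if (!is.null(config$alpha_A3)) {
        collision_rate_ado(config$ion_mass_da, config$neutral_mass_da,
                           config$alpha_A3, config$dipole_D %||% 0,
                           config$temperature_k)
      } else NULL
      prods <- setdiff(names(trace$fractions), trace$parent)
      ab <- vapply(trace$fractions[prods], function(x) x[length(x)], numeric(1))
      cr <- channel_rates(fit$k_prime, n, ab, k_prime_stderr = fit$stderr,
                          k_ado = kado)
      c(fit, list(n_cm3 = n), unclass(cr))
    },
    acidity = {
      acid <- lapply(config$species, function(s) {
        gas_phase_acidity(
          species_thermo(s$neutral_label %||% paste0(s$label, "H"),
                         s$g_neutral, unit = s$unit %||% "hartree"),
          species_thermo(s$label, s$g_anion, unit = s$unit %||% "hartree"),
          proton_g_kjmol = config$proton_g_kjmol %||% -26.28)
      })
      list(acidities = data.frame(
        species = vapply(acid, function(a) a$anion, character(1)),
        dg_acid_kjmol = vapply(acid, function(a) a$dg_acid_kjmol, numeric(1))))
    })
  report <- make_report(config$stage, results, config)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      report, file.path(config$output_dir,
                        paste0(config$stage, "_report.json")),
      auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' Assemble a multi-technique discrimination report
#'
#' Merges per-stage reports into one verdict table per candidate isomer,
#' mirroring the multi-technique argument used to assign deprotomer
#' structures: spectral rank, CCS ordering, reaction efficiency and
#' proton-transfer free-energy sign must point at a consistent candidate.
#'
#' @param spectral Named numeric vector of similarity scores per candidate
#'   (optional).
#' @param ccs Named numeric vector of CCS values per candidate (optional).
#' @param efficiency Named numeric vector of reaction efficiencies (percent)
#'   per candidate (optional).
#' @param dg_rxn Named numeric vector of proton-transfer DG_rxn (kJ mol^-1)
#'   per candidate (optional).
#' @return Object of class `"discrimination_report"`: `table` (one row per
#'   candidate), `verdict` (best spectral candidate, or `NA` without
#'   spectral input), `confidence` (`"low"` with a single stage).
#' @export
assemble_discrimination_report <- function(spectral = NULL, ccs = NULL,
                                           efficiency = NULL, dg_rxn = NULL) {
  stages <- list(spectral_score = spectral, ccs_A2 = ccs,
                 efficiency_pct = efficiency, dg_rxn_kjmol = dg_rxn)
  stages <- stages[!vapply(stages, is.null, logical(1))]
  if (!length(stages)) stop("need at least one stage result")
  labels <- lapply(stages, names)
  common <- Reduce(union, labels)
  mismatch <- Filter(function(l) !setequal(l, common), labels)
  if (length(mismatch)) {
    stop("candidate labels differ across stages: ",
         paste(vapply(labels, paste, character(1), collapse = "/"),
               collapse = " vs "))
  }
  tab <- data.frame(candidate = common)
  for (nm in names(stages)) tab[[nm]] <- as.numeric(stages[[nm]][common])
  verdict <- if (!is.null(spectral)) names(which.max(spectral)) else NA_character_
  structure(list(table = tab, verdict = verdict,
                 confidence = if (length(stages) >= 2) "multi-stage" else "low"),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf("<discrimination_report> verdict: %s (%s)\n", x$verdict,
              x$confidence))
  print(x$table)
  invisible(x)
}
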