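# Plain-text readers and writers. Generators and analysis stages exchange
# the same CSV formats, so synthetic fixtures take no privileged in-memory
# path.

#' Read and write fragmentation scans (long CSV)
#'
#' Long format with columns `energy_cm1`, `mz`, `intensity` and a constant
#' `precursor_mz` column; one scan per distinct energy.
#'
#' @param path CSV path.
#' @return `read_scans_csv()`: list of [fragmentation_scan()] objects.
#' @export
read_scans_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("energy_cm1", "mz", "intensity", "precursor_mz") %in% names(df)))
  lapply(split(df, df$energy_cm1), function(d) {
    fragmentation_scan(d$energy_cm1[1],
                       data.frame(mz = d$mz, intensity = d$intensity),
                       d$precursor_mz[1])
  })
}

#' @rdname read_scans_csv
#' @param scans List of [fragmentation_scan()] objects.
#' @export
write_scans_csv <- function(scans, path) {
  rows <- do.call(rbind, lapply(scans, function(s) {
    data.frame(energy_cm1 = s$energy_cm1, mz = s$peaks$mz,
               intensity = s$peaks$intensity, precursor_mz = s$precursor_mz)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read and write kinetic traces (CSV)
#'
#' Wide format: `time_s` plus one abundance column per species (parent
#' first).
#'
#' @param path CSV path.
#' @param parent Parent column name (default: first species column).
#' @return `read_trace_csv()`: a [kinetic_trace()].
#' @export
read_trace_csv <- function(path, parent = NULL) {
  df <- utils::read.csv(path)
  stopifnot("time_s" %in% names(df))
  species <- setdiff(names(df), "time_s")
  kinetic_trace(df$time_s, df[species], parent = parent %||% species[1])
}

#' @rdname read_trace_csv
#' @param trace A [kinetic_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(cbind(time_s = trace$time_s, trace$fractions), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a stick spectrum from CSV
#'
#' Columns `freq_cm1`, `intensity_km_mol`.
#'
#' @param path CSV path.
#' @param label Candidate label.
#' @param delta_g_kjmol Relative free energy (optional).
#' @return A [stick_spectrum()].
#' @export
read_stick_csv <- function(path, label, delta_g_kjmol = NA_real_) {
  df <- utils::read.csv(path)
  stopifnot(all(c("freq_cm1", "intensity_km_mol") %in% names(df)))
  stick_spectrum(label, df$freq_cm1, df$intensity_km_mol, delta_g_kjmol)
}

#' Read a mobilogram or calibrant ladder from CSV
#'
#' Mobilograms: columns `td_ms`, `intensity`. Calibrant ladders: columns
#' `mz`, `z`, `ccs_A2`, `td_ms` (a `name` column is allowed).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_mobilogram_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("td_ms", "intensity") %in% names(df)))
  df
}

#' @rdname read_mobilogram_csv
#' @export
read_calibrants_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("mz", "z", "ccs_A2", "td_ms") %in% names(df)))
  df
}
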