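# IRMPD action spectra: per-photon-energy fragmentation scans are reduced to
# the photofragmentation yield R = -log[I_p / (I_p + sum I_f)] and assembled
# into a yield-vs-energy spectrum.

#' Construct a fragmentation scan
#'
#' One mass spectrum recorded at a single photon energy: a peak list of
#' integrated intensities plus the precursor m/z and (optional) irradiation
#' time metadata.
#'
#' @param energy_cm1 Photon energy in cm^-1 (> 0).
#' @param peaks Data frame with columns `mz` and `intensity` (>= 0).
#' @param precursor_mz Precursor m/z.
#' @param irradiation_ms Irradiation time in ms (metadata, may be `NA`).
#' @return Object of class `"frag_scan"`.
#' @export
fragmentation_scan <- function(energy_cm1, peaks, precursor_mz,
                               irradiation_ms = NA_real_) {
  stopifnot(is.numeric(energy_cm1), energy_cm1 > 0,
            is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (any(peaks$intensity < 0)) stop("peak intensities must be >= 0")
  structure(
    list(energy_cm1 = energy_cm1,
         peaks = peaks[c("mz", "intensity")],
         precursor_mz = precursor_mz,
         irradiation_ms = irradiation_ms),
    class = "frag_scan"
  )
}

window_intensity <- function(peaks, center, tol) {
  sum(peaks$intensity[abs(peaks$mz - center) <= tol])
}

#' Photofragmentation yield of one scan
#'
#' Computes R = -log[I_p / (I_p + sum I_f)] where I_p is the integrated
#' precursor abundance and sum I_f the summed fragment abundances, each
#' collected within +/- `tol` m/z windows. R = 0 when no fragment signal is
#' present; total precursor depletion (I_p = 0 with fragments present) is
#' flagged with a warning and reported as `Inf`.
#'
#' @param scan A [fragmentation_scan()].
#' @param precursor_mz Precursor window center; defaults to the scan's.
#' @param fragment_mz Numeric vector of fragment window centers.
#' @param tol Half-width of each m/z window (default 0.5, unit-resolution
#'   isolation).
#' @param log_base `"e"` (natural log, default) or `"10"`.
#' @return Yield R (>= 0, possibly `Inf`).
#' @examples
#' sc <- fragmentation_scan(1600, data.frame(mz = c(649.8, 126.9),
#'                                           intensity = c(900, 100)), 649.8)
#' photofragment_yield(sc, fragment_mz = 126.9)
#' @export
photofragment_yield <- function(scan, precursor_mz = scan$precursor_mz,
                                fragment_mz, tol = 0.5, log_base = c("e", "10")) {
  log_base <- match.arg(log_base)
  ip <- window_intensity(scan$peaks, precursor_mz, tol)
  if_sum <- if (length(fragment_mz)) {
    sum(vapply(fragment_mz, window_intensity, numeric(1), peaks = scan$peaks,
               tol = tol))
  } else 0
  if (ip == 0 && if_sum == 0) {
    stop(sprintf("empty scan at %.1f cm^-1: no precursor or fragment signal",
                 scan$energy_cm1))
  }
  if (ip == 0) {
    warning(sprintf("total depletion at %.1f cm^-1: I_p = 0 with fragments",
                    scan$energy_cm1))
    return(Inf)
  }
  r <- -log(ip / (ip + if_sum))
  if (log_base == "10") r <- r / log(10)
  r
}

#' Build an action spectrum from fragmentation scans
#'
#' Reduces each scan to its photofragmentation yield and assembles an
#' energy-ordered spectrum; replicate scans at the same photon energy are
#' averaged.
#'
#' @inheritParams photofragment_yield
#' @param scans List of [fragmentation_scan()] objects spanning at least two
#'   distinct photon energies.
#' @param precursor_mz Precursor window center shared by all scans.
#' @return Data frame (`energy_cm1`, `yield`) of class `"action_spectrum"`,
#'   sorted by increasing energy, with provenance attributes `n_scans` and
#'   `log_base`.
#' @export
build_action_spectrum <- function(scans, precursor_mz, fragment_mz, tol = 0.5,
                                  log_base = c("e", "10")) {
  log_base <- match.arg(log_base)
  stopifnot(length(scans) >= 2)
  energy <- vapply(scans, function(s) s$energy_cm1, numeric(1))
  if (length(unique(energy)) < 2) {
    stop("degenerate spectrum: all scans share one photon energy")
  }
  r <- vapply(scans, photofragment_yield, numeric(1),
              precursor_mz = precursor_mz, fragment_mz = fragment_mz,
              tol = tol, log_base = log_base)
  agg <- stats::aggregate(list(yield = r), by = list(energy_cm1 = energy), FUN = mean)
  agg <- agg[order(agg$energy_cm1), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, class = c("action_spectrum", "data.frame"),
            n_scans = length(scans), log_base = log_base)
}

#' Locate bands in an action spectrum
#'
#' Finds local maxima above a prominence threshold (a fraction of the global
#' maximum yield) and refines each center by three-point parabolic
#' interpolation.
#'
#' @param spectrum An `"action_spectrum"` (or any data frame with
#'   `energy_cm1` and `yield` columns), >= 5 points.
#' @param min_prominence Threshold as a fraction of the maximum yield
#'   (default 0.1).
#' @param min_separation_cm1 Merge radius: maxima closer than this to a
#'   taller one are treated as noise ripples on its flank and dropped
#'   (default 0, no merging).
#' @return Data frame (`center_cm1`, `height`) sorted by center; zero rows
#'   when the spectrum is flat.
#' @export
detect_bands <- function(spectrum, min_prominence = 0.1,
                         min_separation_cm1 = 0) {
  e <- spectrum$energy_cm1
  y <- spectrum$yield
  if (length(e) < 5) stop("insufficient data: need >= 5 spectrum points")
  thr <- min_prominence * max(y)
  centers <- numeric(0)
  heights <- numeric(0)
  for (i in 2:(length(y) - 1L)) {
    if (y[i] > 0 && y[i] >= thr && y[i] > y[i - 1L] && y[i] >= y[i + 1L]) {
      denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
      delta <- if (denom < 0) 0.5 * (y[i - 1L] - y[i + 1L]) / denom else 0
      step <- (e[i + 1L] - e[i - 1L]) / 2
      centers <- c(centers, e[i] + delta * step)
      heights <- c(heights, y[i] - 0.25 * (y[i - 1L] - y[i + 1L]) * delta)
    }
  }
  if (min_separation_cm1 > 0 && length(centers) > 1) {
    keep_idx <- integer(0)
    for (i in order(-heights)) {
      if (!length(keep_idx) ||
          all(abs(centers[i] - centers[keep_idx]) >= min_separation_cm1)) {
        keep_idx <- c(keep_idx, i)
      }
    }
    centers <- centers[keep_idx]
    heights <- heights[keep_idx]
  }
  ord <- order(centers)
  data.frame(center_cm1 = centers[ord], height = heights[ord])
}
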