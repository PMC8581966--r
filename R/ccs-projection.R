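# Projection-approximation collision cross sections: the orientation-averaged
# projected area of the union of hard-sphere atoms (atom radius + probe
# radius), estimated by Monte Carlo over uniform random rotations, plus a
# deterministic grid-rasterization estimator for a fixed orientation.

#' Read an XYZ geometry file
#'
#' Standard XYZ format: atom count, comment line, then `element x y z` rows
#' with coordinates in Angstrom.
#'
#' @param path Path to an XYZ file.
#' @param label Geometry label; defaults to the comment line (or file name).
#' @return Object of class `"geometry"`: `atoms` data frame
#'   (`element`, `x`, `y`, `z`) and `label`.
#' @export
read_xyz <- function(path, label = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed XYZ file: fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("malformed XYZ count on line 1")
  if (length(lines) < 2 + n) {
    stop(sprintf("XYZ atom count %d but only %d atom line(s) present (line %d)",
                 n, length(lines) - 2L, length(lines)))
  }
  rows <- lines[3:(2 + n)]
  parts <- strsplit(trimws(rows), "\\s+")
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) < 4) {
      stop(sprintf("malformed XYZ atom row at line %d", i + 2L))
    }
  }
  el <- vapply(parts, `[[`, character(1), 1L)
  bad <- which(!grepl("^[A-Z][a-z]?$", el))
  if (length(bad)) {
    stop(sprintf("unknown element symbol '%s' at line %d", el[bad[1]],
                 bad[1] + 2L))
  }
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (any(!is.finite(xyz))) stop("non-finite coordinates in XYZ file")
  geometry(el, xyz[, 1], xyz[, 2], xyz[, 3],
           label = label %||% (if (nzchar(trimws(lines[2]))) trimws(lines[2])
                               else basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a geometry
#'
#' @param element Character vector of element symbols.
#' @param x,y,z Coordinates in Angstrom.
#' @param label Geometry label.
#' @return Object of class `"geometry"`.
#' @export
geometry <- function(element, x, y, z, label = "geometry") {
  stopifnot(length(element) >= 1,
            length(x) == length(element), length(y) == length(element),
            length(z) == length(element), all(is.finite(c(x, y, z))))
  structure(list(atoms = data.frame(element = element, x = x, y = y, z = z),
                 label = label),
            class = "geometry")
}

#' Write a geometry to an XYZ file
#'
#' @param geom A [geometry()].
#' @param path Output path.
#' @export
write_xyz <- function(geom, path) {
  a <- geom$atoms
  writeLines(c(nrow(a), geom$label,
               sprintf("%s %.6f %.6f %.6f", a$element, a$x, a$y, a$z)),
             path)
  invisible(path)
}

#' Default collision radii for N2 drift gas
#'
#' Per-element hard-sphere collision radii (A) plus a probe radius for the
#' N2 drift gas. These are editable configuration values, not ground truth;
#' pass a modified copy to [pa_ccs()] to change them.
#'
#' @return List with `radii` (named numeric, A) and `probe` (A).
#' @export
default_collision_radii <- function() {
  list(radii = c(H = 1.10, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                 P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98,
                 Na = 2.27, B = 1.92, Si = 2.10),
       probe = 1.50)
}

# Uniform random rotation matrix from a random unit quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# Monte-Carlo area of the union of disks at (cx, cy) with radii r, sampled
# uniformly over the disks' bounding box.
mc_union_area <- function(cx, cy, r, n_samples) {
  xlo <- min(cx - r); xhi <- max(cx + r)
  ylo <- min(cy - r); yhi <- max(cy + r)
  px <- stats::runif(n_samples, xlo, xhi)
  py <- stats::runif(n_samples, ylo, yhi)
  hit <- rep(FALSE, n_samples)
  for (k in seq_along(cx)) {
    hit <- hit | ((px - cx[k])^2 + (py - cy[k])^2 <= r[k]^2)
  }
  (xhi - xlo) * (yhi - ylo) * mean(hit)
}

#' Projection-approximation CCS by Monte Carlo
#'
#' Estimates the orientation-averaged projected area of the union of
#' hard-sphere atoms (each of radius element radius + probe radius): for each
#' of `n_orientations` uniform random rotations, the projected union-of-disks
#' area is estimated by uniform Monte Carlo sampling over its bounding box,
#' and the CCS is the mean over orientations with a standard error from the
#' spread across orientations.
#'
#' @param geom A [geometry()].
#' @param radii Radii configuration as from [default_collision_radii()].
#' @param n_orientations Number of random orientations (>= 1; default 300).
#' @param n_samples Monte-Carlo samples per orientation (default 2000).
#' @param seed Integer RNG seed (recorded in the result).
#' @return Object of class `"pa_result"`: `ccs_A2`, `se_A2`,
#'   `n_orientations`, `n_samples`, `seed`.
#' @examples
#' g <- geometry("I", 0, 0, 0)
#' pa_ccs(g, list(radii = c(I = 2), probe = 1), n_orientations = 50, seed = 1)
#' @export
pa_ccs <- function(geom, radii = default_collision_radii(),
                   n_orientations = 300, n_samples = 2000, seed = 1) {
  stopifnot(inherits(geom, "geometry"), n_orientations >= 1, n_samples >= 10)
  el <- geom$atoms$element
  missing_el <- setdiff(unique(el), names(radii$radii))
  if (length(missing_el)) {
    stop("no collision radius for element(s): ",
         paste(missing_el, collapse = ", "))
  }
  r <- unname(radii$radii[el]) + radii$probe
  coords <- t(as.matrix(geom$atoms[, c("x", "y", "z")]))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  areas <- vapply(seq_len(n_orientations), function(i) {
    rot <- random_rotation() %*% coords
    mc_union_area(rot[1, ], rot[2, ], r, n_samples)
  }, numeric(1))
  se <- if (n_orientations > 1) stats::sd(areas) / sqrt(n_orientations) else NA_real_
  structure(list(ccs_A2 = mean(areas), se_A2 = se,
                 n_orientations = n_orientations, n_samples = n_samples,
                 seed = seed),
            class = "pa_result")
}

#' @export
print.pa_result <- function(x, ...) {
  cat(sprintf("<pa_result> CCS = %.3f +/- %.3f A^2 (%d orientations x %d samples, seed %d)\n",
              x$ccs_A2, x$se_A2, x$n_orientations, x$n_samples, x$seed))
  invisible(x)
}

#' Deterministic grid projection area for a fixed orientation
#'
#' Rasterizes the union of projected atom disks on a square grid and counts
#' covered cells; a brute-force, RNG-free estimator of the projected area
#' along the z axis of the geometry as given (no rotation).
#'
#' @param geom A [geometry()].
#' @param radii Radii configuration as from [default_collision_radii()].
#' @param resolution Grid spacing in A (default 0.01).
#' @return Projected area in A^2.
#' @export
projection_area_grid <- function(geom, radii = default_collision_radii(),
                                 resolution = 0.01) {
  el <- geom$atoms$element
  r <- unname(radii$radii[el]) + radii$probe
  cx <- geom$atoms$x; cy <- geom$atoms$y
  gx <- seq(min(cx - r), max(cx + r), by = resolution)
  gy <- seq(min(cy - r), max(cy + r), by = resolution)
  covered <- matrix(FALSE, nrow = length(gx), ncol = length(gy))
  for (k in seq_along(cx)) {
    dx2 <- (gx - cx[k])^2
    dy2 <- (gy - cy[k])^2
    covered <- covered | outer(dx2, dy2, `+`) <= r[k]^2
  }
  sum(covered) * resolution^2
}
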