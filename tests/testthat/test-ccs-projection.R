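# Independent oracle for the orientation-averaged projected area of two
# identical spheres of radius r at separation d: projecting along a uniform
# random direction gives disk separation s = d * sin(theta) with cos(theta)
# uniform on [0, 1]; the two-disk union area has a closed form, and the
# orientation average is a 1-D integral evaluated by adaptive quadrature.
two_disk_union <- function(s, r) {
  ifelse(s >= 2 * r, 2 * pi * r^2,
         2 * pi * r^2 - (2 * r^2 * acos(pmin(s / (2 * r), 1)) -
                           (s / 2) * sqrt(pmax(4 * r^2 - s^2, 0))))
}

two_sphere_pa_oracle <- function(d, r) {
  stats::integrate(function(c) two_disk_union(d * sqrt(1 - c^2), r),
                   0, 1, rel.tol = 1e-10)$value
}

toy_radii <- list(radii = c(C = 2.0, I = 2.0), probe = 1.0)

test_that("XYZ files round-trip and malformed files are rejected with line numbers", {
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "", "I 0 0 0"), p)
  g <- read_xyz(p)
  expect_equal(nrow(g$atoms), 1)
  expect_equal(g$atoms$element, "I")
  g3 <- gen_toy_geometry("chain", n_atoms = 3, spacing = 1.2)
  p3 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(g3, p3)
  back <- read_xyz(p3)
  expect_equal(back$atoms[c("x", "y", "z")], g3$atoms[c("x", "y", "z")],
               tolerance = 1e-6)
  writeLines(c("5", "comment", "C 0 0 0"), p)
  expect_error(read_xyz(p), "count 5")
  writeLines(c("x", "comment", "C 0 0 0"), p)
  expect_error(read_xyz(p), "count")
  writeLines(c("1", "", "c15 0 0 0"), p)
  expect_error(read_xyz(p), "element")
})

test_that("single-atom projection CCS equals the analytic disk area", {
  g <- geometry("C", 0, 0, 0)
  res <- pa_ccs(g, toy_radii, n_orientations = 400, n_samples = 2000, seed = 5)
  expect_equal(res$ccs_A2, pi * 3^2, tolerance = 2.5 * res$se_A2 / (pi * 9))
  expect_gt(res$se_A2, 0)
})

test_that("far-separated spheres add their disk areas; overlapping ones match the oracle", {
  far <- gen_toy_geometry("sphere_pair", separation = 100)
  res_far <- pa_ccs(far, toy_radii, n_orientations = 300, n_samples = 4000, seed = 2)
  expect_equal(res_far$ccs_A2, 2 * pi * 9, tolerance = 0.01)
  near <- gen_toy_geometry("sphere_pair", separation = 2)
  res_near <- pa_ccs(near, toy_radii, n_orientations = 600, n_samples = 4000, seed = 3)
  expect_equal(res_near$ccs_A2, two_sphere_pa_oracle(2, 3),
               tolerance = 2 * res_near$se_A2 / res_near$ccs_A2)
  # degenerate overlap: coincident atoms behave like one sphere
  coin <- gen_toy_geometry("sphere_pair", separation = 0)
  res_coin <- pa_ccs(coin, toy_radii, n_orientations = 300, n_samples = 2000, seed = 4)
  expect_equal(res_coin$ccs_A2, pi * 9, tolerance = 3 * res_coin$se_A2 / (pi * 9))
})

test_that("projection CCS is invariant under rotation and translation", {
  g <- gen_toy_geometry("chain", n_atoms = 4, spacing = 1.5)
  res <- pa_ccs(g, toy_radii, n_orientations = 400, n_samples = 2000, seed = 6)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- t(rot %*% t(as.matrix(g$atoms[, c("x", "y", "z")]))) +
    matrix(rep(c(5, -3, 2), each = 4), ncol = 3)
  g2 <- geometry(g$atoms$element, xyz[, 1], xyz[, 2], xyz[, 3])
  res2 <- pa_ccs(g2, toy_radii, n_orientations = 400, n_samples = 2000, seed = 60)
  expect_equal(res2$ccs_A2, res$ccs_A2,
               tolerance = 2 * (res$se_A2 + res2$se_A2) / res$ccs_A2)
})

test_that("CCS grows when atoms are added or radii enlarged, and with elongation", {
  base <- gen_toy_geometry("chain", n_atoms = 3, spacing = 1.5)
  more <- gen_toy_geometry("chain", n_atoms = 5, spacing = 1.5)
  r1 <- pa_ccs(base, toy_radii, n_orientations = 300, n_samples = 2000, seed = 8)
  r2 <- pa_ccs(more, toy_radii, n_orientations = 300, n_samples = 2000, seed = 8)
  expect_gt(r2$ccs_A2, r1$ccs_A2)
  bigger <- list(radii = c(C = 2.5), probe = 1.0)
  r3 <- pa_ccs(base, bigger, n_orientations = 300, n_samples = 2000, seed = 8)
  expect_gt(r3$ccs_A2, r1$ccs_A2)
  # extended conformer exposes more area than its compact counterpart
  ext <- gen_toy_geometry("chain", n_atoms = 10, extended = TRUE)
  cmp <- gen_toy_geometry("chain", n_atoms = 10, extended = FALSE)
  re <- pa_ccs(ext, toy_radii, n_orientations = 300, n_samples = 2000, seed = 9)
  rc <- pa_ccs(cmp, toy_radii, n_orientations = 300, n_samples = 2000, seed = 9)
  expect_gt(re$ccs_A2, rc$ccs_A2)
})

test_that("Monte-Carlo standard error shrinks with more orientations", {
  g <- gen_toy_geometry("chain", n_atoms = 4, spacing = 1.5)
  se_small <- pa_ccs(g, toy_radii, n_orientations = 100, n_samples = 1000,
                     seed = 10)$se_A2
  se_big <- pa_ccs(g, toy_radii, n_orientations = 900, n_samples = 1000,
                   seed = 10)$se_A2
  expect_lt(se_big, se_small)
  expect_equal(se_small / se_big, 3, tolerance = 0.5)
})

test_that("missing radii and seeds are handled explicitly", {
  g <- geometry("Na", 0, 0, 0)
  expect_error(pa_ccs(g, toy_radii), "Na")
  h <- geometry("C", 0, 0, 0)
  a <- pa_ccs(h, toy_radii, n_orientations = 50, seed = 123)
  b <- pa_ccs(h, toy_radii, n_orientations = 50, seed = 123)
  expect_identical(a$ccs_A2, b$ccs_A2)
})

test_that("grid rasterization reproduces the in-plane disk-union area", {
  g <- gen_toy_geometry("sphere_pair", separation = 2)
  area <- projection_area_grid(g, toy_radii, resolution = 0.01)
  expect_equal(area, two_disk_union(2, 3), tolerance = 1e-3)
})
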