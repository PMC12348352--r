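test_that("the calibrated landscape reproduces its anchor values", {
  ls <- default_landscape_cached()
  expect_equal(free_energy(ls, c(48.0, 92.7)), 18.3, tolerance = 1e-9)
  expect_equal(free_energy(ls, c(168.5, 153.0)), 0, tolerance = 1e-9)
  expect_equal(free_energy(ls, c(0, 0)), 2.0, tolerance = 1e-9)
  # exact 360-degree periodicity in both coordinates
  set.seed(3)
  p <- matrix(runif(40, -180, 180), ncol = 2)
  expect_equal(free_energy(ls, p), free_energy(ls, cbind(p[, 1] - 360, p[, 2])))
  expect_equal(free_energy(ls, p), free_energy(ls, cbind(p[, 1], p[, 2] + 360)))
})

test_that("the hydrogen-bond sub-barrier is 4.6 kJ/mol by construction", {
  ls <- default_landscape_cached()
  s <- seq(0.7, 1, by = 1e-4)
  prof <- ls$dense$prof_fun(s)
  submin <- min(prof[s >= 0.75 & s <= 0.85])
  submax <- max(prof[s >= 0.82 & s <= 0.95])
  expect_equal(submax - submin, 4.6, tolerance = 1e-9)
  expect_lte(submax - submin, 5.0)
})

test_that("path construction validates its inputs", {
  expect_error(path_spec(data.frame(s = c(0, 0.5), phi = c(0, 1), psi = c(0, 1)),
                         data.frame(s = c(0, 1), F = c(0, 0))), "s = 0 and s = 1")
  expect_error(path_spec(data.frame(s = c(0, 0.4, 0.4, 1), phi = 1:4, psi = 1:4),
                         data.frame(s = c(0, 1), F = c(0, 0))), "increasing")
  expect_error(path_spec(data.frame(s = c(0, 1), phi = c(0, 10), psi = c(0, 10)),
                         data.frame(s = c(0, 0.5, 1), F = c(2, 1, 0))), "lowest")
})

test_that("gradients vanish at the stationary points and match a richer stencil", {
  ls <- default_landscape_cached()
  g <- free_energy_gradient(ls, rbind(c(0, 0), c(168.5, 153.0), c(48.0, 92.7)))
  expect_true(all(sqrt(rowSums(g^2)) < 1e-3))
  # five-point-stencil oracle at random points; points whose stencil
  # straddles a cut-locus kink of the nearest-branch projection are screened
  # out by a second-difference smoothness check (the surface is only
  # piecewise smooth there, so no finite-difference scheme is consistent)
  set.seed(11)
  pts <- matrix(runif(200, -180, 180), ncol = 2)
  hs <- 0.01
  d2 <- function(dx, dy) abs(free_energy(ls, cbind(pts[, 1] + dx, pts[, 2] + dy)) -
    2 * free_energy(ls, pts) +
    free_energy(ls, cbind(pts[, 1] - dx, pts[, 2] - dy))) / hs^2
  smooth_pts <- d2(hs, 0) < 1 & d2(0, hs) < 1
  expect_gt(mean(smooth_pts), 0.75)
  pts <- pts[smooth_pts, ]
  g2 <- free_energy_gradient(ls, pts)
  h <- 1e-3
  five <- function(f, x) (-f(x + 2 * h) + 8 * f(x + h) - 8 * f(x - h) + f(x - 2 * h)) / (12 * h)
  gphi <- five(function(d) free_energy(ls, cbind(pts[, 1] + d, pts[, 2])), 0)
  gpsi <- five(function(d) free_energy(ls, cbind(pts[, 1], pts[, 2] + d)), 0)
  expect_lt(max(abs(g2[, 1] - gphi)), 1e-4)
  expect_lt(max(abs(g2[, 2] - gpsi)), 1e-4)
})

test_that("transverse displacements feel the harmonic stiffness", {
  # straight path: a 10-degree perpendicular offset gives exactly kt * 10
  straight <- landscape_spec(
    path_spec(data.frame(s = c(0, 1), phi = c(-90, 90), psi = c(0, 0)),
              data.frame(s = c(0, 1), F = c(0, 0)), profile_ends = "secant"),
    transverse_stiffness = 0.02)
  g <- free_energy_gradient(straight, c(0, 10))
  expect_equal(unname(g[1, "psi"]), 0.2, tolerance = 1e-6)
  expect_equal(unname(g[1, "phi"]), 0, tolerance = 1e-6)
})

test_that("basin minima sit at the conformer anchors", {
  ls <- default_landscape_cached()
  m <- locate_minima(ls)
  expect_lt(torus_dist(m$minima[1, ], c(0, 0)), 0.1)
  expect_lt(torus_dist(m$minima[2, ], c(168.5, 153.0)), 0.1)
  expect_equal(m$F[1] - m$F[2], 2.0, tolerance = 1e-6)
  expect_equal(abs(angle_diff(m$minima[2, 1], m$minima[1, 1])), 168.5,
               tolerance = 0.1)
  expect_equal(abs(angle_diff(m$minima[2, 2], m$minima[1, 2])), 153.0,
               tolerance = 0.1)
  g <- free_energy_gradient(ls, m$minima)
  expect_true(all(sqrt(rowSums(g^2)) < 1e-3))
})

test_that("the principal saddle responds linearly to every field axis", {
  ls <- default_landscape_cached()
  s0 <- locate_saddle(ls)
  expect_equal(unname(s0$point), c(48.0, 92.7), tolerance = 1e-3)
  expect_equal(s0$height, 18.3, tolerance = 1e-6)
  for (ax in c("x", "y", "z")) {
    sf <- locate_saddle(ls, field_spec(ax, 1, 41.14e8))
    expect_equal(sf$height, 23.1, tolerance = 1e-6)
  }
  expect_equal(locate_saddle(ls, field_spec("x", 1, 0))$height, s0$height)
  # affine in strength at a fixed point
  p <- c(48, 92.7)
  f1 <- free_energy(ls, p, field_spec("x", 1, 10e8))
  f2 <- free_energy(ls, p, field_spec("x", 1, 20e8))
  f0 <- free_energy(ls, p)
  expect_equal(f2 - f1, f1 - f0, tolerance = 1e-9)
})

test_that("the torus drains into the two conformer basins after merging shallow intermediates", {
  ls <- default_landscape_cached()
  audit <- audit_basins(ls, resolution = 360L)
  expect_equal(audit$n_basins, 2)
  # the multi-step path carries shallow metastable intermediates
  expect_gte(audit$n_raw_basins, 2)
  expect_gte(audit$top2_fraction, 0.99)
  d1 <- min(torus_dist(audit$minima[1, ], c(0, 0)),
            torus_dist(audit$minima[1, ], c(168.5, 153)))
  d2 <- min(torus_dist(audit$minima[2, ], c(0, 0)),
            torus_dist(audit$minima[2, ], c(168.5, 153)))
  expect_lt(max(d1, d2), 2)
  expect_true(validate_landscape(ls, resolution = 360L))
})

test_that("field scans are reproducible, collinear and correctly anchored", {
  t1 <- generate_field_scan(seed = 42)
  t2 <- generate_field_scan(seed = 42)
  expect_identical(t1, t2)
  expect_error(generate_field_scan(seed = 1, noise_fraction = -0.1))
  expect_error(generate_field_scan(seed = 1, quantities = "no_such"), "unknown")
  expect_error(generate_field_scan())

  # noiseless scans are exactly collinear through the reference
  t0 <- generate_field_scan(seed = 9, noise_fraction = 0)
  ser <- subset(as.data.frame(t0), quantity == "dG_proton" & axis == "x" & sign == 1)
  fit <- lm(value ~ strength_Vm, data = ser)
  expect_lt(max(abs(residuals(fit))), 1e-10)
  # proton barrier at the maximum +x field: 17.3 - 11.6 = 5.7
  expect_equal(ser$value[ser$strength_Vm == max(field_strength_grid())], 5.7,
               tolerance = 1e-9)
  # seeded value stays within a few noise standard deviations
  tn <- generate_field_scan(seed = 1, noise_fraction = 0.02)
  sern <- subset(as.data.frame(tn), quantity == "dG_proton" & axis == "x" & sign == 1)
  vmax <- sern$value[sern$strength_Vm == max(field_strength_grid())]
  expect_lt(abs(vmax - 5.7), 4 * 0.02 * 11.6)
  # water phase present with its own reference
  tw <- generate_field_scan(seed = 1, phase = "water", noise_fraction = 0)
  serw <- subset(as.data.frame(tw), quantity == "dG_proton" & axis == "x" & sign == 1)
  expect_equal(serw$value[serw$strength_Vm == 0], 19.3)
})
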