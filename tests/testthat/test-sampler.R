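test_that("a restrained window on a flat surface obeys equipartition", {
  cfg <- sampler_config(n_steps = 2e5)
  w <- sample_window(flat_landscape(), NULL, center = c(0, 0), cfg)
  RT <- physical_constants()$R * 298.15 / 1000
  target <- RT / 100  # rad^2
  expect_equal(unname(diag(w$covariance)[1]), target, tolerance = 0.05)
  expect_equal(unname(diag(w$covariance)[2]), target, tolerance = 0.05)
  # mean stays at the center within 3 standard errors
  tau <- 1 / (cfg$mobility * cfg$spring)
  se_deg <- sqrt(target) * 180 / pi / sqrt(cfg$n_steps * cfg$time_step / (2 * tau))
  expect_lt(max(abs(angle_diff(w$mean_op, w$center))), 3 * se_deg)
})

test_that("identical seeds reproduce the window sample exactly", {
  cfg <- sampler_config(time_step = 2e-4, n_steps = 2000, seed = 77L)
  w1 <- sample_window(doublewell_landscape(), NULL, c(-60, 0), cfg)
  w2 <- sample_window(doublewell_landscape(), NULL, c(-60, 0), cfg)
  expect_identical(w1, w2)
})

test_that("the restraint estimator recovers a linear mean force", {
  cfg <- sampler_config(n_steps = 2e5)
  w <- sample_window(tilted_landscape(5), NULL, center = c(0, 0), cfg)
  f <- mean_force(w)
  expect_equal(f[1], 5, tolerance = 0.05)
  expect_lt(abs(f[2]), 0.5)
  # flat surface: mean force indistinguishable from zero
  wf <- sample_window(flat_landscape(), NULL, c(0, 0), cfg)
  expect_lt(max(abs(mean_force(wf))), 0.5)
})

test_that("the estimator matches the analytic gradient on the landscape", {
  ls <- default_landscape_cached()
  # gently curved path points (near the conformation-1 basin and mid-path)
  pts <- rbind(ls$dense$nodes[101, ], ls$dense$nodes[1101, ])
  cfg <- sampler_config(n_steps = 1e5)
  ws <- ftspath:::.sample_windows(ls, NULL, pts, cfg, seed = 31)
  g <- free_energy_gradient(ls, pts) * 180 / pi  # kJ/mol/rad
  tau <- 1 / (cfg$mobility * cfg$spring)
  se <- cfg$spring * sqrt(physical_constants()$R * 298.15 / 1000 / cfg$spring) /
    sqrt(cfg$n_steps * cfg$time_step / (2 * tau))
  for (k in 1:2) {
    f <- mean_force(ws[[k]])
    expect_lt(max(abs(f - g[k, ])), 3 * se + 0.05 * max(abs(g[k, ])))
  }
})

test_that("sampling honors the Boltzmann distribution across a double well", {
  ls <- doublewell_landscape(barrier = 3)
  cfg <- sampler_config(time_step = 2e-4, n_steps = 8e5, spring = 0.5)
  # analytic bin probabilities from the known surface (transverse marginal
  # integrated by quadrature)
  RT <- physical_constants()$R * 298.15 / 1000
  edges <- seq(-55, 55, length.out = 9)
  phig <- seq(-55, 55, by = 0.25); psig <- seq(-25, 25, by = 0.25)
  FF <- matrix(free_energy(ls, cbind(rep(phig, length(psig)),
                                     rep(psig, each = length(phig)))),
               nrow = length(phig))
  kdeg <- 0.5 / (180 / pi)^2  # restraint spring in kJ/mol/deg^2
  UU <- outer(phig^2, psig^2, `+`) * 0.5 * kdeg
  dens <- rowSums(exp(-(FF + UU) / RT))
  pexp <- vapply(seq_len(8), function(b) {
    sum(dens[phig >= edges[b] & phig < edges[b + 1]])
  }, numeric(1))
  pexp <- pexp / sum(pexp)
  failures <- 0
  for (s in 1:20) {
    cfg$seed <- s
    w <- sample_window(ls, NULL, c(0, 0), cfg, keep_trajectory = TRUE,
                       thin = 1000L)
    phi <- w$trajectory[, 1]
    phi <- phi[phi >= -55 & phi < 55]
    obs <- tabulate(findInterval(phi, edges, rightmost.closed = TRUE), nbins = 8)
    chi2 <- sum((obs - length(phi) * pexp)^2 / (length(phi) * pexp))
    if (chi2 > qchisq(0.99, df = 7)) failures <- failures + 1
  }
  expect_lte(failures, 1)
})

test_that("metric tensors come out as identity or normalized inverse covariance", {
  cfg <- sampler_config(n_steps = 2e5)
  w <- sample_window(flat_landscape(), NULL, c(0, 0), cfg)
  expect_identical(metric_tensor(w, "identity"), diag(2))
  M <- metric_tensor(w, "covariance")
  expect_equal(det(M), 1, tolerance = 1e-9)
  expect_equal(M, diag(2), tolerance = 0.1)
  degenerate <- structure(list(center = c(0, 0), mean_op = c(0, 0),
                               covariance = matrix(0, 2, 2),
                               mean_restraint_force = c(0, 0),
                               n_effective = 10L, spring = 100,
                               temperature = 298.15, trajectory = NULL),
                          class = "window_sample")
  expect_error(metric_tensor(degenerate, "covariance"), "singular")
})

test_that("invalid sampler settings are rejected up front", {
  expect_error(sampler_config(n_steps = 500))
  expect_error(sampler_config(time_step = 0))
  expect_error(sampler_config(spring = -1))
  expect_error(sampler_config(burn_in_fraction = 1))
  # stability: dt * m * (spring + curvature) must stay below 0.5
  bad <- sampler_config(time_step = 0.01)
  expect_error(sample_window(flat_landscape(), NULL, c(0, 0), bad),
               "stability")
})
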