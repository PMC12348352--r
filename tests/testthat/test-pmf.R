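test_that("zero forces give a flat profile and barrier zero", {
  st <- initialize_string(c(0, 0), c(40, 40), 8)
  prof <- integrate_mean_force(st, matrix(0, 8, 2))
  expect_equal(prof$F, rep(0, 8))
  b <- barrier(prof)
  expect_equal(b$height, 0)
  expect_error(integrate_mean_force(st, matrix(0, 5, 2)), "align")
})

test_that("dense exact-gradient windows recover the built-in profile", {
  ls <- default_landscape_cached()
  r <- run_fts(ls, NULL, fts_config(), seed = 1, exact_forces = TRUE)
  pm <- pmf_from_fts(ls, r, exact_forces = TRUE)
  Fd <- free_energy(ls, pm$string$images)
  Fd <- Fd - Fd[1]
  expect_lt(max(abs(pm$profile$F - Fd)), 1)
  b <- barrier(pm$profile)
  expect_equal(b$height, 18.3, tolerance = 0.05)  # relative: ~0.9 kJ/mol
  expect_equal(unname(pm$string$images[which.max(pm$profile$F), 1]), 48,
               tolerance = 0.05)
})

test_that("reversing the string reverses the profile but not the barrier", {
  st <- initialize_string(c(0, 0), c(60, 30), 10)
  set.seed(5)
  f <- matrix(rnorm(20), 10, 2)
  prof <- integrate_mean_force(st, f)
  str_rev <- fts_string(st$images[10:1, ])
  prof_rev <- integrate_mean_force(str_rev, f[10:1, ])
  expect_equal(prof_rev$F, rev(prof$F) - prof$F[10], tolerance = 1e-12)
  expect_equal(barrier(prof, "conformation2")$height,
               barrier(prof_rev, "conformation1")$height, tolerance = 1e-12)
})

test_that("barrier extraction handles monotone, flat and tied profiles", {
  mono <- pmf_profile(seq(0, 1, length.out = 5), c(0, 1, 2, 3, 4))
  b <- barrier(mono, "conformation1")
  expect_equal(b$height, 4)
  expect_equal(b$alpha, 1)
  expect_equal(barrier(pmf_profile(0:4 / 4, rep(2, 5)))$height, 0)
  tied <- pmf_profile(0:3 / 3, c(0, 5, 5, 0))
  expect_equal(barrier(tied)$alpha, 1 / 3)  # ties break toward smaller alpha
})

test_that("WHAM recovers a known double-well profile from window samples", {
  ls <- doublewell_landscape(barrier = 4)
  centers <- cbind(seq(-60, 60, by = 10), 0)
  cfg <- sampler_config(time_step = 2e-4, n_steps = 2e4, spring = 100)
  ws <- ftspath:::.sample_windows(ls, NULL, centers, cfg, seed = 8,
                                  keep_traj = TRUE, thin = 10L)
  st <- initialize_string(c(-60, 0), c(60, 0), 13)
  prof <- wham_profile(ws, st, bins = 60)
  truth <- free_energy(ls, cbind(-60 + prof$alpha * 120, 0))
  ok <- is.finite(prof$F)
  dev <- (prof$F - truth)[ok]
  dev <- dev - mean(dev)  # common gauge
  expect_lt(sqrt(mean(dev^2)), 1)
})

test_that("WHAM rejects degenerate and non-overlapping window sets", {
  ls <- doublewell_landscape()
  cfg <- sampler_config(time_step = 2e-4, n_steps = 2000, spring = 100)
  w1 <- sample_window(ls, NULL, c(0, 0), cfg, keep_trajectory = TRUE)
  st <- initialize_string(c(-60, 0), c(60, 0), 6)
  expect_error(wham_profile(list(w1), st), "at least 4")
  w2 <- sample_window(ls, NULL, c(-60, 0), cfg)  # no trajectory
  expect_error(wham_profile(list(w1, w1, w1, w2), st), "trajectories")
  # windows far apart with a stiff spring cannot overlap
  stiff <- sampler_config(time_step = 2e-5, n_steps = 5000, spring = 8000)
  far <- ftspath:::.sample_windows(ls, NULL,
                                   cbind(c(-60, -50, 30, 60), 0), stiff,
                                   seed = 3, keep_traj = TRUE)
  expect_error(wham_profile(far, st), "overlap")
})

test_that("line-integral and WHAM profiles agree on the default landscape", {
  run <- default_pipeline_run(1)
  ls <- default_landscape_cached()
  pm <- pmf_from_fts(ls, run$fts, keep_trajectories = TRUE, traj_thin = 100L)
  wh <- wham_profile(pm$windows, pm$string, bins = 400)
  li <- approx(pm$profile$alpha, pm$profile$F, xout = wh$alpha)$y
  ok <- is.finite(wh$F) & is.finite(li)
  dev <- (wh$F - li)[ok]
  dev <- dev - mean(dev)
  expect_lt(sqrt(mean(dev^2)), 1.5)
})

test_that("landscape grids are gauged, periodic and field-direction blind", {
  ls <- default_landscape_cached()
  g <- landscape_grid(ls, resolution = 720L)
  expect_equal(min(g$F), 0, tolerance = 1e-9)
  i <- arrayInd(which.min(g$F), dim(g$F))
  expect_equal(c(g$phi[i[1]], g$psi[i[2]]), c(168.5, 153.0))
  f <- 41.14e8
  gx <- landscape_grid(ls, field_spec("x", 1, f), resolution = 60L)
  gy <- landscape_grid(ls, field_spec("y", 1, f), resolution = 60L)
  gz <- landscape_grid(ls, field_spec("z", -1, f), resolution = 60L)
  expect_identical(gx$F, gy$F)
  expect_identical(gx$F, gz$F)
  expect_error(landscape_grid(ls, resolution = 5))
})

test_that("adding a constant to the potential leaves gradients unchanged", {
  wp <- data.frame(s = c(0, 0.5, 1), phi = c(0, 30, 60), psi = c(0, 20, 10))
  pc <- data.frame(s = c(0, 0.5, 1), F = c(1, 6, 0))
  l1 <- landscape_spec(path_spec(wp, pc), transverse_stiffness = 0.05)
  pc2 <- pc; pc2$F <- pc$F + 7
  l2 <- landscape_spec(path_spec(wp, pc2), transverse_stiffness = 0.05)
  set.seed(2)
  pts <- matrix(runif(20, -90, 90), ncol = 2)
  expect_equal(free_energy_gradient(l1, pts), free_energy_gradient(l2, pts),
               tolerance = 1e-9)
  expect_equal(free_energy(l2, pts) - free_energy(l1, pts), rep(7, 10),
               tolerance = 1e-9)
})
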