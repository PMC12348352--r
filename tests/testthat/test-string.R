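test_that("initial strings interpolate along the shortest arc", {
  s <- initialize_string(c(0, 0), c(168.5, 153.0), 20)
  expect_equal(nrow(s$images), 20)
  expect_identical(unname(s$images[1, ]), c(0, 0))
  expect_identical(unname(s$images[20, ]), c(168.5, 153.0))
  expect_equal(unname(s$images[2, ]), c(168.5, 153.0) / 19, tolerance = 1e-9)
  # crossing the +/-180 seam
  sx <- initialize_string(c(-170, 0), c(170, 0), 5)
  expect_equal(unname(sx$images[, 1]), c(-170, -175, -180, 175, 170))
  expect_error(initialize_string(c(1, 2), c(1, 2), 5))
})

test_that("image updates move perpendicular to the string only", {
  st <- initialize_string(c(0, 0), c(40, 0), 5)  # straight line along phi
  n <- nrow(st$images)
  # tangential forces produce no displacement
  f_tan <- cbind(rep(2, n), rep(0, n))
  expect_equal(update_images(st, f_tan, NULL, step = 1)$images, st$images,
               tolerance = 1e-12)
  # perpendicular force: displacement = -step * f (downhill), capped
  f_perp <- cbind(rep(0, n), rep(0.5, n))
  up <- update_images(st, f_perp, NULL, step = 2, cap = 3)
  expect_equal(unname(up$images[2:4, 2]), rep(-1, 3), tolerance = 1e-12)
  expect_equal(up$images[c(1, n), ], st$images[c(1, n), ])  # anchors
  capd <- update_images(st, f_perp * 100, NULL, step = 2, cap = 3)
  expect_equal(unname(abs(capd$images[3, 2])), 3, tolerance = 1e-12)
  # metric tensor scales the displacement linearly
  M2 <- replicate(n, 2 * diag(2), simplify = FALSE)
  up2 <- update_images(st, f_perp, M2, step = 2, cap = 10)
  expect_equal(up2$images[3, 2], 2 * up$images[3, 2], tolerance = 1e-12)
  # coincident neighbors give a zero tangent
  bad <- fts_string(rbind(c(0, 0), c(5, 0), c(0, 0.01), c(5, 0.01)))
  bad$images[3, ] <- bad$images[1, ]  # z[i-1] == z[i+1]
  expect_error(update_images(bad, matrix(0, 4, 2), NULL, step = 1), "tangent")
})

test_that("reparameterization restores equal arc lengths", {
  straight <- initialize_string(c(0, 0), c(40, 0), 9)
  expect_equal(reparameterize(straight)$images, straight$images,
               tolerance = 1e-12)
  expect_error(fts_string(rbind(c(0, 0), c(0, 10))))  # too short
  el4 <- fts_string(rbind(c(0, 0), c(0, 6), c(0, 10), c(10, 10)))
  rp <- reparameterize(el4)
  # equal spacing in arc length along the original polyline (chords across
  # the corner are necessarily shorter than the arc)
  arc <- ftspath:::.project_arc(rp$images, el4)
  expect_lt(max(abs(diff(arc) - mean(diff(arc)))), 1e-6)
  # arc midpoint of the elbow polyline (total length 20) is the corner
  mid <- ftspath:::.resample_string(el4, 5)
  expect_equal(unname(mid$images[3, ]), c(0, 10), tolerance = 1e-9)
})

test_that("smoothing damps zig-zag and fixes collinear strings", {
  st <- initialize_string(c(0, 0), c(40, 0), 9)
  expect_equal(smooth_string(st, 0)$images, st$images)
  expect_equal(smooth_string(st, 0.3)$images, st$images, tolerance = 1e-12)
  h <- 2
  zig <- fts_string(rbind(c(0, 0), c(10, 0), c(20, h), c(30, 0), c(40, 0)))
  sm <- smooth_string(zig, 0.1)
  expect_equal(unname(sm$images[3, 2]), 0.9 * h, tolerance = 1e-12)
  expect_error(smooth_string(st, 1))
})

test_that("the string converges to a straight valley floor", {
  ls <- valley_landscape()
  cfg <- fts_config(n_images = 12, convergence_tol = 0.05)
  r <- run_fts(ls, NULL, cfg, seed = 4, exact_forces = TRUE)
  expect_true(r$converged)
  expect_lt(sqrt(mean(r$string$images[, 2]^2)), 1)
})

test_that("the zero-temperature limit recovers the built-in path", {
  ls <- default_landscape_cached()
  r <- run_fts(ls, NULL, fts_config(), seed = 1, exact_forces = TRUE)
  expect_true(r$converged)
  expect_lte(r$iterations_run, 100)
  d <- ftspath:::.fe_detail(ls, r$string$images)
  expect_lt(sqrt(mean(d$d^2)), 1)
  # convergence flag implies the displacement criterion
  w <- r$config$convergence_window
  expect_true(all(tail(r$displacement_history, w) < r$config$convergence_tol))
})

test_that("equal-arc spacing holds after every iteration", {
  ls <- valley_landscape()
  r <- run_fts(ls, NULL, fts_config(n_images = 8, max_iterations = 5,
                                    convergence_tol = 1e-6),
               seed = 2, exact_forces = TRUE)
  for (st in r$string_history[-1]) {
    seg <- torus_dist(st$images[-1, ], st$images[-nrow(st$images), ])
    expect_lt(max(abs(seg - mean(seg))) / mean(seg), 1e-6)
  }
})
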