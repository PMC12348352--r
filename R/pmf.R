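# Free-energy reconstruction along the string: line integral of the mean
# force (trapezoidal, torus-aware) and a WHAM cross-check on the projected
# path coordinate, plus barrier extraction and 2-D landscape export.

#' Construct a PMF profile
#'
#' @param alpha Parameter grid in \[0, 1\].
#' @param F Free energy per node, kJ/mol; gauged so the first finite value
#'   is 0.
#' @return Object of class `"pmf_profile"` (data frame `alpha`, `F`).
#' @export
pmf_profile <- function(alpha, F) {
  stopifnot(length(alpha) == length(F), !is.unsorted(alpha))
  F <- F - F[which(is.finite(F))[1]]  # gauge: F = 0 at the first node
  structure(data.frame(alpha = alpha, F = F),
            class = c("pmf_profile", "data.frame"))
}

#' Line-integral PMF from per-image mean forces
#'
#' Trapezoidal cumulative integral
#' `F(alpha_i) = sum_j 1/2 (f_j + f_{j+1}) . (z_{j+1} - z_j)` with the
#' displacement taken along the shortest arc and converted to radians to
#' match the force units; gauged to 0 at `alpha = 0`.
#'
#' @param string An `fts_string`.
#' @param forces n x 2 matrix of mean forces at the images,
#'   kJ mol^-1 rad^-1 (as returned by [mean_force()]).
#' @return A [pmf_profile()].
#' @export
integrate_mean_force <- function(string, forces) {
  stopifnot(inherits(string, "fts_string"))
  forces <- matrix(forces, ncol = 2)
  n <- nrow(string$images)
  if (nrow(forces) != n) stop("forces must align with the images")
  dz <- angle_diff(string$images[-1, , drop = FALSE],
                   string$images[-n, , drop = FALSE]) * pi / 180
  mid <- 0.5 * (forces[-1, , drop = FALSE] + forces[-n, , drop = FALSE])
  dF <- rowSums(mid * matrix(dz, ncol = 2))
  pmf_profile(string$alpha, c(0, cumsum(dF)))
}

#' Barrier height of a PMF profile
#'
#' `max(F) - F(end)` for the chosen reference end; ties in the maximum are
#' broken toward the smaller `alpha`. The conformation-2 end is `alpha = 1`
#' (path-end convention), conformation 1 is `alpha = 0`.
#'
#' @param profile A `pmf_profile`.
#' @param from_end `"conformation2"` (default) or `"conformation1"`.
#' @return List with `height` (kJ/mol) and `alpha` of the maximum.
#' @export
barrier <- function(profile, from_end = c("conformation2", "conformation1")) {
  from_end <- match.arg(from_end)
  stopifnot(inherits(profile, "pmf_profile"))
  ok <- is.finite(profile$F)
  Fv <- profile$F[ok]; a <- profile$alpha[ok]
  i <- which.max(Fv)  # which.max takes the first (smallest alpha) on ties
  ref <- if (from_end == "conformation2") Fv[length(Fv)] else Fv[1]
  list(height = Fv[i] - ref, alpha = a[i])
}

# Arc-length coordinate of points projected onto the string polyline
# (nearest point, torus metric). Returns arc positions in degrees.
# Vectorized over points, looping over segments.
.project_arc <- function(points, string) {
  z <- .unwrap_path(string$images)
  n <- nrow(z)
  seg <- diff(z)
  seglen <- sqrt(rowSums(seg^2))
  arc0 <- c(0, cumsum(seglen))
  pts <- .as_points(points)
  best_d2 <- rep(Inf, nrow(pts))
  out <- numeric(nrow(pts))
  for (j in seq_len(n - 1)) {
    dx <- angle_diff(pts[, 1], z[j, 1])
    dy <- angle_diff(pts[, 2], z[j, 2])
    t <- (dx * seg[j, 1] + dy * seg[j, 2]) / seglen[j]^2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (dx - t * seg[j, 1])^2 + (dy - t * seg[j, 2])^2
    hit <- d2 < best_d2
    best_d2[hit] <- d2[hit]
    out[hit] <- arc0[j] + t[hit] * seglen[j]
  }
  attr(out, "total_length") <- arc0[n]
  out
}

#' WHAM estimate of the PMF on the path coordinate
#'
#' Window samples are projected to the arc-length coordinate of the final
#' string; the harmonic restraint enters as its along-path component. The
#' standard self-consistent histogram equations are iterated on `bins`
#' equal-width bins until the maximum change of the window free-energy
#' shifts falls below `tol`.
#'
#' @param windows List of `window_sample` objects carrying trajectories
#'   (see `keep_trajectory` in [sample_window()]); at least 4.
#' @param string The `fts_string` defining the path coordinate.
#' @param bins Number of histogram bins (default 100).
#' @param tol Convergence threshold on the free-energy shifts, kJ/mol.
#' @param max_iter Iteration budget for the self-consistency loop.
#' @param min_overlap Minimum histogram overlap coefficient required
#'   between adjacent windows.
#' @return A [pmf_profile()] on the bin centers (alpha = arc fraction);
#'   bins never visited carry `NA`.
#' @export
wham_profile <- function(windows, string, bins = 100L, tol = 1e-6,
                         max_iter = 10000L, min_overlap = 0.05) {
  if (length(windows) < 4) stop("need at least 4 windows for WHAM")
  if (any(!vapply(windows, function(w) !is.null(w$trajectory), logical(1))))
    stop("all windows must carry trajectories (keep_trajectory = TRUE)")
  RT <- .RT(windows[[1]]$temperature)
  kappa_deg <- windows[[1]]$spring / .DEG2

  arcs <- lapply(windows, function(w) .project_arc(w$trajectory, string))
  L <- attr(arcs[[1]], "total_length")
  centers_arc <- vapply(windows, function(w)
    .project_arc(rbind(w$center), string)[1], numeric(1))

  edges <- seq(0, L, length.out = bins + 1)
  mids <- 0.5 * (edges[-1] + edges[-(bins + 1)])
  counts <- vapply(arcs, function(a) {
    tabulate(pmin(pmax(findInterval(a, edges, rightmost.closed = TRUE), 1L),
                  bins), nbins = bins)
  }, numeric(bins))

  # adjacent-window overlap audit (windows ordered along the path)
  ord <- order(centers_arc)
  for (k in seq_len(length(ord) - 1)) {
    p1 <- counts[, ord[k]] / sum(counts[, ord[k]])
    p2 <- counts[, ord[k + 1]] / sum(counts[, ord[k + 1]])
    ov <- sum(pmin(p1, p2))
    if (ov < min_overlap)
      stop(sprintf(
        "insufficient overlap (%.3f) between adjacent windows at arc %.1f and %.1f deg",
        ov, centers_arc[ord[k]], centers_arc[ord[k + 1]]))
  }

  W <- length(windows)
  Ni <- colSums(counts)
  bias <- outer(mids, centers_arc, function(x, c) 0.5 * kappa_deg * (x - c)^2)
  expb <- exp(-bias / RT)        # bins x windows
  f <- numeric(W)                # window free-energy shifts, kJ/mol
  nj <- rowSums(counts)
  for (it in seq_len(max_iter)) {
    denom <- as.numeric(expb %*% (Ni * exp(f / RT)))
    P <- nj / denom
    fnew <- -RT * log(as.numeric(crossprod(expb, P)))
    fnew <- fnew - fnew[1]
    if (max(abs(fnew - f)) < tol) { f <- fnew; break }
    f <- fnew
  }
  F <- -RT * log(P / sum(P[is.finite(P) & P > 0]))
  F[!is.finite(F) | nj == 0] <- NA_real_
  pmf_profile(mids / L, F)
}

# Resample a string polyline to n_out equal-arc nodes (piecewise linear).
.resample_string <- function(string, n_out) {
  z <- .unwrap_path(string$images)
  n <- nrow(z)
  arc <- c(0, cumsum(sqrt(rowSums(diff(z)^2))))
  target <- seq(0, arc[n], length.out = n_out)
  out <- cbind(approx(arc, z[, 1], xout = target, ties = "ordered")$y,
               approx(arc, z[, 2], xout = target, ties = "ordered")$y)
  out[1, ] <- z[1, ]; out[n_out, ] <- z[n, ]
  fts_string(wrap_angle(out))
}

#' PMF along a converged string: refinement plus a dense window pass
#'
#' The free-energy profile varies on arc scales far shorter than the
#' spacing of the string images, so the line-integral PMF is computed in
#' three stages on top of a converged [run_fts()] string:
#'
#' 1. the string is resampled to `n_refine` images and relaxed for a few
#'    further iterations with progressively stiffer restraints
#'    (`refine_samplers`), pulling the dense string onto the valley floor
#'    where the coarse string cuts corners;
#' 2. `n_windows` umbrella windows are placed at equal arc length along the
#'    refined string and sampled with a stiff spring (`window_sampler`),
#'    whose fluctuation width (about 0.6 degrees at the default
#'    8000 kJ/mol/rad^2) both localizes each window against the steepest
#'    parts of the profile and sets the scale the window spacing must
#'    resolve;
#' 3. the mean forces are integrated with [integrate_mean_force()].
#'
#' With `exact_forces = TRUE` the same geometry is used but the mean forces
#' are the analytic free-energy gradients (deterministic; the
#' zero-temperature limit).
#'
#' @inheritParams free_energy
#' @param result An `fts_result` from [run_fts()].
#' @param n_refine Images of the refined string.
#' @param refine_iterations Iterations per refinement stage (same length as
#'   `refine_samplers`).
#' @param refine_samplers List of [sampler_config()]s, one per refinement
#'   stage.
#' @param refine_step,refine_cap String-update step size and per-image cap
#'   (degrees) during refinement.
#' @param n_windows Windows of the final force pass.
#' @param window_sampler A [sampler_config()] for the final pass.
#' @param seed Seed stream base (default: derived from the run's master
#'   seed).
#' @param exact_forces Use analytic gradients instead of sampling.
#' @param keep_trajectories Keep thinned trajectories of the final windows
#'   (for [wham_profile()]).
#' @param traj_thin Keep every `traj_thin`-th production step when
#'   trajectories are retained.
#' @return List with `profile` (a [pmf_profile()] on the window nodes),
#'   `string` (the refined window `fts_string`), `forces`
#'   (kJ mol^-1 rad^-1) and `windows` (final window samples or `NULL`).
#' @export
pmf_from_fts <- function(landscape, result, field = NULL,
                         n_refine = 121L,
                         refine_iterations = c(12L, 8L),
                         refine_samplers = list(
                           sampler_config(time_step = 1e-4, n_steps = 5e3,
                                          spring = 2000),
                           sampler_config(time_step = 2e-5, n_steps = 12500,
                                          spring = 8000)),
                         refine_step = 5, refine_cap = 1,
                         n_windows = 541L,
                         window_sampler = sampler_config(time_step = 2e-5,
                                                         n_steps = 75000,
                                                         spring = 8000),
                         seed = NULL, exact_forces = FALSE,
                         keep_trajectories = FALSE, traj_thin = 100L) {
  stopifnot(inherits(result, "fts_result"),
            length(refine_iterations) == length(refine_samplers))
  if (is.null(field)) field <- result$field
  if (is.null(seed)) seed <- .iter_seed(result$seed, 424242L)

  st <- .resample_string(result$string, n_refine)
  k <- 0L
  for (stage in seq_along(refine_samplers)) {
    cfg <- refine_samplers[[stage]]
    for (it in seq_len(refine_iterations[stage])) {
      k <- k + 1L
      f <- if (exact_forces) {
        free_energy_gradient(landscape, st$images, field)
      } else {
        ws <- .sample_windows(landscape, field, st$images, cfg,
                              seed = seed + k)
        t(vapply(ws, mean_force, numeric(2))) * pi / 180
      }
      st <- update_images(st, f, NULL, step = refine_step, cap = refine_cap)
      st <- smooth_string(st, 0.1)
      st <- reparameterize(st)
    }
  }

  fine <- .resample_string(st, n_windows)
  if (exact_forces) {
    forces <- free_energy_gradient(landscape, fine$images, field) * 180 / pi
    windows <- NULL
  } else {
    windows <- .sample_windows(landscape, field, fine$images, window_sampler,
                               seed = seed + 997L,
                               keep_traj = keep_trajectories,
                               thin = traj_thin)
    forces <- t(vapply(windows, mean_force, numeric(2)))
  }
  list(profile = integrate_mean_force(fine, forces), string = fine,
       forces = forces, windows = windows)
}

#' Evaluate the landscape on a regular torus grid
#'
#' @inheritParams free_energy
#' @param resolution Nodes per axis (>= 10); grid step is
#'   `360 / resolution` degrees starting at -180.
#' @return List of class `"fe_grid"`: `phi`, `psi` (axes, degrees) and `F`
#'   (matrix, rows indexed by `phi`).
#' @export
landscape_grid <- function(landscape, field = NULL, resolution = 360L) {
  stopifnot(resolution >= 10)
  step <- 360 / resolution
  phi <- seq(-180, 180 - step, by = step)
  psi <- phi
  pts <- cbind(rep(phi, times = length(psi)), rep(psi, each = length(phi)))
  F <- matrix(free_energy(landscape, pts, field),
              nrow = length(phi), ncol = length(psi))
  structure(list(phi = phi, psi = psi, F = F), class = "fe_grid")
}
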