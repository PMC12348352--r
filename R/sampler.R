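# Restrained overdamped Langevin dynamics in order-parameter space and the
# umbrella-window estimators of the mean force and metric tensor.
#
# Overdamped update (internally in degree coordinates, with the spring
# constant and mobility converted from their radian-based units):
#   z <- z - dt * m * grad(F + U) + sqrt(2 RT m dt) * (xi_n + xi_{n+1}) / 2,
#   U = 1/2 * kappa * |z - center|^2,
# the Leimkuhler-Matthews variant of Euler-Maruyama: averaging consecutive
# noise increments makes the stationary distribution (prop. to
# exp(-(F + U)/RT)) second-order accurate in dt at no extra force cost.

.DEG2 <- (180 / pi)^2  # rad^2 -> deg^2

#' Sampler configuration
#'
#' @param time_step Integration step, reduced time units.
#' @param mobility Mobility, rad^2 per kJ mol^-1 per time unit. With the
#'   default spring this gives a window relaxation time of about
#'   `1/(mobility * spring)` = 0.01 time units (10 steps).
#' @param temperature Kelvin.
#' @param n_steps Production (retained) steps per window.
#' @param burn_in_fraction Burn-in run before production, as a fraction of
#'   `n_steps`; discarded.
#' @param seed Integer seed.
#' @param spring Harmonic restraint constant per order parameter,
#'   kJ mol^-1 rad^-2.
#' @return Object of class `"sampler_config"`.
#' @export
sampler_config <- function(time_step = 1e-3, mobility = 1.0,
                           temperature = 298.15, n_steps = 2e4,
                           burn_in_fraction = 0.1, seed = 1L,
                           spring = 100.0) {
  stopifnot(time_step > 0, mobility > 0, temperature > 0,
            n_steps >= 1000, burn_in_fraction >= 0, burn_in_fraction < 1,
            spring > 0)
  structure(list(time_step = time_step, mobility = mobility,
                 temperature = temperature, n_steps = as.integer(n_steps),
                 burn_in_fraction = burn_in_fraction,
                 seed = as.integer(seed), spring = spring),
            class = "sampler_config")
}

# Global harmonic curvature of the landscape (kJ/mol/rad^2): the transverse
# stiffness, the surface's only global quadratic term. Pockets of large
# along-path profile curvature are transient for a restrained walker and
# are controlled by the step size of the landscape half-kicks instead.
.max_curvature_rad <- function(landscape) {
  landscape$transverse_stiffness * .DEG2
}

.check_stability <- function(landscape, config) {
  lhs <- config$time_step * config$mobility *
    (config$spring + .max_curvature_rad(landscape))
  if (lhs >= 0.5)
    stop("sampler stability condition violated: dt * mobility * ",
         "(spring + max curvature) = ", signif(lhs, 4), " >= 0.5")
  invisible(lhs)
}

# Propagate several windows at once with one RNG stream (one C++ call).
# Returns a list of window_sample objects.
.sample_windows <- function(landscape, field, centers, config, seed,
                            keep_traj = FALSE, thin = 10L) {
  .check_stability(landscape, config)
  centers <- .as_points(centers)
  eff <- .effective_prof(landscape, field)
  kappa_deg <- config$spring / .DEG2
  mob_deg <- config$mobility * .DEG2
  RT <- .RT(config$temperature)
  nburn <- as.integer(round(config$burn_in_fraction * config$n_steps))
  # local projection window: wide enough to track the largest plausible
  # per-step displacement (noise + drift), re-anchored by a periodic full
  # projection
  spacing <- max(sqrt(rowSums(diff(landscape$dense$nodes)^2)))
  step_deg <- 4 * sqrt(2 * RT * mob_deg * config$time_step) +
    config$time_step * mob_deg * 2
  halfwin <- as.integer(min(ceiling(step_deg / spacing) + 10L,
                            nrow(landscape$dense$nodes) - 1L))
  res <- .run_windows_cpp(centers, landscape$dense$nodes, eff$prof,
                          eff$dprof_t, landscape$transverse_stiffness,
                          kappa_deg, RT, mob_deg, config$time_step,
                          config$n_steps, nburn,
                          as.numeric(seed), as.integer(thin), keep_traj,
                          500L, halfwin)
  lapply(seq_len(nrow(centers)), function(w) {
    cov_deg <- matrix(res$cov[w, ], 2, 2)
    traj <- NULL
    if (keep_traj) {
      traj <- res$traj[, c(2 * w - 1, 2 * w), drop = FALSE]
      colnames(traj) <- c("phi", "psi")
    }
    structure(list(center = centers[w, ],
                   mean_op = wrap_angle(res$mean_op[w, ]),
                   covariance = cov_deg / .DEG2,
                   mean_restraint_force = config$spring *
                     angle_diff(centers[w, ], res$mean_op[w, ]) * pi / 180,
                   n_effective = res$n_kept,
                   spring = config$spring,
                   temperature = config$temperature,
                   trajectory = traj),
              class = "window_sample")
  })
}

#' Sample one umbrella window
#'
#' Restrained overdamped dynamics around `center`; the stability condition
#' `dt * mobility * (spring + max curvature) < 0.5` is checked before the
#' run, burn-in is discarded, and the result is a pure function of the
#' inputs and the seed.
#'
#' @inheritParams free_energy
#' @param center Window center, `c(phi, psi)` degrees.
#' @param config A [sampler_config()]; its `seed` drives the stream.
#' @param keep_trajectory Keep a thinned trajectory (needed by
#'   [wham_profile()]).
#' @param thin Keep every `thin`-th production step when
#'   `keep_trajectory = TRUE`.
#' @return Object of class `"window_sample"`: `center`, `mean_op` (degrees),
#'   `covariance` (2 x 2, rad^2), `mean_restraint_force` (kJ mol^-1 rad^-1),
#'   `n_effective`, and optionally `trajectory`.
#' @export
sample_window <- function(landscape, field = NULL, center,
                          config = sampler_config(),
                          keep_trajectory = FALSE, thin = 10L) {
  stopifnot(inherits(config, "sampler_config"))
  .sample_windows(landscape, field, rbind(.as_points(center)), config,
                  seed = config$seed, keep_traj = keep_trajectory,
                  thin = thin)[[1]]
}

#' @export
print.window_sample <- function(x, ...) {
  cat("<window_sample>\n")
  cat(sprintf("  center:  (%8.3f, %8.3f) deg\n", x$center[1], x$center[2]))
  cat(sprintf("  mean OP: (%8.3f, %8.3f) deg  (n = %d)\n",
              x$mean_op[1], x$mean_op[2], x$n_effective))
  f <- mean_force(x)
  cat(sprintf("  mean force: (%.3f, %.3f) kJ/mol/rad\n", f[1], f[2]))
  invisible(x)
}

#' Mean-force estimator of a window
#'
#' The restraint-force estimator of the free-energy gradient at the window
#' center: `kappa * (center - mean_op)` (radian units), exact to first
#' order in RT/kappa.
#'
#' @param window A `window_sample`.
#' @return Length-2 numeric, kJ mol^-1 rad^-1.
#' @export
mean_force <- function(window) {
  stopifnot(inherits(window, "window_sample"))
  unname(window$spring * angle_diff(window$center, window$mean_op) * pi / 180)
}

#' Metric tensor of a window
#'
#' `identity` mode returns the 2 x 2 identity (the default preconditioner of
#' the string evolution). `covariance` mode returns `RT * solve(covariance)`
#' normalized to unit determinant, a kinematic preconditioner estimated from
#' the window fluctuations.
#'
#' @param window A `window_sample`.
#' @param mode `"identity"` or `"covariance"`.
#' @return 2 x 2 matrix.
#' @export
metric_tensor <- function(window, mode = c("identity", "covariance")) {
  mode <- match.arg(mode)
  if (mode == "identity") return(diag(2))
  stopifnot(inherits(window, "window_sample"))
  S <- window$covariance
  dS <- det(S)
  if (!is.finite(dS) || dS <= .Machine$double.eps * max(abs(S))^2)
    stop("singular window covariance; cannot form the covariance-mode tensor")
  M <- .RT(window$temperature) * solve(S)
  M / sqrt(det(M))
}
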