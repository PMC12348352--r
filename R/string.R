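# Finite-temperature string method: the string is an ordered set of images
# in (phi, psi) space evolving downhill along the component of the mean
# force perpendicular to itself, with endpoint anchoring, per-iteration
# smoothing and equal-arc-length reparameterization.

#' Construct a string state
#'
#' @param images n x 2 matrix of image coordinates, degrees.
#' @return Object of class `"fts_string"` with `images` and the uniform
#'   parameter grid `alpha` on \[0, 1\].
#' @export
fts_string <- function(images) {
  images <- .as_points(images)
  n <- nrow(images)
  if (n < 4) stop("a string needs at least 4 images")
  if (any(torus_dist(images[-1, , drop = FALSE],
                     images[-n, , drop = FALSE]) == 0))
    stop("consecutive images must be distinct")
  structure(list(images = images, alpha = seq(0, 1, length.out = n)),
            class = "fts_string")
}

#' @export
print.fts_string <- function(x, ...) {
  n <- nrow(x$images)
  cat(sprintf("<fts_string> %d images, arc length %.2f deg\n",
              n, sum(torus_dist(x$images[-1, ], x$images[-n, ]))))
  invisible(x)
}

#' Initial string between two conformations
#'
#' Shortest-arc linear interpolation per coordinate on the torus; the
#' endpoints equal `a` and `b` exactly.
#'
#' @param a,b Endpoint points `c(phi, psi)`, degrees; must differ.
#' @param n_images Number of images including both endpoints.
#' @return An [fts_string()].
#' @export
#' @examples
#' s <- initialize_string(c(0, 0), c(168.5, 153.0), 20)
#' s$images[2, ]  # (8.87, 8.05)
initialize_string <- function(a, b, n_images = 20L) {
  a <- wrap_angle(as.numeric(a)); b <- wrap_angle(as.numeric(b))
  if (all(a == b)) stop("endpoints must differ")
  t <- seq(0, 1, length.out = n_images)
  d <- angle_diff(b, a)
  images <- cbind(a[1] + t * d[1], a[2] + t * d[2])
  images[1, ] <- a; images[n_images, ] <- b  # exact endpoints
  fts_string(images)
}

#' Evolve the string images by the projected mean force
#'
#' Interior images move by `-step * P %*% M %*% f`, where
#' `P = I - t t'` projects out the component along the local tangent
#' (central-difference tangent, one-sided at the ends), `M` is the metric
#' tensor and `f` the mean force at the image. Per-image displacement is
#' capped; endpoints are anchored.
#'
#' @param string An `fts_string`.
#' @param forces n x 2 matrix of mean forces at the images,
#'   kJ mol^-1 deg^-1.
#' @param tensors List of n 2 x 2 metric tensors, or `NULL` for identity.
#' @param step Step size, deg^2 per (kJ mol^-1 deg^-1).
#' @param cap Maximum per-image displacement, degrees.
#' @return The evolved `fts_string`.
#' @export
update_images <- function(string, forces, tensors = NULL, step, cap = 3) {
  stopifnot(inherits(string, "fts_string"), step > 0, cap > 0)
  z <- .unwrap_path(string$images)
  n <- nrow(z)
  forces <- matrix(forces, ncol = 2)
  if (nrow(forces) != n) stop("forces must align with the images")
  if (!is.null(tensors) && length(tensors) != n)
    stop("tensors must align with the images")
  out <- z
  for (i in 2:(n - 1)) {
    tan <- z[i + 1, ] - z[i - 1, ]
    len <- sqrt(sum(tan^2))
    if (len == 0) stop("zero-length tangent at image ", i,
                       " (coincident neighbors)")
    that <- tan / len
    P <- diag(2) - tcrossprod(that)
    M <- if (is.null(tensors)) diag(2) else tensors[[i]]
    disp <- -step * as.numeric(P %*% M %*% forces[i, ])
    dn <- sqrt(sum(disp^2))
    if (dn > cap) disp <- disp * cap / dn
    out[i, ] <- z[i, ] + disp
  }
  fts_string(wrap_angle(out))
}

#' Redistribute images to equal arc length
#'
#' Piecewise-linear interpolation along the current polyline (torus-aware);
#' endpoints fixed, total length preserved to rounding.
#'
#' @param string An `fts_string`.
#' @return The reparameterized `fts_string`; consecutive arc segments are
#'   equal to within 1e-6 of their mean.
#' @export
reparameterize <- function(string) {
  stopifnot(inherits(string, "fts_string"))
  z <- .unwrap_path(string$images)
  n <- nrow(z)
  seg <- sqrt(rowSums(diff(z)^2))
  arc <- c(0, cumsum(seg))
  target <- seq(0, arc[n], length.out = n)
  out <- cbind(approx(arc, z[, 1], xout = target, ties = "ordered")$y,
               approx(arc, z[, 2], xout = target, ties = "ordered")$y)
  out[1, ] <- z[1, ]; out[n, ] <- z[n, ]
  fts_string(wrap_angle(out))
}

#' Smooth the interior of a string
#'
#' `z_i <- (1 - lambda) * z_i + lambda * (z_{i-1} + z_{i+1}) / 2`
#' (torus-aware); endpoints fixed. `lambda = 0` is the identity and a
#' collinear equally-spaced string is a fixed point.
#'
#' @param string An `fts_string`.
#' @param lambda Smoothing weight in \[0, 1).
#' @return The smoothed `fts_string`.
#' @export
smooth_string <- function(string, lambda = 0.1) {
  stopifnot(inherits(string, "fts_string"))
  if (lambda < 0 || lambda >= 1) stop("lambda must be in [0, 1)")
  z <- .unwrap_path(string$images)
  n <- nrow(z)
  out <- z
  out[2:(n - 1), ] <- (1 - lambda) * z[2:(n - 1), ] +
    lambda * 0.5 * (z[1:(n - 2), ] + z[3:n, ])
  fts_string(wrap_angle(out))
}

#' FTS configuration
#'
#' @param n_images Number of string images (2 endpoint states plus
#'   intermediates; default 20).
#' @param max_iterations Iteration budget (default 100).
#' @param string_step Evolution step size, deg^2 per (kJ mol^-1 deg^-1).
#' @param displacement_cap Per-image displacement cap per iteration,
#'   degrees.
#' @param smoothing_lambda Per-iteration smoothing weight.
#' @param convergence_tol RMS image displacement threshold, degrees.
#' @param convergence_window Consecutive iterations below the threshold
#'   required to declare convergence.
#' @param sampler A [sampler_config()].
#' @param tensor_mode `"identity"` or `"covariance"`.
#' @return Object of class `"fts_config"`.
#' @export
fts_config <- function(n_images = 20L, max_iterations = 100L,
                       string_step = 15, displacement_cap = 3,
                       smoothing_lambda = 0.1, convergence_tol = 0.3,
                       convergence_window = 5L,
                       sampler = sampler_config(),
                       tensor_mode = c("identity", "covariance")) {
  tensor_mode <- match.arg(tensor_mode)
  stopifnot(n_images >= 4, max_iterations >= 1, string_step > 0,
            displacement_cap > 0, smoothing_lambda >= 0,
            smoothing_lambda < 1, convergence_tol > 0,
            convergence_window >= 1, inherits(sampler, "sampler_config"))
  structure(list(n_images = as.integer(n_images),
                 max_iterations = as.integer(max_iterations),
                 string_step = string_step,
                 displacement_cap = displacement_cap,
                 smoothing_lambda = smoothing_lambda,
                 convergence_tol = convergence_tol,
                 convergence_window = as.integer(convergence_window),
                 sampler = sampler, tensor_mode = tensor_mode),
            class = "fts_config")
}

# per-iteration sampler seed stream, derived from one master seed
.iter_seed <- function(seed, iter) {
  (as.numeric(seed) %% 2^31) * 1e6 + iter
}

#' Run the finite-temperature string method
#'
#' Anchors the endpoints at the deterministic basin minima, then iterates:
#' sample an umbrella window at every image, estimate mean forces and metric
#' tensors, evolve the interior images by the perpendicular projection of
#' the preconditioned force, smooth, reparameterize to equal arc length and
#' record the RMS image displacement. Convergence is declared when the RMS
#' displacement stays below `convergence_tol` for `convergence_window`
#' consecutive iterations. After the loop one more window pass on the final
#' string yields mean forces aligned with the returned images.
#'
#' @inheritParams free_energy
#' @param config An [fts_config()].
#' @param seed Master seed; all per-iteration sampler streams derive from
#'   it.
#' @param exact_forces Use the analytic free-energy gradient instead of
#'   sampled mean forces (the zero-temperature limit; deterministic).
#' @param keep_trajectories Keep thinned trajectories of the final window
#'   pass (needed for [wham_profile()]).
#' @param verbose Print one line per iteration.
#' @return Object of class `"fts_result"`: `string` (final `fts_string`),
#'   `mean_forces` (n x 2, kJ mol^-1 rad^-1, aligned with the images),
#'   `windows` (final window samples, or `NULL` with `exact_forces`),
#'   `iterations_run`, `converged`, `displacement_history` (degrees),
#'   `string_history`, and the inputs (`config`, `seed`, `field`).
#' @export
run_fts <- function(landscape, field = NULL, config = fts_config(),
                    seed = 1L, exact_forces = FALSE,
                    keep_trajectories = FALSE, verbose = FALSE) {
  stopifnot(inherits(landscape, "fts_landscape"), inherits(config, "fts_config"))
  mins <- locate_minima(landscape, field)
  string <- initialize_string(mins$minima[1, ], mins$minima[2, ],
                              config$n_images)
  if (!exact_forces) .check_stability(landscape, config$sampler)

  image_forces <- function(images, iter_seed) {
    if (exact_forces) {
      g <- free_energy_gradient(landscape, images, field)
      list(forces_rad = g * 180 / pi, tensors = NULL, windows = NULL)
    } else {
      ws <- .sample_windows(landscape, field, images, config$sampler,
                            seed = iter_seed)
      f <- t(vapply(ws, mean_force, numeric(2)))
      tensors <- if (config$tensor_mode == "identity") NULL else
        lapply(ws, metric_tensor, mode = "covariance")
      list(forces_rad = f, tensors = tensors, windows = ws)
    }
  }

  history <- numeric(0)
  strings <- list(string)
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iterations && !converged) {
    iter <- iter + 1L
    fr <- image_forces(string$images, .iter_seed(seed, iter))
    f_deg <- fr$forces_rad * pi / 180
    new <- update_images(string, f_deg, fr$tensors,
                         step = config$string_step,
                         cap = config$displacement_cap)
    new <- smooth_string(new, config$smoothing_lambda)
    new <- reparameterize(new)
    rms <- sqrt(mean(torus_dist(new$images, string$images)^2))
    history <- c(history, rms)
    string <- new
    strings[[iter + 1L]] <- string
    if (verbose)
      message(sprintf("iter %3d  rms displacement %.4f deg  max |f| %.4f",
                      iter, rms, max(abs(fr$forces_rad))))
    if (iter >= config$convergence_window &&
        all(tail(history, config$convergence_window) < config$convergence_tol))
      converged <- TRUE
  }

  # final aligned window pass
  if (exact_forces) {
    fin <- image_forces(string$images, 0)
    windows <- NULL
  } else {
    windows <- .sample_windows(landscape, field, string$images,
                               config$sampler,
                               seed = .iter_seed(seed, 999999L),
                               keep_traj = keep_trajectories)
    fin <- list(forces_rad = t(vapply(windows, mean_force, numeric(2))))
  }

  structure(list(string = string, mean_forces = fin$forces_rad,
                 windows = windows, iterations_run = iter,
                 converged = converged, displacement_history = history,
                 string_history = strings, config = config, seed = seed,
                 field = field),
            class = "fts_result")
}

#' @export
print.fts_result <- function(x, ...) {
  cat("<fts_result>\n")
  cat(sprintf("  images: %d, iterations: %d, converged: %s\n",
              nrow(x$string$images), x$iterations_run, x$converged))
  if (length(x$displacement_history))
    cat(sprintf("  final RMS displacement: %.4f deg\n",
                tail(x$displacement_history, 1)))
  invisible(x)
}
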