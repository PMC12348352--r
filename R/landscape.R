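# Synthetic free-energy landscape over the two torsion angles (phi, psi).
#
# The surface is built around a reference path in order-parameter space: a
# C^1 curve through waypoints (s, (phi, psi)) carrying a C^1 free-energy
# profile F(s). The full surface is
#
#   F(p) = profile(s*) + 1/2 * k_t * d^2 + coupling * |E| * w(s*)
#
# where (s*, d) is the nearest-point projection of p onto the path (torus
# metric, dense discretization), k_t is the transverse stiffness, and w(s)
# is a C^1 cosine bump equal to 1 at the principal saddle and 0 at both
# endpoints, so an external field raises the barrier without moving the
# basins. This emulates the empirically observed torsional landscape of
# 4-pyridone-3-carboxylic acid: two conformer basins, a principal saddle
# near (48.0, 92.7) degrees about 18.3 kJ/mol above the conformation-2
# basin, a small hydrogen-bond sub-barrier, asynchronous phi/psi progression
# and a weak, direction-insensitive field response.

.N_DENSE <- 2001L  # dense path nodes; all default control s values land on nodes

#' Specify a reference path in order-parameter space
#'
#' A path is an ordered set of waypoints `(s, phi, psi)` with `s` strictly
#' increasing from 0 to 1, plus free-energy profile controls `(s, F)`. Both
#' are interpolated by shape-preserving C^1 cubic Hermite splines
#' (Fritsch-Carlson slopes). Profile control points that are local extrema
#' of the control sequence are exact local extrema of the interpolant, and
#' with `profile_ends = "zero"` (default) the profile is stationary at both
#' endpoints, making the path endpoints genuine minima of the surface.
#'
#' @param waypoints Data frame or matrix with columns `s`, `phi`, `psi`
#'   (degrees); must include `s = 0` and `s = 1`.
#' @param profile_controls Data frame or matrix with columns `s`, `F`
#'   (kJ/mol); must include `s = 0` and `s = 1`.
#' @param profile_ends `"zero"` clamps the profile slope to zero at both
#'   ends (endpoints are stationary minima); `"secant"` uses one-sided
#'   secant slopes (used e.g. for exactly linear test profiles).
#' @return Object of class `"path_spec"`.
#' @export
path_spec <- function(waypoints, profile_controls, profile_ends = "zero") {
  wp <- as.data.frame(waypoints)
  pc <- as.data.frame(profile_controls)
  stopifnot(all(c("s", "phi", "psi") %in% names(wp)),
            all(c("s", "F") %in% names(pc)))
  if (is.unsorted(wp$s, strictly = TRUE) || is.unsorted(pc$s, strictly = TRUE))
    stop("waypoint and profile control s values must be strictly increasing")
  if (wp$s[1] != 0 || wp$s[nrow(wp)] != 1 ||
      pc$s[1] != 0 || pc$s[nrow(pc)] != 1)
    stop("s = 0 and s = 1 must be present in waypoints and profile controls")
  ends_F <- pc$F[c(1, nrow(pc))]
  if (any(pc$F[-c(1, nrow(pc))] <= max(ends_F)))
    stop("profile endpoints must be the two lowest control values")
  structure(list(waypoints = wp, profile_controls = pc,
                 profile_ends = profile_ends),
            class = "path_spec")
}

# Build interpolants and the dense discretization for a path.
.path_dense <- function(path, n_dense = .N_DENSE) {
  wp <- path$waypoints
  uw <- .unwrap_path(cbind(wp$phi, wp$psi))
  phi_fun <- .hermite_fun(wp$s, uw[, 1], ends = "secant")
  psi_fun <- .hermite_fun(wp$s, uw[, 2], ends = "secant")
  prof_fun <- .hermite_fun(path$profile_controls$s, path$profile_controls$F,
                           ends = path$profile_ends)
  s <- seq(0, 1, length.out = n_dense)
  nodes <- cbind(phi_fun(s), psi_fun(s))
  list(s = s, nodes = nodes, phi_fun = phi_fun, psi_fun = psi_fun,
       prof_fun = prof_fun, prof = prof_fun(s),
       dprof = prof_fun(s, deriv = 1))
}

# C^1 cosine bump: 0 outside [a, b], 1 at the peak p, zero slope at a, p, b.
.bump_fun <- function(support, peak) {
  a <- support[1]; b <- support[2]; p <- peak
  stopifnot(a < p, p < b)
  function(s, deriv = 0) {
    out <- numeric(length(s))
    i1 <- s > a & s <= p
    i2 <- s > p & s < b
    if (deriv == 0) {
      out[i1] <- 0.5 * (1 - cos(pi * (s[i1] - a) / (p - a)))
      out[i2] <- 0.5 * (1 + cos(pi * (s[i2] - p) / (b - p)))
      out[s == p] <- 1
    } else {
      out[i1] <- 0.5 * pi / (p - a) * sin(pi * (s[i1] - a) / (p - a))
      out[i2] <- -0.5 * pi / (b - p) * sin(pi * (s[i2] - p) / (b - p))
      out[s == p] <- 0
    }
    out
  }
}

#' Specify an external electric field
#'
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param sign `+1` or `-1`.
#' @param strength Field strength, V/m; non-negative.
#' @return Object of class `"field_spec"`.
#' @export
#' @examples
#' field_spec("x", +1, 41.14e8)
field_spec <- function(axis = "x", sign = 1L, strength = 0) {
  axis <- match.arg(axis, c("x", "y", "z"))
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  stopifnot(is.numeric(strength), length(strength) == 1,
            is.finite(strength), strength >= 0)
  structure(list(axis = axis, sign = as.integer(sign), strength = strength),
            class = "field_spec")
}

#' Build a landscape from a path specification
#'
#' @param path A [path_spec()].
#' @param transverse_stiffness Harmonic stiffness perpendicular to the path,
#'   kJ mol^-1 deg^-2.
#' @param field_coupling Field-coupling coefficient, kJ mol^-1 per (V/m);
#'   identical for all axes and both signs (the field response of the
#'   conformational landscape is direction-insensitive). The coupling acts
#'   through the bump weight `w(s)`, so it raises the principal saddle and
#'   leaves both basins untouched.
#' @param bump_support Length-2 numeric, the `s` interval outside which the
#'   field coupling vanishes.
#' @param n_dense Number of dense path nodes used for projection.
#' @return Object of class `"fts_landscape"`.
#' @seealso [build_default_landscape()], [free_energy()]
#' @export
landscape_spec <- function(path, transverse_stiffness = 0.02,
                           field_coupling = 0, bump_support = c(0, 1),
                           n_dense = .N_DENSE) {
  stopifnot(inherits(path, "path_spec"), transverse_stiffness > 0,
            field_coupling >= 0, length(bump_support) == 2)
  dense <- .path_dense(path, n_dense)
  pc <- path$profile_controls
  peak <- pc$s[which.max(pc$F)]
  # degenerate profiles (max at an endpoint, e.g. flat test surfaces) get a
  # mid-support bump; irrelevant unless the field coupling is non-zero
  peak <- min(max(peak, bump_support[1] + 0.01), bump_support[2] - 0.01)
  bump <- .bump_fun(bump_support, peak)
  structure(list(path = path, transverse_stiffness = transverse_stiffness,
                 field_coupling = field_coupling,
                 bump_support = bump_support, saddle_s = peak,
                 dense = dense, bump = bump, w = bump(dense$s),
                 dw = bump(dense$s, deriv = 1)),
            class = "fts_landscape")
}

#' @export
print.fts_landscape <- function(x, ...) {
  pc <- x$path$profile_controls
  cat("<fts_landscape>\n")
  cat(sprintf("  waypoints: %d, profile controls: %d\n",
              nrow(x$path$waypoints), nrow(pc)))
  cat(sprintf("  principal saddle: s = %.2f, F = %.2f kJ/mol\n",
              x$saddle_s, max(pc$F)))
  cat(sprintf("  transverse stiffness: %.3g kJ/mol/deg^2\n",
              x$transverse_stiffness))
  cat(sprintf("  field coupling: %.3g kJ/mol per V/m (max-field rise %.2f kJ/mol)\n",
              x$field_coupling, x$field_coupling * .E_MAX))
  invisible(x)
}

#' The calibrated default landscape
#'
#' Reference path and profile calibrated to the torsional landscape of
#' 4-pyridone-3-carboxylic acid: conformation 1 at (0, 0) by convention,
#' conformation 2 at (168.5, 153.0) (the inter-conformer differences in phi
#' and psi), the principal saddle at (48.0, 92.7) with height 18.3 kJ/mol
#' above the conformation-2 basin, a 4.6 kJ/mol hydrogen-bond sub-barrier
#' between s = 0.80 and s = 0.88, and asynchronous phi/psi progression.
#' Conformation 1 sits 2.0 kJ/mol above conformation 2, keeping the two
#' profile maxima measured from either basin almost equal. The field
#' coupling is calibrated so the principal saddle rises by 4.8 kJ/mol at
#' 41.14e8 V/m on every axis (below the 5.5 kJ/mol ceiling observed for the
#' conformational barrier).
#'
#' @param saddle_rise_max Barrier increase at the maximum grid field
#'   strength, kJ/mol.
#' @return An [landscape_spec()] object.
#' @export
#' @examples
#' ls <- build_default_landscape()
#' free_energy(ls, c(48.0, 92.7))  # 18.3
build_default_landscape <- function(saddle_rise_max = 4.8) {
  wp <- data.frame(
    s   = c(0,  0.18, 0.40, 0.55, 0.68, 0.80, 0.88,  1.00),
    phi = c(0,  20,   48.0, 100,  150,  165,  166.5, 168.5),
    psi = c(0,  60,   92.7, 100,  105,  110,  135,   153.0))
  pc <- data.frame(
    s = c(0,   0.18, 0.40, 0.55, 0.68, 0.80, 0.88, 1.00),
    F = c(2.0, 8.0,  18.3, 14.0, 18.0, 2.4,  7.0,  0.0))
  landscape_spec(path_spec(wp, pc),
                 transverse_stiffness = 0.02,
                 field_coupling = saddle_rise_max / .E_MAX,
                 bump_support = c(0.18, 0.68))
}

# Effective along-path profile (and its derivative per segment-local t) at
# the dense nodes for a given field.
.effective_prof <- function(landscape, field = NULL) {
  prof <- landscape$dense$prof
  dprof_s <- landscape$dense$dprof
  if (!is.null(field)) {
    stopifnot(inherits(field, "field_spec"))
    cE <- landscape$field_coupling * field$strength
    prof <- prof + cE * landscape$w
    dprof_s <- dprof_s + cE * landscape$dw
  }
  list(prof = prof, dprof_t = dprof_s / (length(prof) - 1))
}

#' Evaluate the free energy
#'
#' Total function on the torus: exactly 360-degree periodic in both
#' coordinates, affine in the field strength at fixed axis/sign, and
#' deterministic.
#'
#' @param landscape An `fts_landscape`.
#' @param points Length-2 vector `c(phi, psi)` or an n x 2 matrix, degrees.
#' @param field Optional [field_spec()].
#' @return Free energy values, kJ/mol.
#' @export
#' @examples
#' ls <- build_default_landscape()
#' free_energy(ls, c(168.5, 153.0))  # 0 (conformation-2 anchor)
free_energy <- function(landscape, points, field = NULL) {
  stopifnot(inherits(landscape, "fts_landscape"))
  pts <- .as_points(points)
  eff <- .effective_prof(landscape, field)
  .fe_eval_cpp(pts, landscape$dense$nodes, eff$prof, eff$dprof_t,
               landscape$transverse_stiffness)
}

# Projection detail (s*, d) alongside F; internal helper.
.fe_detail <- function(landscape, points, field = NULL) {
  pts <- .as_points(points)
  eff <- .effective_prof(landscape, field)
  .fe_detail_cpp(pts, landscape$dense$nodes, eff$prof, eff$dprof_t,
                 landscape$transverse_stiffness)
}

#' Free-energy gradient
#'
#' Central finite difference of [free_energy()] with step `h` (default
#' 1e-3 degrees).
#'
#' @inheritParams free_energy
#' @param h Finite-difference step, degrees.
#' @return n x 2 matrix of gradients, kJ mol^-1 deg^-1.
#' @export
free_energy_gradient <- function(landscape, points, field = NULL, h = 1e-3) {
  stopifnot(inherits(landscape, "fts_landscape"), h > 0)
  pts <- .as_points(points)
  eff <- .effective_prof(landscape, field)
  g <- .fe_grad_cpp(pts, landscape$dense$nodes, eff$prof, eff$dprof_t,
                    landscape$transverse_stiffness, h)
  colnames(g) <- c("phi", "psi")
  g
}

#' Locate the two basin minima
#'
#' Local minimization (Nelder-Mead on the free energy) started from both
#' path endpoints. By construction of the default landscape these are
#' conformation 1 (origin) and conformation 2.
#'
#' @inheritParams free_energy
#' @return List with `minima` (2 x 2 matrix, rows conformation 1 and 2),
#'   `F` (their free energies, kJ/mol).
#' @export
#' @examples
#' locate_minima(build_default_landscape())
locate_minima <- function(landscape, field = NULL) {
  stopifnot(inherits(landscape, "fts_landscape"))
  ends <- landscape$dense$nodes[c(1, nrow(landscape$dense$nodes)), ]
  fn <- function(p) free_energy(landscape, p, field)
  res <- apply(ends, 1, function(p0) {
    op <- optim(p0, fn, method = "Nelder-Mead",
                control = list(reltol = 1e-12, maxit = 2000))
    if (op$convergence != 0)
      stop("basin minimization failed to converge (code ", op$convergence, ")")
    c(op$par, op$value)
  })
  minima <- wrap_angle(t(res[1:2, ]))
  dimnames(minima) <- list(c("conformation1", "conformation2"),
                           c("phi", "psi"))
  list(minima = minima, F = unname(res[3, ]))
}

#' Locate the principal saddle
#'
#' Maximum of the along-path effective profile over `s`, refined by 1-D
#' optimization of the continuous interpolants; the height is measured above
#' the conformation-2 basin (the lower-energy path endpoint, `s = 1` by
#' convention).
#'
#' @inheritParams free_energy
#' @return List with `point` (`c(phi, psi)`), `s`, and `height` (kJ/mol)
#'   above the conformation-2 basin.
#' @export
#' @examples
#' locate_saddle(build_default_landscape())  # (48.0, 92.7), 18.3
locate_saddle <- function(landscape, field = NULL) {
  stopifnot(inherits(landscape, "fts_landscape"))
  strength <- if (is.null(field)) 0 else field$strength
  eff <- function(s) {
    landscape$dense$prof_fun(s) +
      landscape$field_coupling * strength * landscape$bump(s)
  }
  s <- landscape$dense$s
  i <- which.max(.effective_prof(landscape, field)$prof)
  lo <- s[max(1, i - 2)]; hi <- s[min(length(s), i + 2)]
  op <- optimize(eff, c(lo, hi), maximum = TRUE, tol = 1e-10)
  s_hat <- op$maximum
  point <- wrap_angle(c(phi = landscape$dense$phi_fun(s_hat),
                        psi = landscape$dense$psi_fun(s_hat)))
  basin <- min(landscape$dense$prof[c(1, length(s))])
  list(point = point, s = s_hat, height = op$objective - basin)
}

#' Audit the critical points of a landscape
#'
#' Grid evaluation at the requested resolution over the full torus followed
#' by steepest-descent basin labeling (each grid cell descends to its lowest
#' 8-neighbor). Basins shallower than `min_depth` — metastable intermediates
#' such as the hydrogen-bond sub-basin of the default landscape, whose
#' escape barriers stay below 5 kJ/mol — are merged into the neighbor across
#' their lowest boundary saddle (persistence merging), so the audit reports
#' the thermodynamically relevant attractors.
#'
#' @inheritParams free_energy
#' @param resolution Nodes per axis (1-degree grid = 360).
#' @param min_depth Persistence threshold, kJ/mol: basins whose escape
#'   barrier is below this are merged. `0` reports the raw labeling.
#' @return List with `n_basins`, `n_raw_basins` (before merging),
#'   `top2_fraction` (fraction of grid points attracted to the two largest
#'   merged basins), and `minima` (grid coordinates of the two largest
#'   basin roots).
#' @export
audit_basins <- function(landscape, field = NULL, resolution = 360L,
                         min_depth = 5) {
  stopifnot(resolution >= 10)
  g <- landscape_grid(landscape, field, resolution)
  lab <- .basin_labels_cpp(g$F)
  n_raw <- length(unique(as.integer(lab)))

  # boundary saddles between basin pairs: for every neighbor direction, the
  # crossing height is the max of the two cell values
  nr <- nrow(lab); nc <- ncol(lab)
  shift <- function(m, di, dj) {
    i <- ((seq_len(nr) - 1 + di) %% nr) + 1
    j <- ((seq_len(nc) - 1 + dj) %% nc) + 1
    m[i, j, drop = FALSE]
  }
  repeat {
    ids <- sort(unique(as.integer(lab)))
    if (length(ids) <= 2) break
    bmin <- vapply(ids, function(b) min(g$F[lab == b]), numeric(1))
    names(bmin) <- ids
    saddle <- matrix(Inf, length(ids), length(ids),
                     dimnames = list(ids, ids))
    for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
      l2 <- shift(lab, d[1], d[2])
      F2 <- shift(g$F, d[1], d[2])
      cross <- pmax(g$F, F2)
      sel <- lab != l2
      if (!any(sel)) next
      df <- data.frame(a = as.character(lab[sel]), b = as.character(l2[sel]),
                       h = cross[sel])
      agg <- stats::aggregate(h ~ a + b, df, min)
      for (k in seq_len(nrow(agg))) {
        a <- agg$a[k]; b <- agg$b[k]
        saddle[a, b] <- min(saddle[a, b], agg$h[k])
        saddle[b, a] <- saddle[a, b]
      }
    }
    depth <- vapply(as.character(ids), function(a)
      min(saddle[a, ]) - bmin[a], numeric(1))
    shallowest <- which.min(depth)
    if (depth[shallowest] >= min_depth) break
    a <- as.character(ids[shallowest])
    target <- as.character(ids[which.min(saddle[a, ])])
    # merge into the deeper of the pair
    keep <- if (bmin[a] < bmin[target]) a else target
    drop <- if (keep == a) target else a
    lab[lab == as.integer(drop)] <- as.integer(keep)
  }

  tab <- sort(table(lab), decreasing = TRUE)
  roots <- as.integer(names(tab))[1:min(2, length(tab))]
  minima <- cbind(phi = g$phi[(roots - 1) %% nr + 1],
                  psi = g$psi[(roots - 1) %/% nr + 1])
  list(n_basins = length(tab), n_raw_basins = n_raw,
       top2_fraction = sum(tab[1:min(2, length(tab))]) / sum(tab),
       minima = minima)
}

#' Validate a landscape against its construction invariants
#'
#' Checks that the free energy is finite on a grid, that the two global
#' minima of the full surface coincide with the path endpoints (grid search
#' at the given resolution), and that the principal-saddle height above the
#' conformation-2 basin equals the profile's max-minus-endpoint value to
#' within 1e-6 kJ/mol.
#'
#' @inheritParams audit_basins
#' @return Invisibly `TRUE`; stops with a diagnostic otherwise.
#' @export
validate_landscape <- function(landscape, resolution = 360L) {
  g <- landscape_grid(landscape, NULL, resolution)
  if (!all(is.finite(g$F))) stop("free energy is not finite everywhere")
  mins <- locate_minima(landscape)
  i <- arrayInd(which.min(g$F), dim(g$F))
  gridmin <- c(g$phi[i[1]], g$psi[i[2]])
  step <- 360 / resolution
  d <- min(torus_dist(gridmin, mins$minima[1, ]),
           torus_dist(gridmin, mins$minima[2, ]))
  if (d > step * sqrt(2))
    stop("global grid minimum does not coincide with a path endpoint")
  sad <- locate_saddle(landscape)
  pc <- landscape$path$profile_controls
  expected <- max(pc$F) - min(pc$F[c(1, nrow(pc))])
  if (abs(sad$height - expected) > 1e-6)
    stop("saddle height inconsistent with profile controls: ",
         sad$height, " vs ", expected)
  invisible(TRUE)
}
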