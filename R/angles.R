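# Torus geometry helpers. All public interfaces use degrees; angles are
# reduced to the half-open interval [-180, 180).

#' Reduce angles to [-180, 180)
#'
#' @param x Numeric vector of angles, degrees.
#' @return Angles reduced to the half-open interval \[-180, 180).
#' @export
#' @examples
#' wrap_angle(c(180, -180, 360, 190.5))
wrap_angle <- function(x) {
  ((x + 180) %% 360) - 180
}

#' Shortest-arc difference between angles
#'
#' Componentwise signed difference `a - b` on the circle, i.e. the shortest
#' arc from `b` to `a`, in (-180, 180].
#'
#' @param a,b Numeric vectors of angles, degrees.
#' @return Signed shortest-arc differences, degrees.
#' @export
#' @examples
#' angle_diff(170, -170)  # -20, crossing the +-180 seam
angle_diff <- function(a, b) {
  d <- wrap_angle(a - b)
  # map -180 to +180 so that diff(a, b) == -diff(b, a) except at the cut
  ifelse(d == -180, 180, d)
}

#' Torus distance between torsion-angle points
#'
#' Euclidean distance with each coordinate measured along the shortest arc.
#'
#' @param p,q Numeric length-2 vectors `c(phi, psi)` or n x 2 matrices,
#'   degrees.
#' @return Numeric vector of distances, degrees.
#' @export
#' @examples
#' torus_dist(c(179, 0), c(-179, 0))  # 2
torus_dist <- function(p, q) {
  p <- rbind(p); q <- rbind(q)
  d <- angle_diff(p, q)
  sqrt(rowSums(matrix(d, ncol = 2)^2))
}

#' Construct a torsion-angle point
#'
#' @param phi,psi Torsion angles, degrees; reduced to \[-180, 180).
#' @return Named numeric vector `c(phi =, psi =)`.
#' @export
#' @examples
#' op_point(360, -190)
op_point <- function(phi, psi) {
  stopifnot(is.numeric(phi), is.numeric(psi),
            length(phi) == 1, length(psi) == 1,
            is.finite(phi), is.finite(psi))
  c(phi = wrap_angle(phi), psi = wrap_angle(psi))
}

# coerce a point or matrix of points to an n x 2 matrix (degrees, wrapped)
.as_points <- function(p) {
  if (is.null(dim(p))) {
    stopifnot(length(p) %% 2 == 0)
    p <- matrix(p, ncol = 2, byrow = TRUE)
  }
  stopifnot(ncol(p) == 2, all(is.finite(p)))
  m <- wrap_angle(unname(as.matrix(p)))
  colnames(m) <- c("phi", "psi")
  m
}

# unwrap a sequence of points into a continuous chart: consecutive
# differences taken along the shortest arc
.unwrap_path <- function(pts) {
  pts <- .as_points(pts)
  n <- nrow(pts)
  if (n == 1) return(pts)
  d <- angle_diff(pts[-1, , drop = FALSE], pts[-n, , drop = FALSE])
  out <- rbind(pts[1, ], matrix(d, ncol = 2))
  apply(out, 2, cumsum)
}
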