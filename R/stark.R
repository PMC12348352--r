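# Closed-form polarization and Stark energies for a molecule in a uniform
# external field, and ordinary-least-squares regression of field-scan
# observables against field strength. The string evolution parameter and
# the polarizability are distinct quantities; polarizabilities are always
# named alpha_* here and the string parameter is `alpha` only inside
# pmf/string objects.

#' Rotor quantum state
#'
#' @param J Total angular momentum quantum number, >= 0.
#' @param K Projection of J on the molecular axis, |K| <= J.
#' @param M Projection of J on the field axis, |M| <= J.
#' @return Object of class `"rotor_state"`.
#' @export
rotor_state <- function(J, K, M) {
  stopifnot(J == round(J), K == round(K), M == round(M))
  if (J < 0) stop("J must be >= 0")
  if (abs(K) > J || abs(M) > J) stop("|K| and |M| must not exceed J")
  structure(list(J = as.integer(J), K = as.integer(K), M = as.integer(M)),
            class = "rotor_state")
}

#' Induced dipole moment
#'
#' `mu_ind = alpha * E`; units follow the declared inputs (SI or atomic
#' units), no silent conversion.
#'
#' @param alpha_pol Polarizability, >= 0.
#' @param E Field strength.
#' @return Induced dipole moment.
#' @export
induced_dipole <- function(alpha_pol, E) {
  if (any(alpha_pol < 0)) stop("polarizability must be non-negative")
  alpha_pol * E
}

#' Polarization (induced-dipole) energy
#'
#' `H = -1/2 (alpha_par - alpha_perp) E^2 Phi^2 - 1/2 alpha_perp E^2`,
#' where `Phi` is the cosine of the angle between the field and the
#' principal molecular axis.
#'
#' @param alpha_parallel,alpha_perp Polarizability components, >= 0.
#' @param E Field strength.
#' @param Phi Orientation cosine in \[-1, 1\].
#' @return Polarization energy (negative for positive polarizabilities).
#' @export
polarization_energy <- function(alpha_parallel, alpha_perp, E, Phi) {
  if (any(alpha_parallel < 0) || any(alpha_perp < 0))
    stop("polarizabilities must be non-negative")
  if (any(abs(Phi) > 1)) stop("|Phi| must not exceed 1")
  -0.5 * (alpha_parallel - alpha_perp) * E^2 * Phi^2 - 0.5 * alpha_perp * E^2
}

#' First-order Stark energy of a symmetric-top state
#'
#' `W = -mu E M K / (J (J + 1))`, the expectation of `-mu E P1(cos theta)`
#' in the |J, K, M> state; zero for J = 0 (where K = M = 0) and for M = 0,
#' and antisymmetric under M -> -M. Exactly linear in E.
#'
#' @param mu Permanent dipole moment.
#' @param E Field strength.
#' @param state A [rotor_state()].
#' @return First-order Stark energy.
#' @export
#' @examples
#' first_order_stark(1, 1, rotor_state(1, 1, 1))  # -1/2
first_order_stark <- function(mu, E, state) {
  stopifnot(inherits(state, "rotor_state"))
  if (state$J == 0) return(0 * mu * E)
  -mu * E * state$M * state$K / (state$J * (state$J + 1))
}

#' Second-order Stark energy (printed closed form)
#'
#' `W = 1/2 mu E Omega * [ (J^2-K^2)(J^2-M^2) / (J^3 (2J-1)(2J+1))
#'   - ((J+1)^2-K^2)((J+1)^2-M^2) / ((J+1)^3 (2J+1)(2J+3)) ]`,
#' with `Omega` a user-supplied proportionality constant for the given
#' field. The expression is singular at J = 0, which is an explicit error.
#' Symmetric under both M -> -M and K -> -K.
#'
#' @param mu Permanent dipole moment.
#' @param E Field strength.
#' @param Omega Proportionality constant for this field.
#' @param state A [rotor_state()] with J >= 1.
#' @return Second-order Stark energy.
#' @export
#' @examples
#' second_order_stark(1, 1, 1, rotor_state(1, 1, 1))  # -0.0375
second_order_stark <- function(mu, E, Omega, state) {
  stopifnot(inherits(state, "rotor_state"))
  J <- state$J; K <- state$K; M <- state$M
  if (J == 0) stop("the second-order expression is singular at J = 0")
  br <- (J^2 - K^2) * (J^2 - M^2) / (J^3 * (2 * J - 1) * (2 * J + 1)) -
    ((J + 1)^2 - K^2) * ((J + 1)^2 - M^2) /
      ((J + 1)^3 * (2 * J + 1) * (2 * J + 3))
  0.5 * mu * E * Omega * br
}

#' Ordinary-least-squares fit of a field-scan series
#'
#' Fits `value ~ strength` for one `(quantity, axis, sign)` series of a
#' field-scan table and reports the slope, intercept and coefficient of
#' determination.
#'
#' @param table A field-scan table (see [generate_field_scan()] /
#'   [read_field_scan()]).
#' @param quantity Quantity label.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param sign `+1` or `-1`.
#' @return Object of class `"response_fit"`: `slope`, `intercept`,
#'   `r_squared`, `n_points`, `quantity`, `direction`.
#' @export
fit_linear_response <- function(table, quantity, axis, sign) {
  table <- as.data.frame(table)
  rows <- table$quantity == quantity & table$axis == axis &
    table$sign == sign
  ser <- table[rows, ]
  if (nrow(ser) == 0)
    stop(sprintf("no rows for series (%s, %s%s)", quantity, axis,
                 ifelse(sign > 0, "+", "-")))
  if (nrow(ser) < 3) stop("need at least 3 points for a series fit")
  if (var(ser$value) == 0)
    stop("zero response variance: R^2 is undefined for a constant series")
  fit <- lm(value ~ strength_Vm, data = ser)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((ser$value - mean(ser$value))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = 1 - ss_res / ss_tot,
                 n_points = nrow(ser), quantity = quantity,
                 direction = paste0(axis, ifelse(sign > 0, "+", "-"))),
            class = "response_fit")
}

#' @export
print.response_fit <- function(x, ...) {
  cat(sprintf("<response_fit> %s along %s: slope %.4g, R^2 %.4f (n = %d)\n",
              x$quantity, x$direction, x$slope, x$r_squared, x$n_points))
  invisible(x)
}

#' Fit every series present in a field-scan table
#'
#' @param table A field-scan table.
#' @return Data frame with one row per `(quantity, axis, sign)` series:
#'   `quantity, axis, sign, slope, intercept, r_squared, n`.
#' @export
fit_all_responses <- function(table) {
  table <- as.data.frame(table)
  series <- unique(table[, c("quantity", "axis", "sign")])
  out <- lapply(seq_len(nrow(series)), function(i) {
    f <- fit_linear_response(table, series$quantity[i], series$axis[i],
                             series$sign[i])
    data.frame(quantity = f$quantity, axis = series$axis[i],
               sign = series$sign[i], slope = f$slope,
               intercept = f$intercept, r_squared = f$r_squared,
               n = f$n_points, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
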