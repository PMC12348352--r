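# Transition-state-theory kinetics with the Wigner tunneling correction and
# the proton-transfer vs conformational-transformation competition report.

#' Wigner tunneling correction
#'
#' `kappa = 1 + (1/24) * (h c nu / (kB T))^2` with `h c / kB` = 1.43877
#' cm K. The quadratic Wigner form is used because only the value of the
#' transmission coefficient (2.18 at 298.15 K in the absence of a field) is
#' known, not the method behind it; the implied imaginary frequency is
#' about 1102.5 cm^-1.
#'
#' @param nu Imaginary-frequency magnitude, cm^-1; non-negative.
#' @param T Temperature, K.
#' @return Dimensionless transmission coefficient, >= 1.
#' @export
#' @examples
#' wigner_kappa(1102.5, 298.15)  # about 2.18
wigner_kappa <- function(nu, T = 298.15) {
  if (any(nu < 0)) stop("nu must be non-negative")
  if (any(T <= 0)) stop("T must be positive")
  1 + (1 / 24) * (.constants$hc_over_kB * nu / T)^2
}

#' Eyring rate constant
#'
#' `k = kappa * (kB T / h) * exp(-dG / (R T))` for a unimolecular step with
#' activation free energy `dG`.
#'
#' @param dG Activation free energy, kJ/mol.
#' @param T Temperature, K.
#' @param kappa Transmission coefficient (>= 1).
#' @return Rate constant, s^-1.
#' @export
#' @examples
#' eyring_rate(17.3, 298.15, wigner_kappa(1102.5))  # about 1.26e10
eyring_rate <- function(dG, T = 298.15, kappa = 1) {
  if (any(T <= 0)) stop("T must be positive")
  if (any(kappa < 1)) stop("kappa must be >= 1")
  kappa * (.constants$kB * T / .constants$h) *
    exp(-dG * 1000 / (.constants$R * T))
}

#' Relative change of a barrier
#'
#' `100 * delta / reference`, in percent. Returned at full precision;
#' display rounding (one decimal) is applied by the report formatters. The
#' map is exactly additive in `delta`.
#'
#' @param reference Reference barrier, kJ/mol; positive.
#' @param delta Change, kJ/mol.
#' @return Percent change.
#' @export
#' @examples
#' relative_change(17.3, 11.6)  # 67.05... -> printed 67.1
relative_change <- function(reference, delta) {
  if (any(reference <= 0)) stop("reference must be positive")
  100 * delta / reference
}

#' Kinetics table from barriers and frequencies
#'
#' Computes the Wigner transmission coefficient and Eyring rate for each row
#' of a table with columns `label`, `dG_kJmol`, `nu_cm1` (optional, NA for
#' no tunneling) and `T_K` (optional, default 298.15).
#'
#' @param df Data frame of kinetics inputs.
#' @return The data frame with `kappa` and `rate_s1` columns appended.
#' @export
kinetics_report <- function(df) {
  df <- as.data.frame(df)
  stopifnot(all(c("label", "dG_kJmol") %in% names(df)))
  if (is.null(df$T_K)) df$T_K <- 298.15
  nu <- if (is.null(df$nu_cm1)) rep(NA_real_, nrow(df)) else df$nu_cm1
  df$kappa <- ifelse(is.na(nu), 1, wigner_kappa(ifelse(is.na(nu), 0, nu), df$T_K))
  df$rate_s1 <- eyring_rate(df$dG_kJmol, df$T_K, df$kappa)
  df
}

#' Compare the two mechanisms condition by condition
#'
#' Element-wise differences between the proton-transfer and
#' conformational-transformation barriers under matching conditions, the
#' maximum absolute difference, and a per-condition verdict on which
#' mechanism is favored (lower barrier).
#'
#' @param proton_barriers,conf_barriers Equal-length numeric vectors,
#'   kJ/mol.
#' @param labels Optional condition labels.
#' @return List of class `"competition_report"`: `table` (data frame with
#'   barriers, difference and verdict), `max_abs_diff` (kJ/mol) and
#'   `verdict` (summary string).
#' @export
#' @examples
#' competition_report(c(21.4, 16.3, 8.6, 7.7), c(17.3, 15.2, 5.7, 6.8))
competition_report <- function(proton_barriers, conf_barriers,
                               labels = NULL) {
  if (length(proton_barriers) != length(conf_barriers))
    stop("barrier lists must have equal length")
  if (length(proton_barriers) < 1) stop("need at least one condition")
  if (is.null(labels))
    labels <- paste0("condition", seq_along(proton_barriers))
  d <- proton_barriers - conf_barriers
  verdict <- ifelse(abs(d) < 1e-9, "comparable",
                    ifelse(d > 0, "conformational transformation favored",
                           "proton transfer favored"))
  tab <- data.frame(label = labels, proton_kJmol = proton_barriers,
                    conformational_kJmol = conf_barriers,
                    difference_kJmol = d, verdict = verdict,
                    stringsAsFactors = FALSE)
  mx <- max(abs(d))
  structure(list(table = tab, max_abs_diff = mx,
                 verdict = sprintf(
                   "barriers of the two mechanisms agree within %.1f kJ/mol; the mechanisms compete",
                   round(mx, 1))),
            class = "competition_report")
}

#' @export
print.competition_report <- function(x, ...) {
  tab <- x$table
  tab$proton_kJmol <- round(tab$proton_kJmol, 1)
  tab$conformational_kJmol <- round(tab$conformational_kJmol, 1)
  tab$difference_kJmol <- round(tab$difference_kJmol, 1)
  print(tab, row.names = FALSE)
  cat(sprintf("max |difference| = %.1f kJ/mol\n", x$max_abs_diff))
  invisible(x)
}
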