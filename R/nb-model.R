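#' Negative binomial parameterisation conversions
#'
#' The package models relapse counts on the mean/overdispersion scale:
#' `Y ~ NB(mean = mu, dispersion = kappa)` with
#' `Var(Y) = mu + mu^2 / kappa`. The classical (gamma, p) parameterisation —
#' `gamma` successes ("size") and per-trial relapse probability `p` — relates
#' to it by `gamma = kappa` and `p = kappa / (kappa + mu)`, so that
#' `mu = gamma (1 - p) / p`. `nb_mean_to_gp()` and `nb_gp_to_mean()` convert
#' between the two and round-trip exactly.
#'
#' @param mu positive mean number of events.
#' @param kappa positive overdispersion parameter; the Poisson limit is
#'   `kappa -> Inf`.
#' @param gamma positive size parameter of the classical form.
#' @param p event probability in (0, 1).
#' @return `nb_mean_to_gp()`: list with `gamma` and `p`; `nb_gp_to_mean()`:
#'   list with `mu` and `kappa`.
#' @examples
#' gp <- nb_mean_to_gp(mu = 2, kappa = 0.5)
#' nb_gp_to_mean(gp$gamma, gp$p)
#' @export
nb_mean_to_gp <- function(mu, kappa) {
  stopifnot(all(mu > 0), all(kappa > 0))
  list(gamma = kappa, p = kappa / (kappa + mu))
}

#' @rdname nb_mean_to_gp
#' @export
nb_gp_to_mean <- function(gamma, p) {
  stopifnot(all(gamma > 0), all(p > 0), all(p < 1))
  list(mu = gamma * (1 - p) / p, kappa = gamma)
}

#' Draw arm-level relapse totals
#'
#' The sum of `n` independent patient counts, each
#' `NB(mean = arr * follow_up, dispersion = kappa)`, is
#' `NB(mean = n * arr * follow_up, dispersion = n * kappa)`; arm totals are
#' drawn in one call rather than patient by patient.
#'
#' @param n number of patients in the arm.
#' @param arr annualised relapse rate (events per person-year).
#' @param follow_up follow-up per patient in years.
#' @param kappa per-patient overdispersion.
#' @return a single non-negative integer relapse total.
#' @keywords internal
rnb_arm_total <- function(n, arr, follow_up, kappa) {
  stats::rnbinom(1L, size = n * kappa, mu = n * arr * follow_up)
}
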