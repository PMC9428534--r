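# Annual life-history processes: allometric weight, density-dependent von
# Bertalanffy growth, threshold maturation, and natural survival.

#' Weight from length
#'
#' Allometric length-weight relation `W = 3.52e-6 * L^3.19`, with length
#' in cm and weight in kg. An 80 cm fish weighs about 4.14 kg.
#'
#' @param length Body length (cm), vectorised, non-negative.
#' @return Weight (kg).
#' @examples
#' weight_from_length(c(45, 78, 80))
#' @export
weight_from_length <- function(length) {
  if (!is.numeric(length) || any(!is.finite(length)) || any(length < 0)) {
    stop("`length` must be non-negative and finite", call. = FALSE)
  }
  3.52e-6 * length^3.19
}

#' Annual von Bertalanffy growth increment with density dependence
#'
#' One annual step along the individual growth curve: the increment
#' `(linf - length) * (1 - exp(-k))` is damped by the density multiplier
#' `max(0, 1 - theta * density_ratio)`, where `density_ratio` is the
#' population biomass over carrying capacity. With `theta = 0` (or an
#' empty sea) repeated steps reproduce the closed-form trajectory
#' `L(t) = linf * (1 - exp(-k t))` exactly.
#'
#' @param length Current length (cm), `0 <= length <= linf`.
#' @param linf Asymptotic length (cm).
#' @param k Growth rate (per year).
#' @param density_ratio Biomass / carrying capacity (dimensionless, >= 0).
#' @param theta Density-dependence strength.
#' @return Length after one year (cm), never exceeding `linf`.
#' @examples
#' grow(0, 80, 0.12) # about 9.047 cm in the first year
#' @export
grow <- function(length, linf, k, density_ratio = 0, theta = 1) {
  if (any(density_ratio < 0)) {
    stop("`density_ratio` must be non-negative", call. = FALSE)
  }
  if (any(length < 0) || any(length > linf + 1e-9)) {
    stop("`length` must lie in [0, linf]", call. = FALSE)
  }
  dd <- pmax(0, 1 - theta * density_ratio)
  pmin(linf, length + (linf - length) * (1 - exp(-k)) * dd)
}

#' Maturation update
#'
#' A fish matures when its length reaches 66% of its individual
#' asymptotic length (boundary inclusive). Maturation is irreversible:
#' an already-mature fish stays mature whatever its length.
#'
#' @param length Current length (cm), vectorised.
#' @param linf Individual asymptotic length (cm).
#' @param mature Current maturity flag(s).
#' @param threshold Maturation threshold as a fraction of `linf`.
#' @return Updated logical maturity flag(s).
#' @export
update_maturation <- function(length, linf, mature = FALSE,
                              threshold = 0.66) {
  mature | (length >= threshold * linf)
}

#' Annual natural survival probability
#'
#' Fish younger than the juvenile age cutoff survive with probability 1
#' (their mortality is folded into the egg-to-recruit bottleneck).
#' Older immature fish survive with `exp(-m_immature)`; mature fish pay
#' the reproductive cost on top, surviving with
#' `exp(-(m_immature + reproductive_cost))`. Independently of these
#' rates, no fish outlives `max_age` (enforced by the annual engine).
#'
#' @param age Age (years), vectorised.
#' @param mature Maturity flag(s).
#' @param params A [mortality_params()] object.
#' @return Survival probability in `[0, 1]`.
#' @examples
#' natural_survival_prob(5, FALSE) # exp(-0.15)
#' natural_survival_prob(5, TRUE)  # exp(-0.25)
#' @export
natural_survival_prob <- function(age, mature, params = mortality_params()) {
  rate <- ifelse(mature, params$m_immature + params$reproductive_cost,
                 params$m_immature)
  ifelse(age < params$juvenile_age_cutoff, 1, exp(-rate))
}
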