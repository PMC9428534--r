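# Size-selective harvest: logistic trawl selectivity above a minimum
# landing size, Bernoulli capture, and the biomass-triggered moratorium.

#' Trawl selectivity at length
#'
#' Logistic selectivity `plogis(sel_intercept + sel_slope * L)`, strictly
#' increasing in length; 0.5 at 50 cm with the default coefficients.
#'
#' @param length Body length (cm), vectorised, non-negative.
#' @param params A [fishing_params()] object.
#' @return Selection probability in `(0, 1)`.
#' @examples
#' selectivity(c(45, 50, 70))
#' @export
selectivity <- function(length, params = fishing_params()) {
  if (any(length < 0)) stop("`length` must be non-negative", call. = FALSE)
  stats::plogis(params$sel_intercept + params$sel_slope * length)
}

#' Annual capture probability
#'
#' Fish at or below the minimum size threshold are exempt (the threshold
#' is exclusive: only fish strictly longer can be captured). Above it the
#' capture probability is `F * selectivity(length)`, so it is bounded by
#' the instantaneous fishing mortality `F`.
#'
#' @inheritParams selectivity
#' @return Capture probability.
#' @examples
#' capture_prob(c(45, 50), fishing_params(F = 0.2))
#' @export
capture_prob <- function(length, params = fishing_params()) {
  ifelse(length <= params$min_size_cm, 0,
         params$F * selectivity(length, params))
}

#' Harvest a population of lengths
#'
#' Each fish is captured through an independent Bernoulli trial at its
#' [capture_prob()]; captured fish are removed and their weights summed
#' into the catch biomass.
#'
#' @param length Vector of body lengths (cm).
#' @param params A [fishing_params()] object.
#' @return A list with `captured` (logical vector), `catch_count` and
#'   `catch_biomass_kg`.
#' @export
harvest <- function(length, params = fishing_params()) {
  captured <- stats::runif(length(length)) < capture_prob(length, params)
  list(captured = captured,
       catch_count = sum(captured),
       catch_biomass_kg = sum(weight_from_length(length[captured])))
}

#' Moratorium trigger
#'
#' Fishing stops as soon as the population biomass has dropped to
#' `stop_fraction` (15% by default) of the biomass at fishing onset; the
#' comparison is boundary inclusive. The annual engine latches the stop:
#' once triggered, fishing never resumes within a run.
#'
#' @param current_biomass Current population biomass (kg).
#' @param biomass_at_onset Biomass in the year fishing began (kg, > 0).
#' @param params A [fishing_params()] object.
#' @return `TRUE` if fishing must stop.
#' @export
fishing_should_stop <- function(current_biomass, biomass_at_onset,
                                params = fishing_params()) {
  if (!is.numeric(biomass_at_onset) || biomass_at_onset <= 0) {
    stop("`biomass_at_onset` must be positive", call. = FALSE)
  }
  current_biomass <= params$stop_fraction * biomass_at_onset
}
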