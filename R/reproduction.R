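# Annual spawning: weight-based fecundity, partitioning of the egg mass
# into within-season batches, whole-batch Bernoulli survival under
# environmental forcing and batch-order costs, and the egg-to-recruit
# bottleneck.

#' Fecundity from body weight
#'
#' Weight-specific fecundity `(0.48 * (W + 0.37)^1.45 + 0.12) * 1e6`
#' eggs, rounded to a count; strictly increasing in weight. The leading
#' factor is expressed in millions of eggs, the natural unit for a highly
#' fecund broadcast spawner: a 78 cm (about 3.8 kg) female produces
#' roughly 4 million eggs.
#'
#' @param weight Body weight (kg), vectorised, non-negative.
#' @return Egg count.
#' @examples
#' fecundity(weight_from_length(78))
#' @export
fecundity <- function(weight) {
  if (!is.numeric(weight) || any(!is.finite(weight)) || any(weight < 0)) {
    stop("`weight` must be non-negative and finite", call. = FALSE)
  }
  round((0.48 * (weight + 0.37)^1.45 + 0.12) * 1e6)
}

#' Number of egg batches in a spawning season
#'
#' A single-batch spawner always sheds one batch. A multiple-batch
#' spawner sheds a number of batches that increases logistically with
#' fork length, `asymptote / (1 + exp((midpoint - L) / scale))`, rounded
#' half-up and floored at one, so batch number saturates at
#' `round(asymptote)` (21 at the defaults) for very large females.
#'
#' @param fork_length Fork length (cm), vectorised, non-negative.
#' @param params A [spawning_params()] object (its `strategy` decides
#'   MBS vs SBS).
#' @return Integer batch count(s).
#' @examples
#' n_batches(55.014, spawning_params("MBS")) # 11
#' n_batches(120, spawning_params("MBS"))    # 21
#' @export
n_batches <- function(fork_length, params = spawning_params()) {
  if (any(fork_length < 0)) {
    stop("`fork_length` must be non-negative", call. = FALSE)
  }
  if (params$strategy == "SBS") {
    return(rep(1L, length(fork_length)))
  }
  raw <- params$batch_asymptote /
    (1 + exp((params$batch_midpoint_cm - fork_length) / params$batch_scale_cm))
  pmax(1L, as.integer(floor(raw + 0.5)))  # round half-up
}

#' Survival probability of one egg batch
#'
#' Every batch faces the environmental forcing `E` (whole-batch death with
#' probability `E`). Multiple-batch spawners additionally pay a quality
#' cost that grows linearly with batch order: batch `b` keeps the factor
#' `1 - cost_slope * (b - 1)`, so at the defaults the cost rises from 0
#' for the first batch to about 0.105 for the 21st. Single-batch spawners
#' pay no cost. The result is clamped to `[0, 1]`.
#'
#' @param batch_index 1-based batch order, vectorised.
#' @param params A [spawning_params()] object.
#' @return Survival probability of the whole batch.
#' @examples
#' batch_survival_prob(21, spawning_params("MBS", env_forcing = 0))
#' @export
batch_survival_prob <- function(batch_index, params = spawning_params()) {
  if (any(batch_index < 1)) {
    stop("`batch_index` is 1-based", call. = FALSE)
  }
  cost <- if (params$strategy == "MBS") {
    1 - params$cost_slope * (batch_index - 1)
  } else {
    rep(1, length(batch_index))
  }
  pmin(1, pmax(0, (1 - params$env_forcing) * cost))
}

#' Spawn one female for one season
#'
#' Computes the season's egg production from weight, splits the eggs as
#' equally as possible across the batches (any remainder egg goes to the
#' earlier batches), and subjects every batch to an independent
#' whole-batch Bernoulli survival trial at its [batch_survival_prob()].
#'
#' @param length Female fork length (cm).
#' @param mature Maturity flag; spawning an immature female is a contract
#'   violation and errors.
#' @param params A [spawning_params()] object.
#' @return A list with `eggs_produced`, `n_batches`, `batches_survived`
#'   and `eggs_surviving`.
#' @examples
#' set.seed(1)
#' spawn(70, params = spawning_params("MBS", env_forcing = 0.2))
#' @export
spawn <- function(length, mature = TRUE, params = spawning_params()) {
  if (!isTRUE(mature)) {
    stop("only mature females spawn", call. = FALSE)
  }
  eggs <- fecundity(weight_from_length(length))
  nb <- n_batches(length, params)
  sizes <- .split_eggs(eggs, nb)
  surv <- stats::runif(nb) < batch_survival_prob(seq_len(nb), params)
  list(eggs_produced = eggs,
       n_batches = nb,
       batches_survived = sum(surv),
       eggs_surviving = sum(sizes[surv]))
}

# Equal split of `eggs` into `nb` batches, remainder to the first batches.
.split_eggs <- function(eggs, nb) {
  base <- eggs %/% nb
  rem <- eggs %% nb
  base + (seq_len(nb) <= rem)
}

#' Recruits from surviving eggs
#'
#' Applies the egg-to-recruit survival probability as a binomial thinning
#' of the season's surviving eggs. The resulting recruits enter the
#' population at age 0 (the probability covers the first three years of
#' life, during which no further natural mortality is applied).
#'
#' @param eggs_surviving Number of eggs that survived the batch trials,
#'   vectorised.
#' @param params A [spawning_params()] object.
#' @return Integer recruit count(s).
#' @examples
#' set.seed(1)
#' recruits_from_eggs(3.956e6)
#' @export
recruits_from_eggs <- function(eggs_surviving, params = spawning_params()) {
  if (any(eggs_surviving < 0)) {
    stop("`eggs_surviving` must be non-negative", call. = FALSE)
  }
  stats::rbinom(length(eggs_surviving), size = round(eggs_surviving),
                prob = params$egg_to_recruit)
}
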