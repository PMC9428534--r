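# Columnar population container. Individuals live in parallel atomic
# vectors plus one allele matrix; all annual processes are vectorised over
# the population. This is the engine-facing representation of the
# conceptual Individual (id, birth year, age, genotype, Linf, k, length,
# maturity, lifetime recruit ledger).

.pop_fields <- c("id", "birth_year", "age", "linf", "k", "length",
                 "mature", "mat_age", "mat_length", "lifetime_recruits")

.pop_empty <- function(n_loci) {
  list(id = integer(0), birth_year = integer(0), age = integer(0),
       linf = numeric(0), k = numeric(0), length = numeric(0),
       mature = logical(0), mat_age = numeric(0), mat_length = numeric(0),
       lifetime_recruits = integer(0),
       G = matrix(integer(0), 0, 2L * n_loci),
       next_id = 1L)
}

#' Population size
#' @param pop A population object (see [initialize_population()]).
#' @return Number of live individuals.
#' @export
pop_size <- function(pop) length(pop$age)

.pop_subset <- function(pop, keep) {
  out <- lapply(pop[.pop_fields], `[`, keep)
  out$G <- pop$G[keep, , drop = FALSE]
  out$next_id <- pop$next_id
  out
}

.pop_append <- function(pop, frag) {
  out <- Map(c, pop[.pop_fields], frag[.pop_fields])
  out$G <- rbind(pop$G, frag$G)
  out$next_id <- max(pop$next_id, frag$next_id)
  out
}

#' Founder population
#'
#' Creates `initial_abundance` founders with independent founder
#' genotypes, expressed phenotypes, ages drawn uniformly on 1-10 years,
#' lengths placed on each fish's own von Bertalanffy trajectory at that
#' age (no density suppression, `L(a) = linf * (1 - exp(-k a))`), and
#' maturity evaluated against the 66% threshold.
#'
#' @param cfg A [scenario_config()] object.
#' @param start_year Calendar year of initialisation; founder birth years
#'   are `start_year - age`.
#' @return A population object: a list of parallel per-individual vectors
#'   (`id`, `birth_year`, `age`, `linf`, `k`, `length`, `mature`,
#'   `mat_age`, `mat_length`, `lifetime_recruits`) plus the allele matrix
#'   `G` (one row per individual).
#' @examples
#' set.seed(1)
#' pop <- initialize_population(scenario_config(initial_abundance = 50,
#'                                              seed = 1))
#' pop_size(pop)
#' @export
initialize_population <- function(cfg, start_year = 1L) {
  n <- cfg$initial_abundance
  G <- .founder_allele_matrix(n, cfg$n_loci, cfg$allele_freq)
  linf <- .express_scores(rowSums(G), cfg$genetics)
  k <- k_from_linf(linf, cfg$genetics)
  age <- sample(1:10, n, replace = TRUE)
  len <- linf * (1 - exp(-k * age))
  mature <- update_maturation(len, linf)
  list(id = seq_len(n),
       birth_year = as.integer(start_year) - age,
       age = age,
       linf = linf, k = k, length = len,
       mature = mature,
       mat_age = ifelse(mature, age, NA_real_),
       mat_length = ifelse(mature, len, NA_real_),
       lifetime_recruits = integer(n) * 0L + 0L,
       G = G,
       next_id = n + 1L)
}

#' Convert a population to a tibble
#'
#' One row per individual with the per-individual fields and the
#' genotypic score; the raw allele matrix is dropped.
#'
#' @param pop A population object.
#' @return A tibble.
#' @export
population_tibble <- function(pop) {
  tibble::tibble(
    id = pop$id, birth_year = pop$birth_year, age = pop$age,
    genotypic_score = if (nrow(pop$G)) rowSums(pop$G) else numeric(0),
    linf = pop$linf, k = pop$k, length = pop$length,
    mature = pop$mature, mat_age = pop$mat_age,
    mat_length = pop$mat_length,
    lifetime_recruits = pop$lifetime_recruits)
}
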