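# Summary statistics of simulated runs: geometric-mean across-
# generational fitness, realized individual fitness, failed-spawning
# proportions, fishing-period lengths, age structure and between-strategy
# comparisons. All metrics are pure functions of the annual records and
# the cohort ledger, so recomputation from saved CSVs reproduces the
# in-run values exactly.

#' Across-generational fitness over a cohort window
#'
#' For every finalized birth-year cohort in `years`, the mean lifetime
#' recruit output per member is computed (each recruit credits both of
#' its parents, so a demographically stationary population sits near a
#' cohort mean of 2). The across-generational fitness is the geometric
#' mean of those cohort means: the nth root of their product. A single
#' zero-output cohort therefore drives the fitness of the window to zero
#' -- the defining sensitivity of geometric-mean fitness to reproductive
#' failure. Unfinalized cohorts (members still alive) are excluded.
#'
#' @param ledger Cohort ledger tibble from [run_scenario()] (columns
#'   `birth_year`, `cohort_size`, `total_output`, `finalized`).
#' @param years Integer vector of birth years defining the window.
#' @return A list with `geometric_mean_fitness` (`NA` if no finalized
#'   cohort falls in the window) and `n_cohorts`.
#' @examples
#' ledger <- tibble::tibble(birth_year = 1:2, cohort_size = c(10, 10),
#'                          total_output = c(10, 40), deaths = c(10, 10),
#'                          finalized = TRUE)
#' across_generational_fitness(ledger, 1:2)$geometric_mean_fitness # 2
#' @export
across_generational_fitness <- function(ledger, years) {
  sel <- ledger$finalized & ledger$birth_year %in% years &
    ledger$cohort_size > 0
  n <- sum(sel)
  if (n == 0L) {
    return(list(geometric_mean_fitness = NA_real_, n_cohorts = 0L))
  }
  means <- ledger$total_output[sel] / ledger$cohort_size[sel]
  gm <- if (any(means == 0)) 0 else exp(mean(log(means)))
  list(geometric_mean_fitness = gm, n_cohorts = n)
}

#' Realized individual fitness per year
#'
#' Recruit abundance divided by mature-adult abundance for each annual
#' record; `NA` where no mature adults were present.
#'
#' @param records Annual records tibble.
#' @return Numeric vector, one value per record row.
#' @export
realized_individual_fitness <- function(records) {
  ifelse(records$mature_count > 0,
         records$recruits / records$mature_count, NA_real_)
}

#' Proportion of failed spawning seasons
#'
#' Failed female-seasons (zero recruits for a spawning female) over all
#' female-seasons in the supplied records.
#'
#' @param records Annual records tibble (typically pre-filtered to a
#'   period).
#' @return A proportion in `[0, 1]`, `NA` if no female spawned.
#' @export
failed_spawning_proportion <- function(records) {
  tot <- sum(records$spawning_females)
  if (tot == 0) return(NA_real_)
  sum(records$failed_seasons) / tot
}

#' Length of the fishing period
#'
#' Number of years with fishing active (onset to moratorium latch,
#' inclusive; capped by the maximum fishing-phase duration).
#'
#' @param records Annual records tibble of one run.
#' @return Integer year count.
#' @export
fishing_period_length <- function(records) {
  sum(records$phase == "fishing")
}

#' Age structure of recorded years
#'
#' Extracts the population pyramid (counts by age) of the requested
#' record years, together with the abundance-weighted mean age and the
#' mean age and length at first maturation among fish maturing in those
#' years.
#'
#' @param records Annual records tibble.
#' @param years Calendar years to include (default: all recorded).
#' @return A list with `pyramid` (ages x years count matrix), `mean_age`
#'   (abundance-weighted, pooled over the selected years),
#'   `mean_maturation_age` and `mean_maturation_length_cm`.
#' @export
age_structure <- function(records, years = records$year) {
  sel <- records$year %in% years
  if (!any(sel)) stop("no records for the requested years", call. = FALSE)
  age_cols <- grep("^age_[0-9]+$", names(records), value = TRUE)
  ages <- as.integer(sub("age_", "", age_cols))
  pyr <- t(as.matrix(records[sel, age_cols]))
  rownames(pyr) <- ages
  colnames(pyr) <- records$year[sel]
  counts <- rowSums(pyr)
  list(pyramid = pyr,
       mean_age = if (sum(counts)) sum(ages * counts) / sum(counts)
                  else NA_real_,
       mean_maturation_age = .wmean(records$mean_maturation_age[sel]),
       mean_maturation_length_cm =
         .wmean(records$mean_maturation_length_cm[sel]))
}

.wmean <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)

#' Compare two matched strategy tables
#'
#' Takes two per-replicate summary tables (one per strategy) on matched
#' scenario grids and computes, for the requested metric, per-scenario
#' mean differences (`A - B`) and the pooled difference with a bootstrap
#' confidence interval over replicates.
#'
#' @param table_a,table_b Tibbles with columns `env_forcing`,
#'   `fishing_F`, `replicate` and the metric column; grids must match.
#' @param metric Name of the metric column to difference.
#' @param n_boot Bootstrap resamples for the pooled CI.
#' @param conf Confidence level.
#' @return A list with `per_scenario` (tibble of per-cell differences)
#'   and `pooled` (difference, CI bounds, replicate count).
#' @export
strategy_comparison <- function(table_a, table_b, metric,
                                n_boot = 1000, conf = 0.95) {
  need <- c("env_forcing", "fishing_F", "replicate", metric)
  if (!all(need %in% names(table_a)) || !all(need %in% names(table_b))) {
    stop("both tables need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ga <- dplyr::arrange(table_a[, need], .data$env_forcing,
                       .data$fishing_F, .data$replicate)
  gb <- dplyr::arrange(table_b[, need], .data$env_forcing,
                       .data$fishing_F, .data$replicate)
  if (!identical(ga[, 1:3], gb[, 1:3])) {
    stop("scenario grids of the two tables do not match", call. = FALSE)
  }
  diffs <- ga
  diffs$diff <- ga[[metric]] - gb[[metric]]
  per_scenario <- dplyr::summarise(
    dplyr::group_by(diffs, .data$env_forcing, .data$fishing_F),
    diff = mean(.data$diff, na.rm = TRUE), .groups = "drop")
  d <- diffs$diff[!is.na(diffs$diff)]
  boot <- replicate(n_boot, mean(sample(d, replace = TRUE)))
  alpha <- (1 - conf) / 2
  list(per_scenario = per_scenario,
       pooled = tibble::tibble(
         diff = mean(d),
         ci_lower = unname(stats::quantile(boot, alpha)),
         ci_upper = unname(stats::quantile(boot, 1 - alpha)),
         n = length(d)))
}
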