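# Period-level summaries of runs: the pre-fishing / during-fishing /
# post-fishing aggregation used throughout the results.

.period_years <- function(records) {
  list(pre = records$year[records$phase == "pre"],
       during = records$year[records$phase == "fishing"],
       post = records$year[records$phase == "post"])
}

#' Summarise one scenario run by period
#'
#' Aggregates a run's annual records and cohort ledger into the three
#' experiment periods (pre-fishing, during-fishing, post-fishing):
#' period means of phenotypic asymptotic length, recruit counts and
#' realized individual fitness; the failed-spawning proportion;
#' across-generational fitness of the cohorts born in the period; and the
#' abundance-weighted mean age of the period's snapshot pyramid (last
#' pre-fishing year, last fishing year, last recorded year).
#'
#' @param run A `scenario_run` from [run_scenario()], or a list with
#'   `records` and `ledger`.
#' @return A one-row tibble.
#' @export
summarize_run <- function(run) {
  records <- run$records
  ledger <- run$ledger
  periods <- .period_years(records)
  snapshots <- list(
    pre = utils::tail(periods$pre, 1),
    during = utils::tail(periods$during, 1),
    post = utils::tail(c(periods$post,
                         utils::tail(records$year, 1)), 1))
  out <- list(
    fishing_years = sum(records$phase == "fishing"),
    extinct = any(records$extinct == 1))
  rif <- realized_individual_fitness(records)
  for (p in names(periods)) {
    yrs <- periods[[p]]
    sel <- records$year %in% yrs
    out[[paste0("mean_linf_", p)]] <-
      if (any(sel)) mean(records$mean_linf_cm[sel], na.rm = TRUE)
      else NA_real_
    out[[paste0("recruits_", p)]] <-
      if (any(sel)) mean(records$recruits[sel]) else NA_real_
    out[[paste0("rif_", p)]] <-
      if (any(sel)) mean(rif[sel], na.rm = TRUE) else NA_real_
    out[[paste0("failed_prop_", p)]] <-
      if (any(sel)) failed_spawning_proportion(records[sel, ])
      else NA_real_
    fit <- across_generational_fitness(ledger, yrs)
    out[[paste0("fitness_", p)]] <- fit$geometric_mean_fitness
    out[[paste0("n_cohorts_", p)]] <- fit$n_cohorts
    snap <- snapshots[[p]]
    out[[paste0("pyramid_age_", p)]] <-
      if (length(snap) && snap %in% records$year) {
        age_structure(records, snap)$mean_age
      } else NA_real_
  }
  tibble::as_tibble(out)
}

#' Summarise a factorial experiment by period
#'
#' Applies [summarize_run()] to every scenario replicate of an
#' experiment, returning one row per cell keyed by strategy, forcing
#' rate, fishing rate and replicate.
#'
#' @param exp The list returned by [run_experiment()].
#' @return A tibble with one row per scenario replicate.
#' @export
summarize_experiment <- function(exp) {
  keys <- dplyr::distinct(exp$records[, c("strategy", "env_forcing",
                                          "fishing_F", "replicate")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sel_r <- exp$records$strategy == k$strategy &
      exp$records$env_forcing == k$env_forcing &
      exp$records$fishing_F == k$fishing_F &
      exp$records$replicate == k$replicate
    sel_l <- exp$ledgers$strategy == k$strategy &
      exp$ledgers$env_forcing == k$env_forcing &
      exp$ledgers$fishing_F == k$fishing_F &
      exp$ledgers$replicate == k$replicate
    out[[i]] <- dplyr::bind_cols(
      k, summarize_run(list(records = exp$records[sel_r, ],
                            ledger = exp$ledgers[sel_l, ])))
  }
  dplyr::bind_rows(out)
}
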