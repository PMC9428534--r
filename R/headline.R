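# Headline experiment-level comparisons: the cross-scenario aggregates
# (trait shifts, fitness declines and recovery, fishing-period lengths,
# age structure, recruitment differences) that summarise a factorial
# experiment in one table.

.scenario_means <- function(summ) {
  dplyr::summarise(
    dplyr::group_by(summ, .data$strategy, .data$env_forcing,
                    .data$fishing_F),
    dplyr::across(dplyr::where(is.numeric),
                  ~ mean(.x, na.rm = TRUE)),
    .groups = "drop")
}

#' Headline metrics of a factorial experiment
#'
#' Condenses a per-replicate period summary (from
#' [summarize_experiment()]) into the study-level headline quantities:
#'
#' * `linf_gap_during`: pooled difference (cm) in mean asymptotic length,
#'   SBS minus MBS, during the fishing phase, first averaged over
#'   scenarios sharing a fishing rate and then across fishing rates.
#' * `max_fitness_decline_pct`: largest percent decline of
#'   across-generational fitness during fishing relative to pre-fishing,
#'   across scenarios.
#' * `post_pre_fitness_pct`: post-moratorium fitness as a percentage of
#'   pre-fishing fitness, pooled over scenarios; `post_pre_fitness_pct_F03`
#'   restricts to the strongest fishing pressure.
#' * `median_fishing_mbs_f01` / `median_fishing_sbs_f01`: median length
#'   (years) of the fishing period at F = 0.1 per strategy.
#' * `mean_age_mbs` / `mean_age_sbs`: mean population age pooled over the
#'   pre/during/post snapshot pyramids and scenarios.
#' * `age_decline_mbs_pct`: percent decline in MBS during-fishing mean age
#'   from F = 0.1 to F = 0.3 (pooled over forcing rates).
#' * `rif_drop_mbs_max`: largest drop of post-fishing realized individual
#'   fitness below its pre/during level across MBS scenarios.
#' * `max_pre_fitness`: highest pre-fishing across-generational fitness
#'   among scenario means.
#' * `recruit_gain_e030_pct`: percent recruitment-abundance advantage of
#'   MBS over SBS at the strongest forcing (E = 0.30) under the lightest
#'   fishing (F = 0.1), during the fishing phase.
#'
#' @param summ Per-replicate summary tibble from [summarize_experiment()].
#' @return A named list; every element is a list with `value` and `n`
#'   (the number of scenario replicates behind the value).
#' @export
headline_metrics <- function(summ) {
  sc <- .scenario_means(summ)
  out <- list()
  n_rep <- nrow(summ)

  # trait gap during fishing, SBS minus MBS, pooled within fishing rate
  wide <- tidyr::pivot_wider(
    sc[, c("strategy", "env_forcing", "fishing_F", "mean_linf_during",
           "recruits_during")],
    names_from = "strategy",
    values_from = c("mean_linf_during", "recruits_during"))
  per_f <- dplyr::summarise(
    dplyr::group_by(wide, .data$fishing_F),
    gap = mean(.data$mean_linf_during_SBS - .data$mean_linf_during_MBS,
               na.rm = TRUE), .groups = "drop")
  out$linf_gap_during <- list(value = mean(per_f$gap), n = n_rep)

  # fitness declines and recovery
  ok_pre <- !is.na(sc$fitness_pre) & sc$fitness_pre > 0
  decl <- 100 * (1 - sc$fitness_during[ok_pre] / sc$fitness_pre[ok_pre])
  out$max_fitness_decline_pct <-
    list(value = max(decl, na.rm = TRUE), n = sum(ok_pre))
  post_ratio <- sc$fitness_post[ok_pre] / sc$fitness_pre[ok_pre]
  out$post_pre_fitness_pct <-
    list(value = 100 * mean(post_ratio, na.rm = TRUE), n = sum(ok_pre))
  f3 <- ok_pre & sc$fishing_F == 0.3
  out$post_pre_fitness_pct_f03 <-
    list(value = 100 * mean(sc$fitness_post[f3] / sc$fitness_pre[f3],
                            na.rm = TRUE), n = sum(f3))

  # fishing-period medians at the lightest fishing pressure
  for (s in c("MBS", "SBS")) {
    sel <- summ$strategy == s & summ$fishing_F == 0.1
    out[[paste0("median_fishing_", tolower(s), "_f01")]] <-
      list(value = stats::median(summ$fishing_years[sel]), n = sum(sel))
  }

  # pooled mean population age from the snapshot pyramids
  for (s in c("MBS", "SBS")) {
    sel <- summ$strategy == s
    ages <- c(summ$pyramid_age_pre[sel], summ$pyramid_age_during[sel],
              summ$pyramid_age_post[sel])
    out[[paste0("mean_age_", tolower(s))]] <-
      list(value = mean(ages, na.rm = TRUE), n = sum(sel))
  }

  # age response of MBS to fishing intensity, during fishing
  a_lo <- mean(summ$pyramid_age_during[summ$strategy == "MBS" &
                                         summ$fishing_F == 0.1],
               na.rm = TRUE)
  a_hi <- mean(summ$pyramid_age_during[summ$strategy == "MBS" &
                                         summ$fishing_F == 0.3],
               na.rm = TRUE)
  out$age_decline_mbs_pct <-
    list(value = 100 * (a_lo - a_hi) / a_lo,
         n = sum(summ$strategy == "MBS" &
                   summ$fishing_F %in% c(0.1, 0.3)))

  # post-fishing drop in realized individual fitness, MBS
  mbs <- sc[sc$strategy == "MBS", ]
  drop <- pmax(mbs$rif_pre, mbs$rif_during) - mbs$rif_post
  out$rif_drop_mbs_max <- list(value = max(drop, na.rm = TRUE),
                               n = nrow(mbs))

  # highest pre-fishing fitness across scenario means
  out$max_pre_fitness <- list(value = max(sc$fitness_pre, na.rm = TRUE),
                              n = nrow(sc))

  # recruitment advantage of MBS at the strongest forcing, lightest fishing
  e30 <- wide[wide$env_forcing == 0.30 & wide$fishing_F == 0.1, ]
  out$recruit_gain_e030_pct <-
    list(value = 100 * (e30$recruits_during_MBS - e30$recruits_during_SBS) /
           e30$recruits_during_SBS,
         n = sum(summ$env_forcing == 0.30 & summ$fishing_F == 0.1))
  out
}
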