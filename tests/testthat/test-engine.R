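test_that("founder populations respect their stated structure", {
  set.seed(1)
  cfg <- scenario_config(initial_abundance = 2000, seed = 1)
  pop <- initialize_population(cfg)
  expect_equal(pop_size(pop), 2000)
  expect_true(all(pop$age >= 1 & pop$age <= 10))
  expect_true(all(pop$length <= pop$linf))
  # founders sit exactly on their own unsuppressed growth curve
  expect_equal(pop$length, pop$linf * (1 - exp(-pop$k * pop$age)))
  expect_equal(pop$mature, pop$length >= 0.66 * pop$linf)
  tb <- population_tibble(pop)
  expect_equal(nrow(tb), 2000)
  expect_true(all(tb$lifetime_recruits == 0))
})

test_that("annual steps conserve individuals and credit parents twice per recruit", {
  set.seed(2)
  cfg <- small_cfg(env_forcing = 0.1)
  pop <- initialize_population(cfg)
  cum_recruits <- 0
  cum_dead_output <- 0
  prev_n <- pop_size(pop)
  for (y in 1:40) {
    st <- annual_step(pop, cfg, phase = if (y > 20) "fishing" else "pre",
                      year = y)
    r <- st$record
    # every removal attributed to exactly one cause
    expect_equal(r$abundance,
                 prev_n + r$recruits - r$deaths_natural - r$catch_count -
                   r$age_culls)
    # pyramid sums to abundance
    hist_cols <- grep("^age_[0-9]+$", names(r), value = TRUE)
    expect_equal(sum(r[, hist_cols]), r$abundance)
    cum_recruits <- cum_recruits + r$recruits
    cum_dead_output <- cum_dead_output + sum(st$dead_output)
    pop <- st$population
    prev_n <- r$abundance
    expect_true(all(pop$length <= pop$linf + 1e-9))
    expect_true(all(pop$age <= 25))
  }
  # dam and sire are each credited once per recruit
  expect_equal(sum(pop$lifetime_recruits) + cum_dead_output,
               2 * cum_recruits)
})

test_that("runs are bit-identical under the same seed", {
  cfg <- small_cfg(seed = 77)
  a <- run_scenario(cfg)
  b <- run_scenario(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$ledger, b$ledger)
})

test_that("derived seeds make any design cell reproducible in isolation", {
  des <- make_design(5, replicates = 2, E_grid = 0.2, F_grid = 0.2,
                     strategies = "MBS")
  expect_equal(nrow(des), 2)
  expect_equal(des$seed[1],
               derive_seed(5, "MBS", 0.2, 0.2, 1))
  exp_out <- run_experiment(des, burn_in_years = 40,
                            initial_abundance = 120,
                            carrying_capacity_kg = 400,
                            pre_fishing_years = 10,
                            max_fishing_years = 20,
                            total_experiment_years = 40)
  cell <- des[2, ]
  solo <- run_scenario(scenario_config(
    strategy = cell$strategy, env_forcing = cell$env_forcing,
    fishing_F = cell$fishing_F, seed = cell$seed, replicate_id = 2,
    burn_in_years = 40, initial_abundance = 120,
    carrying_capacity_kg = 400, pre_fishing_years = 10,
    max_fishing_years = 20, total_experiment_years = 40),
    record_burn_in = FALSE)
  in_design <- exp_out$records[exp_out$records$replicate == 2,
                               names(solo$records)]
  expect_equal(as.data.frame(in_design), as.data.frame(solo$records))
})

test_that("the default design enumerates the full factorial", {
  des <- make_design(1, replicates = 50)
  expect_equal(nrow(des), 36 * 50)
  cells <- unique(des[, c("strategy", "env_forcing", "fishing_F")])
  expect_equal(nrow(cells), 36)
  expect_false(any(duplicated(des$seed)))
})

test_that("phase schedule caps fishing and latches the moratorium permanently", {
  # small, heavily fished population so the 15% trigger fires
  cfg <- small_cfg(fishing_F = 0.3, env_forcing = 0.25, seed = 3,
                   burn_in_years = 150, max_fishing_years = 60,
                   pre_fishing_years = 20, total_experiment_years = 120)
  run <- run_scenario(cfg)
  r <- run$records
  expect_lte(run$fishing_years, 60)
  phases <- rle(r$phase)$values
  expect_true(all(phases %in% c("burn_in", "pre", "fishing", "post")))
  # phases never interleave: once post starts fishing never resumes
  expect_false("fishing" %in% phases[which(phases == "post")[1]:length(phases)])
  post <- r[r$phase == "post", ]
  expect_true(all(post$catch_count == 0))
  if (run$fishing_years < 60) {
    # the latch fired: biomass at latch is at most 15% of onset
    onset <- utils::tail(r$biomass_kg[r$phase == "pre"], 1)
    latch_b <- utils::tail(r$biomass_kg[r$phase == "fishing"], 1)
    expect_lte(latch_b, 0.15 * onset)
  }
  # a no-fishing schedule degenerates to forcing only
  cfg0 <- small_cfg(fishing_F = 0, seed = 4)
  run0 <- run_scenario(cfg0)
  expect_true(all(run0$records$catch_biomass_kg == 0))
})

test_that("burn-in biomass is stationary over the tail of the burn-in", {
  cfg <- scenario_config(strategy = "MBS", env_forcing = 0.1,
                         fishing_F = 0.1, burn_in_years = 600,
                         initial_abundance = 400,
                         carrying_capacity_kg = 1200,
                         total_experiment_years = 1,
                         pre_fishing_years = 0, max_fishing_years = 0,
                         thin_burn_in = 10, seed = 1)
  run <- run_scenario(cfg)
  b <- run$records[run$records$phase == "burn_in" &
                     run$records$year > 300, ]
  fit <- stats::lm(biomass_kg ~ year, data = b)
  drift <- abs(stats::coef(fit)[2]) * 300
  expect_lt(drift, 0.25 * mean(b$biomass_kg))
})

test_that("extinction terminates a run with a flagged record", {
  cfg <- small_cfg(seed = 6, initial_abundance = 30,
                   mortality = mortality_params(m_immature = 20,
                                                reproductive_cost = 0))
  run <- run_scenario(cfg)
  expect_true(run$extinct)
  expect_equal(utils::tail(run$records$extinct, 1), 1)
  expect_lt(nrow(run$records), 80 + 100)
})

test_that("the cohort ledger finalizes only extinct cohorts", {
  cfg <- small_cfg(seed = 9)
  run <- run_scenario(cfg)
  led <- run$ledger
  expect_true(all(led$deaths <= led$cohort_size))
  expect_true(all(led$finalized[led$deaths == led$cohort_size]))
  # recent cohorts with living members stay open
  expect_true(all(!led$finalized | led$deaths == led$cohort_size |
                    led$cohort_size == 0))
})
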