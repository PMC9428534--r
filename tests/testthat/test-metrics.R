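make_ledger <- function(means, sizes = rep(10, length(means)),
                        finalized = TRUE) {
  tibble::tibble(birth_year = seq_along(means), cohort_size = sizes,
                 total_output = means * sizes, deaths = sizes,
                 finalized = finalized)
}

test_that("across-generational fitness is the geometric mean of cohort means", {
  expect_equal(across_generational_fitness(make_ledger(c(3, 3, 3)),
                                           1:3)$geometric_mean_fitness, 3)
  expect_equal(across_generational_fitness(make_ledger(c(1, 4)),
                                           1:2)$geometric_mean_fitness, 2)
  # a zero cohort annihilates the product
  expect_equal(across_generational_fitness(make_ledger(c(0, 4, 9)),
                                           1:3)$geometric_mean_fitness, 0)
  # AM-GM on random ledgers
  set.seed(1)
  for (i in 1:20) {
    m <- rexp(8)
    fit <- across_generational_fitness(make_ledger(m), 1:8)
    expect_lte(fit$geometric_mean_fitness, mean(m) + 1e-12)
  }
  # unfinalized cohorts are excluded; none finalized -> NA
  led <- make_ledger(c(2, 5), finalized = c(TRUE, FALSE))
  expect_equal(across_generational_fitness(led, 1:2)$n_cohorts, 1)
  expect_true(is.na(across_generational_fitness(led, 2)$geometric_mean_fitness))
})

test_that("realized individual fitness is recruits per mature adult", {
  rec <- tibble::tibble(recruits = c(0, 50, 10), mature_count = c(40, 1000, 0))
  expect_equal(realized_individual_fitness(rec), c(0, 0.05, NA))
})

test_that("failed spawning proportion pools female-seasons", {
  rec <- tibble::tibble(failed_seasons = c(0, 30), spawning_females = c(50, 50))
  expect_equal(failed_spawning_proportion(rec), 0.3)
  expect_equal(failed_spawning_proportion(
    tibble::tibble(failed_seasons = 0, spawning_females = 10)), 0)
  expect_equal(failed_spawning_proportion(
    tibble::tibble(failed_seasons = 10, spawning_females = 10)), 1)
  expect_true(is.na(failed_spawning_proportion(
    tibble::tibble(failed_seasons = 0, spawning_females = 0))))
})

test_that("fishing period length counts fishing-phase years", {
  rec <- tibble::tibble(phase = c("pre", "fishing", "fishing", "post"))
  expect_equal(fishing_period_length(rec), 2)
  expect_equal(fishing_period_length(
    tibble::tibble(phase = rep("pre", 5))), 0)
})

test_that("age pyramids conserve abundance on real runs", {
  run <- run_scenario(small_cfg(seed = 21))
  r <- run$records
  yr <- utils::tail(r$year[r$phase == "pre"], 1)
  py <- age_structure(r, yr)
  expect_equal(sum(py$pyramid), r$abundance[r$year == yr])
  expect_true(py$mean_age >= 0 && py$mean_age <= 25)
  # a single-cohort pyramid has that cohort's age as its mean
  fake <- r[r$year == yr, ]
  fake[grep("^age_[0-9]+$", names(fake))] <- 0
  fake$age_7 <- 42
  expect_equal(age_structure(fake, yr)$mean_age, 7)
  expect_error(age_structure(r, -999), "no records")
})

test_that("strategy comparison differences vanish on identical inputs", {
  set.seed(2)
  tab <- tidyr::expand_grid(env_forcing = c(0.1, 0.2),
                            fishing_F = c(0.1, 0.3),
                            replicate = 1:5)
  tab$metric <- rnorm(nrow(tab), 70, 2)
  cmp <- strategy_comparison(tab, tab, "metric", n_boot = 200)
  expect_true(all(cmp$per_scenario$diff == 0))
  expect_equal(cmp$pooled$diff, 0)
  expect_equal(cmp$pooled$ci_lower, 0)
  expect_equal(cmp$pooled$ci_upper, 0)
  bad <- tab
  bad$env_forcing <- bad$env_forcing + 0.05
  expect_error(strategy_comparison(tab, bad, "metric"), "do not match")
})
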