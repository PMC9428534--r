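test_that("fecundity reproduces frozen reference values and is monotone", {
  expect_equal(fecundity(0), 233536)
  expect_equal(fecundity(3.822297), 3955277, tolerance = 1e-6)
  w <- seq(0, 10, by = 0.5)
  expect_true(all(diff(fecundity(w)) > 0))
  expect_error(fecundity(-0.1), "non-negative")
})

test_that("batch number follows the logistic for MBS and is one for SBS", {
  mbs <- spawning_params("MBS")
  sbs <- spawning_params("SBS")
  # at the midpoint the logistic is half the asymptote: 10.578 -> 11
  expect_equal(n_batches(55.014, mbs), 11L)
  expect_equal(n_batches(200, mbs), 21L)   # saturates at round(21.1561)
  expect_equal(n_batches(1, mbs), 1L)      # floored at one batch
  expect_true(all(n_batches(c(0, 30, 55.014, 90), sbs) == 1L))
})

test_that("batch survival combines forcing and order costs", {
  e0 <- spawning_params("MBS", env_forcing = 0)
  expect_equal(batch_survival_prob(1, e0), 1)
  expect_equal(batch_survival_prob(21, e0), 0.8954)
  # the cumulative cost stays inside the reported 0 to 0.11 band
  costs <- 1 - batch_survival_prob(1:21, e0)
  expect_true(all(costs >= 0 & costs <= 0.11))
  e3 <- spawning_params("MBS", env_forcing = 0.3)
  expect_equal(batch_survival_prob(1, e3), 0.7)
  expect_true(all(batch_survival_prob(1:1000, e3) >= 0))
  expect_error(batch_survival_prob(0, e0), "1-based")
})

test_that("spawning conserves eggs without forcing and errors for immature females", {
  set.seed(1)
  out <- spawn(70, params = spawning_params("MBS", env_forcing = 0,
                                            cost_slope = 0))
  expect_equal(out$eggs_surviving, out$eggs_produced)
  expect_equal(out$batches_survived, out$n_batches)
  expect_error(spawn(70, mature = FALSE), "mature")
  sout <- spawn(70, params = spawning_params("SBS", env_forcing = 0))
  expect_equal(sout$n_batches, 1L)
  expect_equal(sout$eggs_surviving, sout$eggs_produced)
})

test_that("multiple batches reduce the variance of surviving eggs by 1/n", {
  # equal split, zero cost: Var_MBS = (N/n)^2 n E(1-E) = Var_SBS / n
  E <- 0.2
  len <- 55.014  # 11 batches
  mbs <- spawning_params("MBS", env_forcing = E, cost_slope = 0)
  sbs <- spawning_params("SBS", env_forcing = E)
  set.seed(42)
  sm <- replicate(4000, spawn(len, params = mbs)$eggs_surviving)
  ss <- replicate(4000, spawn(len, params = sbs)$eggs_surviving)
  eggs <- fecundity(weight_from_length(len))
  expect_equal(var(ss), eggs^2 * E * (1 - E), tolerance = 0.1)
  expect_equal(var(sm), eggs^2 * E * (1 - E) / 11, tolerance = 0.1)
  expect_lt(var(sm), var(ss))
  # equal expected survival: means agree when costs are off
  expect_equal(mean(sm), mean(ss), tolerance = 0.02)
})

test_that("a single-batch season fails with probability E exactly", {
  E <- 0.25
  sbs <- spawning_params("SBS", env_forcing = E)
  set.seed(7)
  fails <- replicate(4000, spawn(60, params = sbs)$eggs_surviving == 0)
  expect_equal(mean(fails), E, tolerance = 0.1)
})

test_that("MBS forced to one batch with zero cost is distributionally identical to SBS", {
  mbs1 <- spawning_params("MBS", env_forcing = 0.2, cost_slope = 0,
                          batch_asymptote = 1)
  sbs <- spawning_params("SBS", env_forcing = 0.2)
  for (len in c(40, 60, 85)) {
    set.seed(123)
    a <- spawn(len, params = mbs1)
    set.seed(123)
    b <- spawn(len, params = sbs)
    expect_identical(a, b)
  }
})

test_that("the egg-to-recruit bottleneck is a binomial thinning", {
  expect_equal(recruits_from_eggs(0), 0L)
  set.seed(11)
  r <- recruits_from_eggs(rep(3955277, 3000))
  expect_equal(mean(r), 3955277 * 1.13e-6, tolerance = 0.05)
  expect_error(recruits_from_eggs(-5), "non-negative")
})
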