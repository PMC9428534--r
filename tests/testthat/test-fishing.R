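test_that("selectivity is the logistic trawl curve", {
  expect_equal(selectivity(50), 0.5)
  expect_equal(selectivity(45), 0.2227001, tolerance = 1e-6)
  expect_equal(selectivity(70), 0.9933071, tolerance = 1e-6)
  s <- selectivity(seq(0, 120, by = 1))
  expect_true(all(diff(s) > 0) && all(s > 0 & s < 1))
})

test_that("capture probability honours the exclusive minimum-size threshold", {
  p2 <- fishing_params(F = 0.2)
  expect_equal(capture_prob(45, p2), 0)       # boundary fish exempt
  expect_gt(capture_prob(45.001, p2), 0)
  expect_equal(capture_prob(50, p2), 0.1)     # F * 0.5
  expect_true(all(capture_prob(seq(0, 120, 0.5), p2) <= p2$F))
  expect_true(all(diff(capture_prob(seq(46, 120, 0.5), p2)) >= 0))
  expect_true(all(capture_prob(seq(0, 120, 0.5), fishing_params(F = 0)) == 0))
})

test_that("harvest removes fish by Bernoulli capture with exact mass bookkeeping", {
  set.seed(1)
  lens <- runif(500, 20, 100)
  none <- harvest(lens, fishing_params(F = 0))
  expect_equal(none$catch_count, 0)
  expect_equal(none$catch_biomass_kg, 0)
  small <- harvest(runif(100, 5, 44), fishing_params(F = 0.3))
  expect_equal(small$catch_count, 0)

  p <- fishing_params(F = 0.25)
  out <- harvest(lens, p)
  expect_equal(out$catch_biomass_kg,
               sum(weight_from_length(lens[out$captured])))
  # expected catch equals the sum of capture probabilities
  set.seed(2)
  counts <- replicate(800, harvest(lens, p)$catch_count)
  expect_equal(mean(counts), sum(capture_prob(lens, p)), tolerance = 0.03)
})

test_that("the moratorium trigger is boundary-inclusive", {
  p <- fishing_params()
  expect_true(fishing_should_stop(0.15 * 1000, 1000, p))
  expect_false(fishing_should_stop(1000, 1000, p))
  expect_false(fishing_should_stop(0.151 * 1000, 1000, p))
  expect_error(fishing_should_stop(10, 0, p), "positive")
})
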