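test_that("founder genotypes have binomial structure and honour degenerate frequencies", {
  set.seed(1)
  expect_equal(genotype_value(founder_genotype(allele_freq = 1)), 20)
  expect_equal(genotype_value(founder_genotype(allele_freq = 0)), 0)
  expect_error(founder_genotype(allele_freq = 1.5), "allele_freq")

  g <- replicate(5000, genotype_value(founder_genotype(10L, 0.5)))
  expect_true(all(g >= 0 & g <= 20))
  # binomial(20, 0.5) moments: mean 10, variance 5
  expect_equal(mean(g), 10, tolerance = 0.02)
  expect_equal(var(g), 5, tolerance = 0.1)
})

test_that("Mendelian inheritance conserves alleles and the midparent expectation", {
  set.seed(2)
  expect_equal(genotype_value(inherit(rep(1L, 20), rep(1L, 20))), 20)
  # fully heterozygous cross: every offspring is exactly midparent
  off <- replicate(50, genotype_value(inherit(rep(1L, 20), rep(0L, 20))))
  expect_true(all(off == 10))
  expect_error(inherit(rep(1L, 20), rep(1L, 10)), "same number of loci")

  # random parents: offspring mean matches the midparent value and no
  # allele leaves {0, 1}
  dam <- founder_genotype(10L, 0.3)
  sire <- founder_genotype(10L, 0.8)
  kids <- replicate(4000, inherit(dam, sire))
  expect_true(all(kids %in% c(0L, 1L)))
  mid <- (genotype_value(dam) + genotype_value(sire)) / 2
  expect_equal(mean(colSums(kids)), mid, tolerance = 0.02)
})

test_that("allele frequencies drift without direction across a generation", {
  set.seed(3)
  n <- 800
  G <- batchspawner:::.founder_allele_matrix(n, 10L, 0.5)
  off <- batchspawner:::.mendelian_offspring(
    G, sample.int(n, n, replace = TRUE), sample.int(n, n, replace = TRUE))
  expect_true(all(off %in% c(0L, 1L)))
  p0 <- mean(G)
  p1 <- mean(off)
  # change bounded by 5 binomial standard errors at 2N samples
  expect_lt(abs(p1 - p0), 5 * sqrt(p0 * (1 - p0) / (2 * n)))
})

test_that("phenotype expression matches the noise-free limit and the variance algebra", {
  p0 <- expression_params(noise_sd = 1e-9, intercept_cm = 60,
                          slope_cm_per_score = 2)
  set.seed(4)
  g10 <- c(rep(1L, 10), rep(0L, 10))
  expect_equal(express_linf(g10, p0), 80, tolerance = 1e-6)

  # Var(Linf) = slope^2 * (Var(g) + noise_sd^2) over founders
  p <- expression_params()
  g <- rowSums(batchspawner:::.founder_allele_matrix(20000, 10L, 0.5))
  linf <- batchspawner:::.express_scores(g, p)
  expect_equal(var(linf), p$slope_cm_per_score^2 * (5 + p$noise_sd^2),
               tolerance = 0.05)
  # floor truncation engages for absurd maps
  pf <- expression_params(intercept_cm = -100, slope_cm_per_score = 0.1)
  expect_true(all(batchspawner:::.express_scores(0:20, pf) >=
                    pf$linf_floor_cm))
})

test_that("growth rate is negatively coupled to asymptotic length", {
  # calibration identity: k(80) = exp(alpha) / 80 for unit elasticity
  expect_equal(k_from_linf(80, expression_params(growth_alpha = log(9.6))),
               0.12, tolerance = 1e-12)
  expect_equal(k_from_linf(80), 0.0825, tolerance = 1e-12)
  expect_gt(k_from_linf(60), k_from_linf(80))
  expect_error(k_from_linf(-1), "positive")
})

test_that("heritability recovers the 0.2-0.3 band and is affine invariant", {
  set.seed(5)
  h2 <- estimate_heritability(12000)
  expect_gte(h2, 0.2 - 0.03)
  expect_lte(h2, 0.3 + 0.03)

  # re-mapping score to cm with any positive slope/intercept leaves the
  # midparent-offspring slope unchanged (same noise stream)
  set.seed(99)
  a <- estimate_heritability(4000, params = expression_params())
  set.seed(99)
  b <- estimate_heritability(4000, params = expression_params(
    intercept_cm = 100, slope_cm_per_score = 5))
  expect_equal(a, b, tolerance = 1e-10)
})
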