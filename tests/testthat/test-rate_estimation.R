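# Rate arithmetic, VEE adjustment, age effect, dispersion and comparisons.

MOUSE_GENOME <- 2222635788

test_that("corrected_mean_mutations divides by the correction product", {
  expect_equal(corrected_mean_mutations(
    18, sensitivity_corrections(0.9, 1, 1)), 20)
  expect_equal(corrected_mean_mutations(7.3, sensitivity_corrections()), 7.3)
  # 0.899 is a typical average callable-genome fraction
  expect_equal(corrected_mean_mutations(
    20, sensitivity_corrections(0.899, 1, 1)), 22.24694, tolerance = 1e-6)
  expect_error(sensitivity_corrections(0, 1, 1), "corrections")
  expect_error(corrected_mean_mutations(-1), ">= 0")
})

test_that("rate_set identities hold exactly", {
  dm <- germline_demography("mouse")
  rs <- rate_set(20, MOUSE_GENOME, dm, n_offspring = 10,
                 total_mutations = 200)
  expect_equal(rs$mu_generation, 4.499163e-9, tolerance = 1e-6)
  expect_equal(rs$mu_year * dm$generation_time_years, rs$mu_generation)
  expect_equal(rs$mu_cell_division *
                 (dm$divisions_paternal + dm$divisions_maternal) / 2,
               rs$mu_generation)
  expect_true(rs$ci_generation[1] <= rs$mu_generation &&
                rs$mu_generation <= rs$ci_generation[2])
  # human per-cell-division conversion: 1.22e-8 over 216 sex-averaged
  dh <- germline_demography("human")
  rsh <- rate_set(1.22e-8 * 2 * 2394138713, 2394138713, dh)
  expect_equal(rsh$mu_cell_division, 5.648148e-11, tolerance = 1e-6)
  # zero mutations: all rates zero, CI lower bound zero
  rs0 <- rate_set(0, MOUSE_GENOME, dm, n_offspring = 10, total_mutations = 0)
  expect_equal(rs0$mu_generation, 0)
  expect_equal(rs0$ci_generation[1], 0)
})

test_that("demography defaults carry the canonical division counts", {
  dm <- germline_demography("mouse")
  dh <- germline_demography("human")
  expect_equal(dm$divisions_paternal + dm$divisions_maternal, 87)
  expect_equal(dh$divisions_paternal + dh$divisions_maternal, 432)
  expect_error(germline_demography(list(generation_time_years = 1)),
               "missing")
})

test_that("VEE transmission fit recovers exact and noisy coefficients", {
  m <- fit_vee_transmission(c(0.1, 0.2, 0.3), c(0.2, 0.4, 0.6))
  expect_equal(m$beta0, 0, tolerance = 1e-12)
  expect_equal(m$beta1, 2, tolerance = 1e-12)
  expect_equal(m$pearson_r, 1, tolerance = 1e-12)
  x <- c(-0.1, 0, 0.1, 0.05, -0.05)
  m <- fit_vee_transmission(x, x)   # mean-centred identity
  expect_equal(m$beta1, 1, tolerance = 1e-12)
  expect_error(fit_vee_transmission(c(0.1, 0.1, 0.1), c(1, 2, 3)),
               "constant")
  expect_error(fit_vee_transmission(c(0.1, 0.2), c(1, 2)), "3 pairs")
  # simulation: n = 26 pairs, known coefficients, Gaussian noise
  set.seed(31)
  hit <- vapply(1:200, function(i) {
    vaf <- runif(26, 0.02, 0.45)
    y <- 0.05 + 1.2 * vaf + rnorm(26, 0, 0.08)
    f <- fit_vee_transmission(vaf, y)
    se <- summary(f$fit)$coefficients["parent_vaf", 2]
    abs(f$beta1 - 1.2) <= 2 * se
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("adjusted_vee_count follows the displayed formula", {
  m <- list(beta0 = 0, beta1 = 2)
  expect_equal(adjusted_vee_count(c(0.25, 0.20), m), 1.8)
  m2 <- list(beta0 = 0.5, beta1 = 0)
  expect_equal(adjusted_vee_count(c(0.1, 0.3, 0.4), m2), 3)  # = raw count
  expect_equal(adjusted_vee_count(numeric(0), m), 0)
  # bounds: 0 <= adjusted <= 2 x raw count
  set.seed(2)
  for (i in 1:20) {
    v <- runif(sample(1:15, 1), 0, 0.5)
    mm <- list(beta0 = runif(1, -0.5, 0.5), beta1 = runif(1, -1, 3))
    a <- adjusted_vee_count(v, mm)
    expect_gte(a, 0)
    expect_lte(a, 2 * length(v))
  }
  expect_error(adjusted_vee_count(0.7, m), "0.5")
})

test_that("stage_rates implements the printed formulas", {
  dh <- germline_demography("human")
  tab <- stage_rates(vee_counts = rep(1, 10), mutations_mean = 70,
                     paternal_phased = 30, maternal_phased = 10,
                     annual_slope = 2, slope_se = 0.2,
                     age_mean_years = 30, demography = dh,
                     genome_size = 2394138713)
  # pre-puberty N = 70 - (30 - 15) * 2 = 40, over 401 - 23*(30-15) divisions
  pre <- tab$rate[tab$stage == "pre_puberty_male"]
  expect_equal(pre, 40 / (401 - 23 * 15) / 2394138713)
  # post-puberty mouse numbers: 4.5 slope over 42 SSC divisions/year
  dm <- germline_demography("mouse")
  tabm <- stage_rates(rep(5, 10), 20, 30, 10, annual_slope = 4.5,
                      slope_se = 1, age_mean_years = 0.47, demography = dm,
                      genome_size = MOUSE_GENOME)
  expect_equal(tabm$rate[tabm$stage == "post_puberty_male"],
               4.820531e-11, tolerance = 1e-6)
  # zero slope: zero post-puberty rate
  tab0 <- stage_rates(rep(5, 10), 20, 30, 10, 0, 0, 0.47, dm, MOUSE_GENOME)
  expect_equal(tab0$rate[tab0$stage == "post_puberty_male"], 0)
  # VEE: mean per offspring / genome / 2 (one division, haploid)
  expect_equal(tabm$rate[tabm$stage == "vee"], 5 / MOUSE_GENOME / 2)
  expect_error(stage_rates(rep(1, 5), 20, 1, 1, 2, 1, 0.01, dm, 1e9),
               "puberty")
})

test_that("age effect is recovered noiselessly and under permutation", {
  age <- rep(c(0.2, 0.4, 0.6, 0.8), each = 5)
  counts <- 10 + 4.5 * age
  f <- suppressWarnings(fit_age_effect(counts, age))  # perfect fit warns
  expect_equal(f$slope, 4.5, tolerance = 1e-8)
  expect_equal(f$intercept, 10, tolerance = 1e-8)
  # permuted ages: slope near zero, p behaves like a null p-value
  set.seed(17)
  ps <- vapply(1:60, function(i) {
    y <- rpois(20, 15)
    fit_age_effect(y, sample(age))$p
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_gt(mean(ps < 0.05), 0)  # sanity: some variation
  expect_error(fit_age_effect(1:5, rep(1, 5)), "distinct ages")
})

test_that("pedigree random intercepts absorb between-family offsets", {
  set.seed(23)
  age <- runif(60, 0.2, 0.9)
  pedig <- rep(c("A", "B", "C"), each = 20)
  offset <- c(A = 0, B = 6, C = -4)[pedig]
  counts <- 12 + offset + 4.5 * age + rnorm(60, 0, 1)
  f <- fit_age_effect(counts, age, pedig)
  expect_equal(f$slope, 4.5, tolerance = 0.2 * 4.5)
  expect_lt(f$p, 0.01)
})

test_that("overdispersion test is calibrated at its extremes", {
  res <- overdispersion_test(rep(4, 10), seed = 1)
  expect_lte(res$phi, 1)
  expect_gte(res$p_value, 0.5)
  # Gamma-Poisson with variance ~3x the mean, n = 40: detected most times
  set.seed(5)
  hits <- vapply(1:20, function(i) {
    lam <- rgamma(40, shape = 2.5, rate = 0.5)  # mean 5, var(count) ~ 3x
    overdispersion_test(rpois(40, lam))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
  expect_error(overdispersion_test(rep(0, 10)), "zero")
  expect_error(overdispersion_test(c(1, 2)), "5 offspring")
})

test_that("compare_rates runs both tests and adjusts by Bonferroni", {
  out <- compare_rates(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_true(all(out$p_adj == 1))
  expect_setequal(out$test, c("wilcoxon", "t"))
  expect_equal(bonferroni(0.01, 7), 0.07)
  expect_equal(bonferroni(0.3, 7), 1)
  # mean + CI mode
  a <- list(mean = 9.07e-11, ci = c(8.41e-11, 9.69e-11))
  b <- list(mean = 5.67e-11, ci = c(5.28e-11, 6.05e-11))
  out <- compare_rates(a, b)
  expect_lt(out$p_raw, 1e-6)
  # power: two Poisson samples with a 3x rate difference, n = 20
  set.seed(12)
  hits <- vapply(1:40, function(i) {
    any(compare_rates(rpois(20, 3), rpois(20, 9))$p_adj < 0.05)
  }, logical(1))
  expect_gt(mean(hits), 0.8)
  expect_error(compare_rates(1:3, list(mean = 1)), "both")
})
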