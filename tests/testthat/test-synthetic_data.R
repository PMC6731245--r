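# The pedigree/germline generator: stated-world invariants, closed-form
# means, determinism and read-sampling behaviour.

null_rates <- list(first_cleavage = 0, embryonic = 0, peri_pgc = 0,
                   post_pgc_pre_puberty = 0, ssc_per_division = 0)

test_that("all-zero stage rates give zero truth records", {
  cfg <- sim_config(seed = 1, rates = null_rates,
                    simulate_parental_vee = FALSE)
  sim <- simulate_germline(cfg)
  expect_equal(nrow(sim$truth), 0L)
})

test_that("zero offspring is rejected; invalid configs are rejected", {
  expect_error(sim_config(n_offspring_wgs = 0, n_offspring_genotyped = 0),
               "offspring")
  expect_error(sim_config(genome_size = 0), "genome_size")
  bad <- null_rates; bad$embryonic <- -1
  expect_error(sim_config(rates = bad), "rates")
})

test_that("first-cleavage-only configs produce pure VEE truth", {
  r <- null_rates; r$first_cleavage <- 2e-9
  cfg <- scale_genome(sim_config(seed = 5, rates = r,
                                 simulate_parental_vee = FALSE), 5e7)
  sim <- simulate_germline(cfg)
  expect_gt(nrow(sim$truth), 0)
  expect_true(all(sim$truth$stage == "VEE"))
  expect_true(all(sim$truth$expected_stratum == "VEE"))
  # mosaic in half the embryo: expected VAF 0.25
  expect_true(all(sim$truth$offspring_fraction == 0.5))
  expect_true(all(sim$truth$n_carriers == 1))
})

test_that("late post-PGC counts match the closed-form Poisson mean", {
  # mean per offspring = 2 r d G when both sexes contribute d divisions
  r <- null_rates; r$post_pgc_pre_puberty <- 2.5e-10
  d <- 12L
  cfg <- sim_config(seed = 7, rates = r, simulate_parental_vee = FALSE,
                    genome_size = 1e9,
                    divisions = list(pre_pgc = 10L, peri_pgc = 3L,
                                     post_pgc_paternal = d,
                                     post_pgc_maternal = d),
                    n_offspring_wgs = 1500L, n_offspring_genotyped = 0L,
                    n_unrelated = 0L)
  sim <- simulate_germline(cfg)
  n_off <- 1500
  lambda <- 2 * r$post_pgc_pre_puberty * d * cfg$genome_size
  mean_obs <- nrow(sim$truth) / n_off
  se <- sqrt(lambda / n_off)
  expect_lt(abs(mean_obs - lambda), 3 * se)
  expect_true(all(sim$truth$stage == "late_post_PGC"))
})

test_that("the same seed reproduces bit-identical outputs", {
  cfg <- scale_genome(sim_config(seed = 3), 2e7)
  s1 <- simulate_germline(cfg); s2 <- simulate_germline(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(simulate_reads(s1), simulate_reads(s2))
})

test_that("peri-PGC founder lineages of one parent never share offspring", {
  sim <- cached_sim()$sim
  peri <- sim$truth[sim$truth$stage == "peri_PGC", ]
  expect_gte(nrow(peri), 2)  # deterministic under the fixture seed
  for (p in unique(peri$origin_id)) {
    sub <- peri[peri$origin_id == p, ]
    by_founder <- split(sub$carriers, sub$founder)
    sets <- lapply(by_founder, function(x) unique(unlist(strsplit(x, ","))))
    if (length(sets) < 2) next
    for (i in seq_along(sets)) for (j in seq_along(sets)) if (i < j)
      expect_length(intersect(sets[[i]], sets[[j]]), 0)
  }
})

test_that("read sampling matches binomial expectations", {
  # constitutive het, deep coverage, no error: VAF concentrates near 0.5
  r <- null_rates; r$post_pgc_pre_puberty <- 1e-9
  cfg <- sim_config(seed = 9, rates = r, simulate_parental_vee = FALSE,
                    genome_size = 5e8, error_rate = 0,
                    n_offspring_wgs = 4L, n_offspring_genotyped = 0L)
  sim <- simulate_germline(cfg)
  calls <- simulate_reads(sim)
  carrier <- calls[calls$true_vaf == 0.5, ]
  vaf <- carrier$alt_reads / (carrier$ref_reads + carrier$alt_reads)
  expect_true(all(abs(vaf - 0.5) < 0.15))
  # non-carriers with zero error rate: zero alt reads everywhere
  expect_true(all(calls$alt_reads[calls$true_vaf == 0] == 0))
})

test_that("VEE mosaic reads centre on VAF 0.25", {
  r <- null_rates; r$first_cleavage <- 1e-8
  cfg <- sim_config(seed = 13, rates = r, simulate_parental_vee = FALSE,
                    genome_size = 2e8, error_rate = 0,
                    n_offspring_wgs = 10L, n_offspring_genotyped = 0L)
  sim <- simulate_germline(cfg)
  calls <- simulate_reads(sim)
  carrier <- calls[calls$true_vaf == 0.25, ]
  expect_gt(nrow(carrier), 50)
  vaf <- carrier$alt_reads / (carrier$ref_reads + carrier$alt_reads)
  # binomial expectation: mean VAF 0.25 within Monte-Carlo error
  mc_se <- sqrt(0.25 * 0.75 / sum(carrier$ref_reads + carrier$alt_reads))
  expect_lt(abs(mean(vaf) - 0.25), 4 * mc_se + 0.005)
})

test_that("optional gamma multiplier over-disperses VEE counts", {
  r <- null_rates; r$first_cleavage <- 2e-9
  base <- list(seed = 21, rates = r, simulate_parental_vee = FALSE,
               genome_size = 1e9, n_offspring_wgs = 300L,
               n_offspring_genotyped = 0L)
  cfg_od <- do.call(sim_config, c(base, list(vee_zygote_shape = 0.5)))
  sim <- simulate_germline(cfg_od)
  per_off <- table(factor(sim$truth$carriers,
                          levels = sim$pedigree$id[sim$pedigree$tier == "wgs" &
                                                     sim$pedigree$role ==
                                                     "offspring"]))
  res <- overdispersion_test(as.integer(per_off), seed = 1)
  expect_gt(res$phi, 1)
  expect_lt(res$p_value, 0.05)
})

test_that("classifier recovers expected strata on default-config data", {
  # end-to-end invariant: >= 90% of discovered events classified into the
  # stratum a perfectly powered classifier would assign
  cache <- cached_sim()
  res <- run_pipeline(cache$calls, cache$sim$pedigree,
                      genome_size = cache$cfg$genome_size)
  tr <- cache$sim$truth
  tkey <- paste(tr$chrom, tr$pos, tr$ref, tr$alt, sep = ":")
  skey <- paste(res$strata$chrom, res$strata$pos, res$strata$ref,
                res$strata$alt, sep = ":")
  truth_label <- tr$expected_stratum[match(skey, tkey)]
  agree <- mean(res$strata$stratum == truth_label, na.rm = TRUE)
  expect_gte(agree, 0.90)
})
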