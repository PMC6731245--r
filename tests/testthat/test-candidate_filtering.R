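# Candidate DNM filters: depth cutoff, mutation-specific error, offspring
# filters, parental-VEE filters.

test_that("depth_cutoff matches the Poisson-CDF scan oracle", {
  scan_oracle <- function(mean, q) {
    d <- 0L
    while (ppois(d, mean, lower.tail = FALSE) >= q) d <- d + 1L
    d
  }
  # frozen from the oracle: smallest d with P(D > d) < 1e-4
  expect_identical(depth_cutoff(25, 1e-4), 46L)
  expect_identical(depth_cutoff(41, 1e-4), 67L)
  expect_identical(depth_cutoff(0.001, 0.5), 0L)  # nearly all mass at zero
  for (m in c(3, 25, 41, 200, 777.5))
    for (q in c(1e-4, 1e-2, 0.3))
      expect_identical(depth_cutoff(m, q), scan_oracle(m, q))
  # monotone in mean depth at fixed quantile (stochastic ordering)
  expect_lte(depth_cutoff(25), depth_cutoff(41))
  expect_error(depth_cutoff(25, 0), "quantile")
  expect_error(depth_cutoff(25, 1), "quantile")
  expect_error(depth_cutoff(0), "mean_depth")
})

test_that("mutation_specific_error pools depth-weighted rates", {
  expect_equal(mutation_specific_error(c(0, 0), c(2500, 2500)), 0)
  expect_equal(mutation_specific_error(c(100, 50), c(2500, 2500)), 0.03)
  expect_true(is.na(mutation_specific_error(c(0, 0), c(0, 0))))
  # pooling equals the depth-weighted mean of per-individual rates
  set.seed(8)
  for (i in 1:10) {
    depths <- sample(100:900, 5)
    alts <- rbinom(5, depths, 0.01)
    expect_equal(mutation_specific_error(alts, depths),
                 sum((alts / depths) * depths) / sum(depths))
  }
})

make_filter_fixture <- function() {
  ped <- tiny_pedigree(n_wgs = 2, n_unrelated = 3)
  calls <- rbind(
    # clean candidate: VAF 0.48 in O1, nothing anywhere else
    site_calls(ped, "1", 1000, list(P1_O1 = 288), depth = 600),
    # low VAF 0.10 in candidate
    site_calls(ped, "1", 2000, list(P1_O1 = 60), depth = 600),
    # parental support: father carries 6% of reads
    site_calls(ped, "1", 3000, list(P1_O2 = 290, P1_F = 36), depth = 600),
    # high mutation-specific error: 3% in unrelated panel
    site_calls(ped, "1", 4000, list(P1_O1 = 290, U1 = 18, U2 = 18, U3 = 18),
               depth = 600),
    # excessive depth at the candidate site
    site_calls(ped, "2", 5000, list(P1_O2 = 500), depth = 1000),
    # masked region
    site_calls(ped, "3", 6000, list(P1_O1 = 280), depth = 600))
  list(ped = ped, calls = calls,
       masks = data.frame(chrom = "3", start = 5990, end = 6010))
}

test_that("offspring filters remove candidates for the documented reasons", {
  fx <- make_filter_fixture()
  out <- filter_offspring_candidates(fx$calls, fx$ped, masks = fx$masks,
                                     mode = "error-rate",
                                     mean_depths = c(P1_O1 = 600,
                                                     P1_O2 = 600))
  # the clean candidate and the parent-supported one survive error-rate
  # mode (the parental filter belongs to reciprocal mode)
  expect_equal(sort(out$retained$pos), c(1000, 3000))
  led <- setNames(out$ledger$reason, out$ledger$site)
  expect_equal(unname(led["1:2000:C:T"]), "low_vaf")
  expect_equal(unname(led["1:4000:C:T"]), "site_error")
  expect_equal(unname(led["2:5000:C:T"]), "depth_cutoff")
  expect_equal(unname(led["3:6000:C:T"]), "region_mask")
  # one named reason per removed candidate
  expect_false(any(is.na(out$ledger$reason)))
})

test_that("reciprocal mode uses parental read support (>5%)", {
  fx <- make_filter_fixture()
  out <- filter_offspring_candidates(fx$calls, fx$ped, masks = fx$masks,
                                     mode = "reciprocal",
                                     mean_depths = c(P1_O1 = 600,
                                                     P1_O2 = 600))
  led <- setNames(out$ledger$reason, out$ledger$site)
  expect_equal(unname(led["1:3000:C:T"]), "parental_support")
  # father at 6% of reads removed; the clean site survives both modes
  expect_true("1:1000:C:T" %in% out$retained$site)
})

test_that("retained set is invariant to call-table row order", {
  fx <- make_filter_fixture()
  set.seed(1)
  shuffled <- fx$calls[sample(nrow(fx$calls)), ]
  a <- filter_offspring_candidates(fx$calls, fx$ped, masks = fx$masks,
                                   mean_depths = c(P1_O1 = 600, P1_O2 = 600))
  b <- filter_offspring_candidates(shuffled, fx$ped, masks = fx$masks,
                                   mean_depths = c(P1_O1 = 600, P1_O2 = 600))
  expect_setequal(paste(a$retained$site, a$retained$individual),
                  paste(b$retained$site, b$retained$individual))
})

test_that("parental-VEE filters apply the stringent thresholds", {
  ped <- tiny_pedigree(n_wgs = 2, n_unrelated = 3)
  calls <- rbind(
    # good candidate: 30/300 per tissue (VAF 0.10), clean elsewhere
    site_calls(ped, "1", 100, list(P1_F = 30), depth = 300),
    # VAF 0.40 > 0.35
    site_calls(ped, "1", 900, list(P1_M = 120), depth = 300),
    # only 4 alt reads total... per tissue 1 -> fails min_alt_reads
    site_calls(ped, "2", 100, list(P1_F = 1), depth = 300),
    # consistent with a constitutive het (VAF 0.5)
    site_calls(ped, "2", 900, list(P1_M = 150), depth = 300),
    # supported in the other parent
    site_calls(ped, "3", 100, list(P1_F = 30, P1_M = 4), depth = 300))
  out <- filter_parental_vee_candidates(calls, ped)
  expect_equal(paste0(out$retained$chrom, ":", out$retained$pos), "1:100")
  led <- setNames(out$ledger$reason, out$ledger$site)
  expect_equal(unname(led["1:900:C:T"]), "high_vaf")
  expect_equal(unname(led["2:100:C:T"]), "low_alt_reads")
  expect_equal(unname(led["2:900:C:T"]), "possibly_constitutive")
  expect_equal(unname(led["3:100:C:T"]), "other_parent_support")
})

test_that("retained good parental-VEE candidate passes both tail tests", {
  # 30 alt / 300 reads per tissue at error 1e-4: both tails computed by
  # direct summation fall far below their thresholds
  err <- 1e-4
  p_pois <- ppois(89, 900 * err, lower.tail = FALSE)  # pooled 3 tissues
  p_bin <- pbinom(90, 900, 0.5)
  expect_lt(p_pois, 0.02)
  expect_lt(p_bin, 0.003)
})

test_that("true mutations survive filtering on clean simulated data", {
  cache <- cached_sim()
  flt <- filter_offspring_candidates(cache$calls, cache$sim$pedigree)
  truth <- cache$sim$truth
  wgs <- cache$sim$pedigree$id[cache$sim$pedigree$tier == "wgs" &
                                 cache$sim$pedigree$role == "offspring"]
  discoverable <- vapply(strsplit(truth$carriers, ","),
                         function(s) any(s %in% wgs), logical(1))
  tkey <- paste(truth$chrom, truth$pos, truth$ref, truth$alt, sep = ":")
  retention <- mean(tkey[discoverable] %in% flt$retained$site)
  expect_gte(retention, 0.95)
})
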