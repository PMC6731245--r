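#' Filter parameters for candidate de novo mutations
#'
#' Thresholds for the offspring candidate filters and the stricter
#' parental first-cleavage (VEE) candidate filters. Defaults:
#' reciprocal-cross VAF caps of 20% (offspring) and 4%
#' (parents), a Poisson depth cutoff at the 1e-4 upper quantile, parental
#' support cap of 5% of reads (reciprocal mode) or a 2% mutation-specific
#' error cap (error-rate mode), and a candidate VAF floor of 15%. The
#' parental-VEE branch additionally requires <= 1 alt read in any other
#' parent, >= 5 alt reads in the candidate, VAF <= 35%, a sequencing-error
#' Poisson tail probability <= 0.02 and a constitutive binomial tail
#' probability <= 0.003.
#'
#' @param reciprocal_offspring_vaf_max,reciprocal_parent_vaf_max VAF caps
#'   in the reciprocal cross.
#' @param depth_quantile Poisson upper-tail quantile for the depth cutoff.
#' @param parent_alt_fraction_max parental read support cap.
#' @param mutation_specific_error_max error-rate-mode cap.
#' @param candidate_vaf_min candidate VAF floor.
#' @param min_site_error floor applied to pooled error rates before tail
#'   tests (guards against zero estimates from finite panels).
#' @param parental_vee named list of the parental-VEE thresholds.
#' @return a `filter_params` list.
#' @export
filter_params <- function(reciprocal_offspring_vaf_max = 0.20,
                          reciprocal_parent_vaf_max = 0.04,
                          depth_quantile = 1e-4,
                          parent_alt_fraction_max = 0.05,
                          mutation_specific_error_max = 0.02,
                          candidate_vaf_min = 0.15,
                          min_site_error = 1e-5,
                          parental_vee = list(alt_in_other_parents_max = 1,
                                              min_alt_reads = 5,
                                              vaf_max = 0.35,
                                              error_poisson_p_max = 0.02,
                                              constitutive_binom_p_min = 0.003,
                                              unrelated_vaf_max = 0.05)) {
  p <- list(reciprocal_offspring_vaf_max = reciprocal_offspring_vaf_max,
            reciprocal_parent_vaf_max = reciprocal_parent_vaf_max,
            depth_quantile = depth_quantile,
            parent_alt_fraction_max = parent_alt_fraction_max,
            mutation_specific_error_max = mutation_specific_error_max,
            candidate_vaf_min = candidate_vaf_min,
            min_site_error = min_site_error,
            parental_vee = parental_vee)
  fr <- unlist(p[1:6])
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (depth_quantile <= 0 || depth_quantile >= 1)
    stop("depth_quantile must lie in (0, 1)")
  class(p) <- "filter_params"
  p
}

#' Poisson depth cutoff
#'
#' Smallest depth `d` such that `P(D > d) < quantile` for
#' `D ~ Poisson(mean_depth)`; sites deeper than `d` are removed as likely
#' mapping errors or collapsed repeats.
#'
#' @param mean_depth mean sequencing depth (> 0).
#' @param quantile upper-tail probability in (0, 1).
#' @return integer cutoff depth.
#' @export
depth_cutoff <- function(mean_depth, quantile = 1e-4) {
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (quantile <= 0 || quantile >= 1) stop("quantile must lie in (0, 1)")
  d <- qpois(1 - quantile, mean_depth)   # first guess, then settle exactly
  while (ppois(d, mean_depth, lower.tail = FALSE) >= quantile) d <- d + 1L
  while (d > 0 && ppois(d - 1L, mean_depth, lower.tail = FALSE) < quantile)
    d <- d - 1L
  as.integer(d)
}

#' Mutation-specific error rate from unrelated individuals
#'
#' Pooled alternate reads divided by pooled depth across all unrelated
#' individuals at a site — the depth-weighted mean of the per-individual
#' error rates.
#'
#' @param alt_reads,depths per-individual alternate read counts and depths
#'   at the site in unrelated individuals.
#' @return pooled error fraction; `NA_real_` (site unfilterable) when the
#'   pooled depth is zero.
#' @export
mutation_specific_error <- function(alt_reads, depths) {
  if (length(alt_reads) != length(depths))
    stop("alt_reads and depths must align")
  td <- sum(depths)
  if (td == 0) return(NA_real_)
  sum(alt_reads) / td
}

# per-site pooled counts for a subset of individuals; returns a frame
# keyed by site with pooled alt/depth
pool_by_site <- function(calls, individuals) {
  sub <- calls[calls$individual %in% individuals, , drop = FALSE]
  key <- site_key(sub)
  alt <- rowsum(sub$alt_reads, key)
  dp <- rowsum(sub$ref_reads + sub$alt_reads, key)
  data.frame(site = rownames(alt), alt = alt[, 1], depth = dp[, 1],
             stringsAsFactors = FALSE, row.names = NULL)
}

site_key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")

#' Filter offspring candidate DNMs
#'
#' Applies, in order: region masks (simple repeats / segmental
#' duplications supplied as BED intervals), reciprocal-cross VAF filters
#' (when a reciprocal pedigree is present in the table), the Poisson depth
#' cutoff, the parental support filter (`reciprocal` mode, > 5% of reads
#' in either parent) or the mutation-specific error filter (`error-rate`
#' mode, > 2% pooled in unrelated individuals), and the candidate VAF
#' floor (>= 15%). Candidates are (site, WGS offspring) pairs with any alt
#' support. The ledger records one named reason (the first failed filter)
#' per removed candidate.
#'
#' @param calls long call table ([read_calls()]).
#' @param pedigree pedigree table ([read_pedigree()]); the candidate
#'   pedigree is the one containing WGS offspring.
#' @param params a [filter_params()].
#' @param mode `"error-rate"` (default; uses unrelated individuals) or
#'   `"reciprocal"` (uses parental read support directly).
#' @param masks optional `data.frame` of masked intervals with columns
#'   `chrom`, `start`, `end` (0-based half-open, BED convention).
#' @param mean_depths named vector of mean depths per individual for the
#'   depth cutoff; estimated from the data when `NULL`.
#' @return list with `retained` (candidate rows) and `ledger`
#'   (`site`, `individual`, `reason`).
#' @export
filter_offspring_candidates <- function(calls, pedigree,
                                        params = filter_params(),
                                        mode = c("error-rate", "reciprocal"),
                                        masks = NULL, mean_depths = NULL) {
  mode <- match.arg(mode)
  validate_pedigree(pedigree)
  unknown <- setdiff(unique(calls$individual), pedigree$id)
  if (length(unknown))
    stop("calls reference individuals missing from the pedigree: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  off <- pedigree[pedigree$role == "offspring" & pedigree$tier == "wgs", ]
  if (!nrow(off)) stop("no WGS offspring in pedigree")
  ped_ids <- unique(off$pedigree)
  parents <- pedigree[pedigree$role == "parent" &
                        pedigree$pedigree %in% ped_ids, ]
  unrelated <- pedigree$id[pedigree$role == "unrelated" |
                             !(pedigree$pedigree %in% ped_ids)]
  ## candidates: per (site, WGS offspring) pooled over tissues
  cand <- calls[calls$individual %in% off$id, , drop = FALSE]
  key <- paste(site_key(cand), cand$individual)
  alt <- rowsum(cand$alt_reads, key)[, 1]
  dp <- rowsum(cand$ref_reads + cand$alt_reads, key)[, 1]
  first <- !duplicated(key)
  cand <- cand[first, c("chrom", "pos", "ref", "alt", "individual")]
  ord <- match(key[first], names(alt))
  cand$alt_reads <- alt[ord]; cand$depth <- dp[ord]
  cand <- cand[cand$alt_reads > 0, , drop = FALSE]
  cand$site <- site_key(cand)
  reason <- rep(NA_character_, nrow(cand))

  ## 1. region masks
  if (!is.null(masks) && nrow(masks)) {
    masked <- vapply(seq_len(nrow(cand)), function(i) {
      any(masks$chrom == cand$chrom[i] & masks$start < cand$pos[i] &
            cand$pos[i] <= masks$end)
    }, logical(1))
    reason[is.na(reason) & masked] <- "region_mask"
  }
  ## 2. reciprocal-cross VAF filters (pooled VAF; flagged design choice)
  recip <- pedigree[!(pedigree$pedigree %in% c(ped_ids, "UNREL")) &
                      pedigree$role != "unrelated", ]
  if (nrow(recip)) {
    r_off <- pool_by_site(calls, recip$id[recip$role == "offspring"])
    r_par <- pool_by_site(calls, recip$id[recip$role == "parent"])
    v <- r_off$alt / pmax(1, r_off$depth)
    bad <- r_off$site[v > params$reciprocal_offspring_vaf_max]
    reason[is.na(reason) & cand$site %in% bad] <- "reciprocal_offspring_vaf"
    v <- r_par$alt / pmax(1, r_par$depth)
    bad <- r_par$site[v > params$reciprocal_parent_vaf_max]
    reason[is.na(reason) & cand$site %in% bad] <- "reciprocal_parent_vaf"
  }
  ## 3. depth cutoff per candidate individual
  if (is.null(mean_depths)) {
    md <- tapply(cand$depth, cand$individual, mean)
  } else md <- mean_depths
  cut <- vapply(as.numeric(md), depth_cutoff,
                integer(1), quantile = params$depth_quantile)
  names(cut) <- names(md)
  too_deep <- cand$depth > cut[cand$individual]
  reason[is.na(reason) & too_deep] <- "depth_cutoff"
  ## 4. parental support or mutation-specific error
  if (mode == "reciprocal") {
    psub <- calls[calls$individual %in% parents$id, ]
    pkey <- paste(site_key(psub), psub$individual)
    palt <- rowsum(psub$alt_reads, pkey)[, 1]
    pdp <- rowsum(psub$ref_reads + psub$alt_reads, pkey)[, 1]
    for (side in c("mother", "father")) {
      pid <- off[[side]][match(cand$individual, off$id)]
      idx <- match(paste(cand$site, pid), names(palt))
      frac <- ifelse(is.na(idx), 0, palt[idx] / pmax(1, pdp[idx]))
      reason[is.na(reason) & frac > params$parent_alt_fraction_max] <-
        "parental_support"
    }
  } else {
    if (!length(unrelated)) stop("error-rate mode requires unrelated individuals")
    err <- pool_by_site(calls, unrelated)
    rate <- err$alt / pmax(1, err$depth)
    bad <- err$site[rate > params$mutation_specific_error_max]
    reason[is.na(reason) & cand$site %in% bad] <- "site_error"
  }
  ## 5. candidate VAF floor
  vaf <- cand$alt_reads / pmax(1, cand$depth)
  reason[is.na(reason) & vaf < params$candidate_vaf_min] <- "low_vaf"

  ledger <- data.frame(site = cand$site, individual = cand$individual,
                       reason = reason,
                       stringsAsFactors = FALSE)[!is.na(reason), ]
  list(retained = cand[is.na(reason), , drop = FALSE],
       ledger = ledger[order(ledger$site), , drop = FALSE])
}

#' Filter parental first-cleavage (VEE) mosaic candidates
#'
#' Stricter filters for sites heterozygous-like in exactly one parent:
#' region masks and strain-variant exclusion, pooled VAF < 5% in
#' unrelated individuals, a Poisson sequencing-error upper-tail
#' probability `P(X >= alt | Poisson(depth x error))` <= 0.02, a
#' constitutive binomial lower-tail probability
#' `P(X <= alt | Binomial(depth, 0.5))` <= 0.003, at most 1 alt read in
#' any other parent, at least 5 alt reads in the candidate parent and a
#' candidate VAF <= 35%.
#'
#' @param calls long call table.
#' @param pedigree pedigree table; all `role == "parent"` rows are
#'   candidate parents.
#' @param params a [filter_params()].
#' @param masks optional BED-interval `data.frame`.
#' @param strain_variants optional character vector of known strain
#'   variant site keys (`chrom:pos:ref:alt`) to exclude.
#' @return list with `retained` (one row per retained (site, parent)) and
#'   `ledger` of removal reasons.
#' @export
filter_parental_vee_candidates <- function(calls, pedigree,
                                           params = filter_params(),
                                           masks = NULL,
                                           strain_variants = character()) {
  validate_pedigree(pedigree)
  pv <- params$parental_vee
  parents <- pedigree$id[pedigree$role == "parent"]
  unrelated <- pedigree$id[pedigree$role == "unrelated"]
  psub <- calls[calls$individual %in% parents, , drop = FALSE]
  pkey <- paste(site_key(psub), psub$individual)
  alt <- rowsum(psub$alt_reads, pkey)[, 1]
  dp <- rowsum(psub$ref_reads + psub$alt_reads, pkey)[, 1]
  first <- !duplicated(pkey)
  cand <- psub[first, c("chrom", "pos", "ref", "alt", "individual")]
  ord <- match(pkey[first], names(alt))
  cand$alt_reads <- alt[ord]; cand$depth <- dp[ord]
  cand$site <- site_key(cand)
  cand <- cand[cand$alt_reads > 0, , drop = FALSE]
  reason <- rep(NA_character_, nrow(cand))

  if (length(strain_variants))
    reason[is.na(reason) & cand$site %in% strain_variants] <- "strain_variant"
  if (!is.null(masks) && nrow(masks)) {
    masked <- vapply(seq_len(nrow(cand)), function(i) {
      any(masks$chrom == cand$chrom[i] & masks$start < cand$pos[i] &
            cand$pos[i] <= masks$end)
    }, logical(1))
    reason[is.na(reason) & masked] <- "region_mask"
  }
  ## single-parent constraint and <= 1 alt read in any other parent
  other_alt <- vapply(seq_len(nrow(cand)), function(i) {
    o <- cand$alt_reads[cand$site == cand$site[i] &
                          cand$individual != cand$individual[i]]
    if (length(o)) max(o) else 0
  }, numeric(1))
  reason[is.na(reason) & other_alt > pv$alt_in_other_parents_max] <-
    "other_parent_support"
  ## unrelated VAF < 5% and error-rate tails
  if (length(unrelated)) {
    err <- pool_by_site(calls, unrelated)
    idx <- match(cand$site, err$site)
    uvaf <- ifelse(is.na(idx), 0, err$alt[idx] / pmax(1, err$depth[idx]))
    reason[is.na(reason) & uvaf >= pv$unrelated_vaf_max] <- "unrelated_vaf"
    rate <- pmax(params$min_site_error, uvaf)
    p_err <- ppois(cand$alt_reads - 1, cand$depth * rate, lower.tail = FALSE)
    reason[is.na(reason) & p_err > pv$error_poisson_p_max] <- "sequencing_error"
  }
  p_const <- pbinom(cand$alt_reads, cand$depth, 0.5)
  reason[is.na(reason) & p_const > pv$constitutive_binom_p_min] <-
    "possibly_constitutive"
  reason[is.na(reason) & cand$alt_reads < pv$min_alt_reads] <- "low_alt_reads"
  vaf <- cand$alt_reads / pmax(1, cand$depth)
  reason[is.na(reason) & vaf > pv$vaf_max] <- "high_vaf"

  ledger <- data.frame(site = cand$site, individual = cand$individual,
                       reason = reason,
                       stringsAsFactors = FALSE)[!is.na(reason), ]
  list(retained = cand[is.na(reason), , drop = FALSE], ledger = ledger)
}

#' @importFrom stats qpois
NULL
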