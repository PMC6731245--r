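#' Classifier parameters
#'
#' @param delta_threshold absolute log-likelihood difference separating
#'   mosaic (VEE) from constitutive verdicts (default 5).
#' @param detect_floor parental cell-fraction detection floor (default
#'   0.016, i.e. 1.6% of cells; cell fraction = 2 x VAF).
#' @param alpha family-wise error for parental mosaic detection, split by
#'   Bonferroni over `n_tests`.
#' @param n_tests number of binomial tests in the experiment family;
#'   `NULL` means (events x parental tissues), computed at run time.
#' @param require_all_tissues demand every parental tissue be individually
#'   significant (observed behaviour of true mosaics; configurable).
#' @param concordance_alpha two-sided exact-test level for the
#'   cross-tissue allele-ratio concordance check before pooling.
#' @param carrier_min_vaf,carrier_min_alt minimum pooled VAF and alt reads
#'   for an individual to be called a carrier.
#' @param min_site_error floor on the site error rate used in mosaic
#'   tests.
#' @return a `classifier_params` list.
#' @export
classifier_params <- function(delta_threshold = 5,
                              detect_floor = 0.016,
                              alpha = 0.05,
                              n_tests = NULL,
                              require_all_tissues = TRUE,
                              concordance_alpha = 0.01,
                              carrier_min_vaf = 0.1,
                              carrier_min_alt = 3L,
                              min_site_error = 1e-5) {
  p <- list(delta_threshold = delta_threshold, detect_floor = detect_floor,
            alpha = alpha, n_tests = n_tests,
            require_all_tissues = isTRUE(require_all_tissues),
            concordance_alpha = concordance_alpha,
            carrier_min_vaf = carrier_min_vaf,
            carrier_min_alt = as.integer(carrier_min_alt),
            min_site_error = min_site_error)
  class(p) <- "classifier_params"
  p
}

#' Log-likelihood difference between mosaic and constitutive models
#'
#' Compares Binomial(depth, 0.25) — a mutation generated in the first
#' cell division contributing to the embryo, mosaic in half the cells —
#' against Binomial(depth, 0.5) — a constitutive heterozygote — at the
#' observed alt count. The binomial coefficient cancels, leaving
#' `delta = k ln(0.25/0.5) + (n-k) ln(0.75/0.5)`. Verdict `vee` when
#' `delta > threshold`, `constitutive` when `delta < -threshold`,
#' otherwise `unassigned` (treated as late post-PGC downstream).
#'
#' @param alt,depth pooled alt reads and depth (vectorised).
#' @param threshold verdict threshold on `delta` (default 5).
#' @param p_mosaic,p_constitutive the two binomial success probabilities.
#' @return `data.frame` with `delta_loglik` and `verdict`.
#' @export
vee_loglik_difference <- function(alt, depth, threshold = 5,
                                  p_mosaic = 0.25, p_constitutive = 0.5) {
  if (any(depth == 0)) stop("depth must be > 0")
  if (any(alt > depth)) stop("alt cannot exceed depth")
  delta <- alt * log(p_mosaic / p_constitutive) +
    (depth - alt) * log((1 - p_mosaic) / (1 - p_constitutive))
  verdict <- ifelse(delta > threshold, "vee",
                    ifelse(delta < -threshold, "constitutive", "unassigned"))
  data.frame(delta_loglik = delta, verdict = verdict,
             stringsAsFactors = FALSE)
}

#' Detect parental somatic mosaicism at a site
#'
#' Per-tissue upper-tail binomial test of the alt count against the
#' site-specific error rate, Bonferroni-corrected across the experiment's
#' test family. A parent is called mosaic when the minimum per-tissue
#' p-value clears `alpha / n_tests` and (by default) every tissue with
#' coverage is individually significant. The mosaic cell fraction is twice
#' the pooled VAF.
#'
#' @param alt_reads,depths per-tissue alt counts and depths for one
#'   parent; zero-depth tissues are excluded.
#' @param site_error site-specific error rate from unrelated individuals.
#' @param n_tests size of the Bonferroni family.
#' @param alpha family-wise error target.
#' @param detect_floor reported detection floor (cell fraction).
#' @param require_all_tissues see [classifier_params()].
#' @param min_site_error floor on `site_error`.
#' @return list with `is_mosaic`, `fraction` (cell fraction), `p`
#'   (minimum per-tissue p-value) and `p_max`.
#' @export
detect_parental_mosaic <- function(alt_reads, depths, site_error, n_tests,
                                   alpha = 0.05, detect_floor = 0.016,
                                   require_all_tissues = TRUE,
                                   min_site_error = 1e-5) {
  keep <- depths > 0
  if (!any(keep)) stop("all tissues have zero depth")
  alt_reads <- alt_reads[keep]; depths <- depths[keep]
  rate <- max(site_error, min_site_error, na.rm = TRUE)
  p <- pbinom(alt_reads - 1, depths, rate, lower.tail = FALSE)
  thr <- alpha / n_tests
  sig <- if (require_all_tissues) all(p < thr) else min(p) < thr
  frac <- 2 * sum(alt_reads) / sum(depths)
  list(is_mosaic = sig, fraction = frac, p = min(p), p_max = max(p))
}

#' Power to detect parental mosaicism by exact enumeration
#'
#' Probability that [detect_parental_mosaic()] fires in a single tissue of
#' the given depth when the true cell fraction is `mosaic_level` (true VAF
#' `mosaic_level / 2`). The rejection region is enumerated exactly from
#' the binomial error model; power is the binomial upper tail of the true
#' model over that region. With several tissues and
#' `require_all_tissues`, power is the product over tissues.
#'
#' @param depth tissue depth (scalar or vector of tissues).
#' @param mosaic_level true mosaic cell fraction.
#' @param site_error site-specific error rate.
#' @param n_tests Bonferroni family size.
#' @param alpha family-wise error target.
#' @param min_site_error floor on `site_error`.
#' @return detection probability.
#' @export
detection_power <- function(depth, mosaic_level, site_error, n_tests,
                            alpha = 0.05, min_site_error = 1e-5) {
  if (all(depth == 0)) return(0)
  rate <- max(site_error, min_site_error)
  thr <- alpha / n_tests
  pow <- vapply(depth, function(d) {
    if (d == 0) return(0)
    k <- qbinom(thr, d, rate, lower.tail = FALSE) + 1L
    while (k > 0 && pbinom(k - 2, d, rate, lower.tail = FALSE) < thr)
      k <- k - 1L
    while (pbinom(k - 1, d, rate, lower.tail = FALSE) >= thr) k <- k + 1L
    pbinom(k - 1, d, mosaic_level / 2, lower.tail = FALSE)
  }, numeric(1))
  prod(pow)
}

#' Build unique mutation events from a filtered call table
#'
#' Groups calls by site across individuals, determines carrier offspring
#' (pooled VAF and alt-read thresholds), and merges sites within the MNV
#' distance carried by the same individual set into one event.
#'
#' @param calls long call table (filtered candidates plus observations in
#'   all individuals).
#' @param pedigree pedigree table.
#' @param params a [classifier_params()].
#' @param max_gap MNV chaining distance (bp).
#' @return `data.frame` of events with carrier sets.
#' @export
build_events <- function(calls, pedigree, params = classifier_params(),
                         max_gap = 5L) {
  validate_pedigree(pedigree)
  off_ids <- pedigree$id[pedigree$role == "offspring"]
  sub <- calls[calls$individual %in% off_ids, , drop = FALSE]
  key <- paste(site_key(sub), sub$individual)
  alt <- rowsum(sub$alt_reads, key)[, 1]
  dp <- rowsum(sub$ref_reads + sub$alt_reads, key)[, 1]
  carrier <- alt >= params$carrier_min_alt &
    alt / pmax(1, dp) >= params$carrier_min_vaf
  ctx_cols <- intersect(c("ctx5", "ctx3"), names(sub))
  sub <- sub[!duplicated(key),
             c("chrom", "pos", "ref", "alt", "individual", ctx_cols)]
  sub <- sub[carrier[match(paste(site_key(sub), sub$individual), names(alt))], ]
  if (!nrow(sub))
    return(data.frame(event_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      carriers = character(), n_carriers = integer(),
                      n_sites = integer(), stringsAsFactors = FALSE))
  ## unique site -> carrier set
  sk <- site_key(sub)
  carr <- vapply(split(sub$individual, sk),
                 function(x) paste(sort(unique(x)), collapse = ","),
                 character(1))
  usite <- sub[!duplicated(sk), c("chrom", "pos", "ref", "alt", ctx_cols)]
  usite$carriers <- carr[site_key(usite)]
  usite <- usite[order(usite$chrom, usite$pos), ]
  ## MNV chaining among sites with identical carrier sets
  same <- c(FALSE, usite$chrom[-1] == usite$chrom[-nrow(usite)] &
              diff(usite$pos) <= max_gap &
              usite$carriers[-1] == usite$carriers[-nrow(usite)])
  grp <- cumsum(!same)
  first <- !duplicated(grp)
  ev <- usite[first, , drop = FALSE]
  ev$n_sites <- as.integer(tabulate(grp))
  ev$event_id <- paste0(ev$chrom, ":", ev$pos)
  ev$n_carriers <- lengths(strsplit(ev$carriers, ","))
  rownames(ev) <- NULL
  ev[c("event_id", "chrom", "pos", "ref", "alt", ctx_cols, "carriers",
       "n_carriers", "n_sites")]
}

#' Assign mutation events to temporal strata of the germline
#'
#' Applies the classification precedence to every event:
#' \enumerate{
#'   \item a parent with statistically significant mosaicism at the site
#'     => early embryonic (EE), origin that parent;
#'   \item otherwise >= 2 carrier offspring with parental pooled cell
#'     fraction below the detection floor => peri-PGC;
#'   \item otherwise (single carrier) the mosaic-vs-constitutive
#'     likelihood verdict: `vee` => VEE; `constitutive` or `unassigned`
#'     => late post-PGC.
#' }
#' Haplotype occupancy < 1, when phase evidence exists, corroborates a
#' VEE verdict but never overrides the likelihood test. Allele ratios are
#' pooled across a carrier's tissues only after a two-sided exact
#' concordance check; discordant events are flagged and the deepest
#' tissue used.
#'
#' @param calls long call table covering all individuals at event sites.
#' @param pedigree pedigree table.
#' @param events event table from [build_events()]; built on the fly when
#'   `NULL`.
#' @param params a [classifier_params()].
#' @return a strata `data.frame`: one row per event with `stratum`,
#'   `delta_loglik`, `parent_fraction`, `parent_p`, `n_carriers`,
#'   `origin`, `ho`, `vaf`, `concordant`.
#' @export
classify_events <- function(calls, pedigree, events = NULL,
                            params = classifier_params()) {
  validate_pedigree(pedigree)
  if (is.null(events)) events <- build_events(calls, pedigree, params)
  if (!nrow(events)) return(cbind(events, empty_strata_cols()))
  off <- pedigree[pedigree$role == "offspring", ]
  parents <- pedigree[pedigree$role == "parent", ]
  unrel <- pedigree$id[pedigree$role == "unrelated"]
  n_tests <- params$n_tests %||% (nrow(events) * 3 * nrow(parents) / 2)

  calls$sk <- site_key(calls)
  rows_by_site <- split(seq_len(nrow(calls)), calls$sk)
  err_tab <- if (length(unrel)) pool_by_site(calls, unrel) else NULL
  n <- nrow(events)
  stratum <- character(n); delta <- rep(NA_real_, n)
  pfrac <- rep(NA_real_, n); pp <- rep(NA_real_, n)
  origin <- rep("unknown", n); ho <- rep(NA_real_, n)
  vaf <- rep(NA_real_, n); concord <- rep(TRUE, n)

  for (i in seq_len(n)) {
    sk <- paste(events$chrom[i], events$pos[i], events$ref[i],
                events$alt[i], sep = ":")
    rows <- calls[rows_by_site[[sk]], , drop = FALSE]
    carriers <- strsplit(events$carriers[i], ",")[[1]]
    site_err <- if (!is.null(err_tab)) {
      j <- match(sk, err_tab$site)
      if (is.na(j)) NA_real_ else err_tab$alt[j] / max(1, err_tab$depth[j])
    } else NA_real_

    ## (1) parental mosaicism — test father and mother of the carriers
    fam <- unique(off[off$id %in% carriers, c("mother", "father")])
    mos <- list(); mos_parent <- character(0)
    for (p in unique(c(fam$father, fam$mother))) {
      pr <- rows[rows$individual == p, , drop = FALSE]
      if (!nrow(pr) || all(pr$ref_reads + pr$alt_reads == 0)) next
      res <- detect_parental_mosaic(pr$alt_reads,
                                    pr$ref_reads + pr$alt_reads,
                                    site_err, n_tests,
                                    alpha = params$alpha,
                                    detect_floor = params$detect_floor,
                                    require_all_tissues =
                                      params$require_all_tissues,
                                    min_site_error = params$min_site_error)
      if (res$is_mosaic) { mos[[p]] <- res; mos_parent <- c(mos_parent, p) }
    }
    par_rows <- rows[rows$individual %in% c(fam$father, fam$mother), ]
    pool_frac <- if (nrow(par_rows))
      2 * sum(par_rows$alt_reads) /
      max(1, sum(par_rows$ref_reads + par_rows$alt_reads)) else NA_real_

    ## carrier pooled VAF (concordance-checked)
    cr <- rows[rows$individual %in% carriers, , drop = FALSE]
    ct <- cr[cr$individual == carriers[1], , drop = FALSE]
    if (nrow(ct) > 1) {
      ft <- fisher.test(rbind(ct$alt_reads, ct$ref_reads))
      if (ft$p.value < params$concordance_alpha) {
        concord[i] <- FALSE
        ct <- ct[which.max(ct$ref_reads + ct$alt_reads), , drop = FALSE]
      }
    }
    vaf[i] <- sum(ct$alt_reads) / max(1, sum(ct$ref_reads + ct$alt_reads))
    dtot <- sum(ct$ref_reads + ct$alt_reads)
    if (dtot > 0) {
      vl <- vee_loglik_difference(sum(ct$alt_reads), dtot,
                                  threshold = params$delta_threshold)
      delta[i] <- vl$delta_loglik
    }
    ## phase evidence
    if ("phase_total" %in% names(rows)) {
      phr <- rows[!is.na(rows$phase_total), , drop = FALSE]
      if (nrow(phr)) {
        ho[i] <- haplotype_occupancy(sum(phr$phase_total),
                                     sum(phr$phase_alt))
        og <- unique(phr$phase_origin[!is.na(phr$phase_origin)])
        if (length(og) == 1) origin[i] <- og
      }
    }

    if (length(mos_parent) == 1) {
      stratum[i] <- "EE"
      pfrac[i] <- mos[[mos_parent]]$fraction; pp[i] <- mos[[mos_parent]]$p
      origin[i] <- if (parents$sex[parents$id == mos_parent] == "male")
        "paternal" else "maternal"
    } else if (events$n_carriers[i] >= 2 &&
               (is.na(pool_frac) || pool_frac < params$detect_floor)) {
      stratum[i] <- "peri_PGC"
      pfrac[i] <- pool_frac
    } else if (events$n_carriers[i] >= 2) {
      stratum[i] <- "unassigned"   # shared but parental support ambiguous
      pfrac[i] <- pool_frac
    } else {
      verdict <- if (is.na(delta[i])) "unassigned" else
        vee_loglik_difference(sum(ct$alt_reads), dtot,
                              threshold = params$delta_threshold)$verdict
      stratum[i] <- if (verdict == "vee") "VEE" else "late_post_PGC"
      pfrac[i] <- pool_frac
    }
  }
  out <- events
  out$stratum <- stratum; out$delta_loglik <- delta
  out$parent_fraction <- pfrac; out$parent_p <- pp
  out$origin <- origin; out$ho <- ho; out$vaf <- vaf
  out$concordant <- concord
  out
}

empty_strata_cols <- function() {
  data.frame(stratum = character(), delta_loglik = numeric(),
             parent_fraction = numeric(), parent_p = numeric(),
             origin = character(), ho = numeric(), vaf = numeric(),
             concordant = logical(), stringsAsFactors = FALSE)
}

#' @importFrom stats qbinom
NULL
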