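#' Simulation configuration for a multi-sibling pedigree
#'
#' Defines the stated world of the generator: a two-parent pedigree with
#' deeply sequenced (WGS-tier) and genotyped-only offspring across timed
#' litters, and stage-specific per-haploid-base per-cell-division mutation
#' rates along the germline genealogy
#' zygote -> embryonic cleavage -> PGC specification -> PGC proliferation /
#' gametogenesis -> (paternal only) spermatogonial stem-cell divisions.
#'
#' Defaults emulate a large mouse pedigree: 10 WGS offspring plus 30
#' genotyped siblings over 7 litters spanning 33 weeks (mean parental age
#' at conception 24.5 weeks), a 2,222,635,788 bp callable autosomal
#' genome, first-cleavage rate high enough to yield ~5 mosaic VEE
#' mutations per offspring, and a spermatogonial stem-cell (SSC) division
#' schedule of 42 divisions/year from puberty at one month, giving a
#' paternal age slope of ~4.5 mutations/year. Stage rates are calibrated
#' once from these observable quantities (see the methods vignette) and
#' are not tuning knobs.
#'
#' @param seed integer seed; all generator randomness flows from it.
#' @param n_offspring_wgs,n_offspring_genotyped offspring counts by
#'   sequencing tier.
#' @param n_litters,litter_gap_weeks,first_conception_age_weeks litter
#'   timing; parental age at conception of litter `l` is
#'   `first_conception_age_weeks + (l-1) * litter_gap_weeks`.
#' @param genome_size callable autosomal bases.
#' @param rates named list of per-haploid-base per-division rates:
#'   `first_cleavage`, `embryonic`, `peri_pgc`, `post_pgc_pre_puberty`,
#'   `ssc_per_division`.
#' @param divisions named list of division counts: `pre_pgc` (first
#'   cleavage plus embryonic divisions before PGC specification),
#'   `peri_pgc`, `post_pgc_paternal`, `post_pgc_maternal` (pre-puberty).
#' @param ssc_divisions_per_year,puberty_weeks paternal post-puberty
#'   schedule.
#' @param n_pgc_founders,founder_alpha number of PGC founder lineages per
#'   parent and the symmetric Dirichlet concentration governing their
#'   unequal contribution to gametes.
#' @param depths named list of mean sequencing depths: `parent_tissue`,
#'   `offspring_wgs_tissue`, `offspring_genotyped_tissue`, `unrelated`.
#' @param error_rate per-base per-read miscall probability.
#' @param n_unrelated unrelated deep-sequenced individuals used for
#'   mutation-specific error rates.
#' @param vee_transmission numeric `c(beta0, beta1)` mapping a parental
#'   somatic VAF to the probability each offspring inherits the mutation.
#' @param simulate_parental_vee also generate first-cleavage mosaics in
#'   the parents themselves (the parental-VEE experiment).
#' @param vee_zygote_shape optional Gamma shape for a per-zygote
#'   first-cleavage rate multiplier (mean 1); `NULL` (default) disables
#'   over-dispersion of VEE counts.
#' @param phase_fraction,phase_pairs_mean fraction of events with read-pair
#'   phase evidence and the mean number of informative pairs.
#' @param spectrum named 7-vector of class probabilities used to draw
#'   ref/alt/context (strand-symmetric).
#' @param n_artifact_sites low-VAF artifact candidate sites injected into
#'   one WGS offspring each (default 0), used to exercise the filters.
#' @param pedigree_id label for the generated pedigree.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_offspring_wgs = 10L,
                       n_offspring_genotyped = 30L,
                       n_litters = 7L,
                       litter_gap_weeks = 5.5,
                       first_conception_age_weeks = 8,
                       genome_size = 2222635788,
                       rates = list(first_cleavage = 1.1e-9,
                                    embryonic = 8e-11,
                                    peri_pgc = 2e-10,
                                    post_pgc_pre_puberty = 8e-11,
                                    ssc_per_division = 4.8e-11),
                       divisions = list(pre_pgc = 10L, peri_pgc = 3L,
                                        post_pgc_paternal = 21L,
                                        post_pgc_maternal = 12L),
                       ssc_divisions_per_year = 42,
                       puberty_weeks = 52 / 12,
                       n_pgc_founders = 8L,
                       founder_alpha = 0.5,
                       depths = list(parent_tissue = 600,
                                     offspring_wgs_tissue = 400,
                                     offspring_genotyped_tissue = 200,
                                     unrelated = 400),
                       error_rate = 1e-3,
                       n_unrelated = 6L,
                       vee_transmission = c(beta0 = 0, beta1 = 1),
                       simulate_parental_vee = TRUE,
                       vee_zygote_shape = NULL,
                       phase_fraction = 0.275,
                       phase_pairs_mean = 8,
                       spectrum = c("CpG_C>T" = 0.10, "nonCpG_C>T" = 0.22,
                                    "T>C" = 0.14, "C>A" = 0.12,
                                    "C>G" = 0.07, "T>A" = 0.27,
                                    "T>G" = 0.08),
                       n_artifact_sites = 0L,
                       pedigree_id = "PED1") {
  cfg <- list(seed = as.integer(seed),
              n_offspring_wgs = as.integer(n_offspring_wgs),
              n_offspring_genotyped = as.integer(n_offspring_genotyped),
              n_litters = as.integer(n_litters),
              litter_gap_weeks = litter_gap_weeks,
              first_conception_age_weeks = first_conception_age_weeks,
              genome_size = genome_size, rates = rates,
              divisions = divisions,
              ssc_divisions_per_year = ssc_divisions_per_year,
              puberty_weeks = puberty_weeks,
              n_pgc_founders = as.integer(n_pgc_founders),
              founder_alpha = founder_alpha, depths = depths,
              error_rate = error_rate, n_unrelated = as.integer(n_unrelated),
              vee_transmission = vee_transmission,
              simulate_parental_vee = isTRUE(simulate_parental_vee),
              vee_zygote_shape = vee_zygote_shape,
              phase_fraction = phase_fraction,
              phase_pairs_mean = phase_pairs_mean,
              spectrum = spectrum / sum(spectrum),
              n_artifact_sites = as.integer(n_artifact_sites),
              pedigree_id = pedigree_id)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_offspring_wgs + cfg$n_offspring_genotyped < 1)
    stop("at least one offspring is required")
  if (any(unlist(cfg$rates) < 0)) stop("stage rates must be >= 0")
  if (any(unlist(cfg$depths) <= 0)) stop("depths must be > 0")
  if (cfg$genome_size <= 0) stop("genome_size must be > 0")
  if (cfg$error_rate < 0 || cfg$error_rate >= 1)
    stop("error_rate must be in [0, 1)")
  invisible(cfg)
}

#' Rescale a simulation to a smaller genome, preserving expected counts
#'
#' Multiplies every stage rate by `old_genome / genome_size` so expected
#' per-offspring mutation counts are unchanged while read simulation and
#' position bookkeeping shrink. Used to keep replicate studies inside a
#' desk-scale compute budget.
#'
#' @param config a [sim_config()].
#' @param genome_size new callable genome size in bases.
#' @return the rescaled config.
#' @export
scale_genome <- function(config, genome_size) {
  f <- config$genome_size / genome_size
  config$rates <- lapply(config$rates, function(r) r * f)
  config$genome_size <- genome_size
  validate_sim_config(config)
  config
}

# parental age (weeks) at conception for each litter
litter_ages <- function(cfg) {
  cfg$first_conception_age_weeks +
    (seq_len(cfg$n_litters) - 1) * cfg$litter_gap_weeks
}

ssc_divisions_at <- function(cfg, age_weeks) {
  pmax(0, (age_weeks - cfg$puberty_weeks) / 52) * cfg$ssc_divisions_per_year
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# draw ref/alt/context consistent with a 7-class spectrum, strand-symmetric
draw_mutation_identity <- function(n, spectrum) {
  cls <- sample(names(spectrum), n, replace = TRUE, prob = spectrum)
  ref <- alt <- ctx5 <- ctx3 <- character(n)
  nt <- c("A", "C", "G", "T")
  ctx5[] <- sample(nt, n, replace = TRUE)
  ctx3[] <- sample(nt, n, replace = TRUE)
  py <- substr(cls, nchar(cls) - 2, nchar(cls))   # "C>T" etc.
  py[cls == "CpG_C>T" | cls == "nonCpG_C>T"] <- "C>T"
  ref <- substr(py, 1, 1)
  alt <- substr(py, 3, 3)
  ctx3[cls == "CpG_C>T"] <- "G"
  i <- cls == "nonCpG_C>T"
  ctx3[i] <- sample(c("A", "C", "T"), sum(i), replace = TRUE)
  flip <- runif(n) < 0.5
  tmp5 <- ctx5
  ref[flip] <- COMPLEMENT[ref[flip]]
  alt[flip] <- COMPLEMENT[alt[flip]]
  ctx5[flip] <- COMPLEMENT[ctx3[flip]]
  ctx3[flip] <- COMPLEMENT[tmp5[flip]]
  data.frame(class = cls, ref = ref, alt = alt, ctx5 = ctx5, ctx3 = ctx3,
             stringsAsFactors = FALSE)
}

# unique autosomal positions with a minimum separation
draw_positions <- function(n, genome_size, autosomes = AUTOSOMES_MOUSE,
                           min_gap = 100L) {
  repeat {
    g <- sort(sample.int(max(genome_size, n * (min_gap + 1)), n))
    if (n < 2 || all(diff(g) > min_gap)) break
  }
  chrom_len <- ceiling(genome_size / length(autosomes))
  data.frame(chrom = autosomes[pmin(length(autosomes),
                                    (g - 1) %/% chrom_len + 1)],
             pos = as.integer((g - 1) %% chrom_len + 1),
             stringsAsFactors = FALSE)
}

#' Simulate a pedigree and its germline mutation truth table
#'
#' Mutations are generated stage by stage along the germline genealogy.
#' Counts per stage are Poisson with mean `rate x divisions x 2 x
#' genome_size`, scaled per transmission as the stage dictates:
#' \itemize{
#'   \item \strong{VEE} (offspring first cleavage): mosaic in 50% of the
#'     offspring's cells (expected VAF 0.25), one per carrier.
#'   \item \strong{parental VEE}: mosaic in 50% of a parent's cells,
#'     transmitted to each offspring with probability
#'     `beta0 + beta1 * 0.25`.
#'   \item \strong{EE} (parental embryonic division k = 2..pre_pgc): cell
#'     fraction `2^-k` in parental soma and germline, transmitted with
#'     probability `beta0 + beta1 * 2^-(k+1)`; carriers are constitutive.
#'   \item \strong{peri-PGC}: clonal in one of `n_pgc_founders` PGC founder
#'     lineages whose gamete contributions follow a Dirichlet draw;
#'     carried by offspring whose gamete descends from that founder, each
#'     with probability 1/2; undetectable in parental soma.
#'   \item \strong{late post-PGC}: private constitutive mutations per
#'     (WGS) offspring, Poisson with mean `genome_size x (post-PGC rate x
#'     divisions + SSC rate x SSC divisions at the paternal age)`; the
#'     paternal SSC term creates the parental age effect.
#' }
#' Singleton classes are generated only for WGS-tier offspring (they are
#' undiscoverable in genotyped-only siblings); parental-side mutations are
#' retained when carried by at least one WGS offspring, or for parental
#' VEE, always (they are discovered in the parents).
#'
#' @param config a [sim_config()].
#' @return an object of class `germ_sim`: list with `pedigree` and `truth`
#'   data frames. Truth columns include the generating `stage`, origin,
#'   carrier set, parental and offspring cell fractions and the
#'   `expected_stratum` a perfectly powered classifier would report.
#' @export
simulate_germline <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  cfg <- config
  ped <- build_sim_pedigree(cfg)
  off <- ped[ped$role == "offspring", , drop = FALSE]
  n_off <- nrow(off)
  wgs_idx <- which(off$tier == "wgs")
  G <- cfg$genome_size
  b0 <- cfg$vee_transmission[[1]]; b1 <- cfg$vee_transmission[[2]]
  mother <- ped$id[ped$role == "parent" & ped$sex == "female"]
  father <- ped$id[ped$role == "parent" & ped$sex == "male"]

  ev <- list()
  add <- function(stage, origin_id, origin_sex, carriers, parent_fraction,
                  offspring_fraction, division, founder = NA_character_) {
    data.frame(stage = stage, origin_id = origin_id, origin_sex = origin_sex,
               carriers = carriers, parent_fraction = parent_fraction,
               offspring_fraction = offspring_fraction, division = division,
               founder = founder, stringsAsFactors = FALSE)
  }

  ## offspring VEE: first cleavage of each WGS offspring
  mult <- if (is.null(cfg$vee_zygote_shape)) rep(1, length(wgs_idx)) else
    rgamma(length(wgs_idx), shape = cfg$vee_zygote_shape,
           rate = cfg$vee_zygote_shape)
  n_vee <- rpois(length(wgs_idx), 2 * G * cfg$rates$first_cleavage * mult)
  for (j in seq_along(wgs_idx)) {
    if (n_vee[j] == 0) next
    sexes <- sample(c("male", "female"), n_vee[j], replace = TRUE)
    ev[[length(ev) + 1]] <- add("VEE",
                                ifelse(sexes == "male", father, mother),
                                sexes, rep(off$id[wgs_idx[j]], n_vee[j]),
                                0, 0.5, 1L)
  }

  ## parental VEE: first cleavage of each parent
  if (cfg$simulate_parental_vee) {
    for (p in c(father, mother)) {
      np <- rpois(1, 2 * G * cfg$rates$first_cleavage)
      if (np == 0) next
      tp <- clip01(b0 + b1 * 0.25)
      cm <- matrix(rbinom(np * n_off, 1, tp), nrow = np)
      carr <- apply(cm, 1, function(z) paste(off$id[z == 1], collapse = ","))
      ev[[length(ev) + 1]] <- add("parental_VEE", p,
                                  ped$sex[ped$id == p], carr, 0.5, 1, 1L)
    }
  }

  ## EE: parental embryonic divisions 2..pre_pgc
  for (p in c(father, mother)) {
    for (k in 2:cfg$divisions$pre_pgc) {
      nk <- rpois(1, 2^k * 2 * G * cfg$rates$embryonic)
      if (nk == 0) next
      frac <- 2^-k
      tp <- clip01(b0 + b1 * frac / 2)
      cm <- matrix(rbinom(nk * n_off, 1, tp), nrow = nk)
      keep <- rowSums(cm[, wgs_idx, drop = FALSE]) > 0
      if (!any(keep)) next
      cm <- cm[keep, , drop = FALSE]
      carr <- apply(cm, 1, function(z) paste(off$id[z == 1], collapse = ","))
      ev[[length(ev) + 1]] <- add("EE", p, ped$sex[ped$id == p], carr,
                                  frac, 1, as.integer(k))
    }
  }

  ## peri-PGC: founder lineages
  founders <- list()
  for (p in c(father, mother)) {
    w <- rgamma(cfg$n_pgc_founders, shape = cfg$founder_alpha)
    w <- w / sum(w)
    assign_f <- sample.int(cfg$n_pgc_founders, n_off, replace = TRUE, prob = w)
    founders[[p]] <- list(weights = w, assignment = assign_f)
    nf <- rpois(cfg$n_pgc_founders,
                2 * G * cfg$rates$peri_pgc * cfg$divisions$peri_pgc)
    for (f in which(nf > 0)) {
      members <- which(assign_f == f)
      for (m in seq_len(nf[f])) {
        carr_idx <- members[rbinom(length(members), 1, 0.5) == 1]
        if (!any(carr_idx %in% wgs_idx)) next
        ev[[length(ev) + 1]] <- add("peri_PGC", p, ped$sex[ped$id == p],
                                    paste(off$id[carr_idx], collapse = ","),
                                    0, 1, cfg$divisions$pre_pgc + 1L,
                                    founder = paste0(p, "_f", f))
      }
    }
  }

  ## late post-PGC: private per WGS offspring, paternal + maternal side
  d_pat <- cfg$divisions$post_pgc_paternal
  d_mat <- cfg$divisions$post_pgc_maternal
  for (j in wgs_idx) {
    ssc <- ssc_divisions_at(cfg, off$parental_age_weeks[j])
    lam_p <- G * (cfg$rates$post_pgc_pre_puberty * d_pat +
                    cfg$rates$ssc_per_division * ssc)
    lam_m <- G * cfg$rates$post_pgc_pre_puberty * d_mat
    np <- rpois(1, lam_p); nm <- rpois(1, lam_m)
    if (np > 0)
      ev[[length(ev) + 1]] <- add("late_post_PGC", father, "male",
                                  rep(off$id[j], np), 0, 1, NA_integer_)
    if (nm > 0)
      ev[[length(ev) + 1]] <- add("late_post_PGC", mother, "female",
                                  rep(off$id[j], nm), 0, 1, NA_integer_)
  }

  truth <- if (length(ev)) do.call(rbind, ev) else
    add(character(0), character(0), character(0), character(0),
        numeric(0), numeric(0), integer(0), character(0))
  n_ev <- nrow(truth)
  if (n_ev) {
    idm <- draw_mutation_identity(n_ev, cfg$spectrum)
    posn <- draw_positions(n_ev, G)
    truth <- cbind(data.frame(event_id = sprintf("E%04d", seq_len(n_ev)),
                              stringsAsFactors = FALSE),
                   posn, idm[c("ref", "alt", "ctx5", "ctx3")], truth)
    truth$n_carriers <- ifelse(truth$carriers == "", 0L,
                               lengths(strsplit(truth$carriers, ",")))
    truth$expected_stratum <- expected_stratum(truth)
    ## read-pair phase evidence for a subset of events
    has_phase <- runif(n_ev) < cfg$phase_fraction
    truth$phase_total <- ifelse(has_phase,
                                1L + rpois(n_ev, cfg$phase_pairs_mean - 1), NA)
    ho <- ifelse(truth$stage == "VEE", 0.5, 1)
    truth$phase_alt <- NA_integer_
    truth$phase_alt[has_phase] <- rbinom(sum(has_phase),
                                         truth$phase_total[has_phase],
                                         ho[has_phase])
    truth$phase_origin <- ifelse(has_phase,
                                 c(male = "paternal",
                                   female = "maternal")[truth$origin_sex],
                                 NA_character_)
  } else {
    truth$event_id <- character(0)
    truth$n_carriers <- integer(0)
    truth$expected_stratum <- character(0)
  }
  out <- list(pedigree = ped, truth = truth, founders = founders,
              config = cfg)
  class(out) <- "germ_sim"
  out
}

build_sim_pedigree <- function(cfg) {
  pid <- cfg$pedigree_id
  mother <- paste0(pid, "_M")
  father <- paste0(pid, "_F")
  n <- cfg$n_offspring_wgs + cfg$n_offspring_genotyped
  litter <- rep(seq_len(cfg$n_litters), length.out = n)
  ages <- litter_ages(cfg)[litter]
  off <- data.frame(
    id = sprintf("%s_O%02d", pid, seq_len(n)),
    sex = rep(c("male", "female"), length.out = n),
    role = "offspring", pedigree = pid,
    mother = mother, father = father, litter = litter,
    parental_age_weeks = ages,
    tier = c(rep("wgs", cfg$n_offspring_wgs),
             rep("genotyped_only", cfg$n_offspring_genotyped)),
    stringsAsFactors = FALSE)
  par <- data.frame(id = c(father, mother), sex = c("male", "female"),
                    role = "parent", pedigree = pid, mother = NA, father = NA,
                    litter = NA, parental_age_weeks = NA, tier = "wgs",
                    stringsAsFactors = FALSE)
  unrel <- if (cfg$n_unrelated > 0)
    data.frame(id = sprintf("UNREL_U%02d", seq_len(cfg$n_unrelated)),
               sex = rep(c("male", "female"), length.out = cfg$n_unrelated),
               role = "unrelated", pedigree = "UNREL", mother = NA,
               father = NA, litter = NA, parental_age_weeks = NA,
               tier = "wgs", stringsAsFactors = FALSE)
  else NULL
  validate_pedigree(rbind(par, off, unrel))
}

# the stratum a perfectly powered classifier should assign, given the
# detection floor for parental mosaicism (cell fraction 0.016)
expected_stratum <- function(truth, detect_floor = 0.016) {
  out <- rep("late_post_PGC", nrow(truth))
  out[truth$stage == "VEE"] <- "VEE"
  detectable <- truth$parent_fraction > detect_floor
  out[truth$stage %in% c("EE", "parental_VEE") & detectable] <- "EE"
  hidden_shared <- !detectable & truth$n_carriers >= 2
  out[truth$stage %in% c("EE", "peri_PGC") & hidden_shared] <- "peri_PGC"
  out[truth$n_carriers == 0] <- NA_character_   # untransmitted parental VEE
  out
}

#' Simulate read counts for every (site, individual, tissue) combination
#'
#' Emulates deep targeted validation sequencing of each truth site in
#' every pedigree member and the unrelated panel: three parental tissues,
#' two tissues per WGS offspring, one per genotyped offspring and one per
#' unrelated individual. Depth is Poisson around the configured tier mean;
#' alt reads are Binomial with success probability
#' `vaf (1 - e) + (1 - vaf) e` where `vaf` is the true variant allele
#' fraction (cell fraction / 2) and `e` the per-read error rate, so
#' non-carriers accumulate error reads at rate `e`. Optionally injects
#' `n_artifact_sites` low-VAF artifact candidates. Deterministic given the
#' config seed.
#'
#' @param sim a `germ_sim` from [simulate_germline()].
#' @param config the same [sim_config()]; defaults to the one stored in
#'   `sim`.
#' @return a long call `data.frame` (see [read_calls()]) with an extra
#'   ground-truth column `true_vaf` that the pipeline never reads.
#' @export
simulate_reads <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "germ_sim"))
  set.seed(config$seed + 1L)
  ped <- sim$pedigree
  truth <- sim$truth
  samp <- sample_sheet(ped, config)
  n_ev <- nrow(truth)
  if (n_ev == 0) return(empty_calls())

  grid <- expand.grid(ev = seq_len(n_ev), sr = seq_len(nrow(samp)),
                      KEEP.OUT.ATTRS = FALSE)
  ind <- samp$individual[grid$sr]
  vaf <- numeric(nrow(grid))
  ## carriers: constitutive or mosaic in offspring
  carr_key <- unlist(lapply(seq_len(n_ev), function(i) {
    if (truth$carriers[i] == "") character(0) else
      paste(i, strsplit(truth$carriers[i], ",")[[1]])
  }))
  carr_frac <- rep(truth$offspring_fraction,
                   ifelse(truth$carriers == "", 0L, truth$n_carriers))
  m <- match(paste(grid$ev, ind), carr_key)
  vaf[!is.na(m)] <- carr_frac[m[!is.na(m)]] / 2
  ## origin parent mosaicism
  pm <- truth$parent_fraction[grid$ev] / 2
  is_origin <- ind == truth$origin_id[grid$ev]
  vaf[is_origin & pm[seq_along(vaf)] > 0] <-
    pm[is_origin & pm > 0]
  e <- config$error_rate
  p_eff <- vaf * (1 - e) + (1 - vaf) * e
  depth <- rpois(nrow(grid), samp$depth[grid$sr])
  alt <- rbinom(nrow(grid), depth, p_eff)
  calls <- data.frame(chrom = truth$chrom[grid$ev],
                      pos = truth$pos[grid$ev],
                      ref = truth$ref[grid$ev], alt = truth$alt[grid$ev],
                      individual = ind, tissue = samp$tissue[grid$sr],
                      ref_reads = depth - alt, alt_reads = alt,
                      ctx5 = truth$ctx5[grid$ev], ctx3 = truth$ctx3[grid$ev],
                      true_vaf = vaf,
                      phase_origin = NA_character_, phase_total = NA_integer_,
                      phase_alt = NA_integer_, stringsAsFactors = FALSE)
  ## attach phase evidence to the first WGS carrier's first tissue row
  phase_ev <- which(!is.na(truth$phase_total))
  wgs_ids <- ped$id[ped$tier == "wgs" & ped$role == "offspring"]
  first_tissue <- samp$tissue[match(samp$individual, samp$individual)]
  for (i in phase_ev) {
    cids <- strsplit(truth$carriers[i], ",")[[1]]
    cid <- cids[cids %in% wgs_ids][1]
    if (is.na(cid)) next
    row <- which(calls$chrom == truth$chrom[i] & calls$pos == truth$pos[i] &
                   calls$individual == cid)[1]
    calls$phase_origin[row] <- truth$phase_origin[i]
    calls$phase_total[row] <- truth$phase_total[i]
    calls$phase_alt[row] <- truth$phase_alt[i]
  }
  if (config$n_artifact_sites > 0)
    calls <- rbind(calls, artifact_calls(config, samp, wgs_ids))
  validate_calls(calls)
}

sample_sheet <- function(ped, cfg) {
  d <- cfg$depths
  rows <- list()
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    if (ped$role[i] == "parent")
      rows[[i]] <- data.frame(individual = id,
                              tissue = c("spleen", "kidney", "tail"),
                              depth = d$parent_tissue)
    else if (ped$role[i] == "unrelated")
      rows[[i]] <- data.frame(individual = id, tissue = "spleen",
                              depth = d$unrelated)
    else if (ped$tier[i] == "wgs")
      rows[[i]] <- data.frame(individual = id,
                              tissue = c("spleen", "kidney"),
                              depth = d$offspring_wgs_tissue)
    else
      rows[[i]] <- data.frame(individual = id, tissue = "tail",
                              depth = d$offspring_genotyped_tissue)
  }
  do.call(rbind, rows)
}

artifact_calls <- function(cfg, samp, wgs_ids) {
  n <- cfg$n_artifact_sites
  posn <- draw_positions(n, cfg$genome_size)
  idm <- draw_mutation_identity(n, cfg$spectrum)
  rows <- lapply(seq_len(n), function(i) {
    ind <- sample(wgs_ids, 1)
    sub <- samp[samp$individual == ind, , drop = FALSE][1, ]
    depth <- rpois(1, sub$depth)
    data.frame(chrom = posn$chrom[i], pos = posn$pos[i], ref = idm$ref[i],
               alt = idm$alt[i], individual = ind, tissue = sub$tissue,
               ref_reads = depth, alt_reads = rbinom(1, depth,
                                                     runif(1, 0.02, 0.12)),
               ctx5 = idm$ctx5[i], ctx3 = idm$ctx3[i], true_vaf = 0,
               phase_origin = NA_character_, phase_total = NA_integer_,
               phase_alt = NA_integer_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ref_reads <- out$ref_reads - out$alt_reads
  out
}

empty_calls <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), individual = character(), tissue = character(),
             ref_reads = integer(), alt_reads = integer(), ctx5 = character(),
             ctx3 = character(), true_vaf = numeric(),
             phase_origin = character(), phase_total = integer(),
             phase_alt = integer(), stringsAsFactors = FALSE)
}

#' Expected adjusted mutation rate per haploid base per generation
#'
#' Closed-form expectation of the germline-weighted (VEE-adjusted) number
#' of mutations per offspring implied by a configuration, divided by
#' `2 x genome_size`. This is the estimand the filtering/classification/
#' rate pipeline targets on simulated data; used as the ground truth in
#' parameter-recovery studies.
#'
#' @param config a [sim_config()].
#' @param age_weeks paternal ages at conception to average over; defaults
#'   to the WGS offspring ages implied by the litter schedule.
#' @return expected haploid per-generation rate (per base).
#' @export
expected_generation_rate <- function(config, age_weeks = NULL) {
  cfg <- config
  G <- cfg$genome_size
  b0 <- cfg$vee_transmission[[1]]; b1 <- cfg$vee_transmission[[2]]
  if (is.null(age_weeks)) {
    n <- cfg$n_offspring_wgs + cfg$n_offspring_genotyped
    litter <- rep(seq_len(cfg$n_litters), length.out = n)
    age_weeks <- litter_ages(cfg)[litter][seq_len(cfg$n_offspring_wgs)]
  }
  vee <- 2 * G * cfg$rates$first_cleavage * (2 * clip01(b0 + b1 * 0.25))
  pvee <- if (cfg$simulate_parental_vee)
    2 * (2 * G * cfg$rates$first_cleavage) * clip01(b0 + b1 * 0.25) else 0
  ks <- 2:cfg$divisions$pre_pgc
  ee <- 2 * sum(2^ks * 2 * G * cfg$rates$embryonic *
                  clip01(b0 + b1 * 2^-(ks + 1)))
  peri <- 2 * G * cfg$rates$peri_pgc * cfg$divisions$peri_pgc
  ssc <- mean(ssc_divisions_at(cfg, age_weeks))
  post <- G * (cfg$rates$post_pgc_pre_puberty *
                 (cfg$divisions$post_pgc_paternal +
                    cfg$divisions$post_pgc_maternal) +
                 cfg$rates$ssc_per_division * ssc)
  (vee + pvee + ee + peri + post) / (2 * G)
}

#' Simulate a known lineage-sharing truth for reconstruction validation
#'
#' Builds a two-parent genealogy over `n_offspring` offspring in which
#' each parent contributes `n_lineages` embryonic lineages; every lineage
#' is marked by `>= min_mutations` shared mutations carried by all its
#' member offspring. Lineages of the same parent are disjoint (an
#' offspring descends from exactly one embryonic lineage per parent).
#'
#' @param n_offspring number of offspring.
#' @param n_lineages lineages per parent.
#' @param min_mutations,max_mutations mutations marking each lineage.
#' @param min_size minimum offspring per lineage.
#' @param max_size maximum offspring per lineage; defaults to
#'   `floor(0.7 * n_offspring)`, the largest carrier set whose
#'   co-occurrence is still distinguishable from chance at the 0.05
#'   threshold.
#' @param seed RNG seed.
#' @return list with the binary `matrix` (mutations x offspring), mutation
#'   `origins` and the true `partition` (list of lineages with `parent`,
#'   `mutations`, `carriers`).
#' @export
simulate_sharing_truth <- function(n_offspring = 20, n_lineages = 2,
                                   min_mutations = 2, max_mutations = 5,
                                   min_size = 2,
                                   max_size = floor(0.7 * n_offspring),
                                   seed = 1) {
  set.seed(seed)
  offspring <- sprintf("O%02d", seq_len(n_offspring))
  rows <- list(); origins <- character(); truth <- list(); mid <- 0
  for (parent in c("paternal", "maternal")) {
    repeat {  # random composition with all lineage sizes in range
      cuts <- sort(sample(seq_len(n_offspring - 1), n_lineages - 1))
      sizes <- diff(c(0, cuts, n_offspring))
      if (all(sizes >= min_size) && all(sizes <= max_size)) break
    }
    perm <- sample(offspring)
    start <- cumsum(c(1, sizes))[seq_len(n_lineages)]
    for (l in seq_len(n_lineages)) {
      members <- perm[seq(start[l], length.out = sizes[l])]
      nm <- sample(min_mutations:max_mutations, 1)
      ids <- sprintf("M%03d", mid + seq_len(nm)); mid <- mid + nm
      for (id in ids) {
        rows[[id]] <- as.integer(offspring %in% members)
        origins[id] <- parent
      }
      truth[[length(truth) + 1]] <- list(parent = parent, mutations = ids,
                                         carriers = sort(members))
    }
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- offspring
  list(matrix = mat, origins = origins, partition = truth)
}

#' Write simulator outputs as TSV files
#'
#' @param sim a `germ_sim`.
#' @param calls call table from [simulate_reads()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, calls, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv(sim$pedigree, file.path(dir, "pedigree.tsv"))
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  write_tsv(calls, file.path(dir, "calls.tsv"))
  invisible(dir)
}
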