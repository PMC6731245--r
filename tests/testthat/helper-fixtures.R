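# Minimal hand-built fixtures shared across test files. Everything is
# generated in code; no binary data.

# two parents, two WGS offspring, optional genotyped sibs and unrelated panel
tiny_pedigree <- function(n_wgs = 2, n_genotyped = 0, n_unrelated = 2,
                          pedigree = "P1") {
  n <- n_wgs + n_genotyped
  off <- data.frame(
    id = sprintf("%s_O%d", pedigree, seq_len(n)),
    sex = rep(c("male", "female"), length.out = n),
    role = "offspring", pedigree = pedigree,
    mother = paste0(pedigree, "_M"), father = paste0(pedigree, "_F"),
    litter = rep(1:2, length.out = n),
    parental_age_weeks = rep(c(10, 20), length.out = n),
    tier = c(rep("wgs", n_wgs), rep("genotyped_only", n_genotyped)),
    stringsAsFactors = FALSE)
  par <- data.frame(id = paste0(pedigree, c("_F", "_M")),
                    sex = c("male", "female"), role = "parent",
                    pedigree = pedigree, mother = NA, father = NA,
                    litter = NA, parental_age_weeks = NA, tier = "wgs",
                    stringsAsFactors = FALSE)
  unrel <- if (n_unrelated > 0)
    data.frame(id = sprintf("U%d", seq_len(n_unrelated)),
               sex = rep(c("male", "female"), length.out = n_unrelated),
               role = "unrelated", pedigree = "UNREL", mother = NA,
               father = NA, litter = NA, parental_age_weeks = NA,
               tier = "wgs", stringsAsFactors = FALSE)
  validate_pedigree(rbind(par, off, unrel))
}

# one call-table row
call_row <- function(chrom, pos, individual, tissue, alt_reads, depth,
                     ref = "C", alt = "T") {
  data.frame(chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
             individual = individual, tissue = tissue,
             ref_reads = depth - alt_reads, alt_reads = alt_reads,
             stringsAsFactors = FALSE)
}

# observations for one site across a whole tiny pedigree: named alt counts
# for chosen individuals, error-free zeros elsewhere
site_calls <- function(ped, chrom, pos, alt_by_ind, depth = 600,
                       ref = "C", alt = "T") {
  rows <- lapply(seq_len(nrow(ped)), function(i) {
    id <- ped$id[i]
    tissues <- if (ped$role[i] == "parent") c("spleen", "kidney", "tail")
    else "spleen"
    a <- if (id %in% names(alt_by_ind)) alt_by_ind[[id]] else 0
    do.call(rbind, lapply(tissues, function(tt)
      call_row(chrom, pos, id, tt, a, depth, ref, alt)))
  })
  do.call(rbind, rows)
}

# a small scaled simulation reused by several files (cached per session)
cached_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- scale_genome(sim_config(seed = 11), 2e7)
      sim <- simulate_germline(cfg)
      cache <<- list(cfg = cfg, sim = sim, calls = simulate_reads(sim))
    }
    cache
  }
})
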