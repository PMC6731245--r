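#' Run the full analysis pipeline
#'
#' Orders the analysis stages — candidate filtering, event building,
#' stratum classification, rate estimation (with the germline adjustment
#' of mosaic first-cleavage mutations), spectrum profiling and lineage
#' reconstruction — on an in-memory call table and pedigree. Any stage
#' failure aborts with the stage name attached.
#'
#' @param calls long call table ([read_calls()]).
#' @param pedigree pedigree table ([read_pedigree()]).
#' @param genome_size callable autosomal bases the counts refer to.
#' @param demography a [germline_demography()].
#' @param filter_mode `"error-rate"` or `"reciprocal"`.
#' @param filter_par a [filter_params()].
#' @param class_par a [classifier_params()].
#' @param corrections a [sensitivity_corrections()].
#' @param vee_model transmission model mapping offspring VEE VAF to
#'   germline weight (`list(beta0, beta1)` or [fit_vee_transmission()]
#'   output). The default (`beta0 = 0, beta1 = 1`) states that somatic
#'   VAF equals the expected gamete fraction.
#' @param masks optional BED-interval `data.frame`.
#' @param lineage_p_threshold agglomeration threshold for lineages.
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic; only [overdispersion_test()] draws random numbers).
#' @return list with `filter` (retained + ledger), `strata`, `counts`
#'   (per WGS offspring), `rates`, `age_effect`, `overdispersion`,
#'   `stage_rates`, `spectrum`, `lineages` and a `manifest`.
#' @export
run_pipeline <- function(calls, pedigree, genome_size,
                         demography = germline_demography("mouse"),
                         filter_mode = "error-rate",
                         filter_par = filter_params(),
                         class_par = classifier_params(),
                         corrections = sensitivity_corrections(),
                         vee_model = list(beta0 = 0, beta1 = 1),
                         masks = NULL,
                         lineage_p_threshold = 0.05,
                         seed = 1L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  flt <- stage("filter", filter_offspring_candidates(
    calls, pedigree, params = filter_par, mode = filter_mode, masks = masks))
  keep_sites <- unique(flt$retained$site)
  kept_calls <- calls[site_key(calls) %in% keep_sites, , drop = FALSE]
  strata <- stage("classify",
                  classify_events(kept_calls, pedigree, params = class_par))

  off <- pedigree[pedigree$role == "offspring" & pedigree$tier == "wgs", ]
  counts <- stage("rates", per_offspring_counts(strata, off, vee_model))
  m_adj <- mean(counts$adjusted)
  m_corr <- corrected_mean_mutations(m_adj, corrections)
  rates <- rate_set(m_corr, genome_size, demography,
                    n_offspring = nrow(off),
                    total_mutations = sum(counts$raw))

  age_effect <- NULL
  if (length(unique(round(counts$age_years, 6))) >= 2)
    age_effect <- fit_age_effect(counts$non_vee, counts$age_years,
                                 counts$pedigree)
  overdisp <- NULL
  if (nrow(counts) >= 5 && any(counts$vee > 0))
    overdisp <- overdispersion_test(counts$vee, seed = seed)
  stage_tab <- NULL
  if (!is.null(age_effect)) {
    phased <- table(factor(strata$origin, c("paternal", "maternal")))
    stage_tab <- tryCatch(stage_rates(
      vee_counts = counts$vee, mutations_mean = m_corr,
      paternal_phased = phased[["paternal"]],
      maternal_phased = phased[["maternal"]],
      annual_slope = age_effect$slope, slope_se = age_effect$se,
      age_mean_years = mean(counts$age_years),
      demography = demography, genome_size = genome_size),
      error = function(e) NULL)
  }
  spectrum <- stage("spectra", mutation_spectrum(strata))
  lineages <- stage("lineages", {
    mat <- sharing_matrix(strata)
    if (nrow(mat) >= 2)
      reconstruct_lineages(mat, p_threshold = lineage_p_threshold)
    else NULL
  })
  manifest <- list(package = "germstrata",
                   version = as.character(utils::packageVersion("germstrata")),
                   seed = seed, genome_size = genome_size,
                   demography = unclass(demography),
                   filter_mode = filter_mode,
                   corrections = unclass(corrections),
                   vee_model = list(beta0 = vee_model$beta0,
                                    beta1 = vee_model$beta1),
                   n_candidates = nrow(flt$retained) + nrow(flt$ledger),
                   n_retained = nrow(flt$retained),
                   n_events = nrow(strata))
  list(filter = flt, strata = strata, counts = counts, rates = rates,
       age_effect = age_effect, overdispersion = overdisp,
       stage_rates = stage_tab, spectrum = spectrum, lineages = lineages,
       manifest = manifest)
}

# per-WGS-offspring raw, non-VEE and germline-adjusted mutation counts
per_offspring_counts <- function(strata, off, vee_model) {
  sets <- strsplit(strata$carriers, ",")
  is_vee <- strata$stratum == "VEE"
  weight <- ifelse(is_vee,
                   2 * clip01(vee_model$beta0 + vee_model$beta1 * strata$vaf),
                   1)
  raw <- nonv <- adj <- vee <- numeric(nrow(off))
  for (j in seq_len(nrow(off))) {
    inx <- vapply(sets, function(s) off$id[j] %in% s, logical(1))
    raw[j] <- sum(inx)
    vee[j] <- sum(inx & is_vee)
    nonv[j] <- sum(inx & !is_vee)
    adj[j] <- sum(weight[inx])
  }
  data.frame(individual = off$id, raw = raw, vee = vee, non_vee = nonv,
             adjusted = adj,
             age_years = off$parental_age_weeks / 52,
             pedigree = off$pedigree, stringsAsFactors = FALSE)
}

#' File-driven pipeline runner
#'
#' Reads the pedigree and call table from disk, runs [run_pipeline()] and
#' writes the strata table, rates JSON, spectrum table, lineage Newick
#' and a manifest into `out_dir`. Reruns with the same inputs produce
#' byte-identical outputs.
#'
#' @param calls_path,pedigree_path input TSVs.
#' @param out_dir output directory.
#' @param genome_size,demography,... forwarded to [run_pipeline()].
#' @return the [run_pipeline()] result, invisibly.
#' @export
run_pipeline_files <- function(calls_path, pedigree_path, out_dir,
                               genome_size,
                               demography = germline_demography("mouse"),
                               ...) {
  calls <- read_calls(calls_path)
  ped <- read_pedigree(pedigree_path)
  res <- run_pipeline(calls, ped, genome_size, demography = demography, ...)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_tsv(res$strata, file.path(out_dir, "strata.tsv"))
  write_tsv(res$spectrum, file.path(out_dir, "spectrum.tsv"))
  jsonlite::write_json(list(
    mu_generation = res$rates$mu_generation,
    ci_generation = res$rates$ci_generation,
    mu_year = res$rates$mu_year,
    mu_cell_division = res$rates$mu_cell_division,
    mean_mutations = res$rates$mean_mutations),
    file.path(out_dir, "rates.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(res$lineages))
    write_lineage_newick(res$lineages, file.path(out_dir, "lineages.nwk"))
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `filter`, `classify`, `rates`, `spectra`,
#' `lineages`, `run`. Arguments are `--key value` pairs; see the README.
#' Installed as the `germstrata` executable script.
#'
#' @param argv character vector of command-line arguments.
#' @return exit status (0 on success).
#' @export
germstrata_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    message("usage: germstrata <simulate|filter|classify|rates|spectra|",
            "lineages|run> [--key value ...]")
    return(1L)
  }
  cmd <- argv[1]
  opts <- parse_cli_args(argv[-1])
  seed <- as.integer(opts$seed %||% 1)
  out <- opts$out %||% "."
  tryCatch({
    switch(cmd,
      simulate = {
        cfg <- sim_config(seed = seed)
        if (!is.null(opts$genome)) cfg <- scale_genome(cfg, as.numeric(opts$genome))
        sim <- simulate_germline(cfg)
        write_sim(sim, simulate_reads(sim), out)
      },
      run = ,
      classify = ,
      rates = ,
      spectra = ,
      lineages = {
        run_pipeline_files(opts$calls, opts$pedigree, out,
                           genome_size = as.numeric(opts$genome %||%
                                                      2222635788),
                           demography =
                             germline_demography(opts$demography %||% "mouse"),
                           seed = seed)
      },
      filter = {
        calls <- read_calls(opts$calls)
        ped <- read_pedigree(opts$pedigree)
        flt <- filter_offspring_candidates(calls, ped,
                                           mode = opts$mode %||% "error-rate")
        if (!dir.exists(out)) dir.create(out, recursive = TRUE)
        write_tsv(flt$retained, file.path(out, "retained.tsv"))
        write_tsv(flt$ledger, file.path(out, "ledger.tsv"))
      },
      stop("unknown subcommand: ", cmd))
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
}

parse_cli_args <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (startsWith(args[i], "--") && i < length(args)) {
      opts[[substring(args[i], 3)]] <- args[i + 1L]
      i <- i + 2L
    } else i <- i + 1L
  }
  opts
}
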