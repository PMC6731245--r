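#' Read and validate a pedigree table
#'
#' The canonical pedigree is a long TSV with one row per individual and
#' columns \code{id}, \code{sex} (\code{male}/\code{female}), \code{role}
#' (\code{parent}/\code{offspring}/\code{unrelated}), \code{pedigree},
#' \code{mother}, \code{father}, \code{litter},
#' \code{parental_age_weeks} (mean parental age at conception, offspring
#' only) and \code{tier} (\code{wgs}/\code{genotyped_only}). Individuals
#' with role \code{unrelated} carry read counts used only for
#' mutation-specific error rates.
#'
#' @param path path to a tab-separated pedigree file.
#' @return a validated pedigree \code{data.frame}.
#' @export
read_pedigree <- function(path) {
  ped <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  num <- intersect(c("litter", "parental_age_weeks"), names(ped))
  for (cc in num) ped[[cc]] <- suppressWarnings(as.numeric(ped[[cc]]))
  validate_pedigree(ped)
}

#' Validate a pedigree data frame
#'
#' Checks the structural invariants: every offspring references exactly one
#' mother and one father present in the same pedigree, sexes of the
#' referenced parents are consistent, litter indices are positive and
#' parental ages at conception are positive.
#'
#' @param ped pedigree `data.frame` (see [read_pedigree()]).
#' @return the pedigree, invisibly unchanged, or an error.
#' @export
validate_pedigree <- function(ped) {
  required <- c("id", "sex", "role", "pedigree")
  miss <- setdiff(required, names(ped))
  if (length(miss)) stop("pedigree missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ped$id)) stop("duplicate individual ids in pedigree")
  if (!all(ped$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (!all(ped$role %in% c("parent", "offspring", "unrelated")))
    stop("role must be parent, offspring or unrelated")
  off <- ped[ped$role == "offspring", , drop = FALSE]
  if (nrow(off)) {
    for (cc in c("mother", "father"))
      if (!cc %in% names(ped)) stop("offspring present but no ", cc, " column")
    idx_m <- match(off$mother, ped$id)
    idx_f <- match(off$father, ped$id)
    if (anyNA(idx_m) || anyNA(idx_f))
      stop("offspring reference parents absent from the pedigree")
    if (any(ped$pedigree[idx_m] != off$pedigree) ||
        any(ped$pedigree[idx_f] != off$pedigree))
      stop("offspring and parents must share a pedigree id")
    if (any(ped$sex[idx_m] != "female") || any(ped$sex[idx_f] != "male"))
      stop("mother must be female and father male")
    if ("parental_age_weeks" %in% names(ped) &&
        any(!is.na(off$parental_age_weeks) & off$parental_age_weeks <= 0))
      stop("parental_age_weeks must be > 0 for offspring")
    if ("litter" %in% names(ped) &&
        any(!is.na(off$litter) & off$litter < 0))
      stop("litter index must be non-negative")
  }
  ped
}

#' Read a long-format candidate call table
#'
#' One row per (site, individual, tissue) with columns \code{chrom},
#' \code{pos}, \code{ref}, \code{alt}, \code{individual}, \code{tissue},
#' \code{ref_reads}, \code{alt_reads}. Optional phase columns
#' (\code{phase_origin}, \code{phase_total}, \code{phase_alt}) and context
#' columns (\code{ctx5}, \code{ctx3}) are preserved when present. Indels
#' and sex-chromosome sites are rejected on ingest: X-linked candidates
#' show strain/sex-specific inflation in reciprocal-cross designs and
#' indels are outside the model.
#'
#' @param path path to a tab-separated call table.
#' @param autosomes character vector of accepted chromosome names.
#' @return a validated call `data.frame`.
#' @export
read_calls <- function(path, autosomes = AUTOSOMES_MOUSE) {
  calls <- read.delim(path, stringsAsFactors = FALSE,
                      colClasses = c(chrom = "character", ref = "character",
                                     alt = "character"))
  validate_calls(calls, autosomes = autosomes)
}

#' Validate a call table
#'
#' @param calls call `data.frame` (see [read_calls()]).
#' @param autosomes accepted chromosome names; everything else is rejected.
#' @return the call table with an error raised on any violated invariant.
#' @export
validate_calls <- function(calls, autosomes = AUTOSOMES_MOUSE) {
  required <- c("chrom", "pos", "ref", "alt", "individual", "tissue",
                "ref_reads", "alt_reads")
  miss <- setdiff(required, names(calls))
  if (length(miss)) stop("call table missing columns: ", paste(miss, collapse = ", "))
  calls$chrom <- as.character(calls$chrom)
  bad_chr <- !calls$chrom %in% autosomes
  if (any(bad_chr))
    stop("non-autosomal sites rejected on ingest: ",
         paste(unique(calls$chrom[bad_chr]), collapse = ", "))
  nt <- c("A", "C", "G", "T")
  if (!all(calls$ref %in% nt) || !all(calls$alt %in% nt))
    stop("only biallelic SNVs are supported (indels are removed from all analyses)")
  if (any(calls$ref == calls$alt)) stop("ref and alt alleles must differ")
  if (any(calls$ref_reads < 0) || any(calls$alt_reads < 0))
    stop("read counts must be non-negative")
  if (any(calls$pos < 1)) stop("positions are 1-based")
  calls
}

#' Write a data frame as TSV
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge clustered substitutions into multinucleotide events
#'
#' Sites within `max_gap` base pairs of any member of a growing cluster on
#' the same chromosome are chained into a single multinucleotide variant
#' (MNV) and counted as one mutational event. Chaining is transitive:
#' positions 100, 104, 108 form one event at `max_gap = 5` even though the
#' outer pair is 8 bp apart. Distances are `|pos_a - pos_b|` on 1-based
#' coordinates.
#'
#' @param calls per-site rows for a single individual with at least
#'   `chrom` and `pos` columns (one row per site).
#' @param max_gap maximum inter-site distance, in bp, for two sites to be
#'   chained (default 5).
#' @return a `data.frame` with one row per event: `event_id`, `chrom`,
#'   `start`, `end`, `n_sites` and the comma-separated `member_pos`.
#' @export
merge_mnv <- function(calls, max_gap = 5L) {
  if (!nrow(calls)) {
    return(data.frame(event_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_sites = integer(), member_pos = character(),
                      stringsAsFactors = FALSE))
  }
  if ("individual" %in% names(calls) && length(unique(calls$individual)) > 1)
    stop("merge_mnv expects calls from a single individual")
  calls <- validate_calls_light(calls)
  ord <- order(calls$chrom, calls$pos)
  chrom <- calls$chrom[ord]
  pos <- calls$pos[ord]
  new_cluster <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                     diff(pos) > max_gap)
  cl <- cumsum(new_cluster)
  out <- data.frame(
    event_id = paste0(chrom[new_cluster], ":", pos[new_cluster]),
    chrom = chrom[new_cluster],
    start = as.integer(tapply(pos, cl, min)),
    end = as.integer(tapply(pos, cl, max)),
    n_sites = as.integer(tabulate(cl)),
    member_pos = as.character(tapply(pos, cl, paste, collapse = ",")),
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

# minimal checks for site-level frames that lack read-count columns
validate_calls_light <- function(calls, autosomes = AUTOSOMES_MOUSE) {
  calls$chrom <- as.character(calls$chrom)
  if (!all(calls$chrom %in% autosomes))
    stop("non-autosomal sites rejected")
  calls
}

#' Haplotype occupancy from read-pair phase evidence
#'
#' The proportion of read pairs spanning both the mutation and a nearby
#' informative heterozygous site, drawn from the haplotype on which the
#' mutation arose, that carry the derived allele. Constitutive mutations
#' have occupancy 1; post-zygotic (mosaic) mutations occupy only part of
#' their ancestral haplotype, so occupancy < 1 and correlates with the
#' mosaic cell fraction.
#'
#' @param informative_pairs_total read pairs spanning mutation and
#'   informative site on the ancestral haplotype.
#' @param informative_pairs_with_alt those carrying the derived allele.
#' @return occupancy in \[0, 1\], or `NA_real_` when no informative pairs
#'   exist (never 0).
#' @export
haplotype_occupancy <- function(informative_pairs_total,
                                informative_pairs_with_alt) {
  if (any(informative_pairs_with_alt > informative_pairs_total, na.rm = TRUE))
    stop("informative_pairs_with_alt cannot exceed informative_pairs_total")
  out <- ifelse(!is.na(informative_pairs_total) & informative_pairs_total > 0,
                informative_pairs_with_alt / informative_pairs_total,
                NA_real_)
  out
}
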