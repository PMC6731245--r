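#' Ingest candidate sites from a VCF
#'
#' Optional VCF ingest restricted to biallelic SNVs: indel and
#' multi-allelic records are skipped with a logged count. Samples map to
#' individuals by name; allele depths are taken from the `AD` genotype
#' field, producing one long-format row per (site, sample).
#'
#' Requires the Bioconductor package \pkg{VariantAnnotation}.
#'
#' @param path VCF file (plain or bgzipped).
#' @param tissue tissue label to assign to all rows (VCF genotype fields
#'   carry no tissue structure, which is why TSV is the canonical
#'   interchange format here).
#' @param autosomes accepted chromosome names.
#' @return a call `data.frame` as from [read_calls()].
#' @export
read_vcf_calls <- function(path, tissue = "unknown",
                           autosomes = AUTOSOMES_MOUSE) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf_calls requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  biallelic <- lengths(altl) == 1
  alt <- rep(NA_character_, length(ref))
  alt[biallelic] <- vapply(as.list(altl[biallelic]),
                           function(a) as.character(a[[1]]), character(1))
  snv <- biallelic & nchar(ref) == 1 & !is.na(alt) & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  skipped <- sum(!snv)
  if (skipped) message(skipped, " non-SNV record(s) skipped")
  if (!any(snv)) return(empty_calls()[0, 1:8])
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop("VCF lacks the AD genotype field")
  chrom <- as.character(GenomicRanges::seqnames(rr))[snv]
  pos <- GenomicRanges::start(rr)[snv]
  samples <- colnames(vcf)
  rows <- list()
  for (s in samples) {
    counts <- ad[snv, s]
    rc <- vapply(counts, function(x) as.integer(x[1]), integer(1))
    ac <- vapply(counts, function(x) as.integer(x[2]), integer(1))
    rows[[s]] <- data.frame(chrom = chrom, pos = pos, ref = ref[snv],
                            alt = alt[snv], individual = s, tissue = tissue,
                            ref_reads = rc, alt_reads = ac,
                            stringsAsFactors = FALSE)
  }
  validate_calls(do.call(rbind, rows), autosomes = autosomes)
}

#' Trinucleotide context from a reference FASTA
#'
#' 1-based lookup of the bases flanking each site. Positions at a
#' chromosome end (or on an unknown chromosome) return `"N"` for the
#' missing flank rather than an error.
#'
#' Requires the Bioconductor package \pkg{Biostrings}.
#'
#' @param fasta path to an (uncompressed or gzipped) FASTA file.
#' @param chrom,pos site coordinates (vectorised).
#' @return `data.frame` with `ctx5` and `ctx3`.
#' @export
fasta_context <- function(fasta, chrom, pos) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("fasta_context requires the Biostrings package")
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  n <- length(chrom)
  ctx5 <- ctx3 <- rep("N", n)
  for (i in seq_len(n)) {
    j <- match(chrom[i], names(seqs))
    if (is.na(j)) next
    len <- Biostrings::width(seqs[j])
    if (pos[i] > 1 && pos[i] <= len)
      ctx5[i] <- as.character(Biostrings::subseq(seqs[[j]], pos[i] - 1,
                                                 pos[i] - 1))
    if (pos[i] >= 1 && pos[i] < len)
      ctx3[i] <- as.character(Biostrings::subseq(seqs[[j]], pos[i] + 1,
                                                 pos[i] + 1))
  }
  data.frame(ctx5 = ctx5, ctx3 = ctx3, stringsAsFactors = FALSE)
}
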