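#' Seven-category mutation classes
#'
#' Strand-collapsed classes of the six distinguishable point mutations,
#' with the C:G>T:A transition split by CpG context of the mutated
#' cytosine on either strand.
#'
#' @export
SPECTRUM_CLASSES <- c("C:G>T:A at CpG", "C:G>T:A at non-CpG", "T:A>C:G",
                      "C:G>A:T", "C:G>G:C", "T:A>A:T", "T:A>G:C")

#' Classify mutations into the seven spectrum categories
#'
#' Each ref>alt pair is collapsed to its pyrimidine-strand representation
#' (a G>A on the forward strand is a C>T on the reverse). For the class
#' chosen by `cpg_split_class` (the transition C:G>T:A by default), a
#' mutation is "at CpG" when the mutated C is followed by G on its own
#' strand — for a forward-strand G>A this means a 5' C. Unknown context
#' for a split-class mutation counts as non-CpG and is flagged via the
#' `unknown_context` attribute.
#'
#' @param ref,alt reference and alternate bases.
#' @param ctx5,ctx3 flanking bases (`NA`/`"N"` = unknown).
#' @param cpg_split_class which collapsed class receives the CpG split;
#'   `"C>T"` (the CpG-hypermutability convention) or `"C>A"`.
#' @return factor over [SPECTRUM_CLASSES].
#' @export
mutation_class <- function(ref, alt, ctx5 = NA, ctx3 = NA,
                           cpg_split_class = c("C>T", "C>A")) {
  cpg_split_class <- match.arg(cpg_split_class)
  n <- length(ref)
  ctx5 <- rep_len(as.character(ctx5), n)
  ctx3 <- rep_len(as.character(ctx3), n)
  flip <- ref %in% c("G", "A")
  r <- ifelse(flip, COMPLEMENT[ref], ref)
  a <- ifelse(flip, COMPLEMENT[alt], alt)
  c3 <- ifelse(flip, COMPLEMENT[ctx5], ctx3)   # 3' on the collapsed strand
  pyr <- paste0(r, ">", a)
  base_class <- c("C>T" = "C:G>T:A", "T>C" = "T:A>C:G", "C>A" = "C:G>A:T",
                  "C>G" = "C:G>G:C", "T>A" = "T:A>A:T", "T>G" = "T:A>G:C")
  cls <- base_class[pyr]
  split_full <- base_class[cpg_split_class]
  is_split <- !is.na(cls) & cls == split_full
  known <- !is.na(c3) & c3 %in% c("A", "C", "G", "T")
  at_cpg <- is_split & known & c3 == "G"
  lab <- cls
  lab[is_split] <- paste(split_full, "at non-CpG")
  lab[at_cpg] <- paste(split_full, "at CpG")
  levels <- SPECTRUM_CLASSES
  if (cpg_split_class != "C>T")
    levels <- unique(c(paste(split_full, c("at CpG", "at non-CpG")),
                       setdiff(c("C:G>T:A", base_class), split_full)))
  out <- factor(lab, levels = levels)
  attr(out, "unknown_context") <- sum(is_split & !known)
  out
}

#' Mutation-spectrum profile
#'
#' Counts, proportions and exact binomial 95% confidence intervals over
#' the seven spectrum categories.
#'
#' @param events `data.frame` with `ref`, `alt` and optional `ctx5`,
#'   `ctx3` columns.
#' @param cpg_split_class see [mutation_class()].
#' @return a `spectrum_profile` data frame (`class`, `count`,
#'   `proportion`, `ci_lo`, `ci_hi`).
#' @export
mutation_spectrum <- function(events, cpg_split_class = "C>T") {
  cls <- mutation_class(events$ref, events$alt,
                        events$ctx5 %||% NA, events$ctx3 %||% NA,
                        cpg_split_class = cpg_split_class)
  counts <- table(cls)
  total <- sum(counts)
  ci <- t(vapply(as.integer(counts), function(k) {
    if (total == 0) return(c(NA_real_, NA_real_))
    as.numeric(binom.test(k, total)$conf.int)
  }, numeric(2)))
  out <- data.frame(class = names(counts), count = as.integer(counts),
                    proportion = if (total > 0) as.numeric(counts) / total
                    else NA_real_,
                    ci_lo = ci[, 1], ci_hi = ci[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "unknown_context") <- attr(cls, "unknown_context")
  class(out) <- c("spectrum_profile", "data.frame")
  out
}

#' Compare two mutation spectra
#'
#' Chi-squared test on the 2 x 7 contingency table of category counts
#' with the degrees of freedom fixed at 6 (six distinguishable mutation
#' classes), plus per-category two-proportion z tests
#' Bonferroni-corrected over the seven categories. Categories with zero
#' total count are pooled out of the statistic with a warning.
#'
#' @param a,b `spectrum_profile`s (or data frames with `class`/`count`).
#' @param df degrees of freedom for the chi-squared reference (default 6).
#' @return list with `chi2`, `df`, `p` and `per_class` post-hoc results.
#' @export
compare_spectra <- function(a, b, df = 6) {
  if (!all(a$class == b$class)) stop("profiles must share categories")
  if (sum(a$count) == 0 || sum(b$count) == 0)
    stop("both profiles need at least one mutation")
  tab <- rbind(a$count, b$count)
  zero <- colSums(tab) == 0
  if (any(zero)) {
    warning(sum(zero), " empty categories pooled out of the statistic")
    tab <- tab[, !zero, drop = FALSE]
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - E)^2 / E)
  p <- pchisq(chi2, df = df, lower.tail = FALSE)
  ## per-category two-proportion z tests
  n1 <- sum(a$count); n2 <- sum(b$count)
  p1 <- a$count / n1; p2 <- b$count / n2
  pool <- (a$count + b$count) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (p1 - p2) / se, 0)
  per <- data.frame(class = a$class, z = z, p_raw = 2 * pnorm(-abs(z)),
                    stringsAsFactors = FALSE)
  per$p_adj <- bonferroni(per$p_raw, nrow(per))
  list(chi2 = chi2, df = df, p = p, per_class = per)
}
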