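#' Binomial co-occurrence p-value for two shared mutations
#'
#' Under the null that two mutations arose in different parental
#' progenitor cells (or different parents) they co-occur in offspring at
#' random: with carrier frequencies `p = |A|/n` and `q = |B|/n` the
#' overlap is compared to `Binomial(n, p q)` and the upper tail
#' `P(X >= |A intersect B|)` is returned — the probability of
#' co-occurrence at least this extreme under independence.
#'
#' @param n_offspring total offspring `n` (> 0).
#' @param carriers_a,carriers_b carrier sets (vectors of offspring ids or
#'   indices), non-empty subsets of the offspring.
#' @return upper-tail probability.
#' @export
cooccurrence_pvalue <- function(n_offspring, carriers_a, carriers_b) {
  if (n_offspring <= 0) stop("n_offspring must be > 0")
  carriers_a <- unique(carriers_a); carriers_b <- unique(carriers_b)
  if (!length(carriers_a) || !length(carriers_b))
    stop("carrier sets must be non-empty")
  if (length(carriers_a) > n_offspring || length(carriers_b) > n_offspring)
    stop("carrier sets exceed the offspring count")
  p <- length(carriers_a) / n_offspring
  q <- length(carriers_b) / n_offspring
  k <- length(intersect(carriers_a, carriers_b))
  pbinom(k - 1, n_offspring, p * q, lower.tail = FALSE)
}

#' Sharing matrix of shared mutations across offspring
#'
#' @param strata strata table (from [classify_events()]) or any frame
#'   with `event_id`, `carriers` (comma-separated) and optionally
#'   `origin`; rows with fewer than 2 carriers are dropped.
#' @param offspring_ids column order; inferred from the carrier sets when
#'   `NULL`.
#' @return binary matrix (mutations x offspring) with an `origins`
#'   attribute.
#' @export
sharing_matrix <- function(strata, offspring_ids = NULL) {
  sets <- strsplit(strata$carriers, ",")
  keep <- lengths(sets) >= 2
  strata <- strata[keep, , drop = FALSE]; sets <- sets[keep]
  if (is.null(offspring_ids)) offspring_ids <- sort(unique(unlist(sets)))
  m <- t(vapply(sets, function(s) as.integer(offspring_ids %in% s),
                integer(length(offspring_ids))))
  if (!nrow(strata)) m <- matrix(integer(), 0, length(offspring_ids))
  rownames(m) <- strata$event_id
  colnames(m) <- offspring_ids
  origins <- strata$origin %||% rep("unknown", nrow(strata))
  origins[is.na(origins)] <- "unknown"
  names(origins) <- strata$event_id
  attr(m, "origins") <- origins
  m
}

#' Reconstruct parental embryonic lineages from shared mutations
#'
#' Iterative agglomeration: at each step compute co-occurrence p-values
#' between all current (pseudo-)mutations; merge the most significant
#' pair whose known parental origins do not conflict (conflicting pairs
#' are skipped in favour of the next-best); the merged pseudo-mutation
#' carries the union of carriers; stop when no admissible pair has
#' `p < p_threshold`. Ties are broken by the lexicographically smallest
#' mutation-id pair, making the procedure deterministic. By default
#' carrier frequencies are recomputed from current pseudo-mutation
#' carrier sets after each merge (`update_freq = TRUE`); the fixed mode
#' performs single-linkage agglomeration on the initial pairwise
#' p-values.
#'
#' @param mat sharing matrix from [sharing_matrix()].
#' @param origins optional named origin vector; defaults to the matrix
#'   attribute.
#' @param p_threshold merge threshold (default 0.05).
#' @param update_freq recompute frequencies during merging (default).
#' @return a `lineage_partition`: list of lineages (`mutations`,
#'   `carriers`, `parent`), plus per-parent residual offspring carrying no
#'   lineage mutation.
#' @export
reconstruct_lineages <- function(mat, origins = attr(mat, "origins"),
                                 p_threshold = 0.05, update_freq = TRUE) {
  n_off <- ncol(mat)
  if (is.null(origins)) origins <- setNames(rep("unknown", nrow(mat)),
                                            rownames(mat))
  clusters <- lapply(rownames(mat), function(id)
    list(mutations = id, carriers = colnames(mat)[mat[id, ] == 1],
         parent = unname(origins[id])))
  init_p <- NULL
  if (!update_freq && length(clusters) > 1) {
    ids <- rownames(mat)
    init_p <- matrix(NA_real_, length(ids), length(ids),
                     dimnames = list(ids, ids))
    for (i in seq_along(ids)) for (j in seq_along(ids)) if (i < j)
      init_p[i, j] <- cooccurrence_pvalue(n_off,
                                          colnames(mat)[mat[i, ] == 1],
                                          colnames(mat)[mat[j, ] == 1])
  }
  repeat {
    k <- length(clusters)
    if (k < 2) break
    best <- NULL
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      oi <- clusters[[i]]$parent; oj <- clusters[[j]]$parent
      if (oi != "unknown" && oj != "unknown" && oi != oj) next
      pv <- if (update_freq) {
        cooccurrence_pvalue(n_off, clusters[[i]]$carriers,
                            clusters[[j]]$carriers)
      } else {
        min(init_p[clusters[[i]]$mutations, clusters[[j]]$mutations,
                   drop = FALSE],
            t(init_p)[clusters[[i]]$mutations, clusters[[j]]$mutations,
                      drop = FALSE], na.rm = TRUE)
      }
      key <- paste(sort(c(min(clusters[[i]]$mutations),
                          min(clusters[[j]]$mutations))), collapse = "|")
      if (is.null(best) || pv < best$p ||
          (pv == best$p && key < best$key))
        best <- list(i = i, j = j, p = pv, key = key)
    }
    if (is.null(best) || best$p >= p_threshold) break
    ci <- clusters[[best$i]]; cj <- clusters[[best$j]]
    merged <- list(mutations = sort(c(ci$mutations, cj$mutations)),
                   carriers = sort(union(ci$carriers, cj$carriers)),
                   parent = if (ci$parent != "unknown") ci$parent else
                     cj$parent)
    clusters[[best$j]] <- NULL
    clusters[[best$i]] <- merged
  }
  in_lineage <- function(parent)
    unique(unlist(lapply(clusters,
                         function(cl) if (cl$parent == parent) cl$carriers)))
  residual <- list(paternal = setdiff(colnames(mat), in_lineage("paternal")),
                   maternal = setdiff(colnames(mat), in_lineage("maternal")))
  out <- list(lineages = clusters, offspring_ids = colnames(mat),
              residual = residual, p_threshold = p_threshold)
  class(out) <- "lineage_partition"
  out
}

#' @export
print.lineage_partition <- function(x, ...) {
  cat(sprintf("Lineage partition: %d lineages over %d offspring\n",
              length(x$lineages), length(x$offspring_ids)))
  for (cl in x$lineages)
    cat(sprintf("  [%s] %d mutations, %d offspring: %s\n", cl$parent,
                length(cl$mutations), length(cl$carriers),
                paste(cl$carriers, collapse = ",")))
  invisible(x)
}

#' Biological concordance of a lineage partition
#'
#' A partition is concordant when no offspring belongs to more than one
#' paternal lineage nor to more than one maternal lineage (each offspring
#' descends from exactly one embryonic lineage per parent).
#' Unknown-origin lineages cannot be checked and are ignored.
#'
#' @param partition a `lineage_partition`, or a list of lineages.
#' @return `TRUE`/`FALSE`.
#' @export
check_concordance <- function(partition) {
  lineages <- if (inherits(partition, "lineage_partition"))
    partition$lineages else partition
  for (parent in c("paternal", "maternal")) {
    seen <- character(0)
    for (cl in lineages) {
      if (cl$parent != parent) next
      if (any(cl$carriers %in% seen)) return(FALSE)
      seen <- c(seen, cl$carriers)
    }
  }
  TRUE
}

#' Random-reassignment validation of a lineage partition
#'
#' Scores how special the reconstructed structure is: random
#' re-assignments of the shared mutations should essentially never be
#' biologically concordant.
#' \describe{
#'   \item{`shuffle_lineage_labels`}{permute the mutation-to-lineage
#'     assignment, keeping the lineage sizes and parent labels; each
#'     replicate's lineage carrier sets are unions of the reassigned
#'     mutations' original carrier sets.}
#'   \item{`random_cluster_sizes`}{draw a fresh random clustering with
#'     cluster sizes between 2 and 10 mutations; each cluster takes the
#'     parent label of its first member's known origin.}
#' }
#'
#' @param partition a `lineage_partition` with >= 2 lineages.
#' @param mat the sharing matrix the partition was built from.
#' @param mode reassignment mode.
#' @param n_reps replicates (default 10000).
#' @param seed RNG seed.
#' @param origins named per-mutation origin vector; defaults to the
#'   matrix attribute, then to each mutation's reconstructed lineage
#'   label.
#' @return number of concordant replicates.
#' @export
reassignment_validation <- function(partition, mat,
                                    mode = c("shuffle_lineage_labels",
                                             "random_cluster_sizes"),
                                    n_reps = 10000, seed = 1,
                                    origins = attr(mat, "origins")) {
  mode <- match.arg(mode)
  if (length(partition$lineages) < 2) stop("need at least 2 lineages")
  set.seed(seed)
  muts <- rownames(mat)
  if (is.null(origins)) {
    origins <- setNames(rep("unknown", length(muts)), muts)
    for (cl in partition$lineages) origins[cl$mutations] <- cl$parent
  }
  sizes <- lengths(lapply(partition$lineages, `[[`, "mutations"))
  labels <- vapply(partition$lineages, `[[`, character(1), "parent")
  concordant <- 0L
  for (r in seq_len(n_reps)) {
    if (mode == "shuffle_lineage_labels") {
      assign_to <- sample(rep(seq_along(sizes), sizes))
      lab <- labels
    } else {
      perm <- sample(muts)
      assign_to <- integer(length(muts)); cl <- 0L; i <- 1L
      while (i <= length(muts)) {
        cl <- cl + 1L
        sz <- min(sample(2:10, 1), length(muts) - i + 1L)
        assign_to[match(perm[i:(i + sz - 1L)], muts)] <- cl
        i <- i + sz
      }
      lab <- vapply(seq_len(cl), function(g) {
        og <- origins[muts[assign_to == g]]
        og <- og[og != "unknown"]
        if (length(og)) og[[1]] else "unknown"
      }, character(1))
    }
    inc <- rowsum(mat, assign_to) > 0   # lineage x offspring incidence
    ok <- TRUE
    for (parent in c("paternal", "maternal")) {
      sel <- lab == parent
      if (sum(sel) < 2) next
      if (any(colSums(inc[sel, , drop = FALSE]) > 1)) { ok <- FALSE; break }
    }
    concordant <- concordant + ok
  }
  concordant
}

#' Write lineages as per-lineage star trees in Newick format
#'
#' @param partition a `lineage_partition`.
#' @param path output file; one star tree per line, lineage mutations as
#'   the root label.
#' @return `path`, invisibly.
#' @export
write_lineage_newick <- function(partition, path) {
  lines <- vapply(partition$lineages, function(cl) {
    sprintf("(%s)%s_%s;", paste(cl$carriers, collapse = ","),
            cl$parent, paste(cl$mutations, collapse = "."))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
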