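# Lineage reconstruction: co-occurrence test, agglomeration, concordance
# and the randomisation validations.

test_that("cooccurrence_pvalue matches direct tail summation", {
  # two mutations in the same 5 of 10 offspring
  p <- cooccurrence_pvalue(10, 1:5, 1:5)
  expect_equal(p, 0.07812691, tolerance = 1e-7)
  # disjoint sets: overlap 0, P(X >= 0) = 1
  expect_equal(cooccurrence_pvalue(10, 1:5, 6:10), 1)
  # oracle: explicit summation of the binomial pmf over the upper tail
  oracle <- function(n, a, b) {
    p <- length(a) / n; q <- length(b) / n
    k <- length(intersect(a, b))
    sum(dbinom(k:n, n, p * q))
  }
  set.seed(3)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    a <- sample(n, sample(1:n, 1))
    b <- sample(n, sample(1:n, 1))
    expect_equal(cooccurrence_pvalue(n, a, b), oracle(n, a, b),
                 tolerance = 1e-12)
  }
  # nesting: A within B gives an overlap at the maximum possible
  expect_lt(cooccurrence_pvalue(12, 1:3, 1:6),
            cooccurrence_pvalue(12, c(1, 7, 8), 1:6))
  expect_error(cooccurrence_pvalue(0, 1, 1), "n_offspring")
  expect_error(cooccurrence_pvalue(5, integer(0), 1), "non-empty")
})

test_that("identical carrier sets merge; disjoint carriers never do", {
  strata <- data.frame(
    event_id = c("m1", "m2", "m3"),
    carriers = c("O01,O02,O03,O04,O05", "O01,O02,O03,O04,O05",
                 "O06,O07,O08"),
    origin = c("paternal", "paternal", "paternal"),
    stringsAsFactors = FALSE)
  # among 10 offspring the identical pair has p ~ 0.0781 > 0.05: under the
  # stopping rule (merge while p < 0.05) nothing may merge
  m10 <- sharing_matrix(strata, sprintf("O%02d", 1:10))
  expect_length(reconstruct_lineages(m10)$lineages, 3)
  # among 20 offspring the same pair has p ~ 0.009 and merges
  mat <- sharing_matrix(strata, sprintf("O%02d", 1:20))
  part <- reconstruct_lineages(mat)
  sizes <- sort(lengths(lapply(part$lineages, `[[`, "mutations")))
  expect_equal(sizes, c(1L, 2L))
  two <- Filter(function(cl) length(cl$mutations) == 2, part$lineages)[[1]]
  expect_setequal(two$mutations, c("m1", "m2"))
  # carrier set of a lineage is the union of its members' carriers
  expect_setequal(two$carriers, sprintf("O%02d", 1:5))
})

test_that("known origins block cross-parent merges", {
  strata <- data.frame(event_id = c("a", "b"),
                       carriers = c("O01,O02,O03", "O01,O02,O03"),
                       origin = c("paternal", "maternal"),
                       stringsAsFactors = FALSE)
  mat <- sharing_matrix(strata, sprintf("O%02d", 1:8))
  part <- reconstruct_lineages(mat)
  expect_length(part$lineages, 2)
})

test_that("simulated genealogies are recovered exactly", {
  for (s in 1:20) {
    tr <- simulate_sharing_truth(n_offspring = 20, n_lineages = 2, seed = s)
    part <- reconstruct_lineages(tr$matrix, origins = tr$origins)
    got <- lapply(part$lineages, function(cl)
      paste(sort(cl$mutations), collapse = ","))
    want <- lapply(tr$partition, function(cl)
      paste(sort(cl$mutations), collapse = ","))
    expect_setequal(unlist(got), unlist(want))
    expect_true(check_concordance(part))
  }
})

test_that("concordance detects offspring in two same-parent lineages", {
  bad <- list(list(parent = "paternal", mutations = "a",
                   carriers = c("O1", "O2")),
              list(parent = "paternal", mutations = "b",
                   carriers = c("O2", "O3")))
  expect_false(check_concordance(bad))
  good <- list(list(parent = "paternal", mutations = "a",
                    carriers = c("O1", "O2")),
               list(parent = "maternal", mutations = "b",
                    carriers = c("O2", "O3")))
  expect_true(check_concordance(good))
  expect_true(check_concordance(list()))  # vacuous
})

test_that("random reassignment essentially never looks biological", {
  tr <- simulate_sharing_truth(n_offspring = 20, n_lineages = 3,
                               min_mutations = 3, max_mutations = 6,
                               seed = 42)
  part <- reconstruct_lineages(tr$matrix, origins = tr$origins)
  n1 <- reassignment_validation(part, tr$matrix,
                                mode = "shuffle_lineage_labels",
                                n_reps = 2000, seed = 7)
  expect_lte(n1, 2000 * 0.005)
  n2 <- reassignment_validation(part, tr$matrix,
                                mode = "random_cluster_sizes",
                                n_reps = 2000, seed = 7)
  expect_lte(n2, 2000 * 0.005)
  # determinism under a fixed seed
  expect_identical(n1, reassignment_validation(
    part, tr$matrix, mode = "shuffle_lineage_labels", n_reps = 2000,
    seed = 7))
  single <- part; single$lineages <- part$lineages[1]
  expect_error(reassignment_validation(single, tr$matrix), "2 lineages")
})

test_that("fixed-frequency mode performs single-linkage agglomeration", {
  strata <- data.frame(
    event_id = c("m1", "m2", "m3"),
    carriers = c("O01,O02,O03,O04,O05", "O01,O02,O03,O04,O06",
                 "O07,O08,O09"),
    origin = "unknown", stringsAsFactors = FALSE)
  mat <- sharing_matrix(strata, sprintf("O%02d", 1:20))
  a <- reconstruct_lineages(mat, update_freq = TRUE)
  b <- reconstruct_lineages(mat, update_freq = FALSE)
  # both modes merge the overlapping pair and leave m3 alone
  for (part in list(a, b)) {
    merged <- Filter(function(cl) length(cl$mutations) == 2, part$lineages)
    expect_length(merged, 1)
    expect_setequal(merged[[1]]$mutations, c("m1", "m2"))
  }
})

test_that("newick export writes one star tree per lineage", {
  tr <- simulate_sharing_truth(seed = 2)
  part <- reconstruct_lineages(tr$matrix, origins = tr$origins)
  f <- tempfile(fileext = ".nwk")
  write_lineage_newick(part, f)
  lines <- readLines(f)
  expect_length(lines, length(part$lineages))
  expect_true(all(grepl("^\\(.*\\).*;$", lines)))
})
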