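#' Germline cellular demography
#'
#' Species parameters for converting per-generation mutation rates into
#' per-year and per-cell-division rates: generation time, the Drost & Lee
#' style per-sex division counts per generation, age at puberty and the
#' annual spermatogonial stem-cell (SSC) division count. Built-in
#' defaults: mouse (0.75 y generation, 62 paternal / 25 maternal
#' divisions, puberty 1 month, 42 SSC divisions/year) and human (30 y,
#' 401 / 31, puberty 15 y, 23 SSC divisions/year).
#'
#' @param species `"mouse"`, `"human"`, or a named list supplying the
#'   fields directly.
#' @return a `germline_demography` list.
#' @export
germline_demography <- function(species = c("mouse", "human")) {
  if (is.list(species)) {
    d <- species
  } else {
    species <- match.arg(species)
    d <- switch(species,
      mouse = list(species = "mouse", generation_time_years = 0.75,
                   divisions_paternal = 62, divisions_maternal = 25,
                   age_at_puberty_years = 1 / 12,
                   ssc_divisions_per_year = 42),
      human = list(species = "human", generation_time_years = 30,
                   divisions_paternal = 401, divisions_maternal = 31,
                   age_at_puberty_years = 15,
                   ssc_divisions_per_year = 23))
  }
  need <- c("generation_time_years", "divisions_paternal",
            "divisions_maternal", "age_at_puberty_years",
            "ssc_divisions_per_year")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("demography missing: ", paste(miss, collapse = ", "))
  if (any(unlist(d[need]) <= 0)) stop("demography values must be positive")
  class(d) <- "germline_demography"
  d
}

#' Sensitivity corrections for the callable genome
#'
#' Fractions of true mutations surviving the depth filters (`p_depth`),
#' the whole-genome region filters (`p_filter`) and validability of the
#' caller's posterior (`p_dnm`). Their product divides the observed mean
#' mutation count.
#'
#' @param p_depth,p_filter,p_dnm fractions in (0, 1].
#' @return a `sensitivity_corrections` list.
#' @export
sensitivity_corrections <- function(p_depth = 1, p_filter = 1, p_dnm = 1) {
  v <- c(p_depth, p_filter, p_dnm)
  if (any(v <= 0) || any(v > 1)) stop("corrections must lie in (0, 1]")
  structure(list(p_depth = p_depth, p_filter = p_filter, p_dnm = p_dnm),
            class = "sensitivity_corrections")
}

#' Sensitivity-corrected mean mutation count
#'
#' `m / (p_depth p_filter p_dnm)` with corrections as fractions; no
#' percentage factor is needed when corrections are expressed as
#' fractions.
#'
#' @param m observed mean mutations per offspring (>= 0).
#' @param corr a [sensitivity_corrections()].
#' @return corrected mean count.
#' @export
corrected_mean_mutations <- function(m, corr = sensitivity_corrections()) {
  if (m < 0) stop("m must be >= 0")
  prod_c <- corr$p_depth * corr$p_filter * corr$p_dnm
  if (prod_c <= 0) stop("correction product must be > 0")
  m / prod_c
}

# exact (Garwood) Poisson 95% CI for a total count
poisson_ci <- function(total, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (total == 0) 0 else qchisq(a, 2 * total) / 2
  hi <- qchisq(1 - a, 2 * total + 2) / 2
  c(lo, hi)
}

#' Mutation rates per generation, per year and per cell division
#'
#' Converts a corrected mean diploid mutation count per offspring into a
#' haploid per-generation rate `mu_generation = (m / genome_size) / 2`,
#' a per-year rate `mu_generation / generation_time` and a sex-averaged
#' per-cell-division rate
#' `mu_generation / ((divisions_paternal + divisions_maternal) / 2)`.
#' 95% confidence intervals come from the exact Poisson (Garwood)
#' interval on the summed raw mutation count, propagated linearly through
#' the correction and the rate identities.
#'
#' @param mean_mutations corrected mean diploid mutations per offspring.
#' @param genome_size callable bases.
#' @param demography a [germline_demography()].
#' @param n_offspring number of offspring behind the mean (for the CI).
#' @param total_mutations raw summed mutation count behind the mean (for
#'   the CI); when `NULL`, intervals are `NA`.
#' @return a `rate_set` list with point estimates and `ci95` per scale.
#' @export
rate_set <- function(mean_mutations, genome_size, demography,
                     n_offspring = NULL, total_mutations = NULL) {
  if (genome_size <= 0) stop("genome_size must be > 0")
  stopifnot(inherits(demography, "germline_demography"))
  mu_gen <- (mean_mutations / genome_size) / 2
  div2 <- (demography$divisions_paternal + demography$divisions_maternal) / 2
  mu_year <- mu_gen / demography$generation_time_years
  mu_cd <- mu_gen / div2
  ci <- rep(NA_real_, 2)
  if (!is.null(total_mutations) && !is.null(n_offspring) && n_offspring > 0) {
    scale <- if (total_mutations > 0)
      mean_mutations / (total_mutations / n_offspring) else 1
    ci <- poisson_ci(total_mutations) / n_offspring * scale
  }
  ci_gen <- (ci / genome_size) / 2
  out <- list(mean_mutations = mean_mutations, genome_size = genome_size,
              demography = demography,
              mu_generation = mu_gen, ci_generation = ci_gen,
              mu_year = mu_year,
              ci_year = ci_gen / demography$generation_time_years,
              mu_cell_division = mu_cd, ci_cell_division = ci_gen / div2)
  class(out) <- "rate_set"
  out
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Germline mutation rates (haploid, per base)\n")
  cat(sprintf("  mean mutations/offspring: %.3f (genome %.4g bp, %s)\n",
              x$mean_mutations, x$genome_size,
              x$demography$species %||% "custom"))
  fmt <- function(mu, ci) sprintf("%.4g  [%.4g, %.4g]", mu, ci[1], ci[2])
  cat("  per generation:   ", fmt(x$mu_generation, x$ci_generation), "\n")
  cat("  per year:         ", fmt(x$mu_year, x$ci_year), "\n")
  cat("  per cell division:", fmt(x$mu_cell_division, x$ci_cell_division), "\n")
  invisible(x)
}

#' Fit the parental-VEE transmission model
#'
#' Ordinary least squares for
#' `proportion of offspring carrying ~ beta0 + beta1 * parental VAF`,
#' from a parental mosaic quantification experiment. Predictions are
#' clipped to \[0, 1\] when used as germline weights.
#'
#' @param parent_vaf parental somatic VAFs.
#' @param offspring_fraction proportion of offspring carrying each
#'   mutation.
#' @return a `vee_transmission` list: `beta0`, `beta1`, `pearson_r`, `p`,
#'   `n`.
#' @export
fit_vee_transmission <- function(parent_vaf, offspring_fraction) {
  if (length(parent_vaf) < 3) stop("need at least 3 pairs")
  if (var(parent_vaf) == 0) stop("parental VAFs are constant")
  fit <- lm(offspring_fraction ~ parent_vaf)
  ct <- cor.test(parent_vaf, offspring_fraction)
  out <- list(beta0 = unname(coef(fit)[1]), beta1 = unname(coef(fit)[2]),
              pearson_r = unname(ct$estimate), p = ct$p.value,
              n = length(parent_vaf), fit = fit)
  class(out) <- "vee_transmission"
  out
}

#' Germline-adjusted count of mosaic first-cleavage mutations
#'
#' `2 * sum_j clip(beta0 + beta1 * VAF_j, 0, 1)` over the offspring VEE
#' VAFs — the expected diploid germline contribution of mutations that
#' are mosaic in the offspring, used in place of their raw count.
#'
#' @param vafs offspring VEE variant allele fractions (in \[0, 0.5\]).
#' @param model a `vee_transmission` (or list with `beta0`, `beta1`).
#' @return adjusted (real-valued) count; 0 for an empty list.
#' @export
adjusted_vee_count <- function(vafs, model) {
  if (!length(vafs)) return(0)
  if (any(vafs < 0 | vafs > 0.5)) stop("VEE VAFs must lie in [0, 0.5]")
  2 * sum(clip01(model$beta0 + model$beta1 * vafs))
}

# quasi-Poisson dispersion of a count vector
dispersion_phi <- function(x) {
  m <- mean(x)
  if (m == 0) stop("all counts are zero")
  sum((x - m)^2 / m) / (length(x) - 1)
}

#' Over-dispersion test for per-offspring mutation counts
#'
#' Pearson dispersion `phi = sum((x - xbar)^2 / xbar) / (n - 1)` against
#' the Poisson expectation `phi = 1`; the p-value comes from a parametric
#' bootstrap of the dispersion statistic under Poisson with the observed
#' mean (upper tail).
#'
#' @param counts per-offspring counts (>= 5 values, not all zero).
#' @param n_boot bootstrap replicates.
#' @param seed optional RNG seed for reproducibility.
#' @return list with `phi` and `p_value`.
#' @export
overdispersion_test <- function(counts, n_boot = 2000, seed = NULL) {
  if (length(counts) < 5) stop("need at least 5 offspring")
  if (all(counts == 0)) stop("all counts are zero")
  if (!is.null(seed)) set.seed(seed)
  n <- length(counts); m <- mean(counts)
  phi <- dispersion_phi(counts)
  boot <- matrix(rpois(n * n_boot, m), nrow = n)
  bm <- colMeans(boot)
  bphi <- colSums(sweep(boot, 2, bm)^2) / bm / (n - 1)
  bphi[bm == 0] <- 0
  p <- (1 + sum(bphi >= phi)) / (n_boot + 1)
  structure(list(phi = phi, p_value = p), class = "overdispersion_result")
}

#' Parental age effect on mutation counts
#'
#' Linear model of per-offspring mutation count on parental age with a
#' per-pedigree random intercept (`N ~ (1|pedigree) + age`, REML fit via
#' lme4). With a single pedigree the model degrades to ordinary least
#' squares. The slope p-value uses a normal approximation to the t
#' statistic. Mosaic first-cleavage (VEE) mutations arise in the
#' offspring and are unaffected by parental age; exclude them from
#' `counts` to sharpen the effect.
#'
#' @param counts per-offspring mutation counts.
#' @param age_years parental age at conception (years).
#' @param pedigree pedigree id per offspring.
#' @return list with `slope` (mutations/year), `se`, `p`, `intercept` and
#'   the fitted `model`.
#' @export
fit_age_effect <- function(counts, age_years, pedigree = NULL) {
  if (length(unique(age_years)) < 2) stop("need at least 2 distinct ages")
  if (is.null(pedigree)) pedigree <- rep("P1", length(counts))
  if (length(unique(pedigree)) > 1) {
    fit <- lme4::lmer(counts ~ age_years + (1 | pedigree), REML = TRUE)
    sm <- summary(fit)$coefficients
    slope <- sm["age_years", "Estimate"]; se <- sm["age_years", "Std. Error"]
    intercept <- sm["(Intercept)", "Estimate"]
  } else {
    fit <- lm(counts ~ age_years)
    sm <- summary(fit)$coefficients
    slope <- sm["age_years", 1]; se <- sm["age_years", 2]
    intercept <- sm[1, 1]
  }
  p <- 2 * pnorm(-abs(slope / se))
  list(slope = slope, se = se, p = p, intercept = intercept, model = fit)
}

#' Stage-specific mutation rates per haploid base per cell division
#'
#' \itemize{
#'   \item VEE: mean mosaic first-cleavage mutations per offspring divided
#'     by `2 x genome_size` (one cell division); the 95% CI assumes a
#'     quasi-Poisson distribution (`mean +/- 1.96 sqrt(phi mean / n)`).
#'   \item average paternal / maternal: mean count scaled by the phased
#'     paternal (maternal) fraction, divided by the sex's divisions per
#'     generation and the genome; Poisson CIs.
#'   \item pre-puberty male: `N = mutations_mean - (age_mean -
#'     age_puberty) x annual_slope`, divided by pre-puberty male divisions
#'     (total paternal minus SSC divisions accrued over `generation_time -
#'     puberty`) and the genome.
#'   \item post-puberty male: `annual_slope / ssc_divisions_per_year /
#'     genome_size`; CI from the slope's standard error.
#' }
#'
#' @param vee_counts per-offspring VEE counts.
#' @param mutations_mean mean (VEE-adjusted) mutations per offspring used
#'   in the pre-puberty subtraction.
#' @param paternal_phased,maternal_phased counts of directly phased
#'   mutations by parental origin.
#' @param annual_slope,slope_se parental age slope (mutations/year) and
#'   its standard error.
#' @param age_mean_years mean parental age at conception.
#' @param demography a [germline_demography()].
#' @param genome_size callable bases.
#' @param n_offspring offspring behind the means.
#' @return `data.frame` with one row per stage: `rate`, `ci_lo`, `ci_hi`.
#' @export
stage_rates <- function(vee_counts, mutations_mean, paternal_phased,
                        maternal_phased, annual_slope, slope_se,
                        age_mean_years, demography, genome_size,
                        n_offspring = length(vee_counts)) {
  stopifnot(inherits(demography, "germline_demography"))
  if (age_mean_years < demography$age_at_puberty_years)
    stop("age_mean_years is below the age at puberty")
  G <- genome_size
  rows <- list()
  ## VEE: one division, haploid
  m_vee <- mean(vee_counts)
  phi <- if (m_vee > 0) dispersion_phi(vee_counts) else 1
  half <- 1.96 * sqrt(phi * m_vee / n_offspring)
  rows$vee <- c(m_vee, m_vee - half, m_vee + half) / G / 2
  ## sex-averaged paternal / maternal rates from phased fractions
  tot_ph <- paternal_phased + maternal_phased
  frac_p <- if (tot_ph > 0) paternal_phased / tot_ph else NA_real_
  tot_mut <- mutations_mean * n_offspring
  for (sex in c("paternal", "maternal")) {
    fr <- if (sex == "paternal") frac_p else 1 - frac_p
    div <- if (sex == "paternal") demography$divisions_paternal else
      demography$divisions_maternal
    mm <- mutations_mean * fr
    ci <- poisson_ci(round(tot_mut * fr)) / n_offspring
    rows[[paste0("average_", sex)]] <- c(mm, ci) / div / G
  }
  ## pre-puberty male
  N <- mutations_mean -
    (age_mean_years - demography$age_at_puberty_years) * annual_slope
  ssc_per_gen <- demography$ssc_divisions_per_year *
    (demography$generation_time_years - demography$age_at_puberty_years)
  div_pre <- demography$divisions_paternal - ssc_per_gen
  se_N <- (age_mean_years - demography$age_at_puberty_years) * slope_se
  rows$pre_puberty_male <- c(N, N - 1.96 * se_N, N + 1.96 * se_N) /
    div_pre / G
  ## post-puberty male (SSC divisions)
  rows$post_puberty_male <- c(annual_slope,
                              annual_slope - 1.96 * slope_se,
                              annual_slope + 1.96 * slope_se) /
    demography$ssc_divisions_per_year / G
  out <- do.call(rbind, rows)
  data.frame(stage = rownames(out), rate = out[, 1], ci_lo = out[, 2],
             ci_hi = out[, 3], row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare mutation rates
#'
#' With two count vectors, runs both the Wilcoxon rank-sum test and
#' Student's t test; with means and 95% confidence intervals only, a t
#' (normal) test on the implied standard errors. P-values are
#' Bonferroni-adjusted over `n_comparisons`.
#'
#' @param a,b count vectors, or lists `list(mean=, ci=c(lo, hi))`.
#' @param n_comparisons Bonferroni family size.
#' @return `data.frame` of tests with raw and adjusted p-values.
#' @export
compare_rates <- function(a, b, n_comparisons = 1) {
  if (is.numeric(a) && is.numeric(b)) {
    w <- suppressWarnings(stats::wilcox.test(a, b))
    t <- stats::t.test(a, b)
    out <- data.frame(test = c("wilcoxon", "t"),
                      p_raw = c(w$p.value, t$p.value),
                      stringsAsFactors = FALSE)
  } else if (is.list(a) && is.list(b)) {
    se_a <- diff(a$ci) / (2 * 1.96); se_b <- diff(b$ci) / (2 * 1.96)
    z <- (a$mean - b$mean) / sqrt(se_a^2 + se_b^2)
    out <- data.frame(test = "t", p_raw = 2 * pnorm(-abs(z)),
                      stringsAsFactors = FALSE)
  } else stop("a and b must both be count vectors or both mean+CI lists")
  out$p_adj <- bonferroni(out$p_raw, n_comparisons)
  out
}

#' Bonferroni adjustment
#'
#' @param p raw p-values.
#' @param m number of tests.
#' @return `min(1, m * p)` elementwise.
#' @export
bonferroni <- function(p, m) pmin(1, m * p)

#' @importFrom stats cor.test
NULL
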