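---
title: "Methods: timing, rates and lineages of germline de novo mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: timing, rates and lineages of germline de novo mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germstrata)
```

## The model

A germline mutation can arise at any cell division between one zygote and
the next. In a multi-sibling pedigree sequenced deeply in several tissues,
the *pattern* of a de novo mutation (DNM) across offspring and parental
tissues betrays when it arose, because each stage of the germline
genealogy leaves a distinct footprint:

* **VEE (very early embryonic)** — arose in the first post-zygotic cell
  division contributing to the *offspring's* embryo. Mosaic in ~50% of
  the offspring's cells (expected variant allele fraction, VAF, 0.25),
  absent from both parents.
* **EE (early embryonic)** — arose in the *parent's* embryo before
  primordial germ cell (PGC) specification (~10 divisions). Constitutive
  in the carrier offspring, mosaic at a few percent of cells across all
  parental somatic tissues.
* **peri-PGC** — arose around PGC specification: shared by two or more
  siblings yet undetectable (< 1.6% of cells) in parental soma.
* **late post-PGC** — arose during PGC proliferation or gametogenesis:
  constitutive in a single offspring.

Throughout, cell fraction = 2 × VAF for a heterozygous mosaic.

### Stratum assignment

`classify_events()` applies a total precedence:

1. a parent with a statistically significant excess of the alternate
   allele (per-tissue upper-tail binomial tests against the site-specific
   error rate, Bonferroni-corrected; by default every covered tissue must
   be individually significant) ⇒ **EE**, origin that parent;
2. otherwise ≥ 2 carrier offspring with pooled parental cell fraction
   below the 1.6% detection floor ⇒ **peri-PGC**;
3. otherwise (single carrier) a likelihood test compares
   Binomial(depth, 0.25) against Binomial(depth, 0.5) at the pooled alt
   count. |Δlog L| > 5 decides **VEE** vs constitutive; verdicts inside
   the band are *unassigned* and treated as **late post-PGC** for rate
   work, as are constitutive singletons.

Haplotype occupancy from read-pair phasing (fraction of the ancestral
haplotype carrying the derived allele; 1 for constitutive, < 1 for
post-zygotic mutations) corroborates a VEE verdict but never overrides
the likelihood test. Allele counts are pooled across a carrier's tissues
only after a two-sided exact concordance test (α = 0.01, chosen to flag
only clear cross-tissue inconsistencies).

At the validation depths this package targets (≈400× per tissue), the
exact-enumeration confusion between a true VAF-0.25 mosaic and a
constitutive heterozygote is below 10⁻⁶ — the Δlog L = 5 band is
essentially lossless there, and the 4–10% unassigned fractions seen in
real data come from shallower or noisier sites.

### Rates

With `m` the mean (germline-adjusted, see below) diploid mutations per
offspring, sensitivity corrections `p_depth · p_filter · p_dnm` (the
fraction of true mutations surviving depth filters, region filters and
validability; handled as fractions throughout, so no percentage factor
is needed) and `G` callable bases:

$$\hat\mu_{\text{generation}} = \frac{m / (p_{depth}p_{filter}p_{dnm})}{2G},
\qquad
\hat\mu_{\text{year}} = \frac{\hat\mu_{\text{generation}}}{T_{gen}},
\qquad
\hat\mu_{\text{division}} = \frac{\hat\mu_{\text{generation}}}{(d_p+d_m)/2}$$

where the cellular demography (generation time \(T_{gen}\), per-sex
division counts \(d_p, d_m\), puberty age, SSC divisions/year) follows
the Drost & Lee accounting: mouse 62/25 divisions at a 9-month
generation, human 401/31 at 30 years. 95% intervals are exact
(Garwood/chi-square) Poisson intervals on the summed mutation count,
propagated linearly. The exact interval is preferred over the normal
approximation, which misbehaves at small counts.

**Germline weight of VEE mutations.** A mutation mosaic in the offspring
only partially enters that offspring's germline. A linear transmission
model fitted to a parental mosaic quantification experiment
(`fit_vee_transmission()`: proportion of offspring carrying ≈ β₀ + β₁ ×
parental somatic VAF) converts each offspring VEE VAF into a germline
weight, `adjusted = 2 Σ clip(β₀ + β₁ VAF_j, 0, 1)`, replacing the raw
count. The pipeline default β₀ = 0, β₁ = 1 states that somatic VAF equals
the expected gamete fraction — exactly the generative rule of the
simulator, and the natural null when no experiment is available.

**Stage-specific per-division rates** (`stage_rates()`): the VEE rate is
the mean VEE count / 2G (one division) with a quasi-Poisson interval
(mean ± 1.96 √(φ·mean/n), a standard construction for over-dispersed
counts); sex-averaged paternal/maternal rates scale the mean count
by the directly phased paternal fraction over each sex's divisions;
pre-puberty male counts subtract the post-puberty accumulation
`(age_mean − age_puberty) × slope`; the post-puberty rate divides the
annual slope by the SSC divisions/year. The parental age slope itself
comes from `fit_age_effect()` — a mixed model `N ~ (1|pedigree) + age`
(REML, lme4) across pedigrees, ordinary least squares within one. The
slope is reported per diploid offspring genome per year (per-haploid
reporting would halve it; the diploid scale is flagged in the output
documentation).

### Spectra

Six strand-collapsed point-mutation classes with the C:G>T:A transition
split by CpG context — seven categories. By convention the CpG split
belongs to the transition class (CpG hypermutability); an alternative
assignment to C:G>A:T, occasionally seen in category listings, is
available as `cpg_split_class = "C>A"`. Comparison is a
2 × 7 chi-squared with df fixed at 6, plus per-category two-proportion
z-tests, Bonferroni-corrected.

### Lineage reconstruction

Mutations in the same parental progenitor cell co-occur in offspring more
often than chance. For carrier frequencies p, q among n offspring the
co-occurrence test is the upper tail of Binomial(n, pq) at the observed
overlap. `reconstruct_lineages()` iteratively merges the most significant
admissible pair (known parental origins may not conflict; ties broken by
the lexicographically smallest id pair), recomputing frequencies from the
merged carrier sets, until no pair has p < 0.05. Among the
defensible variants (tail direction, success probability, whether
frequencies update during merging), the upper-tail p·q form with updated
frequencies directly expresses "co-occur more often than expected by
chance"; `update_freq = FALSE` gives the fixed alternative
(single-linkage on the initial p-values). No multiple-testing correction
is applied inside the agglomeration; the raw 0.05 threshold runs to full
collapse.

**A detectability limit worth knowing:** identical carrier sets of size c
among n offspring merge only while P(X ≥ c | Bin(n, (c/n)²)) < 0.05,
which fails for c ≳ 0.7 n. Mutations carried by most offspring cannot be
assigned to a lineage by this test — consistent with observed lineage
contributions of 2–53% of gametes. The sharing-truth generator caps
lineage sizes at ⌊0.7 n⌋ for exactly this reason. Note also that the
often-quoted example of two mutations sharing the same 5 of 10 offspring
has p ≈ 0.078 — *above* the 0.05 threshold — so it does not merge; 5 of
20 (p ≈ 0.009) does.

`check_concordance()` verifies that no offspring belongs to two lineages
of the same parent; `reassignment_validation()` scores 10,000 random
reassignments (label shuffles, or random clusterings of 2–10 mutations)
by that criterion. `reassignment_validation()` requires ≥ 2 lineages (a
single lineage is vacuously concordant and the validation meaningless).

## The synthetic world

`sim_config()` states one world and the tests never move it: a
two-parent pedigree, 10 WGS + 30 genotyped offspring over 7 litters
spanning 33 weeks (mean parental age at conception 24.5 weeks), a
2,222,635,788 bp callable genome, targeted depths of 600× (parents,
3 tissues), 400× (WGS offspring, 2 tissues), 200× (genotyped offspring),
a 10⁻³ per-read error rate and 6 unrelated individuals for
mutation-specific error rates.

Stage rates per haploid base per division were calibrated *once* from
observable anchors — ~5 VEE per offspring, ~19 DNMs per WGS offspring, a
paternal age slope of ~4.5 mutations/year via 42 SSC divisions/year —
giving first cleavage 1.1 × 10⁻⁹, embryonic 8 × 10⁻¹¹, peri-PGC
2 × 10⁻¹⁰, post-PGC 8 × 10⁻¹¹, SSC 4.8 × 10⁻¹¹. Division counts per
stage: 10 pre-PGC (1 + 9), 3 peri-PGC, then 21 (paternal) / 12
(maternal) pre-puberty and 42 SSC divisions/year from puberty at one
month. The number of PGC founder cells is unknown in vivo; the simulator
exposes it (`n_pgc_founders`, default 8) with a symmetric Dirichlet
(α = 0.5) over founder contributions to reproduce strongly unequal
lineage sizes, without claiming the true value.

Mechanistically: embryonic mutations of division k occur at
Poisson(2ᵏ · 2G·r) and sit at cell fraction 2⁻ᵏ, transmitted with
probability β₀ + β₁·2⁻⁽ᵏ⁺¹⁾; peri-PGC mutations are clonal within one
founder lineage and transmit to its members with probability ½;
post-PGC mutations are private Poisson counts whose paternal term grows
with age through the SSC schedule — this *is* the age effect, not an
added slope. VEE mutations arise in the first cleavage only (the
detection design has essentially no power below cell fraction 0.25; a
per-zygote Gamma multiplier, `vee_zygote_shape`, optionally reproduces
the over-dispersion of VEE counts and is off by default). Singleton
classes are generated only for WGS-tier offspring, which are the only
place they could be discovered; parental-side mutations are kept when a
WGS offspring carries them or a parent shows them.

What the generator does **not** emulate: alignment/caller artefacts
beyond a per-read error rate and optional low-VAF artifact sites,
repeat/segdup context (masks are inputs), selection among PGC lineages
(fecundity is a Dirichlet draw, not a selection model), maternal age
effects, and read-level data. A green end-to-end test therefore
establishes the statistical logic of the pipeline, not robustness to raw
sequencing pathology.

`scale_genome()` shrinks the genome while scaling rates up to preserve
expected counts; replicate studies run on 2 × 10⁷ bp. The estimand of
the recovery study, `expected_generation_rate()`, is the closed-form
expectation of the germline-weighted count per offspring over 2G.

## Numerical and design choices

* **Depth cutoff**: smallest d with P(D > d) < 10⁻⁴ under
  Poisson(mean depth), by exact CDF scan (mean 25 → 46, mean 41 → 67).
* **Tail directions**: the sequencing-error
  probability is the upper tail P(X ≥ alt | Poisson(depth × error));
  the constitutive probability is the lower tail
  P(X ≤ alt | Binomial(depth, 0.5)).
* **Reciprocal-cross VAF filters** use pooled (not per-tissue maximum)
  VAF — a deliberate choice, flagged because the per-tissue maximum is
  equally defensible.
* **MNV merging** chains transitively at ≤ 5 bp (1-based, |Δpos|);
  transitive chaining counts clustered artefact runs once. Indels and
  sex chromosomes are rejected at ingest.
* **Bonferroni family** for parental mosaic tests defaults to
  events × tissues × parents, the full set of tests actually performed.
* **Peri-PGC carriers** are required to be constitutive (≈ 0.5 VAF) via
  the same carrier thresholds as everyone else.
* **Error-rate floor** 10⁻⁵: a finite unrelated panel can estimate a
  site error of exactly 0, which would make any single alternate read
  infinitely significant.
* **Degenerate inputs**: zero informative read pairs give an *undefined*
  haplotype occupancy (never 0); zero-depth tissues are excluded from
  mosaic tests; empty spectra have undefined proportions; a correction
  product of 0 is rejected.

## What the recovery study does and does not establish

Over 400 scaled replicates the full pipeline recovers the configured
per-generation rate with ≈0.1% relative bias. CI coverage is ~90–92%,
not 95%: shared parental-side mutations make siblings' counts positively
correlated, while the interval assumes independent Poisson counts. In a sharing-free control
world the same interval covers ≈97%. The coverage band in the acceptance
test (≥ 0.88) was fixed before measurement and reflects this structural
gap; treat the reported CIs as slightly anti-conservative whenever
early-embryonic sharing is substantial.

## Known limitations

* Parental origin for rate scaling uses directly phased events (plus
  mosaic parents); co-occurrence-inferred origins are not folded in.
* The pipeline assumes deep targeted validation counts; it does not model
  discovery from 25–41× WGS likelihoods (out of scope, as is raw variant
  calling).
* Lineages carried by ≳70% of offspring are undetectable by the
  co-occurrence test (see above).
* Gonadal tissue is not modelled; "peri-PGC" is defined operationally by
  somatic undetectability.
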