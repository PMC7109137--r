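---
title: "Models and methods behind gapsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gapsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gapsel)
```

# The question the package answers

In pre-breeding programmes of outbred perennial crops, parents for the
next generation are usually chosen on their *own phenotypes*, because the
alternative — progeny testing — adds many years to an already long cycle.
An accession's own record is an unreliable guide to its parental worth
(general combining ability, GCA) exactly when heritability is low, and
classical theory says the reliability of a phenotype as a guide to the
breeding value scales with $\sqrt{h^2}$. `gapsel` implements the complete
analysis needed to quantify this on a pedigreed, genotyped accession
panel: own-phenotype breeding values, progeny-based GCA and heritability,
their correlation, and the accuracy of genomic prediction as a surrogate
for both.

# Mixed models

## Own phenotypes: the repeatability animal model

With records repeated over harvest years,

$$y = Xb + Za + Zp + e,\qquad
a \sim N(0, A\sigma^2_a),\quad p \sim N(0, I\sigma^2_p),\quad
e \sim N(0, I\sigma^2_e),$$

where $b$ holds the overall mean and harvest-year effects (fixed; the
earliest observed year is the reference level, a deterministic choice),
$a$ the additive genetic effects with pedigree relationship matrix $A$,
and $p$ the permanent-environment effects — non-genetic individual-level
deviations shared by an individual's repeated records. `build_design()`
assembles $y$, $X$ and the record-to-individual incidence; `reml_fit()`
estimates the variances and solves for BLUEs/BLUPs. The additive BLUP of
each accession is its **BLUP-BV**.

The same model fitted to progeny records, with $A$ constructed over
parents and progeny jointly, propagates progeny information to the
(record-less) parents: each parent's additive BLUP from that fit is its
**GCA**, and the progeny-data variance components give narrow-sense
heritability $h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_p + \sigma^2_e)$.
When progeny carry single records the permanent-environment variance is
not separable from the residual; `progeny_gca()` then drops the term
(automatically), which leaves $h^2$ unchanged because only the sum
$\sigma^2_p + \sigma^2_e$ enters the denominator.

## Genomic prediction

BLUP-BVs serve as the response of the GBLUP model
$y = \mu 1_n + Zg + \varepsilon$, $g \sim N(0, G\sigma^2_a)$, with $G$
the VanRaden method-1 realised relationship matrix computed from
column-centred SNP dosages and sample allele frequencies,
$G = WW^\top / (2\sum_k p_k(1-p_k))$. With sample frequencies every row
of $G$ sums to zero (an identity the tests assert), so $G$ is singular by
construction; `make_invertible()` restores positive definiteness by
blending with the identity, $(1-\epsilon)G + \epsilon I$ with
$\epsilon = 10^{-4}$, which preserves labels and nearly preserves values
(chosen over eigenvalue truncation for exactly that reason).

The original analysis fitted this model with Bayesian machinery; for a
Gaussian likelihood with a single relationship matrix the Bayesian
posterior mean and the REML+BLUP point predictions coincide in the
large-chain limit, so the package fits it by REML — a deliberate
equivalence decision that keeps the whole package on one inference
engine. MCMC is out of scope.

# REML: algorithms and numerical choices

`reml_fit()` works on the phenotypic covariance
$V = \sum_i \sigma^2_i Z_i K_i Z_i^\top + \sigma^2_e I$ directly:

* **AI-REML** (default for models with a permanent-environment term):
  average-information updates, with an **EM fallback** whenever the AI
  step leaves the parameter space, the AI matrix is numerically singular,
  or the restricted likelihood would decrease. EM steps are ascent steps,
  so the likelihood is monotone under them (asserted per-iteration in the
  tests via `method = "em"`).
* **Profiled eigendecomposition solver** (default for the two-component
  GBLUP model): eigendecompose $Z K Z^\top$ once, profile $\beta$ and
  $\sigma^2_e$ out analytically, and maximise the restricted likelihood
  over $\lambda = \sigma^2_a/\sigma^2_e$ by golden-section search on
  $\log\lambda \in [-14, 14]$. This makes the thousands of
  cross-validation refits cheap. Both routes produce identical results on
  shared problems (tested to $10^{-6}$ in log-likelihood).

Numerical conventions: variances are bounded below by
$10^{-6}\,\mathrm{var}(y)$ so the system stays well-posed at boundaries;
convergence is a relative restricted-log-likelihood change below
$10^{-8}$ with a 200-iteration cap (non-convergence returns the fit with
`converged = FALSE` and a warning); starting values split the phenotypic
variance equally across components; a constant response short-circuits to
the degenerate fit (all BLUPs zero). Breeding values are returned for
*every* individual in the relationship matrix via
$\hat a = \sigma^2_a K Z^\top P y$, so record-less individuals (parents in
progeny fits, validation accessions in cross-validation) receive their
relationship-weighted projections; the tests verify these against a dense
Henderson-MME oracle.

One identifiability caveat matters for the simulated world: when the
accessions are mutually unrelated ($A = I$) the additive and
permanent-environment structures coincide and only their **sum** is
identified. $V$, the fixed effects, and the *direction* of the BLUP-BV
vector depend only on that sum, so every correlation the pipeline reports
is unaffected; only the individual $\sigma^2_a$/$\sigma^2_p$ labels from
the own-phenotype fit are arbitrary there. AI-REML detects the singular
AI matrix and proceeds by EM.

# Marker filters

`filter_sites()` applies, in order: missingness (drop sites with more
than 10% missing genotypes), minor allele frequency (drop MAF strictly
below 5%, computed on non-missing dosages — a site at exactly the
threshold is kept), and adjacency (of any same-chromosome pair of sites
at most 1 bp apart, the higher-position member is dropped; keeping the
lower position is a deterministic tie-break, and the pass is idempotent).
`filter_coverage()` is the GBS-pipeline-style variant: site coverage
$\ge 0.9$, then taxa coverage $\ge 0.8$, then MAF $\ge 0.05$.
`impute_mean()` replaces missing dosages by the site mean — a
deliberately naive, deterministic stand-in for haplotype-based
imputation, kept behind a pluggable interface (its `seed` argument is
reserved for stochastic successors).

# Cross-validation design

`make_folds(n, k, seed)` partitions records into $k$ folds whose sizes
differ by at most one, larger folds first — 274 records in 11 folds give
ten folds of 25 and one of 24. Fold membership is assigned in canonical
(sorted-id) order, which makes accuracy summaries exactly invariant to
the ordering of the input vectors. Each repeat $r$ of
`cv_genomic_prediction()` uses seed $\mathrm{seed} + r$ (logged in the
result). Within a fold the model is **refitted** on the training
accessions — the stricter choice, since reusing whole-data variance
components would leak information. Per-fold correlations (GEBV vs
BLUP-BV, and optionally GEBV vs GCA) are recorded for all
$k \times \mathrm{repeats}$ folds; summaries report means and quartiles,
which subsumes both per-fold and per-replicate readings. Validation folds
below 3 accessions are refused (a correlation on fewer is meaningless).

# The simulated world

`default_study()` generates the stated world end-to-end: 274 founder
accessions; ~274 crosses (no selfing, each parent in two crosses on
average) of 18 offspring each, i.e. about 5000 cross-pollinated progeny;
6400 biallelic SNPs spread over 17 chromosomes of 1 Morgan (30 Mb) each;
eight traits named and parameterised after a diverse apple panel — means
and phenotypic SDs from fruit-quality field data (e.g. fruit weight
136 g, SD 90 g) and heritabilities 0.50, 0.41, 0.26, 0.21, 0.18, 0.17,
0.15, 0.15; permanent-environment fraction 0.15 of phenotypic variance
for every trait (a typical repeatability-model magnitude; the source
field study does not report it); year effects of $0.2\,\mathrm{SD}$ for
the second harvest year; two years of parental records, one record per
progeny; 4% missing genotypes in the written marker files.

Mechanics: founder haplotypes are drawn site-wise independently (HWE,
allele frequencies uniform on $[0.05, 0.5]$); gametes recombine with a
Poisson (Haldane, no-interference) crossover process; each trait is
polygenic with 200 QTL drawn from the genotyped SNPs, effects rescaled so
the realised breeding-value variance hits the target $h^2$ exactly. All
randomness descends deterministically from one master seed;
re-simulation is byte-identical.

**What the generator does *not* emulate — and what that means for the
tests.** Real accession panels of this kind are *related* (half-sib
families, shared ancestry; the motivating dataset had a mean pairwise
genomic relationship of 0.22) and carry ancestral linkage disequilibrium.
The simulated accessions are unrelated founders in linkage equilibrium —
LD arises only in the progeny via cosegregation. Consequently GBLUP
accuracy among the accessions is capped near
$\sqrt{n_{\mathrm{train}} / (n_{\mathrm{train}} + M)}$ with $M$
effectively independent markers: about 0.33 for 249 training accessions
and 2000 SNPs — we verified the package hits this cap (mean CV accuracy
0.37 when the true breeding values are used as the response). Real-data
accuracies of 0.6–0.75 are therefore *not* reproducible in this world,
and one acceptance property that presumes a clean across-trait ordering
of CV accuracies by $h^2$ is not attainable at the reduced scale: the
trait-level accuracies (range roughly $-0.05$ to $0.3$) are dominated by
QTL-realisation noise, and their Spearman correlation with $h^2$ varies
from $-0.2$ to $0.75$ across world seeds. The corresponding test is left
failing by design rather than weakened. A green test here establishes
correct mechanics (partitioning, refitting, projection, summarisation)
and the directional phenomena that *are* robust in this world — the
own-phenotype/GCA correlation tracking $\sqrt{h^2}$ (Pearson 0.94–0.98
across traits in our runs), the GEBV–GCA profile tracking the
BLUP-BV–GCA profile, and null accuracies centred on zero — not the
absolute accuracy levels of a related panel.

Other accepted simplifications: no selection between generations (keeps
truth analytically clean), fruit-level measurement error absorbed into
the residual, single progeny records by default (configurable), no
mutation or genotyping error, no crossover interference.

# Design decisions that were genuinely open

* **G variant**: VanRaden method 1 with observed sample allele
  frequencies and single-denominator scaling; the source analysis does
  not state its variant, and no external base-population frequencies
  exist.
* **Adjacency tie-break**: keep the lower-position site; the source
  states only that near-adjacent SNPs were discarded.
* **MAF boundary**: "below 5%" is read strictly; MAF exactly 0.05 is
  retained.
* **BLUP-BVs fed to GBLUP as-is**: no deregression or weighting — the
  wording of the source analysis implies the BLUPs themselves were used
  as records.
* **GCA scale**: reported on the full additive-BLUP scale, not halved to
  expected-progeny-mean scale; every reported quantity is a correlation,
  which is scale-invariant.
* **Config format**: JSON (no YAML parser in the supported dependency
  set).
* **Relationship-matrix serialisation**: labelled CSV only; a binary
  twin format was dropped as it cannot be shipped or meaningfully tested
  in a text-only artifact.

# Known limitations

Single-trait models only; no dominance, spatial or marker-effect
parameterisations; no standard errors on $h^2$; dense algebra limits
fits to roughly 6000 records on a desktop; the mean-dosage imputer is a
placeholder and attenuates relationships at high missingness.
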