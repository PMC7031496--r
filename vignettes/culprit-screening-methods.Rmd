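---
title: "Screening cold tumors for candidate regulators of immune trafficking: methods and design"
author: "culpritScreen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening cold tumors for candidate regulators of immune trafficking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(culpritScreen)
```

## The model in outline

The pipeline asks a simple question of a pan-cancer expression compendium:
which genes are *recurrently* overexpressed in tumors with low CD8+ T-cell
infiltration, across many tumor types at once? Recurrence across
independently analyzed tumor groups is the central statistical device — a
gene that lands near the top of the cold-association ranking in many groups
is unlikely to do so by chance, regardless of the noise structure within
any one group.

Inputs are log2(normalized count + 1) expression matrices (genes ×
samples) with a tumor-group label per sample, held in an
`ExpressionCohort` (a `SummarizedExperiment` subclass whose validity
enforces finite, non-negative values and ≥ 2 samples per group).

### Infiltration scoring

A sample's infiltration is the geometric mean of the log2 expression of a
small signature — by default the four-gene T-cell identity set (CD8A,
CD8B, CD3D, CD3E) or the cytolytic set (GZMA, GZMB, GNLY, PRF1). The
geometric mean is taken of the *log2 values themselves*, not of
linear-scale values; consequently a signature member with zero expression
zeroes the whole score. This is a deliberate, literal reading of the
scoring rule and is the single most consequential convention in the
package: on log2(x+1) data a zero means "undetected", and a tumor in which
CD8A is undetected is cold regardless of the other members. Members absent
from a cohort are dropped with a warning rather than failing, because
treatment cohorts processed with different annotation pipelines routinely
lose a symbol or two.

### Stratification

Tertiles (and quartiles for outcome work) are *balanced rank partitions*,
not quantile-threshold cuts: samples are sorted by score with ties broken
by sample-id order, and block sizes differ by at most one, extras assigned
to the lowest blocks first. With heavy ties a threshold cut can produce
wildly unequal strata; the rank partition keeps group sizes stable, which
the downstream two-sample contrast needs, and the tie rule makes every run
reproducible. For 48 samples this yields the 12/12/12/12 quartile design
used in treatment cohorts.

### Within-group ranking: LFC and SC

The **LFC method** contrasts the high against the low tertile:
`lfc = mean(high) − mean(low)`, so negative values mark genes
overexpressed in cold tumors. Significance comes from an empirical-Bayes
moderated *t*: per-gene pooled variances are shrunk toward a
scaled-inverse-chi-square prior whose parameters are fitted across genes by
method of moments on the log variances, and the statistic is referred to a
*t* distribution with residual-plus-prior degrees of freedom. This is an
in-package implementation (cross-checked in the test suite against
`limma::eBayes` to 1e-6, and reducing exactly to the ordinary pooled *t*
when the prior degrees of freedom are forced to zero). Moderation matters
here for one specific reason: genes constant within both tertiles would
otherwise have zero residual variance and undefined *t*; the prior keeps
their *p*-values finite.

The **SC method** is the tie-corrected Spearman correlation of every gene
with the signature score over *all* of a group's samples (not just the
tertile extremes), with two-sided *p* from the *t* approximation. Constant
genes are flagged and assigned rho = 0, *p* = 1, and are forced to the
bottom of the ranking.

Both statistics are converted to percentile ranks
`pr = 100 · (G − position + 1) / G`, position 1 being the most
cold-associated gene (most negative lfc or rho), ties broken by smaller
BH *q* then gene id. The top-percentile set of a group is the first
`floor(f · G)` positions; at f = 0.01 and G = 20,501 that is exactly 205
genes.

### Cross-group selection: MPR and EBP

**MPR selection** takes per-gene medians of pr and *q* across groups and
selects genes with median pr ≥ 75 by *both* methods and median *q* ≤ 0.1
by both (all bounds inclusive). The conjunction across two only partially
redundant statistics is the guard against method-specific artifacts.

**EBP selection** counts, per method, the number of groups *k* in which a
gene reaches the top-percentile set and computes the Bonferroni-corrected
exact binomial *point* probability

$$p(k) = \min\!\left(1,\; G \binom{T}{k} f^k (1-f)^{T-k}\right),$$

evaluated in log space. Two design choices deserve note. First, the point
probability P(X = k) is used, not the tail P(X ≥ k): at the reference
geometry (T = 23, f = 0.01, G = 20,501) the point form yields the per-k
significance ladder the package reports (0.058 at k = 5 down to 2.5e-14
at k = 12), and the `tail = TRUE` option exposes the alternative. Second, the Bonferroni factor is the universe size
G — the number of genes each of which gets its own recurrence test. Genes
with k ≥ 5 (of 23) are selected; for differently sized compendia the
cutoff should be scaled proportionally (the test suite uses
`minK = ceiling(5 · T / 23)`).

Pairwise overlap of the per-group top sets is tested with the Yates
continuity-corrected χ² on the 2×2 membership table over the constant
G-gene universe, BH-adjusted across all T(T−1)/2 pairs. Genes unmeasured in
some group should be removed pipeline-wide before ranking, so the universe
is identical in every group.

### Mutual exclusivity in cold tumors

Analysis is restricted to the low-tertile samples, the stratum where
exclusion programs are hypothesized to operate. Each gene is binarized at
its mean over that group's low-tertile samples — strictly above → 1, at or
below → 0 (the strict inequality is the deterministic tie rule, and makes
a within-group-constant gene all-zero) — and groups are concatenated.
Because the mean is affine-equivariant, binarization is invariant to any
positive affine rescaling of a group's expression, which the test suite
asserts.

For every gene pair the joint binary states form a 2×2 table; the log2
odds ratio is the cross-product estimate with the Haldane–Anscombe 0.5
correction applied only when a zero cell occurs, while the two-sided
Fisher exact *p* is computed on the *uncorrected* table by the
minimum-likelihood rule (sum of hypergeometric probabilities no larger
than the observed table's). Keeping the correction out of the test
preserves exactness; keeping it in the estimate bounds the OR away from 0
and infinity. Pairs involving an all-0/all-1 gene are reported NA and
excluded from the BH family.

Gene clustering (for the C1/C2 partition and for heat-map leaf order) is
complete-linkage agglomeration on 1 − Spearman rho, applied either to
expression vectors or to rows of the log2 OR matrix; the two children of
the dendrogram root are labeled C1 and C2 by descending size. Synexpression
groups are found by scanning the dendrogram root-to-leaf and reporting
maximal subtrees whose mean pairwise correlation reaches R (default 0.15);
descent stops at a qualifying subtree, so reported groups are disjoint, and
singletons are never reported. Mean pairwise correlation was chosen as the
subtree aggregation because it is the natural sample estimate of the
within-cluster correlation and is monotone under adding a tightly
correlated member; other aggregations (minimum, linkage height) are more
conservative and interact badly with complete linkage on noisy estimates.

### Outcome association

Treatment-cohort samples are scored per signature and quartiled *within*
the pre-treatment and on-treatment strata independently, because the two
biopsy sets differ systematically in scale. Responders are CR/PR,
non-responders SD/PD, and NE samples are excluded; both the Q1-vs-Q4 and
the Q1-vs-(Q2+Q3) contingencies are tested two-sided by Fisher's exact
test. The pooled-across-timing test is the default reading; both modes are
reachable by subsetting the quartile vector, since `responseQuartileTest()`
accepts any named quartile labeling. Survival uses the product-limit
estimator and the standard unweighted log-rank statistic
(`survival::survfit`/`survdiff` under the hood, with a hand-computed
expected-event oracle in the tests); the group construction is free-form —
the natural defaults are Q1 vs Q2–Q4 pooled, or all four quartiles — and
with zero observed events the statistic is defined as 0 with p = 1.

## The synthetic-data generators

`generatePanTumor()` emulates the statistical structure the screen assumes,
not RNA-seq physics. Per sample, a latent infiltration factor
z ~ N(μ_t, 1), with group means μ_t ~ N(0, 1) drawn once per group to force
the pipeline to normalize within groups. Gene values are α + noise
(α = 5 log2 units, σ = 1, both typical of mid-expressed genes on the
log2(x+1) scale), with signature genes loading +β·z (β = 1), culprit genes
−γ·z (γ = 1) in an affected subset of groups (8 of 10 by default —
recurrence without universality), and two programs A/B of 20 genes each
that add δ = 1.5 in cold samples (lower z-tertile within group), each cold
sample activating exactly one program (A with probability π = 0.5). Values
are clipped at zero, mirroring the log2(x+1) floor. The default geometry —
10 groups × 120 samples, 2,000 genes, 50 culprits — is the package's
standard simulated study, large enough for stable tertile contrasts and
small enough that the full screen runs in seconds.

`generateTreatmentCohort()` reuses the expression model as a single group
and couples outcomes to the standardized signature score s:
responder probability `plogis(qlogis(1/3) − b·s)` (a one-third baseline
response rate, typical of checkpoint-inhibitor melanoma cohorts;
responders labeled CR:PR = 1:2, non-responders SD:PD = 1:2, fixed for
reproducibility), and overall survival Exponential with rate
`(1/365)·exp(θ·s)` under independent exponential censoring at one third
the event rate (roughly 25% censoring). Timing (pre/on) and treatment
cohort labels are assigned round-robin with offset periods so they are not
confounded.

What the generators deliberately do *not* emulate: negative-binomial count
noise, library-size and batch effects, gene–gene correlation beyond the
planted factor and programs, or missing annotations. Passing tests
therefore demonstrate that the statistical machinery recovers planted
structure under the stated model — they do not certify performance on real
TCGA data, where group sizes are unbalanced, expression is heavy-tailed,
and infiltration is confounded with purity.

## Numerical and degenerate-input choices

- All recurrence probabilities are computed in log space
  (`dbinom(log = TRUE)`), so k = 23 at f = 0.01 underflows gracefully.
- The variance-prior fit excludes zero variances from the moment
  estimation (their log is −Inf) but still shrinks them, giving finite
  *p*-values; when the observed log-variance spread is no larger than the
  theoretical chi-square spread, the prior degrees of freedom are infinite
  and all variances collapse to the common value.
- Spearman *p*-values use the t approximation everywhere (the same as
  `cor.test(exact = FALSE)`); |rho| = 1 maps to p = 0.
- Every ordering in the package (partitions, percentile ranks, dendrogram
  labels) has an explicit deterministic tie-break, so identical inputs give
  identical outputs on any platform.
- Fail-fast validation with classed error conditions
  (`duplicateIdError`, `unannotatedSampleError`, `smallContextError`, ...)
  replaces silent coercion throughout the readers and constructors.

## Problem sizes used by the test suite

The suite exercises the full screen at the standard simulated geometry
(10 × 120 × 2,000; about six seconds per run), 20 null-generator
replicates for selection calibration, 100 treatment-cohort replicates for
response-test power, 500 replicates for log-rank null uniformity, and an
exhaustive Fisher-exact enumeration over every 2×2 table with n ≤ 24.
These sizes were chosen to keep Monte-Carlo error well below the asserted
margins while keeping a full run within a few minutes.

## Known limitations

- The moderated *t* assumes exchangeable gene variances within a group; it
  uses no precision weights and no covariates, so confounders (purity,
  subtype) are not adjusted for.
- The EBP model treats groups as independent Bernoulli trials with a
  common success probability f; correlated tumor types (e.g. colon/rectal)
  violate independence and make the test anti-conservative.
- Metagene zeroing means a single undetected signature member forces a
  zero score; on sparse data consider filtering signatures to robustly
  detected members first.
- Cutoff directions in the mutual-exclusivity gene selection are fully
  parameterized (`orDirection`) rather than hard-coded, because sensible
  published analyses have used both senses; callers must state which side
  they select.
- Survival analysis is unadjusted (no Cox covariates) and uses the
  unweighted log-rank only.
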