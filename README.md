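# culpritScreen

Pan-cancer screening for transcriptional correlates of T-cell-cold tumors.

## The problem

Solid tumors with few infiltrating CD8+ T cells ("cold" tumors) respond
poorly to immune checkpoint blockade. A recurring observation across cancer
types is that certain genes are consistently *overexpressed* in cold tumors,
suggesting shared transcriptional programs that exclude T cells. This
package implements a complete, testable pipeline for discovering such
candidate regulators of immune trafficking (CulPRITs) from grouped bulk
RNA-seq cohorts, characterizing their mutually exclusive expression
programs, and testing derived signatures against immunotherapy outcomes.
It is aimed at computational immuno-oncology analysts working with
TCGA-style expression matrices (genes × samples, log2(normalized count + 1),
one tumor-group label per sample) and treatment cohorts with RECIST response
and overall-survival annotations.

## The method

1. **Infiltration scoring.** Each tumor's CD8+ T-cell infiltration is
   summarized by a metagene score: the geometric mean of the log2 expression
   of a small signature (CD8A, CD8B, CD3D, CD3E for T-cell identity; GZMA,
   GZMB, GNLY, PRF1 for cytolytic activity). Within each tumor group,
   samples are split into balanced tertiles of the score; the lower tertile
   is the CD8-Low (cold) stratum.
2. **Within-group gene ranking**, by two parallel statistics:
   the **LFC method** (mean log2 fold change, high-minus-low tertile, with
   an empirical-Bayes moderated *t* for *p*/*q* values; negative LFC =
   overexpressed in cold tumors) and the **SC method** (Spearman correlation
   of each gene with the signature score). Each method yields a percentile
   rank pr ∈ (0, 100] per gene per group, with pr = 100 for the most
   cold-associated gene.
3. **Cross-group recurrence.** Genes are selected as CulPRITs either by
   **MPR** (median percentile rank across groups ≥ 75 by *both* methods and
   median BH *q* ≤ 0.1 by both) or by **EBP**, the Bonferroni-corrected
   exact binomial probability of reaching a group's top percentile in *k*
   of *T* groups by chance:

   p(k) = min(1, G · C(T, k) · f^k · (1 − f)^(T−k)),

   with f = 0.01, T = 23 tumor groups and G = 20,501 genes in the reference
   geometry. Yates-corrected χ² tests quantify the pairwise overlap of the
   per-group top-percentile sets.
4. **Mutual exclusivity.** Within cold tumors, expression is binarized at
   the within-group mean, and all gene pairs are tested by Fisher's exact
   test; Haldane-corrected log2 odds ratios < 0 mark mutually exclusive
   pairs. Complete-linkage clustering on Spearman correlation distance
   yields the two predominant clusters C1/C2 and synexpression groups
   (subtrees with average pairwise correlation ≥ 0.15).
5. **Outcome association.** Derived signatures are scored in a treatment
   cohort, samples are split into score quartiles within pre-/on-treatment
   strata, and Q1-vs-Q4 / Q1-vs-(Q2+Q3) responder enrichment (Fisher exact)
   and Kaplan–Meier / log-rank survival differences are tested.

Seeded synthetic-data generators (`generatePanTumor()`,
`generateTreatmentCohort()`) plant a latent infiltration factor,
anti-correlated culprit genes, mutually exclusive programs and
score-dependent clinical outcomes, so every stage of the pipeline is tested
against known ground truth.

## Worked example

```r
library(culpritScreen)

sim <- generatePanTumor(generatorConfig(seed = 42))   # 10 groups x 120, 2000 genes
res <- screenCulprits(sim$cohort, sim$signature, analysisParams(minK = 3))

head(res$mpr[res$mpr$selected, ], 3)
#>        gene mpr_lfc mpr_sc    med_q_lfc     med_q_sc selected
#> 29 gene0029  99.100 99.200 2.672114e-14 6.484164e-12     TRUE
#> 17 gene0017  99.000 99.125 5.410932e-14 8.194652e-12     TRUE
#> 8  gene0008  98.975 99.225 1.539608e-14 3.519638e-13     TRUE

table(plantedRoles(sim$truth)[res$mpr$gene[res$mpr$selected]])
#>  culprit programA
#>       50        1
```

All 50 planted culprit genes are recovered (their median percentile ranks
exceed 98 by both methods with vanishing median *q*), with a single planted
program gene as the only extra call. At the reference 23-group geometry the
recurrence probabilities are

```r
signif(ebp(5:12), 3)
#> [1] 5.76e-02 1.74e-03 4.28e-05 8.65e-07 1.46e-08 2.06e-10 2.46e-12 2.48e-14
```

so five or more recurrences of the same gene are already unexpected by
chance (p ≈ 0.058) after correcting for all genes tested.

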