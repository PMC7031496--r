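## Cross-tumor recurrence analyses: pairwise overlap significance of the
## per-group top-percentile sets, median-percentile-rank (MPR) selection, and
## the Bonferroni-corrected exact binomial probability (EBP) criterion.

#' Yates-corrected chi-square tests of pairwise top-set overlap
#'
#' For every unordered pair of tumor groups, tabulates membership of the
#' universe of G ranked genes in the two groups' top-percentile sets
#' (both / A-only / B-only / neither) and applies the chi-square test with
#' continuity correction; q-values are BH-adjusted across all pairs.
#'
#' @param topSets Named list of per-group gene-id vectors (one method).
#' @param universe Character vector of all ranked gene ids (constant across
#'   groups), or a single number G.
#' @param params An [AnalysisParams-class] (FDR method).
#' @return data.frame with one row per pair: \code{groupA, groupB, sizeA,
#'   sizeB, overlap, chisq, p, q}.
#' @seealso [overlapSignificantFraction()]
#' @export
pairwiseOverlapChi2 <- function(topSets, universe,
                                params = analysisParams()) {
    if (length(topSets) < 2L)
        .err("invalidValueError", ">= 2 groups required")
    G <- if (is.numeric(universe)) universe else length(universe)
    if (!is.numeric(universe)) {
        bad <- !vapply(topSets, function(s) all(s %in% universe), logical(1))
        if (any(bad))
            .err("invalidValueError", "top set(s) not within universe: ",
                 paste(names(topSets)[bad], collapse = ", "))
    }
    groups <- names(topSets)
    pairs <- utils::combn(groups, 2L)
    res <- apply(pairs, 2L, function(pr) {
        a <- topSets[[pr[1L]]]; b <- topSets[[pr[2L]]]
        both <- length(intersect(a, b))
        tab <- matrix(c(both, length(a) - both,
                        length(b) - both,
                        G - length(a) - length(b) + both), 2L, 2L)
        ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
        data.frame(groupA = pr[1L], groupB = pr[2L],
                   sizeA = length(a), sizeB = length(b), overlap = both,
                   chisq = unname(ct$statistic), p = ct$p.value)
    })
    out <- do.call(rbind, res)
    out$q <- stats::p.adjust(out$p, method = params@fdrMethod)
    out
}

#' Fraction of group pairs with significant top-set overlap
#'
#' The bar-chart statistic summarizing [pairwiseOverlapChi2()]: the
#' proportion of pairs whose overlap q-value falls below each threshold.
#'
#' @param overlapTable Output of [pairwiseOverlapChi2()].
#' @param qThresholds Numeric thresholds.
#' @return Named numeric vector of fractions in [0, 1].
#' @export
overlapSignificantFraction <- function(overlapTable,
                                       qThresholds = c(0.05, 0.01, 0.001)) {
    vapply(stats::setNames(qThresholds, paste0("q<", qThresholds)),
           function(th) mean(overlapTable$q < th), numeric(1))
}

#' Median percentile rank (MPR) table and CulPRIT selection
#'
#' For each gene, the median across tumor groups of its percentile ranks and
#' FDR q-values, per ranking method. A gene is selected as an MPR CulPRIT iff
#' its MPR is at least \code{mprMin} by \emph{both} the LFC and SC methods
#' and its median q is at most \code{medianQMax} by both methods (all bounds
#' inclusive). Genes missing from any group's table are dropped with a
#' warning.
#'
#' @param rankTable Output of [rankGenes()] (all groups).
#' @param params An [AnalysisParams-class].
#' @return data.frame with one row per gene: \code{gene, mpr_lfc, mpr_sc,
#'   med_q_lfc, med_q_sc, selected}, sorted by decreasing
#'   \code{pmin(mpr_lfc, mpr_sc)}.
#' @export
medianPercentileTable <- function(rankTable, params = analysisParams()) {
    nGroups <- length(unique(rankTable$group))
    if (nGroups == 0L) .err("invalidValueError", "zero groups")
    cnt <- table(rankTable$gene)
    keep <- names(cnt)[cnt == nGroups]
    if (length(keep) < length(cnt))
        warning(length(cnt) - length(keep),
                " gene(s) missing from some group(s) dropped")
    d <- rankTable[rankTable$gene %in% keep, ]
    med <- function(col) {
        m <- tapply(d[[col]], d$gene, stats::median)
        m[keep]
    }
    out <- data.frame(gene = keep,
                      mpr_lfc = unname(med("pr_lfc")),
                      mpr_sc = unname(med("pr_sc")),
                      med_q_lfc = unname(med("q_lfc")),
                      med_q_sc = unname(med("q_sc")),
                      row.names = NULL)
    out$selected <- out$mpr_lfc >= params@mprMin &
        out$mpr_sc >= params@mprMin &
        out$med_q_lfc <= params@medianQMax &
        out$med_q_sc <= params@medianQMax
    out[order(-pmin(out$mpr_lfc, out$mpr_sc), out$gene), , drop = FALSE]
}

#' Bonferroni-corrected exact binomial recurrence probability (EBP)
#'
#' The probability that one given gene lands in the top-percentile set
#' (per-group success probability f) of exactly k out of T tumor groups,
#' Bonferroni-multiplied by the number of genes tested:
#' \deqn{p = \min(1,\; G \binom{T}{k} f^k (1-f)^{T-k}).}
#' Computed in log space. With \code{tail = TRUE} the upper-tail probability
#' \eqn{P(X \ge k)} is used instead of the point probability.
#'
#' @param k Recurrence count(s), 0 <= k <= T (vectorized).
#' @param nGroups Number of tumor groups T (default 23).
#' @param params An [AnalysisParams-class] supplying f (topFraction) and the
#'   Bonferroni factor G (universeSize).
#' @param tail Use the upper-tail instead of the point probability.
#' @return Numeric vector of corrected probabilities in (0, 1].
#' @examples
#' ebp(12)          # 2.48e-14 at the 23-group, 20,501-gene geometry
#' round(ebp(5), 3) # 0.058
#' @export
ebp <- function(k, nGroups = 23, params = analysisParams(), tail = FALSE) {
    if (any(k < 0 | k > nGroups | k != floor(k)))
        .err("invalidValueError", "k must be an integer in [0, nGroups]")
    f <- params@topFraction
    G <- params@universeSize
    if (tail) {
        logp <- stats::pbinom(k - 1, nGroups, f, lower.tail = FALSE,
                              log.p = TRUE)
    } else {
        logp <- stats::dbinom(k, nGroups, f, log = TRUE)
    }
    pmin(1, exp(log(G) + logp))
}

#' EBP CulPRIT selection from per-group top sets
#'
#' Counts, per gene and per ranking method, the number of groups k in which
#' the gene reaches the top-percentile set, attaches the Bonferroni-corrected
#' exact binomial probability at that k, and flags genes with
#' \code{k >= minK} per method.
#'
#' @param topSetsLfc,topSetsSc Named lists of per-group gene sets (from
#'   [topSetsByGroup()]).
#' @param params An [AnalysisParams-class].
#' @return data.frame with one row per gene appearing in any set:
#'   \code{gene, k_lfc, k_sc, p_bonf_lfc, p_bonf_sc, selected_lfc,
#'   selected_sc}, sorted by decreasing max(k) then gene id.
#' @export
selectEbpCulprits <- function(topSetsLfc, topSetsSc,
                              params = analysisParams()) {
    T <- length(topSetsLfc)
    if (length(topSetsSc) != T)
        .err("invalidValueError",
             "both methods need top sets for the same groups")
    kOf <- function(sets, genes) {
        tab <- table(unlist(sets, use.names = FALSE))
        k <- as.integer(tab[genes])
        k[is.na(k)] <- 0L
        k
    }
    genes <- sort(unique(c(unlist(topSetsLfc, use.names = FALSE),
                           unlist(topSetsSc, use.names = FALSE))))
    kLfc <- kOf(topSetsLfc, genes)
    kSc <- kOf(topSetsSc, genes)
    out <- data.frame(gene = genes, k_lfc = kLfc, k_sc = kSc,
                      p_bonf_lfc = ebp(kLfc, T, params),
                      p_bonf_sc = ebp(kSc, T, params),
                      selected_lfc = kLfc >= params@minK,
                      selected_sc = kSc >= params@minK,
                      row.names = NULL)
    out[order(-pmax(out$k_lfc, out$k_sc), out$gene), , drop = FALSE]
}

#' Run the full pan-tumor screening pipeline
#'
#' Convenience wrapper: [rankGenes()], [topSetsByGroup()],
#' [pairwiseOverlapChi2()] (per method), [medianPercentileTable()] and
#' [selectEbpCulprits()].
#'
#' @param cohort An [ExpressionCohort-class].
#' @param signature A [GeneSignature-class].
#' @param params An [AnalysisParams-class].
#' @return List with elements \code{rankTable}, \code{topSets},
#'   \code{overlapLfc}, \code{overlapSc}, \code{mpr}, \code{ebp}.
#' @export
screenCulprits <- function(cohort, signature, params = analysisParams()) {
    rt <- rankGenes(cohort, signature, params)
    ts <- topSetsByGroup(rt, params)
    G <- length(unique(rt$gene))
    list(rankTable = rt,
         topSets = ts,
         overlapLfc = pairwiseOverlapChi2(ts$lfc, G, params),
         overlapSc = pairwiseOverlapChi2(ts$sc, G, params),
         mpr = medianPercentileTable(rt, params),
         ebp = selectEbpCulprits(ts$lfc, ts$sc, params))
}
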