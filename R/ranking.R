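## Within-group gene ranking against the T-cell-cold state: the LFC method
## (low-vs-high tertile contrast with an empirical-Bayes moderated t) and the
## SC method (Spearman correlation with the signature score), plus the 0-100
## percentile-rank machinery and top-percentile set extraction.

## Solve trigamma(x) = y by Newton iteration on the log scale.
.trigammaInverse <- function(y) {
    if (!is.finite(y) || y <= 0) return(Inf)
    if (y > 1e7) return(1 / sqrt(y))
    if (y < 1e-6) return(1 / y)
    x <- 0.5 + 1 / y
    for (i in 1:75) {
        tri <- trigamma(x)
        dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
        x <- x + dif
        if (abs(dif / x) < 1e-10) break
    }
    x
}

## Fit a scaled inverse chi-square prior to per-gene pooled variances by
## method of moments on log(s2): returns c(df0, s02). df0 = Inf means the
## variances are consistent with a single common value.
.fitVariancePrior <- function(s2, df) {
    z <- suppressWarnings(log(unname(s2)))
    z <- z[is.finite(z)]
    if (length(z) < 2L)
        return(c(df0 = Inf,
                 s02 = if (length(z)) exp(z[1L]) else mean(s2)))
    e <- z - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    evar <- stats::var(e) - trigamma(df / 2)
    if (evar <= 0)
        return(c(df0 = Inf, s02 = exp(emean)))
    df0 <- 2 * .trigammaInverse(evar)
    s02 <- exp(emean + digamma(df0 / 2) - log(df0 / 2))
    c(df0 = df0, s02 = s02)
}

#' Low-vs-high tertile differential expression (LFC method)
#'
#' For one tumor group, contrasts the CD8-Low against the CD8-High tertile:
#' \code{lfc = mean(high) - mean(low)} per gene, so negative values mark
#' genes overexpressed in CD8-Low (cold) tumors. P-values come from an
#' empirical-Bayes moderated t: the per-gene pooled variance is shrunk
#' toward a scaled-inverse-chi-square prior fitted across genes by method of
#' moments on the log variances, and the t statistic is referred to a t
#' distribution with residual + prior degrees of freedom.
#'
#' @param cohort An [ExpressionCohort-class].
#' @param tertiles Named factor from [partitionTertiles()] (levels low, mid,
#'   high) covering at least the group's samples.
#' @param group Group label to analyze.
#' @param priorDf Override for the prior degrees of freedom; \code{NULL}
#'   (default) estimates them from the data, \code{0} disables moderation and
#'   yields the ordinary pooled-variance two-sample t.
#' @return data.frame with one row per gene: \code{gene, lfc, t_mod, p_lfc}.
#' @export
differentialLfc <- function(cohort, tertiles, group, priorDf = NULL) {
    gs <- names(sampleGroups(cohort))[sampleGroups(cohort) == group]
    tert <- tertiles[gs]
    lowIds <- gs[!is.na(tert) & tert == "low"]
    highIds <- gs[!is.na(tert) & tert == "high"]
    n1 <- length(lowIds); n2 <- length(highIds)
    if (n1 < 2L || n2 < 2L)
        .err("smallContextError", "group '", group,
             "' needs >= 2 samples in both low and high tertiles")
    v <- exprValues(cohort)
    lo <- v[, lowIds, drop = FALSE]
    hi <- v[, highIds, drop = FALSE]
    mlo <- rowMeans(lo)
    mhi <- rowMeans(hi)
    lfc <- mhi - mlo
    df <- n1 + n2 - 2L
    if (df < 1L)
        .err("smallContextError", "zero residual degrees of freedom")
    ss <- rowSums((lo - mlo)^2) + rowSums((hi - mhi)^2)
    s2 <- ss / df
    if (is.null(priorDf)) {
        prior <- .fitVariancePrior(s2, df)
        df0 <- prior[["df0"]]; s02 <- prior[["s02"]]
    } else if (priorDf == 0) {
        df0 <- 0; s02 <- 0
    } else {
        df0 <- priorDf
        s02 <- .fitVariancePrior(s2, df)[["s02"]]
    }
    s2post <- if (is.infinite(df0)) rep(s02, length(s2))
              else (df0 * s02 + df * s2) / (df0 + df)
    se <- sqrt(s2post * (1 / n1 + 1 / n2))
    tmod <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
    dfTotal <- df + df0
    p <- 2 * stats::pt(-abs(tmod), df = dfTotal)
    p[lfc == 0 & se == 0] <- 1
    data.frame(gene = rownames(v), lfc = lfc, t_mod = tmod, p_lfc = p,
               row.names = NULL)
}

#' Per-gene Spearman correlation with the signature score (SC method)
#'
#' Tie-corrected Spearman rho of every gene's expression against the immune
#' signature score over one group's samples, irrespective of tertiles, with
#' two-sided p from the t approximation. Genes constant within the group get
#' \code{rho = 0, p = 1} and \code{flagged = TRUE}.
#'
#' @param cohort An [ExpressionCohort-class].
#' @param scores Named numeric signature score vector (see
#'   [metageneScore()]).
#' @param group Group label to analyze (>= 4 samples).
#' @return data.frame with one row per gene: \code{gene, rho, p_sc,
#'   flagged}.
#' @export
spearmanAssoc <- function(cohort, scores, group) {
    gs <- names(sampleGroups(cohort))[sampleGroups(cohort) == group]
    if (length(gs) < 4L)
        .err("smallContextError", "group '", group, "' needs >= 4 samples")
    s <- scores[gs]
    if (stats::sd(s) == 0)
        .err("constantScoreError",
             "signature score constant within group '", group, "'")
    v <- exprValues(cohort)[, gs, drop = FALSE]
    n <- length(gs)
    rx <- t(apply(v, 1L, rank))
    ry <- rank(s)
    flagged <- apply(v, 1L, function(x) stats::sd(x) == 0)
    rho <- suppressWarnings(as.vector(stats::cor(t(rx), ry)))
    rho[flagged] <- 0
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p[abs(rho) >= 1] <- 0
    p[flagged] <- 1
    data.frame(gene = rownames(v), rho = rho, p_sc = p, flagged = flagged,
               row.names = NULL)
}

#' Percentile ranks of a per-gene statistic
#'
#' Genes are sorted so position 1 is the most CD8-Low-associated (the most
#' negative statistic under the default orientation), ties broken by smaller
#' q-value then gene-id order, flagged genes forced to the bottom; the
#' percentile rank is \code{pr = 100 * (G - position + 1) / G}, a bijection
#' onto \{100/G, 200/G, ..., 100\} with position 1 mapped to 100.
#'
#' @param statistic Named numeric per-gene statistic (lfc or rho).
#' @param q Optional per-gene q-values used as first tie-break.
#' @param moreNegativeIsTop If TRUE (default), more negative statistics rank
#'   higher (toward pr = 100).
#' @param flagged Optional logical; flagged genes sort after all others.
#' @return Named numeric percentile ranks in (0, 100].
#' @examples
#' percentileRanks(c(a = -2, b = -1, c = 0, d = 3))  # 100 75 50 25
#' @export
percentileRanks <- function(statistic, q = NULL, moreNegativeIsTop = TRUE,
                            flagged = NULL) {
    G <- length(statistic)
    if (G == 0L) .err("invalidValueError", "empty statistic vector")
    ids <- names(statistic)
    if (is.null(ids)) .err("invalidValueError", "statistic must be named")
    if (is.null(q)) q <- rep(0, G)
    if (is.null(flagged)) flagged <- rep(FALSE, G)
    key <- if (moreNegativeIsTop) statistic else -statistic
    ord <- order(flagged, key, q, ids)
    pr <- numeric(G)
    pr[ord] <- 100 * (G - seq_len(G) + 1) / G
    names(pr) <- ids
    pr
}

#' Top-percentile gene set
#'
#' The genes occupying positions \code{1..floor(f * G)} of the rank order,
#' i.e. those with the largest percentile ranks; with f = 0.01 this is the
#' group's "99th percentile" set.
#'
#' @param pr Named percentile-rank vector from [percentileRanks()].
#' @param params An [AnalysisParams-class]; \code{topFraction} is f.
#' @return Character vector of gene ids, cardinality exactly
#'   \code{floor(f * length(pr))}.
#' @export
topPercentileSet <- function(pr, params = analysisParams()) {
    G <- length(pr)
    n <- floor(params@topFraction * G)
    if (n < 1)
        .err("invalidValueError",
             "topFraction * universe < 1; no genes selectable")
    names(sort(pr, decreasing = TRUE))[seq_len(n)]
}

#' Rank all genes in all tumor groups by both methods
#'
#' The per-group workhorse: computes the signature score, partitions each
#' group into tertiles, runs [differentialLfc()] and [spearmanAssoc()],
#' adjusts p-values (per group, per method, across all genes) and assigns
#' percentile ranks for both methods.
#'
#' @param cohort An [ExpressionCohort-class].
#' @param signature A [GeneSignature-class] (e.g. the CD8 T-cell metagene).
#' @param params An [AnalysisParams-class].
#' @param priorDf Passed to [differentialLfc()].
#' @return data.frame with columns \code{group, gene, lfc, t_mod, p_lfc,
#'   q_lfc, rho, p_sc, q_sc, pr_lfc, pr_sc}.
#' @export
rankGenes <- function(cohort, signature, params = analysisParams(),
                      priorDf = NULL) {
    scores <- metageneScore(cohort, signature)
    grp <- sampleGroups(cohort)
    tert <- partitionTertiles(scores, grp)
    res <- lapply(levels(grp), function(g) {
        de <- differentialLfc(cohort, tert, g, priorDf = priorDf)
        sc <- spearmanAssoc(cohort, scores, g)
        stopifnot(identical(de$gene, sc$gene))
        qLfc <- stats::p.adjust(de$p_lfc, method = params@fdrMethod)
        qSc <- stats::p.adjust(sc$p_sc, method = params@fdrMethod)
        prLfc <- percentileRanks(stats::setNames(de$lfc, de$gene),
                                 q = qLfc)
        prSc <- percentileRanks(stats::setNames(sc$rho, sc$gene),
                                q = qSc, flagged = sc$flagged)
        data.frame(group = g, gene = de$gene, lfc = de$lfc,
                   t_mod = de$t_mod, p_lfc = de$p_lfc, q_lfc = qLfc,
                   rho = sc$rho, p_sc = sc$p_sc, q_sc = qSc,
                   pr_lfc = unname(prLfc[de$gene]),
                   pr_sc = unname(prSc[de$gene]), row.names = NULL)
    })
    do.call(rbind, res)
}

#' Per-group top-percentile sets for both ranking methods
#'
#' @param rankTable Output of [rankGenes()].
#' @param params An [AnalysisParams-class].
#' @return List with elements \code{lfc} and \code{sc}, each a named list of
#'   per-group gene sets.
#' @export
topSetsByGroup <- function(rankTable, params = analysisParams()) {
    byGroup <- split(rankTable, rankTable$group)
    lfc <- lapply(byGroup, function(d)
        topPercentileSet(stats::setNames(d$pr_lfc, d$gene), params))
    sc <- lapply(byGroup, function(d)
        topPercentileSet(stats::setNames(d$pr_sc, d$gene), params))
    list(lfc = lfc, sc = sc)
}
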