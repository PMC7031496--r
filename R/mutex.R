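## Mutual exclusivity / co-occurrence among selected genes within CD8-Low
## tumors: within-group mean binarization, all-pairs Fisher log2 odds ratios,
## threshold-based gene selection, hierarchical clustering, and synexpression
## group extraction.

#' Binarize expression over CD8-Low samples, within groups
#'
#' Restricts the cohort to the low-tertile (cold) samples, then per gene and
#' per group thresholds expression at the mean over that group's low-tertile
#' samples: strictly above the mean codes 1 (high), at or below codes 0
#' (low). Groups are concatenated into one pan-tumor matrix.
#'
#' @param cohort An [ExpressionCohort-class].
#' @param tertiles Named factor from [partitionTertiles()].
#' @param genes Optional subset of gene ids (e.g. the selected CulPRITs).
#' @return A [BinaryMatrix-class].
#' @export
binarizeWithinGroup <- function(cohort, tertiles, genes = NULL) {
    grp <- sampleGroups(cohort)
    v <- exprValues(cohort)
    if (!is.null(genes)) {
        miss <- setdiff(genes, rownames(v))
        if (length(miss))
            .err("invalidValueError", "gene(s) absent from cohort: ",
                 paste(miss, collapse = ", "))
        v <- v[genes, , drop = FALSE]
    }
    cols <- list(); glab <- list()
    for (g in levels(grp)) {
        gs <- names(grp)[grp == g]
        lowIds <- gs[!is.na(tertiles[gs]) & tertiles[gs] == "low"]
        if (length(lowIds) < 2L)
            .err("smallContextError", "group '", g,
                 "' has < 2 low-tertile samples")
        sub <- v[, lowIds, drop = FALSE]
        m <- rowMeans(sub)
        cols[[g]] <- (sub > m) * 1L
        glab[[g]] <- rep(g, length(lowIds))
    }
    mat <- do.call(cbind, cols)
    methods::new("BinaryMatrix", values = mat,
                 group = factor(unlist(glab, use.names = FALSE)))
}

## Haldane-Anscombe-corrected log2 odds ratio of a 2x2 count vector
## c(a, b, c, d) laid out [gene_i=1&gene_j=1, i=1&j=0, i=0&j=1, i=0&j=0].
.log2OrHaldane <- function(a, b, c, d) {
    if (min(a, b, c, d) == 0) {
        a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    }
    log2((a * d) / (b * c))
}

#' All-pairs Fisher exact mutual-exclusivity analysis
#'
#' For every unordered gene pair, cross-tabulates the joint binary states
#' over all concatenated samples and computes (i) the log2 odds ratio from
#' the cross-product, with the Haldane-Anscombe 0.5 correction applied to
#' every cell when any cell is zero (point estimate only); (ii) the
#' two-sided Fisher exact p-value on the uncorrected table (sum of
#' hypergeometric probabilities no larger than the observed table's); and
#' (iii) BH q-values over all testable pairs. Negative log2 ORs indicate
#' mutual exclusion, positive co-occurrence. Pairs involving a degenerate
#' gene (all 0 or all 1) are NA and excluded from the q computation.
#'
#' @param binary A [BinaryMatrix-class].
#' @param genes Optional gene subset.
#' @return A [MutexResult-class].
#' @export
pairwiseFisher <- function(binary, genes = NULL) {
    m <- binaryValues(binary)
    if (!is.null(genes)) m <- m[genes, , drop = FALSE]
    n <- nrow(m)
    if (n < 2L) .err("invalidValueError", ">= 2 genes required")
    if (ncol(m) < 4L) .err("invalidValueError", ">= 4 samples required")
    rs <- rowSums(m)
    degenerate <- rs == 0L | rs == ncol(m)
    if (any(degenerate))
        warning(sum(degenerate), " degenerate gene(s) (all-0/all-1) ",
                "flagged; their pairs are excluded from q computation")
    lor <- p <- matrix(NA_real_, n, n, dimnames = list(rownames(m),
                                                       rownames(m)))
    N <- ncol(m)
    ## a = both high; joint counts for all pairs at once
    A <- tcrossprod(m)
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            a <- A[i, j]
            b <- rs[i] - a
            c <- rs[j] - a
            d <- N - a - b - c
            lor[i, j] <- lor[j, i] <- .log2OrHaldane(a, b, c, d)
            if (!degenerate[i] && !degenerate[j]) {
                pv <- stats::fisher.test(matrix(c(a, b, c, d), 2L, 2L),
                                         alternative = "two.sided")$p.value
                p[i, j] <- p[j, i] <- pv
            }
        }
    }
    q <- matrix(NA_real_, n, n, dimnames = dimnames(p))
    ut <- upper.tri(p)
    testable <- ut & !is.na(p)
    q[testable] <- stats::p.adjust(p[testable], method = "BH")
    q[lower.tri(q)] <- t(q)[lower.tri(q)]
    methods::new("MutexResult", log2or = lor, p = p, q = q)
}

#' Select genes participating in significant mutually exclusive pairs
#'
#' Returns the genes belonging to at least one pair whose log2 odds ratio
#' falls on the configured side of \code{orCutoff} and whose q-value is
#' below \code{qCutoff}. The default direction \code{"below"} with a
#' negative cutoff selects mutual exclusion; \code{"above"} selects
#' co-occurrence.
#'
#' @param mutex A [MutexResult-class].
#' @param orCutoff log2 OR cutoff (default from \code{params}).
#' @param qCutoff q cutoff (default from \code{params}).
#' @param orDirection \code{"below"} or \code{"above"}.
#' @param params An [AnalysisParams-class] supplying defaults.
#' @return Character vector of gene ids (possibly empty).
#' @export
thresholdMutexGenes <- function(mutex, orCutoff = params@mutexOrCutoff,
                                qCutoff = params@mutexQCutoff,
                                orDirection = c("below", "above"),
                                params = analysisParams()) {
    orDirection <- match.arg(orDirection)
    lor <- log2OddsRatios(mutex)
    q <- qValues(mutex)
    hit <- if (orDirection == "below") lor < orCutoff else lor > orCutoff
    hit <- hit & q < qCutoff
    hit[is.na(hit)] <- FALSE
    rownames(lor)[rowSums(hit) > 0]
}

#' Hierarchical clustering of genes on Spearman correlation distance
#'
#' Agglomerative complete-linkage clustering with distance
#' \code{1 - Spearman rho} between per-gene feature vectors — applicable both
#' to expression profiles and to rows of the log2 odds-ratio matrix. Genes
#' with constant features (undefined correlation) are excluded with a
#' warning. The children of the dendrogram root define the cluster labels,
#' C1 and C2 by descending size (ties by gene-id order of the first member).
#'
#' @param features Numeric matrix, genes x features. NA entries (e.g. the
#'   masked diagonal of an odds-ratio matrix) are ignored pairwise;
#'   infinities are rejected.
#' @param k Number of clusters to cut (default 2).
#' @return A [GeneClusterSet-class].
#' @export
clusterGenes <- function(features, k = 2L) {
    if (nrow(features) < 2L) .err("invalidValueError", ">= 2 genes required")
    if (any(is.infinite(features)))
        .err("invalidValueError", "features must not contain infinities")
    const <- apply(features, 1L,
                   function(x) stats::sd(x, na.rm = TRUE) == 0)
    if (any(const)) {
        warning(sum(const), " constant gene vector(s) excluded")
        features <- features[!const, , drop = FALSE]
        if (nrow(features) < 2L)
            .err("invalidValueError", "< 2 non-constant genes")
    }
    rho <- stats::cor(t(features), method = "spearman",
                      use = "pairwise.complete.obs")
    h <- stats::hclust(stats::as.dist(1 - rho), method = "complete")
    cut <- stats::cutree(h, k = min(k, nrow(features)))
    sizes <- sort(table(cut), decreasing = TRUE)
    relabel <- stats::setNames(paste0("C", seq_along(sizes)), names(sizes))
    labels <- relabel[as.character(cut)]
    names(labels) <- names(cut)
    avg <- vapply(unique(labels), function(cl) {
        g <- names(labels)[labels == cl]
        if (length(g) < 2L) return(NA_real_)
        sub <- rho[g, g]
        mean(sub[upper.tri(sub)])
    }, numeric(1))
    methods::new("GeneClusterSet", tree = h, labels = labels, avgCorr = avg)
}

## Member leaves of every internal node of an hclust tree.
.nodeMembers <- function(tree) {
    n <- nrow(tree$merge)
    members <- vector("list", n)
    for (i in seq_len(n)) {
        kids <- tree$merge[i, ]
        members[[i]] <- unlist(lapply(kids, function(kk)
            if (kk < 0) tree$labels[-kk] else members[[kk]]))
    }
    members
}

#' Synexpression groups: correlated dendrogram subtrees
#'
#' Scans the dendrogram root-to-leaf and reports the maximal subtrees whose
#' mean pairwise Spearman correlation reaches \code{minAvgCorr}; once a
#' subtree qualifies, descent stops, so reported clusters are disjoint.
#' Singletons are never reported.
#'
#' @param corMatrix Symmetric gene x gene Spearman correlation matrix.
#' @param tree \code{\link[stats]{hclust}} tree over the same genes (e.g.
#'   from [clusterGenes()] via [clusterTree()]).
#' @param minAvgCorr Minimum average pairwise correlation R (default 0.15).
#' @return List of character vectors, one per qualifying cluster, in
#'   dendrogram order.
#' @export
synexpressionGroups <- function(corMatrix, tree, minAvgCorr = 0.15) {
    if (!all(tree$labels %in% rownames(corMatrix)))
        .err("invalidValueError",
             "correlation matrix must cover all tree genes")
    members <- .nodeMembers(tree)
    avgCorr <- function(g) {
        sub <- corMatrix[g, g]
        mean(sub[upper.tri(sub)])
    }
    out <- list()
    visit <- function(node) {
        if (node < 0) return(invisible())  # singleton leaf
        g <- members[[node]]
        if (avgCorr(g) >= minAvgCorr) {
            out[[length(out) + 1L]] <<- g
        } else {
            visit(tree$merge[node, 1L])
            visit(tree$merge[node, 2L])
        }
    }
    visit(nrow(tree$merge))
    out
}
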