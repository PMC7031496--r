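## Metagene scoring and sample stratification.

#' Metagene score of a gene signature
#'
#' The per-sample score is the geometric mean of the log2 expression values
#' of the signature members: \code{score_s = (prod_g v_gs)^(1/m)} over the m
#' members present in the cohort. Because the geometric mean is taken of the
#' log2 values themselves, any member with value 0 zeroes the sample's score.
#' Members absent from the cohort are dropped with a warning; if none remain
#' an error is raised.
#'
#' @param cohort An [ExpressionCohort-class].
#' @param signature A [GeneSignature-class].
#' @return Named numeric vector of scores, one per sample, with attribute
#'   \code{"signature"} set to the signature name.
#' @examples
#' m <- rbind(CD8A = c(1, 2), CD8B = c(2, 2), CD3D = c(4, 2), CD3E = c(8, 2))
#' colnames(m) <- c("s1", "s2")
#' cohort <- ExpressionCohort(m, group = c("A", "A"))
#' metageneScore(cohort, GeneSignature("TSIG", rownames(m)))
#' # s1 = (1*2*4*8)^(1/4) = 2.8284, s2 = 2
#' @export
metageneScore <- function(cohort, signature) {
    members <- signatureMembers(signature)
    present <- intersect(members, geneIds(cohort))
    absent <- setdiff(members, present)
    if (length(absent))
        warning("signature '", signatureName(signature), "': ",
                length(absent), " member(s) absent from cohort dropped: ",
                paste(absent, collapse = ", "))
    if (!length(present))
        .err("emptySignatureError", "no signature members present in cohort")
    v <- exprValues(cohort)[present, , drop = FALSE]
    # geometric mean via logs; a zero member annihilates the product
    score <- apply(v, 2L, function(x)
        if (any(x == 0)) 0 else exp(mean(log(x))))
    attr(score, "signature") <- signatureName(signature)
    score
}

## Balanced rank-based partition into k blocks: samples sorted ascending by
## score, ties broken by sample-id order; block sizes differ by <= 1 with
## extras assigned to the earliest (lowest) blocks.
.balancedPartition <- function(score, ids, k, labels) {
    n <- length(score)
    ord <- order(score, ids)
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    lab <- rep(labels, times = sizes)
    out <- character(n)
    out[ord] <- lab
    names(out) <- ids
    out
}

.partitionStrata <- function(scores, context, k, labels, minN) {
    if (is.null(names(scores)))
        .err("invalidValueError", "scores must be named by sample")
    context <- as.factor(context)
    if (length(context) != length(scores))
        .err("invalidValueError", "context must have one label per sample")
    out <- character(length(scores))
    names(out) <- names(scores)
    for (ctx in levels(context)) {
        idx <- which(context == ctx)
        if (length(idx) < minN)
            .err("smallContextError", "context '", ctx, "' has ",
                 length(idx), " sample(s); >= ", minN, " required")
        out[idx] <- .balancedPartition(scores[idx], names(scores)[idx],
                                       k, labels)
    }
    factor(out, levels = labels)
}

#' Partition samples into tertiles of a signature score
#'
#' Within each context (typically the tumor group), samples are sorted
#' ascending by score (ties broken by sample-id order) and split into three
#' near-equal blocks; block sizes differ by at most 1, extras going to the
#' lowest blocks first. The \code{"low"} block is the CD8-Low (cold)
#' stratum.
#'
#' @param scores Named numeric score vector (see [metageneScore()]).
#' @param context Factor/character of per-sample context labels (e.g. the
#'   tumor group); each context needs >= 3 samples.
#' @return Named factor with levels \code{low, mid, high}.
#' @examples
#' s <- setNames(1:10, paste0("s", sprintf("%02d", 1:10)))
#' table(partitionTertiles(s, rep("g", 10)))  # 4/3/3
#' @export
partitionTertiles <- function(scores, context) {
    .partitionStrata(scores, context, 3L, c("low", "mid", "high"), 3L)
}

#' Partition samples into quartiles of a signature score
#'
#' As [partitionTertiles()] but into four blocks \code{Q1..Q4}, Q1 being the
#' lowest-score quartile. Each context needs >= 4 samples.
#'
#' @inheritParams partitionTertiles
#' @return Named factor with levels \code{Q1, Q2, Q3, Q4}.
#' @export
partitionQuartiles <- function(scores, context) {
    .partitionStrata(scores, context, 4L, paste0("Q", 1:4), 4L)
}

## Spearman rho with tie-corrected ranks plus two-sided p via the
## t approximation (as stats::cor.test with exact = FALSE).
.spearmanRhoP <- function(x, y) {
    n <- length(x)
    rx <- rank(x)
    ry <- rank(y)
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
        return(c(rho = NA_real_, p = NA_real_))
    rho <- stats::cor(rx, ry)
    if (abs(rho) >= 1) return(c(rho = rho, p = 0))
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    c(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Correlate signature scores with a numeric sample annotation
#'
#' Spearman rank correlation of the score against an external per-sample
#' measurement, computed within each context; pairs with missing values are
#' dropped. Contexts where either vector is constant are flagged with NA.
#'
#' @param scores Named numeric score vector.
#' @param annotation Numeric vector of per-sample values, aligned with
#'   \code{scores} (names used if present).
#' @param context Per-sample context labels; default a single context.
#' @return data.frame with columns \code{context, n, rho, p}.
#' @export
scoreAnnotationCorrelation <- function(scores, annotation,
        context = rep("all", length(scores))) {
    if (!is.null(names(annotation)))
        annotation <- annotation[names(scores)]
    context <- as.factor(context)
    res <- lapply(levels(context), function(ctx) {
        idx <- which(context == ctx)
        ok <- idx[!is.na(scores[idx]) & !is.na(annotation[idx])]
        if (length(ok) < 3L)
            .err("smallContextError", "context '", ctx,
                 "' has < 3 paired values")
        rp <- .spearmanRhoP(scores[ok], annotation[ok])
        data.frame(context = ctx, n = length(ok), rho = rp[["rho"]],
                   p = rp[["p"]])
    })
    do.call(rbind, res)
}
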