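## Treatment-cohort outcome analyses: signature quartiles vs immunotherapy
## response (Fisher exact) and overall survival (Kaplan-Meier / log-rank).

#' Score signatures and assign quartiles in a treatment cohort
#'
#' Computes the metagene score of each signature and partitions samples into
#' score quartiles independently within the pre-treatment and on-treatment
#' strata (Q1 = lowest scores).
#'
#' @param cohort An [ExpressionCohort-class] of the treatment cohort.
#' @param signatures List of [GeneSignature-class] (e.g. C1, C2, TSIG).
#' @param clinical A [ClinicalTable-class] covering all cohort samples.
#' @return A \code{DataFrame} with \code{sample_id}, \code{timing}, and per
#'   signature \code{<name>_score} and \code{<name>_quartile} columns.
#' @export
scoreTreatmentCohort <- function(cohort, signatures, clinical) {
    ids <- sampleIds(cohort)
    miss <- setdiff(ids, clinical$sample_id)
    if (length(miss))
        .err("unannotatedSampleError", "sample(s) missing from clinical: ",
             paste(miss, collapse = ", "))
    timing <- clinical$timing[match(ids, clinical$sample_id)]
    if (anyNA(timing))
        .err("invalidValueError", "timing label required for every sample")
    out <- S4Vectors::DataFrame(sample_id = ids, timing = timing,
                                row.names = ids)
    if (methods::is(signatures, "GeneSignature"))
        signatures <- list(signatures)
    for (sig in signatures) {
        sc <- metageneScore(cohort, sig)
        qt <- partitionQuartiles(sc, timing)
        out[[paste0(signatureName(sig), "_score")]] <- unname(sc)
        out[[paste0(signatureName(sig), "_quartile")]] <- unname(qt)
    }
    out
}

#' Fisher exact tests of response by signature quartile
#'
#' Responders are CR/PR, non-responders SD/PD; NE samples are excluded.
#' Tests two 2x2 tables: responder status crossed with (Q1 vs Q4) and with
#' (Q1 vs Q2+Q3), two-sided Fisher exact each.
#'
#' @param quartiles Named factor of quartile labels (\code{Q1..Q4}) per
#'   sample, e.g. a column of [scoreTreatmentCohort()] named by sample.
#' @param clinical A [ClinicalTable-class].
#' @return List: \code{counts} (responder x quartile contingency matrix over
#'   the evaluable samples), \code{p_q1_vs_q4}, \code{p_q1_vs_q23},
#'   \code{responderDef}.
#' @export
responseQuartileTest <- function(quartiles, clinical) {
    ids <- names(quartiles)
    if (is.null(ids))
        .err("invalidValueError", "quartiles must be named by sample")
    resp <- clinical$response[match(ids, clinical$sample_id)]
    keep <- !is.na(resp) & resp != "NE"
    if (!any(keep))
        .err("emptyStratumError", "no evaluable samples after NE exclusion")
    qt <- factor(as.character(quartiles[keep]), levels = paste0("Q", 1:4))
    responder <- factor(ifelse(resp[keep] %in% c("CR", "PR"),
                               "responder", "non_responder"),
                        levels = c("responder", "non_responder"))
    counts <- table(responder, quartile = qt)
    if (any(colSums(counts)[c("Q1", "Q4")] == 0))
        .err("emptyStratumError", "empty quartile stratum after exclusion")
    tabQ1Q4 <- counts[, c("Q1", "Q4")]
    tabQ1Q23 <- cbind(Q1 = counts[, "Q1"],
                      `Q2+Q3` = counts[, "Q2"] + counts[, "Q3"])
    list(counts = counts,
         p_q1_vs_q4 = stats::fisher.test(tabQ1Q4)$p.value,
         p_q1_vs_q23 = stats::fisher.test(tabQ1Q23)$p.value,
         responderDef = "CR/PR vs SD/PD, NE excluded")
}

#' Kaplan-Meier curves and log-rank test across groups
#'
#' Product-limit survival estimate per group plus the standard (unweighted)
#' k-group log-rank test. With zero observed events the statistic is 0 and
#' p = 1.
#'
#' @param clinical A [ClinicalTable-class].
#' @param groups Named character/factor of group labels per sample (e.g.
#'   quartiles, or \code{Q1} vs \code{Q2-Q4} pooled); samples with NA are
#'   dropped.
#' @return List: \code{curves} (data.frame \code{group, time, n_risk,
#'   n_event, surv}), \code{chisq}, \code{df}, \code{p}, \code{n}.
#' @export
kmLogrank <- function(clinical, groups) {
    ids <- names(groups)
    if (is.null(ids))
        .err("invalidValueError", "groups must be named by sample")
    idx <- match(ids, clinical$sample_id)
    keep <- !is.na(idx) & !is.na(groups)
    g <- factor(as.character(groups[keep]))
    if (nlevels(g) < 2L)
        .err("invalidValueError", ">= 2 non-empty groups required")
    time <- clinical$os_time[idx[keep]]
    event <- clinical$os_event[idx[keep]]
    fit <- survival::survfit(survival::Surv(time, event) ~ g)
    st <- summary(fit)
    strat <- if (is.null(st$strata)) rep(levels(g)[1L], length(st$time))
             else sub("^g=", "", as.character(st$strata))
    curves <- data.frame(group = strat, time = st$time,
                         n_risk = st$n.risk, n_event = st$n.event,
                         surv = st$surv, row.names = NULL)
    if (sum(event) == 0) {
        chisq <- 0; df <- nlevels(g) - 1L; p <- 1
    } else {
        sd <- survival::survdiff(survival::Surv(time, event) ~ g)
        chisq <- unname(sd$chisq)
        df <- length(sd$n) - 1L
        p <- stats::pchisq(chisq, df = df, lower.tail = FALSE)
    }
    list(curves = curves, chisq = chisq, df = df, p = p, n = sum(keep))
}

#' Spearman correlation between two signature score vectors
#'
#' @param scoresA,scoresB Named numeric score vectors over the same samples.
#' @return List with \code{rho} and two-sided \code{p}.
#' @export
signatureScoreCorrelation <- function(scoresA, scoresB) {
    if (!is.null(names(scoresA)) && !is.null(names(scoresB)))
        scoresB <- scoresB[names(scoresA)]
    if (length(scoresA) < 3L)
        .err("smallContextError", ">= 3 paired scores required")
    if (stats::sd(scoresA) == 0 || stats::sd(scoresB) == 0)
        .err("constantScoreError", "constant score vector")
    rp <- .spearmanRhoP(scoresA, scoresB)
    list(rho = unname(rp[["rho"]]), p = unname(rp[["p"]]))
}
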