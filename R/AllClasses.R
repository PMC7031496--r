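#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ExpressionCohort: a grouped log2-expression matrix
#'
#' The universal input container of the package: a genes x samples matrix of
#' \code{log2(normalized count + 1)} values together with a tumor-group label
#' per sample, stored as a \linkS4class{SummarizedExperiment} with a single
#' assay \code{"logexpr"} and a \code{group} column in \code{colData}.
#'
#' @slot .
#'   Inherits all slots from \linkS4class{SummarizedExperiment}.
#'
#' @section Validity:
#' All values must be finite and non-negative; gene and sample identifiers
#' must be unique; every sample carries exactly one group label and every
#' group has at least 2 samples.
#'
#' @seealso [ExpressionCohort()] for the constructor, [exprValues()],
#'   [sampleGroups()], [geneIds()], [sampleIds()] for accessors.
#' @exportClass ExpressionCohort
setClass("ExpressionCohort", contains = "SummarizedExperiment")

setValidity("ExpressionCohort", function(object) {
    msg <- character()
    if (!"logexpr" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'logexpr' is required")
    else {
        v <- SummarizedExperiment::assay(object, "logexpr")
        if (!is.numeric(v))
            msg <- c(msg, "'logexpr' must be numeric")
        else if (any(!is.finite(v)))
            msg <- c(msg, "all expression values must be finite")
        else if (any(v < 0))
            msg <- c(msg, "all expression values must be >= 0 (log2(x+1) scale)")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be present and unique")
    if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    else {
        g <- SummarizedExperiment::colData(object)$group
        if (anyNA(g))
            msg <- c(msg, "every sample must have a group label")
        else if (any(table(g) < 2))
            msg <- c(msg, "every group must contain at least 2 samples")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionCohort
#'
#' @param values Numeric matrix of log2(normalized count + 1) expression,
#'   genes as rows, samples as columns, with unique dimnames.
#' @param group Character or factor of tumor-group labels, one per column of
#'   \code{values} (recycled names are matched positionally).
#' @return A validated [ExpressionCohort-class] object.
#' @examples
#' m <- matrix(abs(rnorm(12)), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ExpressionCohort(m, group = c("A", "A", "B", "B"))
#' @export
ExpressionCohort <- function(values, group) {
    values <- as.matrix(values)
    group <- factor(group)
    if (length(group) != ncol(values))
        stop("'group' must have one label per sample")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(logexpr = values),
        colData = S4Vectors::DataFrame(group = group, row.names = colnames(values)))
    methods::new("ExpressionCohort", se)
}

#' GeneSignature: a named gene set
#'
#' A small set of gene identifiers summarized into a per-sample metagene
#' score, e.g. the 4-gene CD8+ T-cell identity signature (CD8A, CD8B, CD3D,
#' CD3E) or the cytolytic-activity signature (GZMA, GZMB, GNLY, PRF1).
#'
#' @slot name Single character label.
#' @slot members Non-empty character vector of unique gene identifiers.
#' @seealso [metageneScore()], [readGeneSetsGmt()]
#' @exportClass GeneSignature
setClass("GeneSignature",
    representation(name = "character", members = "character"))

setValidity("GeneSignature", function(object) {
    msg <- character()
    if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    if (length(object@members) == 0L)
        msg <- c(msg, "'members' must be non-empty")
    if (anyDuplicated(object@members))
        msg <- c(msg, "'members' must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSignature
#'
#' Duplicate members are removed with a warning (set semantics).
#'
#' @param name Signature label.
#' @param members Character vector of gene identifiers.
#' @return A [GeneSignature-class] object.
#' @examples
#' GeneSignature("TSIG", c("CD8A", "CD8B", "CD3D", "CD3E"))
#' @export
GeneSignature <- function(name, members) {
    members <- as.character(members)
    if (anyDuplicated(members)) {
        warning("duplicate members in signature '", name, "' removed")
        members <- unique(members)
    }
    methods::new("GeneSignature", name = as.character(name), members = members)
}

setMethod("show", "GeneSignature", function(object) {
    cat("GeneSignature '", object@name, "' with ", length(object@members),
        " member(s): ", sep = "")
    m <- object@members
    cat(paste(utils::head(m, 6), collapse = ", "))
    if (length(m) > 6) cat(", ...")
    cat("\n")
})

#' AnalysisParams: the shared parameter registry
#'
#' Holds every tunable threshold of the screening pipeline.
#'
#' @slot topFraction Fraction f of genes forming a group's top-percentile set
#'   (default 0.01, i.e. the 99th percentile).
#' @slot universeSize Number G of ranked genes; also the Bonferroni factor of
#'   the exact binomial recurrence probability (default 20501).
#' @slot mprMin Median-percentile-rank selection cutoff, inclusive
#'   (default 75).
#' @slot medianQMax Median FDR q cutoff for MPR selection, inclusive
#'   (default 0.1).
#' @slot minK Minimum number of groups in which a gene must reach the
#'   top-percentile set for EBP selection (default 5, for 23 groups).
#' @slot mutexOrCutoff log2 odds-ratio cutoff for mutual-exclusivity gene
#'   selection (default -1).
#' @slot mutexQCutoff FDR q cutoff for mutual-exclusivity gene selection
#'   (default 1e-30).
#' @slot synexprMinCorr Minimum average pairwise Spearman correlation R of a
#'   reported synexpression cluster (default 0.15).
#' @slot fdrMethod Multiple-testing procedure passed to
#'   \code{\link[stats]{p.adjust}} (default "BH").
#' @exportClass AnalysisParams
setClass("AnalysisParams",
    representation(topFraction = "numeric", universeSize = "numeric",
        mprMin = "numeric", medianQMax = "numeric", minK = "numeric",
        mutexOrCutoff = "numeric", mutexQCutoff = "numeric",
        synexprMinCorr = "numeric", fdrMethod = "character"))

setValidity("AnalysisParams", function(object) {
    msg <- character()
    ok1 <- function(x) length(x) == 1L && is.finite(x)
    if (!ok1(object@topFraction) || object@topFraction <= 0 ||
        object@topFraction >= 1)
        msg <- c(msg, "topFraction must be in (0, 1)")
    if (!ok1(object@universeSize) || object@universeSize < 1)
        msg <- c(msg, "universeSize must be >= 1")
    if (!ok1(object@mprMin) || object@mprMin < 0 || object@mprMin > 100)
        msg <- c(msg, "mprMin must be in [0, 100]")
    if (!ok1(object@medianQMax) || !ok1(object@minK) ||
        !ok1(object@mutexOrCutoff) || !ok1(object@mutexQCutoff) ||
        !ok1(object@synexprMinCorr))
        msg <- c(msg, "all thresholds must be finite scalars")
    if (length(msg)) msg else TRUE
})

#' Construct an AnalysisParams registry
#'
#' @param topFraction,universeSize,mprMin,medianQMax,minK,mutexOrCutoff,mutexQCutoff,synexprMinCorr,fdrMethod
#'   See [AnalysisParams-class] for meanings and defaults.
#' @return An [AnalysisParams-class] object.
#' @examples
#' analysisParams()                      # defaults (23-group TCGA geometry)
#' analysisParams(minK = 3)              # scaled-down recurrence cutoff
#' @export
analysisParams <- function(topFraction = 0.01, universeSize = 20501,
        mprMin = 75, medianQMax = 0.1, minK = 5, mutexOrCutoff = -1,
        mutexQCutoff = 1e-30, synexprMinCorr = 0.15, fdrMethod = "BH") {
    methods::new("AnalysisParams", topFraction = topFraction,
        universeSize = universeSize, mprMin = mprMin,
        medianQMax = medianQMax, minK = minK,
        mutexOrCutoff = mutexOrCutoff, mutexQCutoff = mutexQCutoff,
        synexprMinCorr = synexprMinCorr, fdrMethod = fdrMethod)
}

setMethod("show", "AnalysisParams", function(object) {
    cat("AnalysisParams:\n",
        "  topFraction    = ", object@topFraction, "\n",
        "  universeSize   = ", object@universeSize, "\n",
        "  mprMin         = ", object@mprMin, "\n",
        "  medianQMax     = ", object@medianQMax, "\n",
        "  minK           = ", object@minK, "\n",
        "  mutexOrCutoff  = ", object@mutexOrCutoff, "\n",
        "  mutexQCutoff   = ", object@mutexQCutoff, "\n",
        "  synexprMinCorr = ", object@synexprMinCorr, "\n",
        "  fdrMethod      = ", object@fdrMethod, "\n", sep = "")
})

#' ClinicalTable: treatment-cohort annotations
#'
#' A \linkS4class{DFrame} subclass whose rows are samples of a treatment
#' cohort, with required columns \code{sample_id}, \code{cohort} (e.g.
#' Ipi-Naive / Ipi-Prog), \code{timing} ("pre"/"on" treatment biopsy),
#' \code{response} (RECIST: CR, PR, SD, PD, NE), \code{os_time} (days),
#' \code{os_event} (0 censored / 1 death).
#'
#' @exportClass ClinicalTable
setClass("ClinicalTable", contains = "DFrame")

.RESPONSE_LEVELS <- c("CR", "PR", "SD", "PD", "NE")
.TIMING_LEVELS <- c("pre", "on")

setValidity("ClinicalTable", function(object) {
    msg <- character()
    need <- c("sample_id", "cohort", "timing", "response", "os_time",
              "os_event")
    miss <- setdiff(need, colnames(object))
    if (length(miss))
        return(paste("missing column(s):", paste(miss, collapse = ", ")))
    if (anyDuplicated(object$sample_id))
        msg <- c(msg, "sample_id must be unique")
    if (!all(object$timing %in% .TIMING_LEVELS))
        msg <- c(msg, "timing must be 'pre' or 'on'")
    if (!all(object$response %in% .RESPONSE_LEVELS))
        msg <- c(msg, paste("response must be one of",
                            paste(.RESPONSE_LEVELS, collapse = "/")))
    if (!is.numeric(object$os_time) || any(!is.finite(object$os_time)) ||
        any(object$os_time < 0))
        msg <- c(msg, "os_time must be finite and >= 0")
    if (!all(object$os_event %in% c(0, 1)))
        msg <- c(msg, "os_event must be 0 or 1")
    if (length(msg)) msg else TRUE
})

#' Construct a ClinicalTable
#'
#' @param df data.frame (or DataFrame) with columns \code{sample_id},
#'   \code{cohort}, \code{timing}, \code{response}, \code{os_time},
#'   \code{os_event}.
#' @return A validated [ClinicalTable-class].
#' @export
ClinicalTable <- function(df) {
    d <- S4Vectors::DataFrame(as.data.frame(df))
    rownames(d) <- d$sample_id
    methods::new("ClinicalTable", d)
}

#' GeneratorConfig: synthetic-cohort generator settings
#'
#' Parameters of the planted-structure expression generator. A single latent
#' infiltration factor z per sample drives the planted signal: signature
#' genes load positively on z, culprit genes load negatively (in the affected
#' groups only), and two mutually exclusive expression programs A/B activate
#' in cold (low-z) samples.
#'
#' @slot nGroups Number of tumor groups T.
#' @slot samplesPerGroup Samples per group (scalar or length-T).
#' @slot nGenes Total number of genes G.
#' @slot baseline Baseline log2 expression alpha (default 5).
#' @slot noiseSd Gene-level Gaussian noise sd sigma (> 0; default 1).
#' @slot signatureEffect Loading beta > 0 of signature genes on z (default 1).
#' @slot nSignature Number of signature genes (default 4, mirroring the
#'   4-gene CD8 metagenes).
#' @slot nCulprits Number of planted culprit genes (default 50).
#' @slot culpritEffect Negative loading gamma >= 0 of culprits on z
#'   (default 1).
#' @slot culpritGroups Indices of groups carrying the culprit effect
#'   (default 1..8 of 10).
#' @slot programSizeA,programSizeB Sizes of planted programs A and B
#'   (default 20 each).
#' @slot programEffect Additive activation effect delta (default 1.5).
#' @slot programProb Probability pi that a cold sample activates program A
#'   rather than B (default 0.5).
#' @slot seed Integer RNG seed.
#' @seealso [generatorConfig()], [generatePanTumor()],
#'   [generateTreatmentCohort()]
#' @exportClass GeneratorConfig
setClass("GeneratorConfig",
    representation(nGroups = "numeric", samplesPerGroup = "numeric",
        nGenes = "numeric", baseline = "numeric", noiseSd = "numeric",
        signatureEffect = "numeric", nSignature = "numeric",
        nCulprits = "numeric", culpritEffect = "numeric",
        culpritGroups = "numeric", programSizeA = "numeric",
        programSizeB = "numeric", programEffect = "numeric",
        programProb = "numeric", seed = "numeric"))

setValidity("GeneratorConfig", function(object) {
    msg <- character()
    if (object@nGroups < 1)
        msg <- c(msg, "nGroups must be >= 1")
    if (!length(object@samplesPerGroup) %in% c(1L, object@nGroups) ||
        any(object@samplesPerGroup < 2))
        msg <- c(msg, "samplesPerGroup must be >= 2, scalar or per-group")
    planted <- object@nSignature + object@nCulprits + object@programSizeA +
        object@programSizeB
    if (planted > object@nGenes)
        msg <- c(msg, "planted gene counts exceed nGenes")
    if (object@noiseSd <= 0)
        msg <- c(msg, "noiseSd must be > 0")
    if (object@signatureEffect <= 0)
        msg <- c(msg, "signatureEffect must be > 0")
    if (object@culpritEffect < 0)
        msg <- c(msg, "culpritEffect must be >= 0")
    if (length(object@culpritGroups) &&
        (any(object@culpritGroups < 1) ||
         any(object@culpritGroups > object@nGroups)))
        msg <- c(msg, "culpritGroups out of range")
    if (object@programProb < 0 || object@programProb > 1)
        msg <- c(msg, "programProb must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneratorConfig
#'
#' Defaults describe the standard simulated pan-tumor study: 10 tumor groups
#' of 120 samples, 2,000 genes, 50 culprits with unit negative loading in 8
#' of the 10 groups, unit noise, and two 20-gene mutually exclusive programs
#' with activation effect 1.5.
#'
#' @param nGroups,samplesPerGroup,nGenes,baseline,noiseSd,signatureEffect,nSignature,nCulprits,culpritEffect,culpritGroups,programSizeA,programSizeB,programEffect,programProb,seed
#'   See [GeneratorConfig-class].
#' @return A [GeneratorConfig-class] object.
#' @examples
#' generatorConfig(seed = 1)
#' @export
generatorConfig <- function(nGroups = 10, samplesPerGroup = 120,
        nGenes = 2000, baseline = 5, noiseSd = 1, signatureEffect = 1,
        nSignature = 4, nCulprits = 50, culpritEffect = 1,
        culpritGroups = seq_len(min(8, nGroups)), programSizeA = 20,
        programSizeB = 20, programEffect = 1.5, programProb = 0.5,
        seed = 1L) {
    methods::new("GeneratorConfig", nGroups = nGroups,
        samplesPerGroup = samplesPerGroup, nGenes = nGenes,
        baseline = baseline, noiseSd = noiseSd,
        signatureEffect = signatureEffect, nSignature = nSignature,
        nCulprits = nCulprits, culpritEffect = culpritEffect,
        culpritGroups = culpritGroups, programSizeA = programSizeA,
        programSizeB = programSizeB, programEffect = programEffect,
        programProb = programProb, seed = seed)
}

#' PlantedTruth: ground truth of a synthetic cohort
#'
#' @slot z Named numeric, per-sample latent infiltration factor.
#' @slot roleOf Named character, gene -> one of "signature", "culprit",
#'   "programA", "programB", "null".
#' @slot programOf Named character, sample -> "A", "B" or "none".
#' @slot effects List of the effect sizes used.
#' @exportClass PlantedTruth
setClass("PlantedTruth",
    representation(z = "numeric", roleOf = "character",
        programOf = "character", effects = "list"))

setMethod("show", "PlantedTruth", function(object) {
    cat("PlantedTruth:", length(object@z), "samples,",
        length(object@roleOf), "genes\n  gene roles:\n")
    print(table(object@roleOf))
})

#' BinaryMatrix: binarized expression over CD8-Low samples
#'
#' Genes x samples 0/1 matrix obtained by thresholding each gene at its
#' within-group mean over the low-tertile (cold) samples only, concatenated
#' across groups.
#'
#' @slot values 0/1 integer matrix, genes x samples.
#' @slot group Factor, source tumor group per sample (column).
#' @exportClass BinaryMatrix
setClass("BinaryMatrix",
    representation(values = "matrix", group = "factor"))

setValidity("BinaryMatrix", function(object) {
    msg <- character()
    if (!all(object@values %in% c(0L, 1L)))
        msg <- c(msg, "entries must be 0/1")
    if (length(object@group) != ncol(object@values))
        msg <- c(msg, "one group label per sample required")
    if (length(msg)) msg else TRUE
})

setMethod("show", "BinaryMatrix", function(object) {
    cat("BinaryMatrix:", nrow(object@values), "genes x",
        ncol(object@values), "low-tertile samples in",
        nlevels(object@group), "group(s)\n")
})

#' MutexResult: all-pairs Fisher odds-ratio matrices
#'
#' Symmetric gene x gene matrices of Haldane-corrected log2 odds ratios
#' (negative = mutual exclusion, positive = co-occurrence), two-sided Fisher
#' exact p-values, and BH q-values over all pairs. Diagonals are NA; pairs
#' involving a degenerate (all-0 or all-1) gene are NA and excluded from the
#' q computation.
#'
#' @slot log2or,p,q Symmetric numeric matrices with NA diagonal.
#' @exportClass MutexResult
setClass("MutexResult",
    representation(log2or = "matrix", p = "matrix", q = "matrix"))

setValidity("MutexResult", function(object) {
    d <- dim(object@log2or)
    if (!identical(d, dim(object@p)) || !identical(d, dim(object@q)))
        return("matrices must share dimensions")
    TRUE
})

setMethod("show", "MutexResult", function(object) {
    n <- nrow(object@log2or)
    cat("MutexResult:", n, "genes,", n * (n - 1) / 2, "pairs\n")
})

#' GeneClusterSet: hierarchical gene clusters
#'
#' Complete-linkage clustering of genes on 1 - Spearman correlation, with the
#' two children of the dendrogram root labeled C1 and C2 by descending size.
#'
#' @slot tree The \code{\link[stats]{hclust}} merge tree.
#' @slot labels Named character, gene -> cluster label.
#' @slot avgCorr Named numeric, per-cluster average pairwise Spearman rho.
#' @exportClass GeneClusterSet
setClass("GeneClusterSet",
    representation(tree = "ANY", labels = "character", avgCorr = "numeric"))

setMethod("show", "GeneClusterSet", function(object) {
    cat("GeneClusterSet:", length(object@labels), "genes in",
        length(unique(object@labels)), "cluster(s)\n")
    print(table(object@labels))
})
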