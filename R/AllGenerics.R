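#' Accessors for ExpressionCohort and friends
#'
#' \code{exprValues} returns the genes x samples log2-expression matrix;
#' \code{sampleGroups} the named factor of tumor-group labels;
#' \code{geneIds} and \code{sampleIds} the identifier vectors;
#' \code{signatureMembers} and \code{signatureName} the gene-set contents.
#'
#' @param x An [ExpressionCohort-class], [GeneSignature-class],
#'   [BinaryMatrix-class], [MutexResult-class] or [GeneClusterSet-class]
#'   object as appropriate.
#' @return See the individual descriptions.
#' @name accessors
#' @examples
#' cohort <- ExpressionCohort(
#'   matrix(1:12 / 2, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4))),
#'   group = c("A", "A", "B", "B"))
#' dim(exprValues(cohort))
#' sampleGroups(cohort)
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionCohort", function(x)
    SummarizedExperiment::assay(x, "logexpr"))

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname accessors
#' @export
setMethod("sampleGroups", "ExpressionCohort", function(x) {
    g <- SummarizedExperiment::colData(x)$group
    names(g) <- colnames(x)
    g
})

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionCohort", function(x) rownames(x))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionCohort", function(x) colnames(x))

#' @rdname accessors
#' @export
setGeneric("signatureMembers", function(x) standardGeneric("signatureMembers"))

#' @rdname accessors
#' @export
setMethod("signatureMembers", "GeneSignature", function(x) x@members)

#' @rdname accessors
#' @export
setGeneric("signatureName", function(x) standardGeneric("signatureName"))

#' @rdname accessors
#' @export
setMethod("signatureName", "GeneSignature", function(x) x@name)

#' @rdname accessors
#' @export
setGeneric("binaryValues", function(x) standardGeneric("binaryValues"))

#' @rdname accessors
#' @export
setMethod("binaryValues", "BinaryMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("sampleGroups", "BinaryMatrix", function(x) {
    g <- x@group
    names(g) <- colnames(x@values)
    g
})

#' @rdname accessors
#' @export
setGeneric("log2OddsRatios", function(x) standardGeneric("log2OddsRatios"))

#' @rdname accessors
#' @export
setMethod("log2OddsRatios", "MutexResult", function(x) x@log2or)

#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname accessors
#' @export
setMethod("pValues", "MutexResult", function(x) x@p)

#' @rdname accessors
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))

#' @rdname accessors
#' @export
setMethod("qValues", "MutexResult", function(x) x@q)

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setMethod("clusterLabels", "GeneClusterSet", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("clusterTree", function(x) standardGeneric("clusterTree"))

#' @rdname accessors
#' @export
setMethod("clusterTree", "GeneClusterSet", function(x) x@tree)

#' @rdname accessors
#' @export
setGeneric("clusterAvgCorr", function(x) standardGeneric("clusterAvgCorr"))

#' @rdname accessors
#' @export
setMethod("clusterAvgCorr", "GeneClusterSet", function(x) x@avgCorr)

#' @rdname accessors
#' @export
setGeneric("plantedZ", function(x) standardGeneric("plantedZ"))

#' @rdname accessors
#' @export
setMethod("plantedZ", "PlantedTruth", function(x) x@z)

#' @rdname accessors
#' @export
setGeneric("plantedRoles", function(x) standardGeneric("plantedRoles"))

#' @rdname accessors
#' @export
setMethod("plantedRoles", "PlantedTruth", function(x) x@roleOf)

#' @rdname accessors
#' @export
setGeneric("plantedPrograms", function(x) standardGeneric("plantedPrograms"))

#' @rdname accessors
#' @export
setMethod("plantedPrograms", "PlantedTruth", function(x) x@programOf)
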