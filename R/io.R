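## File readers/writers. Validation is fail-fast with classed conditions so
## callers can distinguish malformed input from unannotated samples etc.

.err <- function(class, ...) {
    stop(errorCondition(paste0(...), class = c(class, "culpritScreenError")))
}

#' log2(x + 1) transform of a raw count matrix
#'
#' @param rawCounts Numeric matrix/vector of normalized counts, all entries
#'   finite and >= 0.
#' @return The matrix with each entry x replaced by log2(x + 1).
#' @examples
#' log2Transform(c(0, 1, 7))  # 0 1 3
#' @export
log2Transform <- function(rawCounts) {
    if (!is.numeric(rawCounts))
        .err("invalidValueError", "counts must be numeric")
    if (any(!is.finite(rawCounts)))
        .err("invalidValueError", "counts must be finite")
    if (any(rawCounts < 0))
        .err("invalidValueError", "counts must be >= 0")
    log2(rawCounts + 1)
}

#' Read an expression matrix TSV plus sample annotation into an
#' ExpressionCohort
#'
#' The matrix file has a header row of sample ids and gene ids in the first
#' column (Firebrowse Level-3 layout, genes as rows). The annotation file
#' maps \code{sample_id} to \code{group} (first two columns; extra columns
#' are ignored here).
#'
#' @param path Expression TSV.
#' @param annotationPath Sample annotation TSV with a header.
#' @return A validated [ExpressionCohort-class].
#' @section Errors: classed conditions \code{malformedHeaderError},
#'   \code{nonNumericValueError}, \code{duplicateIdError},
#'   \code{unannotatedSampleError}.
#' @seealso [writeExpressionTsv()]
#' @export
readExpressionTsv <- function(path, annotationPath) {
    lines <- readLines(path)
    if (length(lines) < 1L || !grepl("\t", lines[[1L]]))
        .err("malformedHeaderError",
             "expression file needs a tab-separated header row: ", path)
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    sampleIds <- header[-1L]
    if (length(sampleIds) < 1L)
        .err("malformedHeaderError", "no sample columns in header: ", path)
    if (anyDuplicated(sampleIds))
        .err("duplicateIdError", "duplicated sample id in header: ", path)
    body <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                              colClasses = c("character",
                                             rep("character",
                                                 length(sampleIds))))
    geneIds <- body[[1L]]
    if (anyDuplicated(geneIds))
        .err("duplicateIdError", "duplicated gene id(s): ",
             paste(unique(geneIds[duplicated(geneIds)]), collapse = ", "))
    vals <- suppressWarnings(
        vapply(body[-1L], as.numeric, numeric(nrow(body))))
    vals <- matrix(vals, nrow = length(geneIds),
                   dimnames = list(geneIds, sampleIds))
    if (any(is.na(vals)))
        .err("nonNumericValueError",
             "non-numeric expression cell(s) in ", path)
    ann <- utils::read.delim(annotationPath, header = TRUE,
                             check.names = FALSE,
                             colClasses = "character")
    if (ncol(ann) < 2L)
        .err("malformedHeaderError",
             "annotation needs >= 2 columns (sample_id, group): ",
             annotationPath)
    annId <- ann[[1L]]
    missing <- setdiff(sampleIds, annId)
    if (length(missing))
        .err("unannotatedSampleError", "sample(s) without group label: ",
             paste(missing, collapse = ", "))
    group <- ann[[2L]][match(sampleIds, annId)]
    ExpressionCohort(vals, group = group)
}

#' Write an ExpressionCohort as expression + annotation TSVs
#'
#' @param cohort An [ExpressionCohort-class].
#' @param path Expression TSV to write.
#' @param annotationPath Annotation TSV to write.
#' @return Invisibly, \code{path}.
#' @export
writeExpressionTsv <- function(cohort, path, annotationPath) {
    v <- exprValues(cohort)
    df <- data.frame(gene_id = rownames(v), v, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ann <- data.frame(sample_id = sampleIds(cohort),
                      group = as.character(sampleGroups(cohort)))
    utils::write.table(ann, annotationPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' \code{name<TAB>description<TAB>member1<TAB>member2...}.
#'
#' @param path GMT file.
#' @return A list of [GeneSignature-class], in file order; empty list for an
#'   empty file. Duplicate members within a line are removed with a warning.
#' @export
readGeneSetsGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    out <- vector("list", length(lines))
    for (i in seq_along(lines)) {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            .err("malformedGmtError", "GMT line ", i,
                 " has fewer than 3 fields")
        out[[i]] <- GeneSignature(f[[1L]], f[-(1:2)])
    }
    names(out) <- vapply(out, signatureName, character(1))
    out
}

#' Write gene signatures to a GMT file
#'
#' @param signatures List of [GeneSignature-class].
#' @param path Output path.
#' @param description Description field (recycled).
#' @return Invisibly, \code{path}.
#' @export
writeGeneSetsGmt <- function(signatures, path, description = "na") {
    description <- rep_len(description, length(signatures))
    lines <- vapply(seq_along(signatures), function(i)
        paste(c(signatureName(signatures[[i]]), description[[i]],
                signatureMembers(signatures[[i]])), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a clinical table TSV
#'
#' Columns exactly: \code{sample_id, cohort, timing, response, os_time,
#' os_event}.
#'
#' @param path Clinical TSV.
#' @return A [ClinicalTable-class].
#' @export
readClinicalTsv <- function(path) {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    ClinicalTable(df)
}

#' Write a clinical table TSV
#'
#' @param clinical A [ClinicalTable-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeClinicalTsv <- function(clinical, path) {
    utils::write.table(as.data.frame(clinical), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read AnalysisParams from a YAML config file
#'
#' Plain key: value pairs mirroring [analysisParams()] arguments; keys absent
#' from the file keep their defaults, unknown keys error.
#'
#' @param path YAML file.
#' @return An [AnalysisParams-class].
#' @export
readAnalysisParams <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(analysisParams))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        .err("unknownParamError", "unknown parameter(s): ",
             paste(bad, collapse = ", "))
    do.call(analysisParams, vals)
}
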