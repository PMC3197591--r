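.asMatrix <- function(values, what) {
    if (is.data.frame(values)) values <- as.matrix(values)
    if (!is.matrix(values) || !is.numeric(values))
        stop("'", what, "' must be a numeric matrix with row and column names",
             call. = FALSE)
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("'", what, "' must carry row (feature) and column (sample) names",
             call. = FALSE)
    values
}

#' Construct a BetaMatrix
#'
#' @param values Numeric matrix of percent methylation, probes or genes as
#'   rows, samples as columns (dimnames required). Values in \[0, 100\] or
#'   `NA`.
#' @param referenceId Column name of the melanocyte-pool reference.
#' @return A [BetaMatrix-class] object.
#' @examples
#' b <- BetaMatrix(matrix(c(80, 5, 10, 4), 2,
#'                        dimnames = list(c("g1", "g2"), c("MM1", "MEL"))),
#'                 referenceId = "MEL")
#' assay(b)
#' @export
BetaMatrix <- function(values, referenceId) {
    values <- .asMatrix(values, "values")
    new("BetaMatrix",
        SummarizedExperiment(assays = SimpleList(beta = values)),
        referenceId = as.character(referenceId))
}

#' Construct an ExpressionMatrix
#'
#' @param values Numeric matrix, genes (or probe sets) x samples.
#' @param referenceId Column name of the reference sample.
#' @param scaleTag Scale of `values`: `"linear"` (default), `"log2"`, or
#'   `"log2centered"`.
#' @return An [ExpressionMatrix-class] object.
#' @export
ExpressionMatrix <- function(values, referenceId, scaleTag = "linear") {
    values <- .asMatrix(values, "values")
    new("ExpressionMatrix",
        SummarizedExperiment(assays = SimpleList(exprs = values)),
        referenceId = as.character(referenceId),
        scaleTag = scaleTag)
}

#' Construct a FoldChangeMatrix
#'
#' @param values Numeric matrix of treated/mock fold changes, genes x lines.
#' @return A [FoldChangeMatrix-class] object.
#' @export
FoldChangeMatrix <- function(values) {
    values <- .asMatrix(values, "values")
    new("FoldChangeMatrix",
        SummarizedExperiment(assays = SimpleList(fc = values)))
}

.DeltaMethylation <- function(values, referenceId) {
    new("DeltaMethylation",
        SummarizedExperiment(assays = SimpleList(delta = values)),
        referenceId = as.character(referenceId))
}

.ExpressionRatio <- function(values, referenceId) {
    new("ExpressionRatio",
        SummarizedExperiment(assays = SimpleList(ratio = values)),
        referenceId = as.character(referenceId))
}

#' Default thresholds of the candidate cascade
#'
#' Defaults follow the screen's published criteria: >=60 percent delta
#' methylation together with a 4-fold expression decrease in at least 2
#' samples, and an average post-demethylation re-expression fold change
#' strictly greater than 4.
#'
#' @param methMin Delta-methylation floor in percent (inclusive; default 60).
#' @param minSamples Minimum qualifying samples (default 2).
#' @param downregFold Constitutive down-regulation fold (default 4, i.e.
#'   ratio <= 0.25).
#' @param reexprMeanMin Strict lower bound on mean re-expression fold
#'   (default 4).
#' @return A [FilterThresholds-class] object.
#' @export
FilterThresholds <- function(methMin = 60, minSamples = 2, downregFold = 4,
                             reexprMeanMin = 4) {
    new("FilterThresholds", methMin = as.numeric(methMin),
        minSamples = as.integer(minSamples),
        downregFold = as.numeric(downregFold),
        reexprMeanMin = as.numeric(reexprMeanMin))
}

#' Default exclusion lists of the candidate cascade
#'
#' Defaults carry the screen's oncogene list (ADM, ENPP2, RAC2, SERPINE1)
#' and previously identified gene (PPP1R3C); the "unannotated" removal is an
#' explicit list plus an optional regex (default flags `orf`/`FLJ`/`CCDC`
#' style names) because such lists are study-specific.
#'
#' @param oncogenes,previouslyIdentified,unannotated Symbol vectors.
#' @param unannotatedPattern Regex applied case-insensitively to symbols;
#'   `NA` disables.
#' @param fpMethMin,fpFcMax,fpMinLines False-positive rule: methylated
#'   (delta >= `fpMethMin`) in >= `fpMinLines` lines showing no
#'   re-expression (fold change <= `fpFcMax`) in those same lines.
#' @return An [ExclusionLists-class] object.
#' @export
ExclusionLists <- function(oncogenes = c("ADM", "ENPP2", "RAC2", "SERPINE1"),
                           previouslyIdentified = "PPP1R3C",
                           unannotated = character(),
                           unannotatedPattern = "(^C[0-9]+ORF|^FLJ[0-9]|^CCDC[0-9])",
                           fpMethMin = 60, fpFcMax = 2, fpMinLines = 2) {
    new("ExclusionLists",
        oncogenes = as.character(oncogenes),
        previouslyIdentified = as.character(previouslyIdentified),
        unannotated = as.character(unannotated),
        unannotatedPattern = as.character(unannotatedPattern),
        fpMethMin = as.numeric(fpMethMin), fpFcMax = as.numeric(fpFcMax),
        fpMinLines = as.integer(fpMinLines))
}

#' @rdname referenceId
#' @export
setGeneric("referenceId", function(x) standardGeneric("referenceId"))

#' Reference-sample identifier of a matrix object
#'
#' @param x A [BetaMatrix-class], [ExpressionMatrix-class],
#'   [DeltaMethylation-class] or [ExpressionRatio-class] object.
#' @return Single character identifier.
#' @rdname referenceId
#' @export
setMethod("referenceId", "BetaMatrix", function(x) x@referenceId)

#' @rdname referenceId
#' @export
setMethod("referenceId", "ExpressionMatrix", function(x) x@referenceId)

#' @rdname referenceId
#' @export
setMethod("referenceId", "DeltaMethylation", function(x) x@referenceId)

#' @rdname referenceId
#' @export
setMethod("referenceId", "ExpressionRatio", function(x) x@referenceId)

#' @rdname scaleTag
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))

#' Scale tag of an expression matrix
#'
#' @param x An [ExpressionMatrix-class] object.
#' @return `"linear"`, `"log2"` or `"log2centered"`.
#' @rdname scaleTag
#' @export
setMethod("scaleTag", "ExpressionMatrix", function(x) x@scaleTag)

.showPanel <- function(object, what) {
    cat(class(object), ": ", what, "\n", sep = "")
    cat("  ", nrow(object), " features x ", ncol(object), " samples\n",
        sep = "")
}

setMethod("show", "BetaMatrix", function(object) {
    .showPanel(object, "percent methylation (beta)")
    cat("  reference sample: ", object@referenceId, "\n", sep = "")
})

setMethod("show", "DeltaMethylation", function(object) {
    .showPanel(object, "delta methylation vs reference")
    cat("  reference (dropped): ", object@referenceId, "\n", sep = "")
})

setMethod("show", "ExpressionMatrix", function(object) {
    .showPanel(object, paste0("expression [", object@scaleTag, "]"))
    cat("  reference sample: ", object@referenceId, "\n", sep = "")
})

setMethod("show", "ExpressionRatio", function(object) {
    .showPanel(object, "expression ratio vs reference")
})

setMethod("show", "FoldChangeMatrix", function(object) {
    .showPanel(object, "treated/mock re-expression fold change")
})

setMethod("show", "FilterThresholds", function(object) {
    cat("FilterThresholds: delta >= ", object@methMin,
        "% and ratio <= 1/", object@downregFold,
        " in >= ", object@minSamples, " samples; mean re-expression > ",
        object@reexprMeanMin, "\n", sep = "")
})

setMethod("show", "ExclusionLists", function(object) {
    cat("ExclusionLists:\n")
    cat("  oncogenes: ", paste(object@oncogenes, collapse = ", "), "\n")
    cat("  previously identified: ",
        paste(object@previouslyIdentified, collapse = ", "), "\n")
    cat("  unannotated: ", paste(object@unannotated, collapse = ", "),
        if (!is.na(object@unannotatedPattern))
            paste0(" + /", object@unannotatedPattern, "/i"), "\n")
    cat("  false-positive rule: delta >= ", object@fpMethMin, "% & FC <= ",
        object@fpFcMax, " in >= ", object@fpMinLines, " lines\n", sep = "")
})
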