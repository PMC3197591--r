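#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#' @importFrom S4Vectors SimpleList metadata
NULL

.checkPercentAssay <- function(x, what) {
    v <- assay(x, withDimnames = FALSE)
    bad <- !is.na(v) & (v < 0 | v > 100)
    if (any(bad))
        return(sprintf("%s values must lie in [0, 100] (or NA); %d offend",
                       what, sum(bad)))
    NULL
}

.checkReference <- function(x) {
    ref <- x@referenceId
    if (length(ref) != 1L || is.na(ref) || !nzchar(ref))
        return("'referenceId' must be a single non-empty sample identifier")
    if (!ref %in% colnames(x))
        return(sprintf("reference sample '%s' is not among the columns", ref))
    NULL
}

#' Percent-methylation matrix with a designated reference sample
#'
#' A `SummarizedExperiment` holding one assay, `"beta"`, of percent
#' methylation values (0--100, `NA` for no-signal probes) for probes or
#' genes (rows) across samples (columns). One column, named by
#' `referenceId`, is the melanocyte-pool reference against which deltas are
#' taken.
#'
#' @slot referenceId Single sample identifier of the reference column.
#' @seealso [BetaMatrix()], [computeDelta()], [summarizeGeneMethylation()]
#' @export
setClass("BetaMatrix",
    contains = "SummarizedExperiment",
    representation(referenceId = "character"))

setValidity("BetaMatrix", function(object) {
    msg <- c(
        if (!"beta" %in% names(assays(object))) "assay 'beta' is required",
        .checkPercentAssay(object, "beta"),
        .checkReference(object))
    if (length(msg)) msg else TRUE
})

#' Signed delta methylation against the reference
#'
#' A `SummarizedExperiment` with one assay `"delta"` holding each
#' non-reference sample's percent methylation minus the reference's, so
#' values lie in \[-100, 100\]: positive means relative hypermethylation of
#' the melanoma line, negative a line-specific decrease. The reference
#' column itself is dropped; its identifier is retained for provenance.
#'
#' @slot referenceId Identifier of the reference the deltas were taken
#'   against (not a column of this object).
#' @seealso [computeDelta()]
#' @export
setClass("DeltaMethylation",
    contains = "SummarizedExperiment",
    representation(referenceId = "character"))

setValidity("DeltaMethylation", function(object) {
    msg <- NULL
    if (!"delta" %in% names(assays(object)))
        msg <- c(msg, "assay 'delta' is required")
    else {
        v <- assay(object, withDimnames = FALSE)
        bad <- !is.na(v) & (v < -100 | v > 100)
        if (any(bad))
            msg <- c(msg, sprintf(
                "delta values must lie in [-100, 100]; %d offend", sum(bad)))
    }
    if (length(object@referenceId) != 1L)
        msg <- c(msg, "'referenceId' must be length 1")
    else if (object@referenceId %in% colnames(object))
        msg <- c(msg, "the reference sample must not appear as a delta column")
    if (length(msg)) msg else TRUE
})

#' Expression matrix with reference sample and scale tag
#'
#' A `SummarizedExperiment` with one assay `"exprs"` of relative expression
#' per gene (or probe set) per sample. The `scaleTag` slot records whether
#' values are on the linear scale (`"linear"`, strictly positive), plain
#' log2 (`"log2"`), or log2 after two-pass median centering
#' (`"log2centered"`). Ratios against the reference are only ever taken on
#' the linear scale.
#'
#' @slot referenceId Identifier of the melanocyte-pool reference column.
#' @slot scaleTag One of `"linear"`, `"log2"`, `"log2centered"`.
#' @seealso [ExpressionMatrix()], [floorAndLog()], [medianCenter()],
#'   [expressionRatio()]
#' @export
setClass("ExpressionMatrix",
    contains = "SummarizedExperiment",
    representation(referenceId = "character", scaleTag = "character"))

setValidity("ExpressionMatrix", function(object) {
    msg <- NULL
    if (!"exprs" %in% names(assays(object)))
        msg <- c(msg, "assay 'exprs' is required")
    tag <- object@scaleTag
    if (length(tag) != 1L || !tag %in% c("linear", "log2", "log2centered"))
        msg <- c(msg,
            "'scaleTag' must be one of 'linear', 'log2', 'log2centered'")
    else if ("exprs" %in% names(assays(object))) {
        v <- assay(object, "exprs", withDimnames = FALSE)
        if (tag == "linear" && any(!is.na(v) & v <= 0))
            msg <- c(msg, "linear-scale expression values must be > 0")
    }
    msg <- c(msg, .checkReference(object))
    if (length(msg)) msg else TRUE
})

#' Fold-ratio expression against the reference
#'
#' Assay `"ratio"` holds linear fold ratios line / reference per gene and
#' non-reference sample; a gene is down k-fold in a sample iff its ratio is
#' <= 1/k there.
#'
#' @slot referenceId Identifier of the reference the ratios were taken
#'   against (not a column).
#' @seealso [expressionRatio()]
#' @export
setClass("ExpressionRatio",
    contains = "SummarizedExperiment",
    representation(referenceId = "character"))

setValidity("ExpressionRatio", function(object) {
    msg <- NULL
    if (!"ratio" %in% names(assays(object)))
        msg <- c(msg, "assay 'ratio' is required")
    else {
        v <- assay(object, withDimnames = FALSE)
        if (any(!is.na(v) & v <= 0))
            msg <- c(msg, "expression ratios must be > 0")
    }
    if (length(object@referenceId) == 1L &&
        object@referenceId %in% colnames(object))
        msg <- c(msg, "the reference sample must not appear as a ratio column")
    if (length(msg)) msg else TRUE
})

#' Treated/mock re-expression fold changes
#'
#' Assay `"fc"` holds per-gene, per-line fold changes of expression after
#' demethylating treatment (treated / mock); `NA` marks lines without data
#' for a gene, which are excluded from means and prevent a gene from
#' counting as reactivated "in all lines".
#'
#' @seealso [foldChange()], [reexpressedGenes()], [filterUbiquitous()]
#' @export
setClass("FoldChangeMatrix", contains = "SummarizedExperiment")

setValidity("FoldChangeMatrix", function(object) {
    msg <- NULL
    if (!"fc" %in% names(assays(object)))
        msg <- c(msg, "assay 'fc' is required")
    else {
        v <- assay(object, withDimnames = FALSE)
        if (any(!is.na(v) & v <= 0))
            msg <- c(msg, "fold changes must be > 0 where defined")
    }
    if (length(msg)) msg else TRUE
})

#' Thresholds of the cross-platform candidate cascade
#'
#' Numeric thresholds of the integration filter: a sample qualifies for a
#' gene when its delta methylation is at least `methMin` (inclusive) and its
#' expression ratio shows at least a `downregFold`-fold decrease
#' (ratio <= 1/downregFold); a gene passes with at least `minSamples`
#' qualifying samples and an average re-expression fold change strictly
#' greater than `reexprMeanMin`.
#'
#' @slot methMin Delta-methylation floor in percent, in (0, 100].
#' @slot minSamples Minimum number of qualifying samples (>= 1).
#' @slot downregFold Fold decrease in constitutive expression (> 1).
#' @slot reexprMeanMin Strict lower bound on the mean re-expression fold (> 1).
#' @seealso [FilterThresholds()], [runCascade()]
#' @export
setClass("FilterThresholds",
    representation(methMin = "numeric", minSamples = "integer",
                   downregFold = "numeric", reexprMeanMin = "numeric"))

setValidity("FilterThresholds", function(object) {
    msg <- NULL
    if (!(length(object@methMin) == 1L && object@methMin > 0 &&
          object@methMin <= 100))
        msg <- c(msg, "'methMin' must be a single value in (0, 100]")
    if (!(length(object@minSamples) == 1L && object@minSamples >= 1L))
        msg <- c(msg, "'minSamples' must be a single count >= 1")
    if (!(length(object@downregFold) == 1L && object@downregFold > 1))
        msg <- c(msg, "'downregFold' must be a single fold > 1")
    if (!(length(object@reexprMeanMin) == 1L && object@reexprMeanMin > 1))
        msg <- c(msg, "'reexprMeanMin' must be a single fold > 1")
    if (length(msg)) msg else TRUE
})

#' Exclusion lists and false-positive rule of the cascade
#'
#' Gene symbols removed after the numeric filters: known oncogenes,
#' previously identified genes, and genes without a described function
#' ("unannotated", given as an explicit list and/or a regular expression on
#' the symbol). The false-positive rule flags genes that look methylated on
#' the beadarray yet show no re-expression after demethylating treatment:
#' delta >= `fpMethMin` in at least `fpMinLines` lines whose fold change is
#' <= `fpFcMax`.
#'
#' @slot oncogenes,previouslyIdentified,unannotated Character vectors of
#'   official symbols (matched case-insensitively).
#' @slot unannotatedPattern Optional regex (e.g. `"orf"`-style names);
#'   `NA_character_` disables it.
#' @slot fpMethMin,fpFcMax,fpMinLines Parameters of the false-positive rule.
#' @seealso [ExclusionLists()], [detectFalsePositives()], [runCascade()]
#' @export
setClass("ExclusionLists",
    representation(oncogenes = "character",
                   previouslyIdentified = "character",
                   unannotated = "character",
                   unannotatedPattern = "character",
                   fpMethMin = "numeric", fpFcMax = "numeric",
                   fpMinLines = "integer"))

setValidity("ExclusionLists", function(object) {
    msg <- NULL
    lists <- list(oncogenes = toupper(object@oncogenes),
                  previously = toupper(object@previouslyIdentified),
                  unannotated = toupper(object@unannotated))
    all <- unlist(lists, use.names = FALSE)
    if (anyDuplicated(all))
        msg <- c(msg, "exclusion lists must be disjoint after symbol normalization")
    if (length(object@unannotatedPattern) != 1L)
        msg <- c(msg, "'unannotatedPattern' must be a single regex or NA")
    if (!(length(object@fpMethMin) == 1L && object@fpMethMin > 0))
        msg <- c(msg, "'fpMethMin' must be a single positive percent")
    if (!(length(object@fpFcMax) == 1L && object@fpFcMax > 0))
        msg <- c(msg, "'fpFcMax' must be a single positive fold")
    if (!(length(object@fpMinLines) == 1L && object@fpMinLines >= 1L))
        msg <- c(msg, "'fpMinLines' must be a single count >= 1")
    if (length(msg)) msg else TRUE
})
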