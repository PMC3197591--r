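#' Treated/mock re-expression fold change
#'
#' `FC[g, l] = treated[g, l] / mock[g, l]` per gene and cell line, on the
#' linear scale. Gene and line identifiers must match exactly between the
#' two matrices.
#'
#' @param treated,mock Linear-scale [ExpressionMatrix-class] objects (or
#'   bare named matrices) over the same genes and lines.
#' @return A [FoldChangeMatrix-class].
#' @export
foldChange <- function(treated, mock) {
    t <- if (is(treated, "ExpressionMatrix")) assay(treated, "exprs") else treated
    m <- if (is(mock, "ExpressionMatrix")) assay(mock, "exprs") else mock
    dg <- c(setdiff(rownames(t), rownames(m)), setdiff(rownames(m), rownames(t)))
    dl <- c(setdiff(colnames(t), colnames(m)), setdiff(colnames(m), colnames(t)))
    if (length(dg) || length(dl))
        stop("treated/mock identifiers differ: ",
             paste(utils::head(unique(c(dg, dl)), 10), collapse = ", "),
             call. = FALSE)
    m <- m[rownames(t), colnames(t), drop = FALSE]
    FoldChangeMatrix(t / m)
}

#' Genes re-expressed after demethylating treatment
#'
#' A gene counts as re-expressed in a line when its fold change is strictly
#' greater than `threshold` there (so exactly 2.0 does not qualify at the
#' default); it is returned when that holds in at least `minLines` lines.
#' Duplicate gene identifiers are collapsed to non-redundant symbols (per
#' line, a symbol is re-expressed if any of its rows is) before counting.
#'
#' @param fc A [FoldChangeMatrix-class].
#' @param threshold Fold-change threshold, > 1 (default 2, strict).
#' @param minLines Minimum qualifying lines (default 1).
#' @return `data.frame` with columns `symbol` and `n_lines` (count of
#'   qualifying lines), one row per re-expressed gene.
#' @export
reexpressedGenes <- function(fc, threshold = 2, minLines = 1) {
    if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 1)
        stop("'threshold' must be a single fold > 1", call. = FALSE)
    if (minLines < 1)
        stop("'minLines' must be >= 1", call. = FALSE)
    v <- assay(fc, "fc")
    hit <- !is.na(v) & v > threshold
    if (anyDuplicated(rownames(hit)))
        hit <- rowsum(hit + 0L, rownames(hit)) > 0L
    n <- rowSums(hit)
    keep <- n >= minLines
    data.frame(symbol = rownames(hit)[keep],
               n_lines = unname(as.integer(n[keep])),
               stringsAsFactors = FALSE)
}

#' Remove ubiquitously reactivated genes
#'
#' Genes re-expressed (fold change strictly above `threshold`) in every
#' line, with no line missing, are removed: ubiquitous reactivation marks a
#' generic stress/demethylation response, not lineage-specific silencing. A
#' gene with any missing line is conservatively kept (it cannot be shown to
#' be reactivated in all lines).
#'
#' @param genes Character vector of symbols (typically
#'   `reexpressedGenes(fc)$symbol`).
#' @param fc A [FoldChangeMatrix-class].
#' @param threshold Fold threshold (default 2).
#' @return Character vector: `genes` minus the ubiquitous set.
#' @export
filterUbiquitous <- function(genes, fc, threshold = 2) {
    v <- assay(fc, "fc")
    v <- v[rownames(v) %in% genes, , drop = FALSE]
    hit <- !is.na(v) & v > threshold
    if (anyDuplicated(rownames(hit)))
        hit <- rowsum(hit + 0L, rownames(hit)) > 0L
    ubiq <- rownames(hit)[rowSums(hit) == ncol(hit)]
    setdiff(genes, ubiq)
}

#' Mean re-expression fold change per gene
#'
#' Arithmetic mean (default) of the treated/mock fold changes over the
#' available (non-missing) lines; the screen's ">4 average" criterion is
#' applied to this value. The geometric mean is available for a
#' log-symmetric reading.
#'
#' @param fc A [FoldChangeMatrix-class].
#' @param type `"arithmetic"` (default) or `"geometric"`.
#' @return Named numeric vector, `NA` for all-missing genes.
#' @export
meanReexpression <- function(fc, type = c("arithmetic", "geometric")) {
    type <- match.arg(type)
    v <- assay(fc, "fc")
    out <- if (type == "arithmetic") rowMeans(v, na.rm = TRUE)
           else exp(rowMeans(log(v), na.rm = TRUE))
    out[rowSums(!is.na(v)) == 0L] <- NA_real_
    out
}

#' Bookkeeping of the re-expression filter
#'
#' Counts mirroring the screen's flow: non-redundant genes re-expressed in
#' at least one line, genes removed as ubiquitously reactivated, and genes
#' retained.
#'
#' @param fc A [FoldChangeMatrix-class].
#' @param threshold Fold threshold (default 2).
#' @return Named list `n_reexpressed`, `n_removed_ubiquitous`, `n_retained`.
#' @export
reexpressionSummary <- function(fc, threshold = 2) {
    re <- reexpressedGenes(fc, threshold = threshold, minLines = 1)
    kept <- filterUbiquitous(re$symbol, fc, threshold = threshold)
    list(n_reexpressed = nrow(re),
         n_removed_ubiquitous = nrow(re) - length(kept),
         n_retained = length(kept))
}
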