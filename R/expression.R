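#' Floor small values and log2-transform
#'
#' Replaces every linear-scale value `v` by `log2(max(v, floor))`; the
#' default floor of 0.1 guards against unstable ratios among near-zero
#' signals. Missing values propagate.
#'
#' @param x An [ExpressionMatrix-class] on the linear scale.
#' @param floor Positive floor (default 0.1).
#' @return An [ExpressionMatrix-class] tagged `"log2"`.
#' @export
floorAndLog <- function(x, floor = 0.1) {
    if (!is.numeric(floor) || length(floor) != 1L || is.na(floor) ||
        floor <= 0)
        stop("'floor' must be a single positive number", call. = FALSE)
    if (!is(x, "ExpressionMatrix") || scaleTag(x) != "linear")
        stop("'x' must be a linear-scale ExpressionMatrix", call. = FALSE)
    v <- log2(pmax(assay(x, "exprs"), floor))
    ExpressionMatrix(v, referenceId = referenceId(x), scaleTag = "log2")
}

#' Two-pass median centering
#'
#' Subtracts each sample's median, then each gene's median, in that order
#' (the two orders differ in general; sample-first is fixed here). Exactly
#' one pass is made over each dimension, so after the gene pass the sample
#' medians are close to, but not in general exactly, zero; iterating the two
#' passes to convergence would be Tukey's median polish, which is not what
#' is done here. An all-missing row or column is emitted as missing with a
#' warning.
#'
#' @param x An [ExpressionMatrix-class] on the log2 scale.
#' @return An [ExpressionMatrix-class] tagged `"log2centered"`.
#' @export
medianCenter <- function(x) {
    if (!is(x, "ExpressionMatrix") || scaleTag(x) != "log2")
        stop("'x' must be a log2-scale ExpressionMatrix (see floorAndLog)",
             call. = FALSE)
    v <- assay(x, "exprs")
    allNAcol <- colSums(!is.na(v)) == 0L
    allNArow <- rowSums(!is.na(v)) == 0L
    if (any(allNAcol) || any(allNArow))
        warning("all-missing row(s)/column(s) emitted as missing",
                call. = FALSE)
    smed <- apply(v, 2L, stats::median, na.rm = TRUE)
    smed[allNAcol] <- 0
    v <- sweep(v, 2L, smed)
    gmed <- apply(v, 1L, stats::median, na.rm = TRUE)
    gmed[allNArow] <- 0
    v <- sweep(v, 1L, gmed)
    ExpressionMatrix(v, referenceId = referenceId(x),
                     scaleTag = "log2centered")
}

#' Expression ratio against the melanocyte reference
#'
#' `ratio[g, s] = value[g, s] / value[g, reference]` on the linear scale; a
#' gene is down k-fold in sample `s` iff `ratio[g, s] <= 1/k` (so exactly
#' 4-fold down, ratio 0.25, counts as a 4-fold decrease).
#'
#' @param x A linear-scale [ExpressionMatrix-class] whose reference column
#'   is strictly positive.
#' @return An [ExpressionRatio-class] without the reference column.
#' @export
expressionRatio <- function(x) {
    if (!is(x, "ExpressionMatrix") || scaleTag(x) != "linear")
        stop("ratios are taken on the linear scale only", call. = FALSE)
    ref <- referenceId(x)
    v <- assay(x, "exprs")
    r <- v[, setdiff(colnames(v), ref), drop = FALSE] / v[, ref]
    .ExpressionRatio(r, referenceId = ref)
}

#' Collapse probe sets to gene symbols
#'
#' Multiple probe sets mapping to one symbol are aggregated by their median
#' (default) or mean per sample, `NA`s excluded.
#'
#' @param x An [ExpressionMatrix-class] keyed by probe set.
#' @param annotation `data.frame` with columns `probe_id`, `gene_symbol`.
#' @param aggregator `"median"` or `"mean"`.
#' @return A gene-keyed [ExpressionMatrix-class] with the same scale tag.
#' @export
summarizeGeneExpression <- function(x, annotation,
                                    aggregator = c("median", "mean")) {
    aggregator <- match.arg(aggregator)
    map <- stats::setNames(as.character(annotation$gene_symbol),
                           as.character(annotation$probe_id))
    v <- assay(x, "exprs")
    missing <- setdiff(rownames(v), names(map))
    if (length(missing))
        stop("unannotated probe set(s): ",
             paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    fun <- if (aggregator == "median") {
        function(z) if (all(is.na(z))) NA_real_ else stats::median(z, na.rm = TRUE)
    } else {
        function(z) if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE)
    }
    out <- do.call(rbind, lapply(split(seq_len(nrow(v)), map[rownames(v)]),
        function(i) apply(v[i, , drop = FALSE], 2L, fun)))
    ExpressionMatrix(out, referenceId = referenceId(x), scaleTag = scaleTag(x))
}
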