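#' Percent methylation (beta) from allele intensities
#'
#' Computes beta = Max(M, 0) / (Max(M, 0) + Max(U, 0) + offset) x 100 from
#' the fluorescence intensities of the methylated (M) and unmethylated (U)
#' alleles. Negative background-corrected intensities are clamped to zero
#' before the ratio is taken; a zero denominator (no signal on either
#' channel, offset 0) yields `NA` rather than a value or an error, so
#' missingness propagates explicitly.
#'
#' The default `offset = 0` matches the formula as used here; Infinium
#' processing conventionally adds a small stabilizing constant (often 100),
#' which can be supplied instead.
#'
#' @param M,U Numeric vectors of methylated / unmethylated allele
#'   intensities (recycled to a common length). Must be finite.
#' @param offset Non-negative denominator constant (default 0).
#' @param probeId,sampleId Optional identifiers used only to label errors.
#' @return Numeric vector of percent methylation in \[0, 100\], `NA` where
#'   the denominator is zero.
#' @examples
#' computeBeta(300, 100)   # 75
#' computeBeta(-50, 100)   # 0: negative M clamped
#' computeBeta(0, 0)       # NA: no signal
#' @export
computeBeta <- function(M, U, offset = 0, probeId = NULL, sampleId = NULL) {
    if (!is.numeric(offset) || length(offset) != 1L || is.na(offset) ||
        offset < 0)
        stop("'offset' must be a single non-negative number", call. = FALSE)
    n <- max(length(M), length(U))
    M <- rep_len(as.numeric(M), n)
    U <- rep_len(as.numeric(U), n)
    bad <- !is.finite(M) | !is.finite(U)
    if (any(bad)) {
        lab <- which(bad)[1L]
        where <- paste0(
            if (!is.null(probeId)) paste0(" probe ", rep_len(probeId, n)[lab]),
            if (!is.null(sampleId)) paste0(" sample ",
                                           rep_len(sampleId, n)[lab]))
        stop("non-finite intensity at position ", lab, where, call. = FALSE)
    }
    m <- pmax(M, 0)
    u <- pmax(U, 0)
    den <- m + u + offset
    ifelse(den == 0, NA_real_, m / den * 100)
}

#' Build a BetaMatrix from a long intensity table
#'
#' @param intensities `data.frame` with columns `probe_id`, `sample_id`,
#'   `M`, `U` (one row per probe-sample pair).
#' @param referenceId Sample identifier of the melanocyte-pool reference.
#' @param offset Denominator constant passed to [computeBeta()].
#' @return A [BetaMatrix-class] keyed by probe.
#' @export
betaFromIntensities <- function(intensities, referenceId, offset = 0) {
    need <- c("probe_id", "sample_id", "M", "U")
    miss <- setdiff(need, names(intensities))
    if (length(miss))
        stop("intensity table lacks column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
    beta <- computeBeta(intensities$M, intensities$U, offset,
                        probeId = intensities$probe_id,
                        sampleId = intensities$sample_id)
    probes <- unique(as.character(intensities$probe_id))
    samples <- unique(as.character(intensities$sample_id))
    m <- matrix(NA_real_, length(probes), length(samples),
                dimnames = list(probes, samples))
    m[cbind(as.character(intensities$probe_id),
            as.character(intensities$sample_id))] <- beta
    BetaMatrix(m, referenceId = referenceId)
}

#' Delta methylation against the melanocyte reference
#'
#' Subtracts the reference column from every other sample:
#' `delta[p, s] = beta[p, s] - beta[p, reference]`. Positive values mark a
#' line- and site-specific increase in methylation relative to melanocytes,
#' negative a decrease. Probes with a missing reference value are missing
#' throughout the output.
#'
#' @param beta A [BetaMatrix-class].
#' @return A [DeltaMethylation-class] without the reference column.
#' @examples
#' b <- BetaMatrix(matrix(c(80, 10, 5, 5), 2,
#'                        dimnames = list(c("g1", "g2"), c("MM1", "MEL"))),
#'                 referenceId = "MEL")
#' assay(computeDelta(b))   # g1: 75, g2: 5
#' @export
computeDelta <- function(beta) {
    if (!is(beta, "BetaMatrix"))
        stop("'beta' must be a BetaMatrix", call. = FALSE)
    ref <- referenceId(beta)
    v <- assay(beta, "beta")
    d <- v[, setdiff(colnames(v), ref), drop = FALSE] - v[, ref]
    .DeltaMethylation(d, referenceId = ref)
}

#' Collapse probe-level methylation to gene symbols
#'
#' Aggregates multi-probe genes by the mean (default) or the maximum of the
#' per-probe beta values in each sample; `NA`s are excluded from the
#' aggregation and an all-missing group stays `NA`. `max` gives an
#' "any probe methylated" reading.
#'
#' @param beta A probe-keyed [BetaMatrix-class].
#' @param annotation `data.frame` with columns `probe_id`, `gene_symbol`;
#'   every probe in `beta` must be annotated, one symbol per probe.
#' @param aggregator `"mean"` or `"max"`.
#' @return A gene-keyed [BetaMatrix-class] (rows sorted by symbol).
#' @export
summarizeGeneMethylation <- function(beta, annotation,
                                     aggregator = c("mean", "max")) {
    aggregator <- match.arg(aggregator)
    if (!all(c("probe_id", "gene_symbol") %in% names(annotation)))
        stop("annotation needs columns 'probe_id' and 'gene_symbol'",
             call. = FALSE)
    map <- stats::setNames(as.character(annotation$gene_symbol),
                           as.character(annotation$probe_id))
    if (anyDuplicated(names(map)))
        stop("annotation maps some probe to more than one symbol",
             call. = FALSE)
    v <- assay(beta, "beta")
    missing <- setdiff(rownames(v), names(map))
    if (length(missing))
        stop("unannotated probe(s): ",
             paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    genes <- map[rownames(v)]
    fun <- if (aggregator == "mean") {
        function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    } else {
        function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
    }
    out <- do.call(rbind, lapply(split(seq_len(nrow(v)), genes), function(i)
        apply(v[i, , drop = FALSE], 2L, fun)))
    BetaMatrix(out, referenceId = referenceId(beta))
}
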