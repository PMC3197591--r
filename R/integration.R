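.commonSymbols <- function(...) {
    sets <- lapply(list(...), function(x) toupper(rownames(x)))
    common <- Reduce(intersect, sets)
    unmatched <- setdiff(unique(unlist(sets)), common)
    list(common = common, unmatched = unmatched)
}

.upperRows <- function(m) { rownames(m) <- toupper(rownames(m)); m }

#' Samples where hypermethylation and down-regulation co-occur
#'
#' For each gene, a sample qualifies when both conditions hold in that same
#' sample: delta methylation at least `methMin` (inclusive, so exactly 60
#' qualifies at the default) and an expression ratio of at most
#' `1/downregFold` (inclusive, so exactly 4-fold down qualifies). A gene
#' passes the filter when at least `minSamples` samples qualify.
#'
#' Gene symbols are matched case-insensitively across the two inputs;
#' symbols present in only one input are reported in the `"unmatched"`
#' attribute, never silently dropped.
#'
#' @param delta A [DeltaMethylation-class].
#' @param ratios An [ExpressionRatio-class] over the same samples.
#' @param thresholds A [FilterThresholds-class].
#' @return Named list (one element per common gene symbol) of character
#'   vectors of qualifying sample identifiers, with attribute `"unmatched"`.
#' @export
jointSampleFilter <- function(delta, ratios, thresholds = FilterThresholds()) {
    validObject(thresholds)
    d <- .upperRows(assay(delta, "delta"))
    r <- .upperRows(assay(ratios, "ratio"))
    samples <- intersect(colnames(d), colnames(r))
    if (!length(samples))
        stop("delta and ratio matrices share no sample", call. = FALSE)
    sym <- .commonSymbols(d, r)
    if (!length(sym$common))
        stop("delta and ratio matrices share no gene symbol", call. = FALSE)
    d <- d[sym$common, samples, drop = FALSE]
    r <- r[sym$common, samples, drop = FALSE]
    ok <- !is.na(d) & !is.na(r) &
        d >= thresholds@methMin & r <= 1 / thresholds@downregFold
    out <- lapply(seq_len(nrow(ok)),
                  function(i) samples[ok[i, ]])
    names(out) <- sym$common
    attr(out, "unmatched") <- sym$unmatched
    out
}

#' Flag beadarray false positives
#'
#' Genes that look methylated on the array yet show no re-expression after
#' demethylating treatment are flagged: delta >= `fpMethMin` in at least
#' `fpMinLines` lines whose fold change is at most `fpFcMax` in those same
#' lines. (EEF1A2 and HSPA2 were the motivating examples of this failure
#' mode.)
#'
#' @param delta A [DeltaMethylation-class].
#' @param fc A [FoldChangeMatrix-class] over the same lines.
#' @param exclusions An [ExclusionLists-class] carrying the rule parameters.
#' @return Character vector of flagged symbols (uppercased).
#' @export
detectFalsePositives <- function(delta, fc, exclusions = ExclusionLists()) {
    d <- .upperRows(assay(delta, "delta"))
    f <- .upperRows(assay(fc, "fc"))
    samples <- intersect(colnames(d), colnames(f))
    sym <- .commonSymbols(d, f)
    if (!length(samples) || !length(sym$common)) return(character())
    d <- d[sym$common, samples, drop = FALSE]
    f <- f[sym$common, samples, drop = FALSE]
    bad <- !is.na(d) & !is.na(f) &
        d >= exclusions@fpMethMin & f <= exclusions@fpFcMax
    sym$common[rowSums(bad) >= exclusions@fpMinLines]
}

.FILTERS <- c("joint_sample", "mean_reexpression", "oncogene",
              "previously_identified", "unannotated", "false_positive")

#' Cross-platform candidate cascade
#'
#' Applies, in order: the joint methylation/down-regulation sample filter;
#' the strict mean re-expression bound (> `reexprMeanMin`, so exactly 4.0
#' fails at the default); removal of oncogenes, previously identified
#' genes, and unannotated symbols; and removal of beadarray false
#' positives. Every input gene receives a complete pass/fail trail over all
#' six filters and a terminal status: `"candidate"` if all passed, else
#' `"excluded:<first failed filter>"`.
#'
#' @param delta A [DeltaMethylation-class].
#' @param ratios An [ExpressionRatio-class].
#' @param fc A [FoldChangeMatrix-class].
#' @param thresholds A [FilterThresholds-class].
#' @param exclusions An [ExclusionLists-class].
#' @param keep Optional character vector: when supplied, candidates are
#'   additionally restricted to these symbols (stand-in for downstream
#'   bench confirmation such as qRT-PCR and CpG-island checks, which are
#'   outside this package).
#' @return `data.frame` with one row per gene on the common symbol
#'   universe: `symbol`, `n_qualifying`, `qualifying_samples`
#'   (comma-separated), `mean_fc`, `status`, `trail`; sorted by
#'   qualifying-sample count (desc), mean re-expression (desc), then
#'   symbol. Attributes: `"summary"` (stage-by-stage counts),
#'   `"unmatched"` (symbols absent from some input).
#' @examples
#' # see the package vignette for a full synthetic-data walk-through
#' @export
runCascade <- function(delta, ratios, fc, thresholds = FilterThresholds(),
                       exclusions = ExclusionLists(), keep = NULL) {
    validObject(thresholds)
    validObject(exclusions)

    qual <- jointSampleFilter(delta, ratios, thresholds)
    genes <- names(qual)
    nq <- lengths(qual)

    f <- .upperRows(assay(fc, "fc"))
    fcGenes <- intersect(genes, rownames(f))
    meanfc <- rep(NA_real_, length(genes))
    names(meanfc) <- genes
    if (length(fcGenes)) {
        mf <- meanReexpression(FoldChangeMatrix(f[fcGenes, , drop = FALSE]))
        meanfc[names(mf)] <- mf
    }

    fp <- detectFalsePositives(delta, fc, exclusions)

    pass <- cbind(
        joint_sample = nq >= thresholds@minSamples,
        mean_reexpression = !is.na(meanfc) & meanfc > thresholds@reexprMeanMin,
        oncogene = !genes %in% toupper(exclusions@oncogenes),
        previously_identified =
            !genes %in% toupper(exclusions@previouslyIdentified),
        unannotated = !(genes %in% toupper(exclusions@unannotated) |
            (!is.na(exclusions@unannotatedPattern) &
             grepl(exclusions@unannotatedPattern, genes, ignore.case = TRUE))),
        false_positive = !genes %in% fp)

    firstFail <- apply(pass, 1L, function(p)
        if (all(p)) NA_character_ else .FILTERS[which(!p)[1L]])
    status <- ifelse(is.na(firstFail), "candidate",
                     paste0("excluded:", firstFail))
    if (!is.null(keep))
        status[status == "candidate" & !genes %in% toupper(keep)] <-
            "excluded:keep_list"
    trail <- apply(pass, 1L, function(p)
        paste(paste0(.FILTERS, ":", ifelse(p, "pass", "fail")),
              collapse = ";"))

    out <- data.frame(
        symbol = genes,
        n_qualifying = as.integer(nq),
        qualifying_samples = vapply(qual, paste, "", collapse = ","),
        mean_fc = as.numeric(meanfc),
        status = status,
        trail = trail,
        row.names = NULL, stringsAsFactors = FALSE)
    out <- out[order(-out$n_qualifying,
                     -ifelse(is.na(out$mean_fc), -Inf, out$mean_fc),
                     out$symbol), , drop = FALSE]
    rownames(out) <- NULL

    surv <- function(k) sum(apply(pass[, seq_len(k), drop = FALSE], 1L, all))
    summary <- c(list(n_input = length(genes)),
                 stats::setNames(lapply(seq_along(.FILTERS), surv),
                                 paste0("n_after_", .FILTERS)),
                 list(n_candidates = sum(out$status == "candidate")))
    attr(out, "summary") <- summary
    attr(out, "unmatched") <- attr(qual, "unmatched")
    out
}

#' Stage-by-stage counts of a cascade run
#'
#' @param cascade Result of [runCascade()].
#' @return Named list of gene counts surviving each successive filter.
#' @export
cascadeSummary <- function(cascade) attr(cascade, "summary")
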