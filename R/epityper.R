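.UNIT_COLS <- c("gene", "amplicon_id", "unit_index", "n_cpgs", "sample",
                "meth_ratio_pct", "error_pct", "overlap_flag")

#' Validate a CpG-unit table
#'
#' The atomic datum of the mass-spectrometry methylation assay is the CpG
#' unit: a cleavage fragment carrying one or more consecutive CpG
#' dinucleotides with a single methylation ratio and error estimate. One
#' row per unit and sample.
#'
#' @param units `data.frame` with columns `gene`, `amplicon_id`,
#'   `unit_index`, `n_cpgs`, `sample`, `meth_ratio_pct`, `error_pct`,
#'   `overlap_flag`.
#' @return The table, invisibly, after checks (ratio in \[0, 100\],
#'   `error_pct >= 0`, `n_cpgs >= 1`).
#' @export
validateCpGUnits <- function(units) {
    miss <- setdiff(.UNIT_COLS, names(units))
    if (length(miss))
        stop("CpG-unit table lacks column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    r <- units$meth_ratio_pct
    if (any(!is.na(r) & (r < 0 | r > 100)))
        stop("'meth_ratio_pct' must lie in [0, 100]", call. = FALSE)
    if (any(!is.na(units$error_pct) & units$error_pct < 0))
        stop("'error_pct' must be >= 0", call. = FALSE)
    if (any(units$n_cpgs < 1))
        stop("'n_cpgs' must be >= 1", call. = FALSE)
    invisible(units)
}

#' Quality filter on CpG units
#'
#' Drops units whose cleavage fragment overlaps another fragment in the
#' mass spectrum (`overlap_flag`) and units whose ratio uncertainty is not
#' strictly below `maxError` (only estimated errors smaller than the
#' threshold are retained, so exactly 10 percent is dropped at the
#' default). Retained rows are unchanged.
#'
#' @param units CpG-unit table (see [validateCpGUnits()]).
#' @param maxError Uncertainty threshold in percent (default 10).
#' @return The retained subset of `units`.
#' @export
qcFilterUnits <- function(units, maxError = 10) {
    if (!is.numeric(maxError) || length(maxError) != 1L || maxError <= 0)
        stop("'maxError' must be a single positive percent", call. = FALSE)
    validateCpGUnits(units)
    keep <- !units$overlap_flag & !is.na(units$error_pct) &
        units$error_pct < maxError
    units[keep, , drop = FALSE]
}

.ampliconSampleMeans <- function(units) {
    if (!nrow(units))
        return(data.frame(gene = character(), amplicon_id = character(),
                          sample = character(), mean_pct = numeric(),
                          stringsAsFactors = FALSE))
    key <- interaction(units$gene, units$amplicon_id, units$sample,
                       drop = TRUE, sep = "\r")
    means <- tapply(units$meth_ratio_pct, key,
                    function(x) mean(x, na.rm = TRUE))
    parts <- do.call(rbind, strsplit(names(means), "\r", fixed = TRUE))
    data.frame(gene = parts[, 1L], amplicon_id = parts[, 2L],
               sample = parts[, 3L], mean_pct = as.numeric(means),
               stringsAsFactors = FALSE)
}

#' Amplicon informativeness
#'
#' An amplicon is informative when the tumor-panel average of its
#' per-sample mean methylation is strictly above `panelMin` while the
#' reference (melanocyte) mean stays strictly below `refMax`: only regions
#' differentially methylated between panel and reference carry signal for
#' the screen. Amplicons with no surviving unit are reported
#' `"uninformative: no data"`.
#'
#' @param units QC-filtered CpG-unit table (any number of amplicons).
#' @param panelSamples,refSamples Disjoint, non-empty sample-identifier
#'   vectors.
#' @param panelMin Panel-mean threshold in percent (default 20, strict >).
#' @param refMax Reference-mean ceiling in percent (default 10, strict <).
#' @return `data.frame` per amplicon: `gene`, `amplicon_id`, `panel_mean`,
#'   `ref_mean`, `informative`, `note`.
#' @export
ampliconInformative <- function(units, panelSamples, refSamples,
                                panelMin = 20, refMax = 10) {
    if (!length(panelSamples) || !length(refSamples) ||
        length(intersect(panelSamples, refSamples)))
        stop("panel and reference sample sets must be disjoint and non-empty",
             call. = FALSE)
    validateCpGUnits(units)
    amps <- unique(units[, c("gene", "amplicon_id")])
    if (!nrow(amps))
        return(data.frame(gene = character(), amplicon_id = character(),
                          panel_mean = numeric(), ref_mean = numeric(),
                          informative = logical(), note = character(),
                          stringsAsFactors = FALSE))
    m <- .ampliconSampleMeans(units)
    res <- lapply(seq_len(nrow(amps)), function(i) {
        mi <- m[m$gene == amps$gene[i] & m$amplicon_id == amps$amplicon_id[i], ]
        pm <- mi$mean_pct[mi$sample %in% panelSamples]
        rm_ <- mi$mean_pct[mi$sample %in% refSamples]
        if (!length(pm) && !length(rm_))
            return(data.frame(panel_mean = NA_real_, ref_mean = NA_real_,
                              informative = FALSE,
                              note = "uninformative: no data"))
        pmean <- if (length(pm)) mean(pm, na.rm = TRUE) else NA_real_
        rmean <- if (length(rm_)) mean(rm_, na.rm = TRUE) else NA_real_
        inf <- isTRUE(pmean > panelMin) && isTRUE(rmean < refMax)
        data.frame(panel_mean = pmean, ref_mean = rmean, informative = inf,
                   note = if (inf) "informative" else "uninformative")
    })
    cbind(amps, do.call(rbind, res), row.names = NULL)
}

#' Select informative CpG units
#'
#' Within informative amplicons, only the units showing high methylation
#' across the tumor panel (panel-mean ratio >= `siteMin`) enter the final
#' per-gene percentage; `n_informative_sites` counts the CpG dinucleotides
#' (sum of `n_cpgs`) in the retained units.
#'
#' @param units CpG-unit table restricted to informative amplicons.
#' @param panelSamples Tumor-panel sample identifiers.
#' @param siteMin Panel-mean threshold in percent (default 20, inclusive).
#' @return List with `units` (retained rows) and `n_informative_sites`
#'   (named by gene).
#' @export
selectInformativeSites <- function(units, panelSamples, siteMin = 20) {
    validateCpGUnits(units)
    key <- paste(units$gene, units$amplicon_id, units$unit_index, sep = "\r")
    inPanel <- units$sample %in% panelSamples
    pm <- tapply(units$meth_ratio_pct[inPanel], key[inPanel],
                 function(x) mean(x, na.rm = TRUE))
    keepKeys <- names(pm)[!is.na(pm) & pm >= siteMin]
    kept <- units[key %in% keepKeys, , drop = FALSE]
    uu <- kept[!duplicated(paste(kept$gene, kept$amplicon_id,
                                 kept$unit_index, sep = "\r")), ]
    n_sites <- tapply(uu$n_cpgs, uu$gene, sum)
    list(units = kept,
         n_informative_sites = stats::setNames(as.integer(n_sites),
                                               names(n_sites)))
}

#' Per-gene percent methylation from selected units
#'
#' Per sample, a gene's percent methylation is the mean ratio of its
#' selected units in that sample (missing units skipped; a sample with no
#' surviving unit is missing). The panel average is the mean of the
#' per-sample percentages over the panel samples; the reference average is
#' computed identically over the reference samples.
#'
#' @param units Selected CpG-unit table (see [selectInformativeSites()]).
#' @param panelSamples,refSamples Sample-identifier vectors.
#' @return List with `perSample` (genes x samples matrix of percent
#'   methylation) and `summary` (`data.frame`: `gene`, `panel_avg`,
#'   `ref_avg`).
#' @export
genePercentMethylation <- function(units, panelSamples, refSamples) {
    validateCpGUnits(units)
    if (!nrow(units))
        stop("no units selected; cannot compute percent methylation",
             call. = FALSE)
    genes <- sort(unique(units$gene))
    samples <- unique(c(panelSamples, refSamples))
    perSample <- matrix(NA_real_, length(genes), length(samples),
                        dimnames = list(genes, samples))
    sub <- units[units$sample %in% samples, , drop = FALSE]
    key <- interaction(sub$gene, sub$sample, drop = TRUE, sep = "\r")
    m <- tapply(sub$meth_ratio_pct, key, function(x)
        if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
    parts <- do.call(rbind, strsplit(names(m), "\r", fixed = TRUE))
    perSample[cbind(parts[, 1L], parts[, 2L])] <- as.numeric(m)
    rowAvg <- function(cols) {
        v <- perSample[, intersect(samples, cols), drop = FALSE]
        out <- rowMeans(v, na.rm = TRUE)
        out[rowSums(!is.na(v)) == 0L] <- NA_real_
        out
    }
    list(perSample = perSample,
         summary = data.frame(gene = genes,
                              panel_avg = unname(rowAvg(panelSamples)),
                              ref_avg = unname(rowAvg(refSamples)),
                              stringsAsFactors = FALSE))
}

#' Three-class methylation call
#'
#' Maps a percent methylation to the screen's groups: no/low for \[0, 20\],
#' medium for (20, 50\], high for (50, 100\]. The boundaries are half-open
#' so the printed ranges "0-20%", "20-50%" and ">50%" partition the scale;
#' only the 50 boundary is forced (">50%" is high), the 20 boundary is a
#' convention (20.0 is no/low).
#'
#' @param percent Numeric vector in \[0, 100\].
#' @return Factor with levels `no/low`, `medium`, `high`.
#' @examples
#' classifyMethylation(c(5, 42, 66))   # no/low, medium, high
#' @export
classifyMethylation <- function(percent) {
    if (any(!is.na(percent) & (percent < 0 | percent > 100)))
        stop("percent methylation must lie in [0, 100]", call. = FALSE)
    cut(percent, breaks = c(0, 20, 50, 100),
        labels = c("no/low", "medium", "high"),
        right = TRUE, include.lowest = TRUE)
}

#' Panel-to-reference methylation ratio
#'
#' Fold ratio of the panel-average percent methylation over the reference
#' average, computed on unrounded values; a zero (or missing) reference
#' yields a missing ratio.
#'
#' @param panelAvg,refAvg Numeric vectors of percent methylation.
#' @return Numeric vector of fold ratios.
#' @export
referenceRatio <- function(panelAvg, refAvg) {
    ifelse(is.na(refAvg) | refAvg == 0, NA_real_, panelAvg / refAvg)
}

#' Full EpiTYPER-style reduction
#'
#' QC-filters the units, scores amplicon informativeness, selects
#' high-methylation units within informative amplicons, and reduces to
#' per-gene per-sample percent methylation with panel/reference averages,
#' the panel-to-reference fold ratio, and the three-class call. Genes with
#' no informative amplicon appear in the summary with missing percentages
#' and the note `"no differential methylation"`.
#'
#' @param units CpG-unit table.
#' @param panelSamples,refSamples Disjoint sample-identifier vectors.
#' @param maxError QC uncertainty threshold in percent (default 10).
#' @param panelMin,refMax Amplicon-informativeness thresholds (defaults 20
#'   and 10).
#' @param siteMin Unit-selection threshold in percent (default 20).
#' @return List of class `"GeneMethylationCalls"`: `perSample` matrix,
#'   `summary` (`gene`, `panel_avg`, `ref_avg`, `ratio`, `group`,
#'   `n_informative_sites`, `note`), `amplicons` (the informativeness
#'   report).
#' @export
epityperReduce <- function(units, panelSamples, refSamples, maxError = 10,
                           panelMin = 20, refMax = 10, siteMin = 20) {
    qc <- qcFilterUnits(units, maxError = maxError)
    allGenes <- sort(unique(units$gene))
    amp <- ampliconInformative(qc, panelSamples, refSamples,
                               panelMin = panelMin, refMax = refMax)
    keep <- amp[amp$informative, c("gene", "amplicon_id")]
    inAmp <- qc[paste(qc$gene, qc$amplicon_id) %in%
                paste(keep$gene, keep$amplicon_id), , drop = FALSE]
    sel <- selectInformativeSites(inAmp, panelSamples, siteMin = siteMin)
    if (nrow(sel$units)) {
        gp <- genePercentMethylation(sel$units, panelSamples, refSamples)
        perSample <- gp$perSample
        smry <- gp$summary
    } else {
        perSample <- matrix(NA_real_, 0L, 0L)
        smry <- data.frame(gene = character(), panel_avg = numeric(),
                           ref_avg = numeric(), stringsAsFactors = FALSE)
    }
    drop <- setdiff(allGenes, smry$gene)
    if (length(drop))
        smry <- rbind(smry, data.frame(gene = drop, panel_avg = NA_real_,
                                       ref_avg = NA_real_))
    smry <- smry[order(smry$gene), , drop = FALSE]
    smry$ratio <- referenceRatio(smry$panel_avg, smry$ref_avg)
    smry$group <- classifyMethylation(smry$panel_avg)
    ns <- sel$n_informative_sites
    smry$n_informative_sites <- ifelse(smry$gene %in% names(ns),
                                       ns[smry$gene], 0L)
    smry$note <- ifelse(smry$gene %in% drop, "no differential methylation",
                        "called")
    rownames(smry) <- NULL
    structure(list(perSample = perSample, summary = smry, amplicons = amp),
              class = "GeneMethylationCalls")
}

#' @export
print.GeneMethylationCalls <- function(x, ...) {
    cat("GeneMethylationCalls:", nrow(x$summary), "genes,",
        sum(x$amplicons$informative), "of", nrow(x$amplicons),
        "amplicons informative\n")
    print(utils::head(x$summary, 10))
    invisible(x)
}
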