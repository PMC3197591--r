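#' Run the full screen end to end
#'
#' Orchestrates the stages over either a synthetic dataset or user-supplied
#' files: (simulate) -> beta/delta -> expression ratios -> demethylation
#' response -> candidate cascade -> EpiTYPER-style reduction ->
#' methylation-expression correlation. Returns a run report with
#' stage-by-stage gene counts; optionally writes every intermediate table,
#' the report JSON, and a config echo.
#'
#' @param config Named list. Exactly one of:
#'   * `synthetic`: a `"SyntheticConfig"` (or argument list for
#'     [syntheticConfig()]), or
#'   * `paths`: list with `beta`, `expression`, `treated`, `mock`,
#'     `cpg_units` (TSV paths), `reference` (reference sample id), and
#'     optionally `amplicons` (BED).
#'   Optional entries: `thresholds` ([FilterThresholds-class]),
#'   `exclusions` ([ExclusionLists-class]), `epityper` (list with
#'   `max_error`, `panel_min`, `ref_max`, `site_min`), `formula`
#'   (`"standard"` or `"as_printed"`), `seed` (overrides the synthetic
#'   block's seed).
#' @param outDir Optional output directory for TSVs and `report.json`.
#' @return List of class `"ScreenReport"`: `counts` (stage-by-stage),
#'   `candidates` (cascade table), `calls` (methylation calls summary),
#'   `correlations`, `reexpression` (filter bookkeeping), `config_echo`.
#' @examples
#' rep <- runPipeline(list(synthetic = syntheticConfig(n_genes = 60,
#'                                                     n_planted = 4)))
#' rep$counts$n_candidates
#' @export
runPipeline <- function(config, outDir = NULL) {
    if (!is.null(config$synthetic) && !is.null(config$paths))
        stop("configuration error: provide exactly one of 'synthetic' or ",
             "'paths', not both", call. = FALSE)
    if (is.null(config$synthetic) && is.null(config$paths))
        stop("configuration error: provide one of 'synthetic' or 'paths'",
             call. = FALSE)
    thresholds <- config$thresholds %||% FilterThresholds()
    exclusions <- config$exclusions %||% ExclusionLists()
    validObject(thresholds); validObject(exclusions)
    ep <- config$epityper %||% list()
    maxError <- ep$max_error %||% 10
    panelMin <- ep$panel_min %||% 20
    refMax <- ep$ref_max %||% 10
    siteMin <- ep$site_min %||% 20
    formula <- config$formula %||% "standard"

    if (!is.null(config$synthetic)) {
        syn <- config$synthetic
        if (!inherits(syn, "SyntheticConfig"))
            syn <- do.call(syntheticConfig, as.list(syn))
        if (!is.null(config$seed)) {
            syn$seed <- as.integer(config$seed)
            syn <- do.call(syntheticConfig, unclass(syn))
        }
        ds <- generateDataset(syn)
        beta <- ds$beta
        expression <- ds$expression
        treated <- ds$treated; mock <- ds$mock
        units <- ds$cpg_units
    } else {
        p <- config$paths
        for (f in c("beta", "expression", "treated", "mock", "cpg_units"))
            if (is.null(p[[f]]))
                stop("configuration error: paths$", f, " is required",
                     call. = FALSE)
        if (is.null(p$reference))
            stop("configuration error: paths$reference is required",
                 call. = FALSE)
        beta <- readBetaMatrix(p$beta, referenceId = p$reference)
        expression <- readExpressionMatrix(p$expression,
                                           referenceId = p$reference)
        treated <- .readMatrixTSV(p$treated)
        mock <- .readMatrixTSV(p$mock)
        units <- readCpGUnits(p$cpg_units)
    }

    delta <- computeDelta(beta)
    ratios <- expressionRatio(expression)
    fc <- foldChange(treated, mock)
    reexpr <- reexpressionSummary(fc, threshold = 2)
    cascade <- runCascade(delta, ratios, fc, thresholds = thresholds,
                          exclusions = exclusions, keep = config$keep)

    lines <- colnames(assay(fc, "fc"))
    refId <- referenceId(beta)
    calls <- epityperReduce(units,
                            panelSamples = lines, refSamples = refId,
                            maxError = maxError, panelMin = panelMin,
                            refMax = refMax, siteMin = siteMin)
    correlations <- methylationExpressionPanel(calls, ratios,
                                               formula = formula)

    counts <- c(list(n_genes = nrow(beta)), reexpr,
                cascadeSummary(cascade),
                list(n_called_genes = sum(calls$summary$note == "called"),
                     n_correlated = sum(correlations$tested)))
    report <- structure(list(counts = counts,
                             candidates = cascade,
                             calls = calls$summary,
                             correlations = correlations,
                             reexpression = reexpr,
                             config_echo = .echoConfig(config)),
                        class = "ScreenReport")
    if (!is.null(outDir)) .writeReport(report, delta, ratios, fc, calls,
                                       outDir)
    report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.echoConfig <- function(config) {
    e <- config
    if (!is.null(e$synthetic)) e$synthetic <- unclass(e$synthetic)
    if (!is.null(e$thresholds))
        e$thresholds <- list(methMin = e$thresholds@methMin,
                             minSamples = e$thresholds@minSamples,
                             downregFold = e$thresholds@downregFold,
                             reexprMeanMin = e$thresholds@reexprMeanMin)
    if (!is.null(e$exclusions))
        e$exclusions <- list(oncogenes = e$exclusions@oncogenes,
                             previouslyIdentified =
                                 e$exclusions@previouslyIdentified,
                             unannotated = e$exclusions@unannotated,
                             unannotatedPattern =
                                 e$exclusions@unannotatedPattern,
                             fpMethMin = e$exclusions@fpMethMin,
                             fpFcMax = e$exclusions@fpFcMax,
                             fpMinLines = e$exclusions@fpMinLines)
    e
}

.writeReport <- function(report, delta, ratios, fc, calls, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    .writeTSV(assay(delta, "delta"), file.path(outDir, "delta.tsv"),
              rowLabel = "gene")
    .writeTSV(assay(ratios, "ratio"), file.path(outDir, "ratios.tsv"),
              rowLabel = "gene")
    .writeTSV(assay(fc, "fc"), file.path(outDir, "fold_change.tsv"),
              rowLabel = "gene")
    .writeTSV(report$candidates, file.path(outDir, "candidates.tsv"))
    .writeTSV(report$calls, file.path(outDir, "gene_calls.tsv"))
    .writeTSV(calls$amplicons, file.path(outDir, "amplicon_qc.tsv"))
    .writeTSV(report$correlations, file.path(outDir, "correlations.tsv"))
    jsonlite::write_json(list(counts = report$counts,
                              config = report$config_echo),
                         file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    invisible(outDir)
}

#' @export
print.ScreenReport <- function(x, ...) {
    cat("ScreenReport\n")
    for (nm in names(x$counts))
        cat(sprintf("  %-28s %s\n", nm, x$counts[[nm]]))
    invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' Convenience wrapper turning a YAML file into the list [runPipeline()]
#' expects; nested `thresholds` and `exclusions` blocks are converted to
#' their classes.
#'
#' @param path YAML path.
#' @return Configuration list.
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (!is.null(cfg$thresholds))
        cfg$thresholds <- do.call(FilterThresholds, cfg$thresholds)
    if (!is.null(cfg$exclusions))
        cfg$exclusions <- do.call(ExclusionLists, cfg$exclusions)
    cfg
}

.SUPPORTED_ACCESSIONS <- c("GSE28356", "GSE7127", "GSE32492")

#' Fetch the screen's deposited series (convenience; needs network)
#'
#' Downloads a GEO series matrix for one of the deposited accessions
#' (Infinium Methylation27 methylation, U133 Plus 2.0 constitutive
#' expression, post-demethylation re-expression). Purely optional: the
#' pipeline never requires it, and it fails with a clear error when the
#' network is unavailable.
#'
#' @param accession One of `GSE28356`, `GSE7127`, `GSE32492`.
#' @param destDir Download directory.
#' @return Path of the downloaded file.
#' @export
fetchAccessions <- function(accession, destDir = ".") {
    if (length(accession) != 1L || !accession %in% .SUPPORTED_ACCESSIONS)
        stop("unsupported accession; supported: ",
             paste(.SUPPORTED_ACCESSIONS, collapse = ", "), call. = FALSE)
    stub <- sub("[0-9]{3}$", "nnn", accession)
    url <- sprintf(
        "https://ftp.ncbi.nlm.nih.gov/geo/series/%s/%s/matrix/%s_series_matrix.txt.gz",
        stub, accession, accession)
    dest <- file.path(destDir, basename(url))
    ok <- tryCatch(utils::download.file(url, dest, quiet = TRUE) == 0,
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok)
        stop("download of ", accession, " failed (network unavailable?); ",
             "the pipeline does not require fetched data", call. = FALSE)
    dest
}
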