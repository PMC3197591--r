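.writeTSV <- function(df, path, rowLabel = NULL) {
    if (!is.null(rowLabel)) {
        df <- cbind(stats::setNames(data.frame(rownames(df),
                                               stringsAsFactors = FALSE),
                                    rowLabel),
                    as.data.frame(df, stringsAsFactors = FALSE))
        rownames(df) <- NULL
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

.readMatrixTSV <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    mode(m) <- "numeric"
    rownames(m) <- as.character(df[[1L]])
    m
}

#' Read a beta matrix from TSV
#'
#' Expects features (probes or genes) as rows, samples as columns, the
#' first column holding feature identifiers, `NA` for missing.
#'
#' @param path TSV path.
#' @param referenceId Reference sample column name.
#' @return A [BetaMatrix-class].
#' @export
readBetaMatrix <- function(path, referenceId)
    BetaMatrix(.readMatrixTSV(path), referenceId = referenceId)

#' Read an expression matrix from TSV
#'
#' The scale is taken from a sidecar JSON (`<path>.json`, field `scale`)
#' when present, so ratios are never taken on log-scale data by mistake;
#' otherwise `scaleTag` is used.
#'
#' @param path TSV path.
#' @param referenceId Reference sample column name.
#' @param scaleTag Fallback scale tag (default `"linear"`).
#' @return An [ExpressionMatrix-class].
#' @export
readExpressionMatrix <- function(path, referenceId, scaleTag = "linear") {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
        meta <- jsonlite::read_json(sidecar)
        if (!is.null(meta$scale)) scaleTag <- meta$scale
    }
    ExpressionMatrix(.readMatrixTSV(path), referenceId = referenceId,
                     scaleTag = scaleTag)
}

#' Read a CpG-unit table from TSV
#'
#' @param path TSV path with the unit schema (see [validateCpGUnits()]).
#' @return Validated CpG-unit `data.frame`.
#' @export
readCpGUnits <- function(path) {
    units <- utils::read.delim(path, stringsAsFactors = FALSE)
    units$overlap_flag <- as.logical(units$overlap_flag)
    validateCpGUnits(units)
    units
}

#' Read amplicon definitions from BED
#'
#' 6-column BED (0-based half-open); the `name` field is expected to be
#' `<gene>_<amplicon id>`.
#'
#' @param path BED path.
#' @return A `GenomicRanges::GRanges` with `name` and derived `gene`
#'   metadata columns.
#' @export
readAmplicons <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    gr$gene <- sub("_[^_]*$", "", gr$name)
    gr
}

#' Write a synthetic dataset to a directory
#'
#' Emits the exact TSV schemas consumed by the pipeline (`beta.tsv`,
#' `expression.tsv` with sidecar scale JSON, `treated.tsv`, `mock.tsv`,
#' `cpg_units.tsv`), `amplicons.bed` (6-column BED), the blind-evaluation
#' `truth.tsv` manifest, and `config.yaml`.
#'
#' @param dataset A `"SyntheticDataset"` from [generateDataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    .writeTSV(assay(dataset$beta, "beta"), file.path(dir, "beta.tsv"),
              rowLabel = "gene")
    .writeTSV(assay(dataset$expression, "exprs"),
              file.path(dir, "expression.tsv"), rowLabel = "gene")
    jsonlite::write_json(list(scale = scaleTag(dataset$expression),
                              reference = referenceId(dataset$expression)),
                         file.path(dir, "expression.tsv.json"),
                         auto_unbox = TRUE)
    .writeTSV(dataset$treated, file.path(dir, "treated.tsv"),
              rowLabel = "gene")
    .writeTSV(dataset$mock, file.path(dir, "mock.tsv"), rowLabel = "gene")
    .writeTSV(dataset$cpg_units, file.path(dir, "cpg_units.tsv"))
    rtracklayer::export(dataset$amplicons, file.path(dir, "amplicons.bed"),
                        format = "BED")
    .writeTSV(dataset$truth, file.path(dir, "truth.tsv"))
    cfg <- unclass(dataset$config)
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
    invisible(dir)
}
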