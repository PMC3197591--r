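#' Configuration of the synthetic-data generator
#'
#' Defines the study conditions emulated by the generator: a panel of
#' melanoma-like cell lines plus one melanocyte-pool reference, a handful
#' of planted silenced genes (high promoter methylation, suppressed
#' constitutive expression, strong re-expression after demethylating
#' treatment, in the same subset of lines), and an EpiTYPER-style CpG-unit
#' panel over the planted genes plus background contrast genes.
#'
#' Methylation values are drawn from normal distributions on the percent
#' scale and clamped to \[0, 100\] -- simple and sufficient to exercise
#' every threshold; a beta-distribution noise model would also be
#' defensible but is not used. The reference expression column is the
#' unsuppressed per-gene baseline; per-line suppression is applied
#' multiplicatively before log-normal noise.
#'
#' @param n_genes Number of genes (default 500).
#' @param n_lines Number of cell lines besides the reference (default 11).
#' @param n_planted Number of truly silenced genes (default 20).
#' @param meth_high_mean Planted-gene methylation center in methylated
#'   lines, percent (default 80).
#' @param meth_bg_mean Background methylation center, percent (default 5).
#' @param meth_noise_sd Methylation noise SD, percent (default 5).
#' @param silencing_factor Fold suppression of constitutive expression in
#'   methylated lines (default 8).
#' @param reexpr_fold_mean Central treated/mock fold for planted genes in
#'   their methylated lines (default 10).
#' @param penetrance Fraction of lines in which a planted gene is
#'   methylated (default 0.6); `ceiling(penetrance * n_lines)` must be
#'   >= 2 so planted genes can satisfy the two-sample filter.
#' @param n_amplicons_per_gene Amplicons per gene on the CpG-unit panel
#'   (default 2).
#' @param n_units_per_amplicon CpG units per amplicon (default 5).
#' @param unit_error_rate Fraction of unit measurements given a
#'   disqualifying error estimate (>= 10 percent) or an overlap flag
#'   (default 0.1).
#' @param n_background_panel Background genes included on the CpG-unit
#'   panel for contrast (default: `n_planted`, capped by availability).
#' @param seed Integer seed; identical configurations produce identical
#'   datasets.
#' @return Validated list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(n_genes = 500, n_lines = 11, n_planted = 20,
                            meth_high_mean = 80, meth_bg_mean = 5,
                            meth_noise_sd = 5, silencing_factor = 8,
                            reexpr_fold_mean = 10, penetrance = 0.6,
                            n_amplicons_per_gene = 2,
                            n_units_per_amplicon = 5,
                            unit_error_rate = 0.1,
                            n_background_panel = NULL,
                            seed = 1) {
    cfg <- list(n_genes = as.integer(n_genes), n_lines = as.integer(n_lines),
                n_planted = as.integer(n_planted),
                meth_high_mean = meth_high_mean, meth_bg_mean = meth_bg_mean,
                meth_noise_sd = meth_noise_sd,
                silencing_factor = silencing_factor,
                reexpr_fold_mean = reexpr_fold_mean, penetrance = penetrance,
                n_amplicons_per_gene = as.integer(n_amplicons_per_gene),
                n_units_per_amplicon = as.integer(n_units_per_amplicon),
                unit_error_rate = unit_error_rate,
                n_background_panel =
                    if (is.null(n_background_panel)) as.integer(n_planted)
                    else as.integer(n_background_panel),
                seed = as.integer(seed))
    if (cfg$n_genes < 1)
        stop("invalid configuration: n_genes must be >= 1", call. = FALSE)
    if (cfg$n_lines < 2)
        stop("invalid configuration: n_lines must be >= 2", call. = FALSE)
    if (cfg$n_planted < 0 || cfg$n_planted > cfg$n_genes)
        stop("invalid configuration: need 0 <= n_planted <= n_genes",
             call. = FALSE)
    for (p in c("meth_high_mean", "meth_bg_mean", "meth_noise_sd"))
        if (cfg[[p]] < 0 || cfg[[p]] > 100)
            stop("invalid configuration: ", p, " must lie in [0, 100]",
                 call. = FALSE)
    for (p in c("silencing_factor", "reexpr_fold_mean"))
        if (cfg[[p]] <= 0)
            stop("invalid configuration: ", p, " must be > 0", call. = FALSE)
    if (cfg$penetrance <= 0 || cfg$penetrance > 1)
        stop("invalid configuration: penetrance must lie in (0, 1]",
             call. = FALSE)
    if (cfg$n_planted > 0 && ceiling(cfg$penetrance * cfg$n_lines) < 2)
        stop("invalid configuration: penetrance * n_lines must be >= 2 ",
             "(planted genes could not pass the two-sample filter)",
             call. = FALSE)
    if (cfg$unit_error_rate < 0 || cfg$unit_error_rate > 1)
        stop("invalid configuration: unit_error_rate must lie in [0, 1]",
             call. = FALSE)
    if (cfg$n_amplicons_per_gene < 1 || cfg$n_units_per_amplicon < 1)
        stop("invalid configuration: amplicon/unit counts must be >= 1",
             call. = FALSE)
    if (cfg$n_background_panel < 0 ||
        cfg$n_background_panel > cfg$n_genes - cfg$n_planted)
        stop("invalid configuration: n_background_panel must lie in ",
             "[0, n_genes - n_planted]", call. = FALSE)
    structure(cfg, class = "SyntheticConfig")
}

.clamp01 <- function(x) pmin(pmax(x, 0), 100)

.REFERENCE_ID <- "MELPOOL"

#' Generate a paired synthetic dataset with planted silenced genes
#'
#' Draws a complete set of linked tables over one gene universe and one
#' sample panel: beadarray-style percent methylation (with the melanocyte
#' reference column), linear constitutive expression (reference column =
#' unsuppressed baseline), a treated/mock expression pair for the
#' demethylation response, an EpiTYPER-style CpG-unit panel, amplicon
#' definitions, and the ground-truth manifest. Planted genes are methylated
#' near `meth_high_mean` (delta vs reference >= 60 by construction at the
#' defaults) in exactly `ceiling(penetrance * n_lines)` lines, suppressed
#' `silencing_factor`-fold in those same lines, and re-expressed about
#' `reexpr_fold_mean`-fold there after treatment; background genes draw
#' from the background distributions throughout.
#'
#' The truth manifest is a separate table never consumed by the pipeline,
#' so downstream evaluation is blind.
#'
#' @param config A `"SyntheticConfig"` from [syntheticConfig()].
#' @return List of class `"SyntheticDataset"`: `beta` ([BetaMatrix-class]),
#'   `expression` (linear [ExpressionMatrix-class] with reference),
#'   `treated`, `mock` (genes x lines matrices, no reference column),
#'   `cpg_units` (CpG-unit `data.frame`), `amplicons`
#'   (`GenomicRanges::GRanges`), `truth` (`data.frame`: `gene`,
#'   `methylated_lines`, `n_methylated`), `config`.
#' @examples
#' ds <- generateDataset(syntheticConfig(n_genes = 50, n_planted = 3))
#' ds$truth$gene
#' @export
generateDataset <- function(config) {
    if (!inherits(config, "SyntheticConfig"))
        config <- do.call(syntheticConfig, as.list(config))
    set.seed(config$seed)
    genes <- sprintf("GENE%04d", seq_len(config$n_genes))
    lines <- sprintf("MM%02d", seq_len(config$n_lines))
    ref <- .REFERENCE_ID

    planted <- sort(sample(genes, config$n_planted))
    nMeth <- ceiling(config$penetrance * config$n_lines)
    state <- matrix(FALSE, config$n_genes, config$n_lines,
                    dimnames = list(genes, lines))
    for (g in planted)
        state[g, sample(config$n_lines, nMeth)] <- TRUE

    # beadarray beta: clamped normals around high/background centers
    center <- ifelse(state, config$meth_high_mean, config$meth_bg_mean)
    beta <- .clamp01(matrix(
        stats::rnorm(length(center), center, config$meth_noise_sd),
        nrow(center), dimnames = dimnames(center)))
    betaRef <- .clamp01(stats::rnorm(config$n_genes, config$meth_bg_mean,
                                     config$meth_noise_sd))
    betaMat <- BetaMatrix(cbind(beta, matrix(betaRef, ncol = 1,
                                             dimnames = list(genes, ref))),
                          referenceId = ref)

    # constitutive expression: reference = unsuppressed baseline;
    # suppression applied multiplicatively before log-normal noise
    baseline <- stats::rlnorm(config$n_genes, meanlog = log(100), sdlog = 1)
    suppress <- ifelse(state, 1 / config$silencing_factor, 1)
    noise <- matrix(stats::rlnorm(length(state), 0, 0.2), nrow(state))
    exprLines <- baseline * suppress * noise
    dimnames(exprLines) <- dimnames(state)
    exprMat <- ExpressionMatrix(
        cbind(exprLines, matrix(baseline, ncol = 1,
                                dimnames = list(genes, ref))),
        referenceId = ref, scaleTag = "linear")

    # demethylation response: mock = constitutive line values; treated
    # multiplies in the re-expression fold for methylated planted cells
    fold <- matrix(stats::rlnorm(length(state), 0, 0.15), nrow(state))
    fold[state] <- stats::rlnorm(sum(state),
                                 log(config$reexpr_fold_mean), 0.2)
    mock <- exprLines
    treated <- mock * fold
    dimnames(treated) <- dimnames(state)

    truth <- data.frame(
        gene = planted,
        methylated_lines = vapply(planted, function(g)
            paste(lines[state[g, ]], collapse = ","), ""),
        n_methylated = vapply(planted, function(g)
            sum(state[g, ]), 0L),
        row.names = NULL, stringsAsFactors = FALSE)

    panelGenes <- c(planted,
                    sort(sample(setdiff(genes, planted),
                                config$n_background_panel)))
    ds <- structure(list(
        beta = betaMat, expression = exprMat,
        treated = treated, mock = mock,
        cpg_units = NULL, amplicons = NULL,
        truth = truth, state = state, panel_genes = panelGenes,
        config = config), class = "SyntheticDataset")
    ep <- generateEpityperPanel(config, truth, panelGenes = panelGenes)
    ds$cpg_units <- ep$units
    ds$amplicons <- ep$amplicons
    ds
}

#' Generate an EpiTYPER-style CpG-unit panel
#'
#' Per-unit methylation ratios are drawn around the planted methylation
#' state (high in a planted gene's methylated lines, background elsewhere
#' and in the reference), so every planted gene has amplicons whose panel
#' mean exceeds 20 percent while the reference stays below 10 percent. A
#' `unit_error_rate` fraction of unit measurements receives either an
#' error estimate of at least 10 percent or an overlap flag, to exercise
#' the QC filter.
#'
#' Uses its own seed stream (derived from `config$seed`) so the same
#' `config` and `truth` give the same panel whether this is called
#' standalone or from [generateDataset()].
#'
#' @param config A `"SyntheticConfig"`.
#' @param truth Truth manifest from [generateDataset()] (`gene`,
#'   `methylated_lines`).
#' @param panelGenes Genes to place on the panel (default: the truth genes
#'   only).
#' @return List with `units` (CpG-unit `data.frame`, one row per unit and
#'   sample, reference included) and `amplicons`
#'   (`GenomicRanges::GRanges`, one range per amplicon within 2500 bp
#'   upstream of each gene's nominal transcription start).
#' @export
generateEpityperPanel <- function(config, truth, panelGenes = NULL) {
    if (!inherits(config, "SyntheticConfig"))
        config <- do.call(syntheticConfig, as.list(config))
    set.seed(config$seed + 1L)
    if (is.null(panelGenes)) panelGenes <- truth$gene
    lines <- sprintf("MM%02d", seq_len(config$n_lines))
    samples <- c(lines, .REFERENCE_ID)
    methLines <- stats::setNames(
        strsplit(truth$methylated_lines, ",", fixed = TRUE), truth$gene)

    if (!length(panelGenes)) {
        units <- data.frame(gene = character(), amplicon_id = character(),
                            unit_index = integer(), n_cpgs = integer(),
                            sample = character(), meth_ratio_pct = numeric(),
                            error_pct = numeric(), overlap_flag = logical(),
                            stringsAsFactors = FALSE)
        return(list(units = units, amplicons = GenomicRanges::GRanges()))
    }
    nA <- config$n_amplicons_per_gene
    nU <- config$n_units_per_amplicon
    grid <- expand.grid(unit_index = seq_len(nU), amplicon = seq_len(nA),
                        gene = panelGenes, stringsAsFactors = FALSE)
    grid$amplicon_id <- paste0(grid$gene, "_amp", grid$amplicon)
    grid$n_cpgs <- sample(1:4, nrow(grid), replace = TRUE)

    rows <- grid[rep(seq_len(nrow(grid)), each = length(samples)), ]
    rows$sample <- rep(samples, nrow(grid))
    isMeth <- mapply(function(g, s) s %in% methLines[[g]],
                     rows$gene, rows$sample)
    center <- ifelse(isMeth, config$meth_high_mean, config$meth_bg_mean)
    rows$meth_ratio_pct <- .clamp01(
        stats::rnorm(nrow(rows), center, config$meth_noise_sd))
    bad <- stats::runif(nrow(rows)) < config$unit_error_rate
    overlap <- bad & stats::runif(nrow(rows)) < 0.3
    rows$error_pct <- ifelse(bad & !overlap,
                             stats::runif(nrow(rows), 10, 30),
                             stats::runif(nrow(rows), 0, 9.9))
    rows$overlap_flag <- overlap
    units <- rows[, .UNIT_COLS]
    rownames(units) <- NULL

    amps <- unique(grid[, c("gene", "amplicon", "amplicon_id")])
    geneIdx <- match(amps$gene, sort(unique(amps$gene)))
    tss <- geneIdx * 10000L
    start0 <- tss - 2500L + (amps$amplicon - 1L) * 500L   # 0-based
    gr <- GenomicRanges::GRanges(
        seqnames = "chr1",
        ranges = IRanges::IRanges(start = start0 + 1L, width = 500L),
        strand = "+",
        name = amps$amplicon_id, score = 0L, gene = amps$gene)
    list(units = validateCpGUnits(units), amplicons = gr)
}

#' @export
print.SyntheticDataset <- function(x, ...) {
    cat("SyntheticDataset:", x$config$n_genes, "genes x",
        x$config$n_lines, "lines (+ reference), ",
        nrow(x$truth), "planted silenced genes\n")
    invisible(x)
}
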