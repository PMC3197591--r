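# Small fixture builders, all seeded by the caller.

randomBeta <- function(nGenes = 8, nSamples = 4, ref = "MELPOOL",
                       naFrac = 0) {
    v <- matrix(runif(nGenes * (nSamples + 1), 0, 100), nGenes,
                dimnames = list(sprintf("G%02d", seq_len(nGenes)),
                                c(sprintf("S%02d", seq_len(nSamples)), ref)))
    if (naFrac > 0)
        v[, seq_len(nSamples)][
            sample(length(v[, seq_len(nSamples)]),
                   round(naFrac * nGenes * nSamples))] <- NA
    BetaMatrix(v, referenceId = ref)
}

randomExpression <- function(nGenes = 8, nSamples = 4, ref = "MELPOOL") {
    v <- matrix(rlnorm(nGenes * (nSamples + 1), log(50), 1), nGenes,
                dimnames = list(sprintf("G%02d", seq_len(nGenes)),
                                c(sprintf("S%02d", seq_len(nSamples)), ref)))
    ExpressionMatrix(v, referenceId = ref, scaleTag = "linear")
}

randomFoldChange <- function(nGenes = 8, nLines = 5) {
    FoldChangeMatrix(matrix(rlnorm(nGenes * nLines, 0, 1), nGenes,
                            dimnames = list(sprintf("G%02d", seq_len(nGenes)),
                                            sprintf("L%02d", seq_len(nLines)))))
}

randomUnits <- function(nGenes = 3, nAmps = 2, nUnits = 3,
                        samples = c("S1", "S2", "S3", "MELPOOL")) {
    grid <- expand.grid(unit_index = seq_len(nUnits),
                        amp = seq_len(nAmps),
                        gene = sprintf("G%d", seq_len(nGenes)),
                        sample = samples, stringsAsFactors = FALSE)
    data.frame(gene = grid$gene,
               amplicon_id = paste0(grid$gene, "_a", grid$amp),
               unit_index = grid$unit_index,
               n_cpgs = rep_len(c(1L, 2L, 3L), nrow(grid)),
               sample = grid$sample,
               meth_ratio_pct = runif(nrow(grid), 0, 100),
               error_pct = runif(nrow(grid), 0, 9),
               overlap_flag = FALSE,
               stringsAsFactors = FALSE)
}
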