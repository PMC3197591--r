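test_that("syntheticConfig names the violated bound", {
    expect_error(syntheticConfig(n_planted = 30, n_genes = 20), "n_planted")
    expect_error(syntheticConfig(meth_high_mean = 120), "meth_high_mean")
    expect_error(syntheticConfig(silencing_factor = 0), "silencing_factor")
    expect_error(syntheticConfig(penetrance = 0), "penetrance")
    expect_error(syntheticConfig(n_lines = 4, penetrance = 0.2),
                 "two-sample")
    expect_error(syntheticConfig(unit_error_rate = 1.5), "unit_error_rate")
})

test_that("identical configurations give byte-identical datasets", {
    cfg <- syntheticConfig(n_genes = 40, n_planted = 3, seed = 123)
    d1 <- generateDataset(cfg)
    d2 <- generateDataset(syntheticConfig(n_genes = 40, n_planted = 3,
                                          seed = 123))
    expect_identical(assay(d1$beta), assay(d2$beta))
    expect_identical(d1$cpg_units, d2$cpg_units)
    expect_identical(d1$truth, d2$truth)
    dir1 <- file.path(tempdir(), "ds1"); dir2 <- file.path(tempdir(), "ds2")
    writeDataset(d1, dir1); writeDataset(d2, dir2)
    for (f in list.files(dir1))
        expect_identical(readLines(file.path(dir1, f)),
                         readLines(file.path(dir2, f)))
    # a different seed changes the data
    d3 <- generateDataset(syntheticConfig(n_genes = 40, n_planted = 3,
                                          seed = 124))
    expect_false(identical(assay(d1$beta), assay(d3$beta)))
})

test_that("planted genes satisfy the cascade preconditions by construction", {
    cfg <- syntheticConfig(n_genes = 200, n_planted = 10, seed = 5)
    ds <- generateDataset(cfg)
    delta <- assay(computeDelta(ds$beta))
    ratio <- assay(expressionRatio(ds$expression))
    fc <- assay(foldChange(ds$treated, ds$mock))
    nMeth <- ceiling(cfg$penetrance * cfg$n_lines)
    for (i in seq_len(nrow(ds$truth))) {
        g <- ds$truth$gene[i]
        lines <- strsplit(ds$truth$methylated_lines[i], ",")[[1]]
        expect_length(lines, nMeth)
        expect_true(all(delta[g, lines] >= 60))
        expect_true(all(ratio[g, lines] <= 0.25))
        expect_true(mean(fc[g, ]) > 4)
        # not reactivated in ALL lines: unmethylated lines stay near 1
        expect_true(any(fc[g, setdiff(colnames(fc), lines)] < 2))
    }
})

test_that("background genes fail the cascade across seeds", {
    for (seed in c(101, 202, 303)) {
        ds <- generateDataset(syntheticConfig(n_genes = 300, n_planted = 5,
                                              seed = seed))
        cas <- runCascade(computeDelta(ds$beta),
                          expressionRatio(ds$expression),
                          foldChange(ds$treated, ds$mock))
        cand <- cas$symbol[cas$status == "candidate"]
        expect_length(setdiff(cand, toupper(ds$truth$gene)), 0)
    }
})

test_that("no planted genes means an empty truth list and no candidates", {
    ds <- generateDataset(syntheticConfig(n_genes = 100, n_planted = 0,
                                          seed = 6))
    expect_equal(nrow(ds$truth), 0L)
    expect_equal(nrow(ds$cpg_units), 0L)
    cas <- runCascade(computeDelta(ds$beta),
                      expressionRatio(ds$expression),
                      foldChange(ds$treated, ds$mock))
    expect_equal(sum(cas$status == "candidate"), 0L)
})

test_that("unit_error_rate 0 keeps and 1 removes every unit", {
    cfg0 <- syntheticConfig(n_genes = 30, n_planted = 3, seed = 7,
                            unit_error_rate = 0)
    ds0 <- generateDataset(cfg0)
    expect_equal(nrow(qcFilterUnits(ds0$cpg_units)), nrow(ds0$cpg_units))

    cfg1 <- syntheticConfig(n_genes = 30, n_planted = 3, seed = 7,
                            unit_error_rate = 1)
    ds1 <- generateDataset(cfg1)
    expect_equal(nrow(qcFilterUnits(ds1$cpg_units)), 0L)
    red <- epityperReduce(ds1$cpg_units,
                          panelSamples = sprintf("MM%02d", 1:11),
                          refSamples = "MELPOOL")
    expect_true(all(is.na(red$summary$panel_avg)))   # calls are missing
})

test_that("epityper panel separates planted genes from the reference", {
    cfg <- syntheticConfig(n_genes = 80, n_planted = 6, seed = 8)
    ds <- generateDataset(cfg)
    qc <- qcFilterUnits(ds$cpg_units)
    amp <- ampliconInformative(qc, panelSamples = sprintf("MM%02d", 1:11),
                               refSamples = "MELPOOL")
    for (g in ds$truth$gene)
        expect_true(any(amp$informative[amp$gene == g]))

    # reduced per-gene percent in methylated lines tracks the planted level
    red <- epityperReduce(ds$cpg_units,
                          panelSamples = sprintf("MM%02d", 1:11),
                          refSamples = "MELPOOL")
    for (i in seq_len(nrow(ds$truth))) {
        g <- ds$truth$gene[i]
        lines <- strsplit(ds$truth$methylated_lines[i], ",")[[1]]
        per <- red$perSample[g, lines]
        expect_true(all(abs(per - cfg$meth_high_mean) <= 10))
    }

    # panel/reference fold ratio is consistent with the construction:
    # panel average mixes methylated and background lines
    nMeth <- ceiling(cfg$penetrance * cfg$n_lines)
    expectPanel <- (nMeth * cfg$meth_high_mean +
                    (cfg$n_lines - nMeth) * cfg$meth_bg_mean) / cfg$n_lines
    planted <- red$summary[red$summary$gene %in% ds$truth$gene, ]
    expect_true(all(abs(planted$panel_avg - expectPanel) <= 10))
    # the reference average over ~10 units has CV near 30%, so per-gene
    # ratios scatter around the constructed differential within a factor
    # of two; their mean tracks it much more closely
    expectRatio <- expectPanel / cfg$meth_bg_mean
    expect_true(all(planted$ratio > expectRatio / 2 &
                    planted$ratio < expectRatio * 2))
    expect_lt(abs(mean(planted$ratio) - expectRatio) / expectRatio, 0.25)
})

test_that("standalone epityper panel equals the one bundled by generateDataset", {
    cfg <- syntheticConfig(n_genes = 50, n_planted = 4, seed = 9)
    ds <- generateDataset(cfg)
    ep <- generateEpityperPanel(cfg, ds$truth, panelGenes = ds$panel_genes)
    expect_identical(ep$units, ds$cpg_units)
})

test_that("written dataset round-trips through the readers", {
    ds <- generateDataset(syntheticConfig(n_genes = 25, n_planted = 2,
                                          seed = 10))
    dir <- file.path(tempdir(), "roundtrip")
    writeDataset(ds, dir)
    b <- readBetaMatrix(file.path(dir, "beta.tsv"), referenceId = "MELPOOL")
    expect_equal(assay(b), assay(ds$beta), tolerance = 1e-12)
    e <- readExpressionMatrix(file.path(dir, "expression.tsv"),
                              referenceId = "MELPOOL")
    expect_equal(scaleTag(e), "linear")   # from the sidecar JSON
    u <- readCpGUnits(file.path(dir, "cpg_units.tsv"))
    expect_equal(nrow(u), nrow(ds$cpg_units))
    gr <- readAmplicons(file.path(dir, "amplicons.bed"))
    expect_equal(length(gr), length(ds$amplicons))
    expect_setequal(unique(gr$gene), unique(ds$amplicons$gene))
})
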