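.mkDelta <- function(v) MethylScreen:::.DeltaMethylation(v, "MELPOOL")
.mkRatio <- function(v) MethylScreen:::.ExpressionRatio(v, "MELPOOL")

.smallPanel <- function(deltaRows, ratioRows, samples = paste0("S", 1:4)) {
    genes <- names(deltaRows)
    d <- do.call(rbind, deltaRows)
    r <- do.call(rbind, ratioRows)
    dimnames(d) <- list(genes, samples)
    dimnames(r) <- list(genes, samples)
    list(delta = .mkDelta(d), ratio = .mkRatio(r))
}

test_that("jointSampleFilter requires both criteria in the same sample", {
    p <- .smallPanel(
        list(g1 = c(65, 70, 5, 80), g2 = c(65, 5, 70, 5)),
        list(g1 = c(0.2, 0.1, 1.0, 0.9), g2 = c(0.2, 0.1, 1.0, 0.9)))
    q <- jointSampleFilter(p$delta, p$ratio)
    expect_equal(q$G1, c("S1", "S2"))
    expect_equal(q$G2, "S1")     # S2 down-regulated but unmethylated
})

test_that("jointSampleFilter boundaries are inclusive at 60 and 1/4", {
    p <- .smallPanel(
        list(g1 = c(60, 59.9, 60, 60), g2 = c(70, 70, 70, 70)),
        list(g1 = c(0.25, 0.25, 0.2501, 0.25), g2 = rep(0.26, 4)))
    q <- jointSampleFilter(p$delta, p$ratio)
    expect_equal(q$G1, c("S1", "S4"))  # 59.9 fails, ratio just above 1/4 fails
    expect_equal(q$G2, character(0))
})

test_that("jointSampleFilter equals an exhaustive double loop", {
    set.seed(41)
    for (rep in 1:10) {
        genes <- sprintf("g%02d", 1:15)
        samples <- sprintf("S%d", 1:6)
        d <- matrix(runif(90, -20, 100), 15,
                    dimnames = list(genes, samples))
        r <- matrix(rlnorm(90, -1, 1), 15, dimnames = list(genes, samples))
        got <- jointSampleFilter(.mkDelta(d), .mkRatio(r))
        want <- oracle_joint_filter(d, r, 60, 4)
        names(want) <- toupper(names(want))
        expect_equal(got[order(names(got))],
                     want[order(names(want))], ignore_attr = TRUE)
    }
})

test_that("detectFalsePositives flags methylation without re-expression", {
    genes <- c("gFlag", "gOK")
    lines <- sprintf("L%d", 1:4)
    d <- matrix(c(70, 70, 70, 5, 70, 70, 70, 5), 2, byrow = TRUE,
                dimnames = list(genes, lines))
    fcFlag <- matrix(c(1.1, 1.1, 1.1, 1, 6, 6, 6, 1), 2, byrow = TRUE,
                     dimnames = list(genes, lines))
    flagged <- detectFalsePositives(.mkDelta(d), FoldChangeMatrix(fcFlag))
    expect_equal(flagged, "GFLAG")
})

test_that("runCascade excludes listed oncogenes even when numerics pass", {
    genes <- c("ADM", "GOODGENE")
    samples <- sprintf("S%d", 1:4)
    d <- matrix(80, 2, 4, dimnames = list(genes, samples))
    r <- matrix(0.1, 2, 4, dimnames = list(genes, samples))
    f <- matrix(c(8, 8, 8, 1), 2, 4, byrow = TRUE,
                dimnames = list(genes, samples))
    cas <- runCascade(.mkDelta(d), .mkRatio(r), FoldChangeMatrix(f))
    expect_equal(cas$status[cas$symbol == "ADM"], "excluded:oncogene")
    expect_equal(cas$status[cas$symbol == "GOODGENE"], "candidate")
    expect_match(cas$trail[cas$symbol == "ADM"], "oncogene:fail")
})

test_that("mean re-expression of exactly 4 fails the strict bound", {
    genes <- c("gAt4", "gAbove4")
    samples <- sprintf("S%d", 1:3)
    d <- matrix(80, 2, 3, dimnames = list(genes, samples))
    r <- matrix(0.1, 2, 3, dimnames = list(genes, samples))
    f <- matrix(c(4, 4, 4, 4.01, 4, 4), 2, byrow = TRUE,
                dimnames = list(genes, samples))
    cas <- runCascade(.mkDelta(d), .mkRatio(r), FoldChangeMatrix(f))
    expect_equal(cas$status[cas$symbol == "GAT4"],
                 "excluded:mean_reexpression")
    expect_equal(cas$status[cas$symbol == "GABOVE4"], "candidate")
})

test_that("unannotated symbols are removed by list or pattern", {
    genes <- c("C10ORF116", "FLJ20551", "NICEGENE")
    samples <- sprintf("S%d", 1:3)
    d <- matrix(80, 3, 3, dimnames = list(genes, samples))
    r <- matrix(0.1, 3, 3, dimnames = list(genes, samples))
    f <- matrix(8, 3, 3, dimnames = list(genes, samples))
    cas <- runCascade(.mkDelta(d), .mkRatio(r), FoldChangeMatrix(f))
    expect_setequal(
        cas$status[cas$symbol %in% c("C10ORF116", "FLJ20551")],
        "excluded:unannotated")
    expect_equal(cas$status[cas$symbol == "NICEGENE"], "candidate")
})

test_that("no gene is both a flagged false positive and a candidate", {
    set.seed(42)
    ds <- generateDataset(syntheticConfig(n_genes = 80, n_planted = 6,
                                          seed = 7))
    delta <- computeDelta(ds$beta)
    ratios <- expressionRatio(ds$expression)
    fc <- foldChange(ds$treated, ds$mock)
    cas <- runCascade(delta, ratios, fc)
    flagged <- detectFalsePositives(delta, fc)
    expect_length(intersect(flagged,
                            cas$symbol[cas$status == "candidate"]), 0)
})

test_that("cascade trail is complete and candidate status means all-pass", {
    set.seed(43)
    ds <- generateDataset(syntheticConfig(n_genes = 60, n_planted = 5,
                                          seed = 8))
    cas <- runCascade(computeDelta(ds$beta),
                      expressionRatio(ds$expression),
                      foldChange(ds$treated, ds$mock))
    expect_equal(sort(cas$symbol), sort(toupper(rownames(ds$beta))))
    expect_false(anyDuplicated(cas$symbol) > 0)
    allPass <- !grepl("fail", cas$trail)
    expect_equal(cas$status == "candidate", allPass)
    smry <- cascadeSummary(cas)
    expect_equal(smry$n_input, 60L)
    expect_equal(smry$n_candidates, sum(cas$status == "candidate"))
})

test_that("tightening any threshold never increases the candidate count", {
    set.seed(44)
    ds <- generateDataset(syntheticConfig(n_genes = 120, n_planted = 10,
                                          seed = 9, meth_noise_sd = 15))
    delta <- computeDelta(ds$beta)
    ratios <- expressionRatio(ds$expression)
    fc <- foldChange(ds$treated, ds$mock)
    base <- sum(runCascade(delta, ratios, fc)$status == "candidate")
    for (th in list(FilterThresholds(methMin = 70),
                    FilterThresholds(minSamples = 4),
                    FilterThresholds(downregFold = 6),
                    FilterThresholds(reexprMeanMin = 6))) {
        n <- sum(runCascade(delta, ratios, fc,
                            thresholds = th)$status == "candidate")
        expect_lte(n, base)
    }
})

test_that("the cascade is idempotent on its own candidate set", {
    set.seed(45)
    ds <- generateDataset(syntheticConfig(n_genes = 100, n_planted = 8,
                                          seed = 10))
    delta <- computeDelta(ds$beta)
    ratios <- expressionRatio(ds$expression)
    fc <- foldChange(ds$treated, ds$mock)
    cas <- runCascade(delta, ratios, fc)
    cand <- cas$symbol[cas$status == "candidate"]
    sub <- function(se, assayName) {
        v <- assay(se, assayName)
        v[toupper(rownames(v)) %in% cand, , drop = FALSE]
    }
    cas2 <- runCascade(
        MethylScreen:::.DeltaMethylation(sub(delta, "delta"), "MELPOOL"),
        MethylScreen:::.ExpressionRatio(sub(ratios, "ratio"), "MELPOOL"),
        FoldChangeMatrix(sub(fc, "fc")))
    expect_setequal(cas2$symbol[cas2$status == "candidate"], cand)
})

test_that("threshold and exclusion constructors validate their bounds", {
    expect_error(FilterThresholds(methMin = 0), "methMin")
    expect_error(FilterThresholds(downregFold = 1), "downregFold")
    expect_error(FilterThresholds(minSamples = 0), "minSamples")
    expect_error(ExclusionLists(oncogenes = c("ADM", "PPP1R3C")),
                 "disjoint")
    expect_error(ExclusionLists(fpMinLines = 0), "fpMinLines")
})
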