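.unitRow <- function(gene = "G1", amp = "G1_a1", unit = 1L, n_cpgs = 1L,
                     sample = "S1", ratio = 50, err = 1, overlap = FALSE)
    data.frame(gene = gene, amplicon_id = amp, unit_index = unit,
               n_cpgs = n_cpgs, sample = sample, meth_ratio_pct = ratio,
               error_pct = err, overlap_flag = overlap,
               stringsAsFactors = FALSE)

test_that("qcFilterUnits drops overlaps and uncertain ratios", {
    u <- rbind(.unitRow(unit = 1L, err = 12),
               .unitRow(unit = 2L, err = 10),   # boundary: strict < 10
               .unitRow(unit = 3L, err = 1, overlap = TRUE),
               .unitRow(unit = 4L, err = 9.99))
    kept <- qcFilterUnits(u)
    expect_equal(kept$unit_index, 4L)
    expect_equal(kept$meth_ratio_pct, 50)   # retained rows unchanged
    expect_error(qcFilterUnits(u, maxError = 0), "positive")
    bad <- u; bad$meth_ratio_pct[1] <- 120
    expect_error(qcFilterUnits(bad), "0, 100")
})

test_that("ampliconInformative applies strict panel/reference bounds", {
    mk <- function(panelRatio, refRatio) rbind(
        .unitRow(sample = "S1", ratio = panelRatio),
        .unitRow(sample = "S2", ratio = panelRatio),
        .unitRow(sample = "MELPOOL", ratio = refRatio))
    a <- ampliconInformative(mk(25, 5), c("S1", "S2"), "MELPOOL")
    expect_true(a$informative)
    expect_equal(a$panel_mean, 25)
    expect_equal(a$ref_mean, 5)
    expect_false(ampliconInformative(mk(25, 12), c("S1", "S2"),
                                     "MELPOOL")$informative)
    expect_false(ampliconInformative(mk(20, 5), c("S1", "S2"),
                                     "MELPOOL")$informative)  # strict > 20
    expect_false(ampliconInformative(mk(25, 10), c("S1", "S2"),
                                     "MELPOOL")$informative)  # strict < 10
    expect_error(ampliconInformative(mk(25, 5), c("S1", "MELPOOL"),
                                     "MELPOOL"), "disjoint")
})

test_that("amplicons with no surviving units are uninformative: no data", {
    u <- .unitRow(err = 20)
    qc <- qcFilterUnits(u)
    a <- ampliconInformative(qc, "S1", "MELPOOL")
    expect_equal(nrow(a), 0L)
    # via the full reduction the gene is reported without a call
    red <- epityperReduce(u, panelSamples = "S1", refSamples = "MELPOOL")
    expect_equal(red$summary$note, "no differential methylation")
    expect_true(is.na(red$summary$panel_avg))
})

test_that("selectInformativeSites keeps high-methylation units and counts CpGs", {
    u <- rbind(.unitRow(unit = 1L, ratio = 5, n_cpgs = 2L),
               .unitRow(unit = 2L, ratio = 30, n_cpgs = 3L),
               .unitRow(unit = 3L, ratio = 60, n_cpgs = 1L))
    sel <- selectInformativeSites(u, panelSamples = "S1")
    expect_equal(sort(unique(sel$units$unit_index)), c(2L, 3L))
    expect_equal(unname(sel$n_informative_sites["G1"]), 4L)
    all <- selectInformativeSites(u, panelSamples = "S1", siteMin = 0)
    expect_equal(nrow(all$units), 3L)    # siteMin 0 is the identity
})

test_that("selectInformativeSites equals a brute-force scan and is monotone", {
    set.seed(51)
    for (rep in 1:10) {
        u <- randomUnits()
        sm <- runif(1, 0, 80)
        got <- selectInformativeSites(u, c("S1", "S2", "S3"), siteMin = sm)
        want <- oracle_select_sites(u, c("S1", "S2", "S3"), sm)
        expect_equal(got$units[order(got$units$gene, got$units$amplicon_id,
                                     got$units$unit_index, got$units$sample), ],
                     want[order(want$gene, want$amplicon_id, want$unit_index,
                                want$sample), ],
                     ignore_attr = TRUE)
    }
    u <- randomUnits()
    ns <- vapply(c(0, 10, 30, 60, 90), function(sm) {
        s <- selectInformativeSites(u, c("S1", "S2", "S3"), siteMin = sm)
        sum(s$n_informative_sites)
    }, 0)
    expect_true(all(diff(ns) <= 0))   # lowering siteMin never loses sites
})

test_that("genePercentMethylation is a two-level mean", {
    u <- rbind(.unitRow(unit = 1L, ratio = 40),
               .unitRow(unit = 2L, ratio = 60),
               .unitRow(unit = 1L, sample = "S2", ratio = 10),
               .unitRow(unit = 2L, sample = "S2", ratio = 30),
               .unitRow(unit = 1L, sample = "MELPOOL", ratio = 4))
    g <- genePercentMethylation(u, c("S1", "S2"), "MELPOOL")
    expect_equal(g$perSample["G1", "S1"], 50)
    expect_equal(g$perSample["G1", "S2"], 20)
    expect_equal(g$summary$panel_avg, 35)
    expect_equal(g$summary$ref_avg, 4)
    single <- genePercentMethylation(.unitRow(ratio = 33), "S1", "MELPOOL")
    expect_equal(single$perSample["G1", "S1"], 33)   # identity
    expect_true(is.na(single$perSample["G1", "MELPOOL"]))
})

test_that("genePercentMethylation matches the oracle and ignores row order", {
    set.seed(52)
    for (rep in 1:8) {
        u <- randomUnits()
        panel <- c("S1", "S2", "S3")
        g <- genePercentMethylation(u, panel, "MELPOOL")
        for (gene in unique(u$gene)) {
            for (s in c(panel, "MELPOOL")) {
                v <- u$meth_ratio_pct[u$gene == gene & u$sample == s]
                expect_equal(g$perSample[gene, s], mean(v))
            }
            expect_equal(g$summary$panel_avg[g$summary$gene == gene],
                         mean(sapply(panel, function(s)
                             mean(u$meth_ratio_pct[u$gene == gene &
                                                   u$sample == s]))))
        }
        shuffled <- u[sample(nrow(u)), ]
        g2 <- genePercentMethylation(shuffled, panel, "MELPOOL")
        expect_equal(g2$perSample, g$perSample)
        dup <- rbind(u, u)   # duplication then deduplication
        dedup <- dup[!duplicated(dup), ]
        expect_equal(genePercentMethylation(dedup, panel,
                                            "MELPOOL")$perSample,
                     g$perSample)
    }
})

test_that("classifyMethylation partitions [0, 100] at 20 and 50", {
    expect_equal(as.character(classifyMethylation(c(0, 20, 20.01))),
                 c("no/low", "no/low", "medium"))
    expect_equal(as.character(classifyMethylation(c(50, 50.01, 100))),
                 c("medium", "high", "high"))
    # published panel averages: 66 is high, 42 is medium
    expect_equal(as.character(classifyMethylation(66)), "high")
    expect_equal(as.character(classifyMethylation(42)), "medium")
    expect_error(classifyMethylation(101), "0, 100")
    set.seed(53)
    x <- runif(200, 0, 100)
    cls <- classifyMethylation(x)
    expect_false(any(is.na(cls)))          # every value maps to one class
    expect_equal(levels(cls), c("no/low", "medium", "high"))
})

test_that("referenceRatio divides unrounded averages and handles zero", {
    expect_equal(referenceRatio(40, 5), 8)
    expect_equal(referenceRatio(37, 37), 1)
    expect_true(is.na(referenceRatio(40, 0)))
    expect_equal(referenceRatio(c(40, 10), c(5, 2)), c(8, 5))
})

test_that("end-to-end reduction calls planted genes high in methylated lines", {
    cfg <- syntheticConfig(n_genes = 60, n_planted = 5, seed = 77)
    ds <- generateDataset(cfg)
    red <- epityperReduce(ds$cpg_units,
                          panelSamples = sprintf("MM%02d", 1:11),
                          refSamples = "MELPOOL")
    for (i in seq_len(nrow(ds$truth))) {
        g <- ds$truth$gene[i]
        lines <- strsplit(ds$truth$methylated_lines[i], ",")[[1]]
        per <- red$perSample[g, lines]
        expect_true(all(classifyMethylation(per) == "high"))
    }
    refCls <- classifyMethylation(red$summary$ref_avg[
        red$summary$gene %in% ds$truth$gene])
    expect_true(all(refCls == "no/low"))
})
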