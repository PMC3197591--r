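---
title: "Screening for genes silenced by promoter methylation: methods and design notes"
author: "MethylScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for genes silenced by promoter methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MethylScreen)
```

# The screening problem

Tumor-suppressor genes are frequently inactivated not by mutation but by
hypermethylation of the CpG island in their promoter. A single data type is
a weak witness for this mechanism: array methylation alone cannot show that
the methylation is consequential, expression alone cannot show why a gene
is off, and re-expression after a demethylating drug
(5-aza-2'-deoxycytidine with trichostatin A) is notoriously unspecific.
MethylScreen implements the cross-platform alternative: a gene is nominated
only when, in the *same* cell lines, it is hypermethylated relative to a
normal (melanocyte-pool) reference, transcriptionally suppressed relative
to that same reference, and reactivated by demethylating treatment — and
the nomination is then quantified on an independent, higher-resolution
methylation assay (EpiTYPER-style CpG units) and correlated with
expression.

The package is organised around that flow:

1. **Beadarray methylation** — percent methylation (beta) from allele
   intensities; deltas against the reference.
2. **Expression profiling** — flooring, log2, two-pass median centering;
   linear ratios to the reference.
3. **Demethylation response** — treated/mock fold changes; the
   ubiquitous-reactivation filter; mean re-expression.
4. **Candidate integration** — the joint filter cascade with exclusion
   lists and a beadarray false-positive rule.
5. **EpiTYPER reduction** — CpG-unit QC, amplicon informativeness, site
   selection, per-gene percent methylation and a three-class call.
6. **Correlation** — Spearman methylation-expression correlation with a
   t-based significance test.
7. **Synthetic data** — a generator with planted silenced genes, so all of
   the above is testable offline against a known truth.

# Models and conventions

## Beta values and deltas

Percent methylation at a probe is

$$\beta = \frac{\max(M, 0)}{\max(M, 0) + \max(U, 0) + c} \times 100,$$

where $M$ and $U$ are the methylated- and unmethylated-allele
fluorescence intensities and $c$ is a denominator constant whose default
is 0. Background-corrected intensities can be negative; clamping happens
before the ratio. When both clamped intensities are zero the probe has no
signal and the value is *missing* — not 0, not an error — so missingness
propagates visibly instead of masquerading as "unmethylated". The
platform's conventional stabilizing constant is nonzero (often 100), so
`offset` is exposed; the default follows the formula as used by the
screen.

Every methylation value in the package lives on the percent scale
$[0, 100]$, asserted by class validity. A line's methylation is expressed
as a **delta**: its beta minus the reference beta at the same site.
Positive deltas mean relative hypermethylation of the tumor line. Multiple
probes per gene are collapsed by the mean (default) or the maximum
("any probe methylated" reading); the choice is exposed because platforms
do not agree on one convention.

## Expression

Linear-scale values below 0.1 are floored to 0.1 before log2 — near-zero
signals otherwise produce wild log ratios. Median centering subtracts each
sample's median, then each gene's median, exactly once each and in that
order. One pass each is what the upstream normalization performs; note
that after the gene pass the sample medians are no longer exactly zero
(iterating to convergence would be Tukey's median polish, which this
deliberately is not). Each pass has its own conservation law: the sample
pass preserves within-sample differences, the gene pass preserves
within-gene differences.

Down-regulation is assessed on **linear ratios** to the reference
(`ratio <= 1/k` means "down k-fold"); whether the original screen used
linear ratios or centered log values is not documented, so the log view is
available but the cascade consumes linear ratios. "4-fold down" is
inclusive: a ratio of exactly 0.25 qualifies. The scale of every
expression table is carried in a `scaleTag` (and a sidecar JSON on disk),
so ratios can never silently be taken on log-scale data.

## Demethylation response

Fold change is treated/mock per gene and line. A gene is *re-expressed* in
a line when its fold change is strictly above 2 (exactly 2.0 does not
count). Genes reactivated in **all** lines are removed: blanket
reactivation marks a generic stress or lineage response rather than
gene-specific silencing. A gene with a missing line is conservatively kept
— it cannot be shown to be ubiquitous. The ">4 average re-expression"
criterion uses the arithmetic mean of fold ratios, matching the original
phrasing; the geometric mean is available for a log-symmetric reading.

## The cascade

With default thresholds a gene becomes a candidate when:

* delta methylation $\geq 60$ **and** expression ratio $\leq 0.25$ hold in
  the *same* sample, for at least 2 samples;
* its mean re-expression fold change is strictly $> 4$;
* it is not on the oncogene list (defaults: ADM, ENPP2, RAC2, SERPINE1),
  not previously identified (default: PPP1R3C), and not "unannotated"
  (an explicit list plus an optional regex for orf/FLJ/CCDC-style names —
  the original study's own two tellings of this list disagree, so nothing
  is hard-coded);
* it is not a beadarray false positive: methylated (delta $\geq 60$) in
  at least 2 lines that show *no* re-expression (fold change $\leq 2$).
  The original study names EEF1A2 and HSPA2 as this failure mode but
  gives no numbers; the quantification is ours and fully configurable.

Every input gene receives a complete pass/fail trail over all six filters
and a terminal status, so the stage counts (the "flow-through") can be
reconstructed from any run. Symbols are matched case-insensitively across
platforms; symbols missing from one input are reported, never silently
dropped. The downstream bench confirmations of the original study
(qRT-PCR fold validation, CpG-island presence) depend on data outside any
array table and are represented only as an optional user-supplied keep
list.

## EpiTYPER-style reduction

The atomic measurement is the CpG **unit** — a cleavage fragment carrying
one or more consecutive CpGs with one methylation ratio and one error
estimate; per-CpG deconvolution within a unit is not attempted because the
assay cannot resolve it. QC drops units overlapping other fragments in the
mass spectrum and units whose error estimate is not strictly below 10%.
An amplicon is **informative** when its panel-average methylation is
strictly above 20% while the reference stays strictly below 10%; genes
with no informative amplicon are reported as showing no differential
methylation (the fate of LOX and RGC32 in the original screen). Within
informative amplicons, units with panel-mean methylation $\geq 20\%$ are
selected — the original text says "high methylation ratios" without a
number, so the amplicon threshold is reused, configurable. The per-gene
percent is a two-level mean (units within sample, then samples), and the
three-class call is

no/low $[0, 20]$, medium $(20, 50]$, high $(50, 100]$.

Only the 50 boundary is forced by the published ">50%" label; making the
classes half-open keeps them a partition, and 20.0 falling into no/low is
a convention, tested as such. Amplicon coordinates are BED-convention
(0-based, half-open); strand is recorded but unused.

## Correlation and its test

Methylation-expression association uses Spearman correlation (Pearson is
provided for protein-level comparisons). Two t statistics are computed:

* standard: $t = r\sqrt{(n-2)/(1-r^2)}$, exactly $t_{n-2}$ under the null
  for Gaussian data — the default source of p-values;
* as printed in the original methods: $t = r / S_r$ with
  $S_r = (1-r^2)/n$, which differs from any textbook standard error of
  $r$ and is almost certainly a typo; it is reported alongside for
  fidelity, never endorsed.

Both use $n-2$ degrees of freedom (the original states none). Missing
values are removed pairwise. Null calibration: with independent Gaussian
inputs at the panel size ($n = 11$), 1000 replicates of the
standard-formula p-value sit within Kolmogorov–Smirnov distance
$\approx 0.03$ of uniform; the discreteness of rank correlation at this
$n$ is mild enough not to matter.

# The synthetic-data generator

The generator emulates the structure of the study's three deposited data
types on one shared gene universe: 11 cell lines plus a melanocyte-pool
reference; planted silenced genes that are methylated (mean 80%, SD 5,
clamped to the percent scale) in a penetrance-determined subset of lines
(default 60% of lines, i.e. 7 of 11), suppressed 8-fold in exactly those
lines, and re-expressed about 10-fold there after treatment; and an
EpiTYPER-style unit panel (2 amplicons x 5 units per gene, over the
planted genes plus an equal number of background genes for contrast) in
which 10% of unit measurements carry a disqualifying error estimate or an
overlap flag. Background genes draw methylation from the 5% background
everywhere and fold changes near 1, so at default thresholds they fail the
cascade with overwhelming probability. Defaults were chosen once as a
realistic strong-signal regime consistent with the effect sizes the
original screen reports (deltas well above 60 in methylated lines,
re-expression averages above 4), and the recovery properties are then
*consequences*, verified by tests rather than assumed.

Distributional choices the data do not dictate are surfaced as
configuration: clamped normals on the percent scale (a beta distribution
would be the natural alternative), log-normal expression noise (sdlog
0.2), log-normal fold-change noise. What the generator does **not**
emulate: probe-level intensity noise, batch and dye effects, correlated
probes within an island, stromal contamination of tumors, and the heavy
left tail of real reference pools. Passing tests therefore demonstrate
the pipeline's logic and thresholds, not its robustness to real-world
array artifacts.

The ground-truth manifest is written as a separate table and never read by
any pipeline stage, so evaluation against it is blind. All randomness
flows from the single config seed; the unit panel uses a derived stream
(seed + 1) so the same config and truth give the same panel whether it is
generated standalone or as part of the full dataset.

# Worked example

```{r example}
cfg <- syntheticConfig(n_genes = 200, n_planted = 8, seed = 42)
ds <- generateDataset(cfg)

delta <- computeDelta(ds$beta)
ratios <- expressionRatio(ds$expression)
fc <- foldChange(ds$treated, ds$mock)

cascade <- runCascade(delta, ratios, fc)
head(cascade[, c("symbol", "n_qualifying", "mean_fc", "status")], 10)
cascadeSummary(cascade)

calls <- epityperReduce(ds$cpg_units,
                        panelSamples = sprintf("MM%02d", 1:11),
                        refSamples = "MELPOOL")
subset(calls$summary, note == "called")[1:4, ]

corr <- methylationExpressionPanel(calls, ratios)
subset(corr, tested)[1:4, c("gene", "n", "spearman_r", "p")]
```

The same flow is available as one call,
`runPipeline(list(synthetic = cfg), outDir = "...")`, which writes every
intermediate table and a JSON report of the stage counts.

# Numerical and design notes

* **Problem sizes.** Tests and the acceptance script use 500-gene panels
  with 20 planted genes for recovery checks and 1000 replicates for the
  null calibration — sizes at which every distributional property asserted
  is already stable.
* **Boundary conventions** are tested exactly as specified: delta 60.0
  qualifies, ratio 0.25 qualifies, fold change 2.0 is not re-expression,
  mean fold 4.0 is not a pass, error 10.0 is dropped, 20.0 is no/low,
  50.0 is medium.
* **Ties in ranks** share the average rank; the test suite checks this
  against an independent average-rank implementation rather than trusting
  one library path.
* **Degenerate inputs**: all-missing rows or columns stay missing with a
  warning; a zero reference makes a ratio missing with a note; constant
  vectors make a correlation untested rather than 0.
* **Known limitations.** The published candidate counts (26 -> 12 -> 10)
  depend on multi-accession integration and bench follow-up that are not
  reproducible from the released summaries, and the published Spearman
  coefficients lack their underlying n; neither is therefore asserted
  anywhere. The re-expression bookkeeping (8,144 re-expressed, 3,125
  retained) is reported as counts so any discrepancy on real data stays
  visible. `fetchAccessions()` can pull the deposited series matrices for
  a real-data run but the pipeline never requires network access.
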