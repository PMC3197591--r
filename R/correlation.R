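.pairComplete <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    list(x = x[ok], y = y[ok], n = sum(ok))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties share the mean rank),
#' computed on pairwise-complete observations. Fewer than 3 pairs, or a
#' constant vector, yields `NA`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation coefficient in \[-1, 1\], or `NA`.
#' @examples
#' spearmanR(1:3, c(6, 4, 2))   # -1
#' @export
spearmanR <- function(x, y) {
    p <- .pairComplete(x, y)
    if (p$n < 3 || length(unique(p$x)) < 2 || length(unique(p$y)) < 2)
        return(NA_real_)
    stats::cor(p$x, p$y, method = "spearman")
}

#' Pearson product-moment correlation
#'
#' @inheritParams spearmanR
#' @return Correlation coefficient in \[-1, 1\], or `NA`.
#' @export
pearsonR <- function(x, y) {
    p <- .pairComplete(x, y)
    if (p$n < 3 || length(unique(p$x)) < 2 || length(unique(p$y)) < 2)
        return(NA_real_)
    stats::cor(p$x, p$y, method = "pearson")
}

#' Significance of a correlation coefficient
#'
#' Two t statistics are computed side by side. The standard one,
#' `t = r * sqrt((n - 2) / (1 - r^2))`, is exactly t-distributed with
#' `n - 2` degrees of freedom under the null for Gaussian data and is the
#' default source of the two-sided p-value. The `as_printed` variant,
#' `t = r / Sr` with `Sr = (1 - r^2) / n`, follows the screen's published
#' formula verbatim; it differs from the textbook standard error of `r`
#' (most likely a typo for `sqrt((1 - r^2)/(n - 2))`) and is reported for
#' fidelity, never endorsed. Both use `n - 2` degrees of freedom.
#'
#' @param r Correlation coefficient in \[-1, 1\].
#' @param n Number of paired samples (>= 3).
#' @param formula `"standard"` (default) or `"as_printed"`: which t feeds
#'   the p-value.
#' @return List of class `"CorrelationResult"`: `r`, `n`, `t_standard`,
#'   `t_as_printed`, `t`, `p`, `formula`, `exact_monotone` (TRUE when
#'   `|r| = 1`, where both statistics diverge and `p` is reported as 0).
#' @examples
#' correlationTest(0.5, 12, formula = "as_printed")$t   # 8
#' correlationTest(0.6, 27)$t                           # 3.75
#' @export
correlationTest <- function(r, n, formula = c("standard", "as_printed")) {
    formula <- match.arg(formula)
    if (is.na(r)) {
        return(structure(list(r = NA_real_, n = n, t_standard = NA_real_,
                              t_as_printed = NA_real_, t = NA_real_,
                              p = NA_real_, formula = formula,
                              exact_monotone = FALSE),
                         class = "CorrelationResult"))
    }
    if (abs(r) > 1) stop("'r' must lie in [-1, 1]", call. = FALSE)
    if (n < 3) stop("'n' must be >= 3", call. = FALSE)
    df <- n - 2
    if (abs(r) == 1) {
        t_std <- t_prt <- sign(r) * Inf
        p <- 0
        exact <- TRUE
    } else {
        t_std <- r * sqrt(df / (1 - r^2))
        t_prt <- r / ((1 - r^2) / n)
        p <- 2 * stats::pt(-abs(if (formula == "standard") t_std else t_prt),
                           df)
        exact <- FALSE
    }
    structure(list(r = r, n = as.integer(n), t_standard = t_std,
                   t_as_printed = t_prt,
                   t = if (formula == "standard") t_std else t_prt,
                   p = p, formula = formula, exact_monotone = exact),
              class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
    cat(sprintf(
        "r = %.4f (n = %d): t_standard = %.4f, t_as_printed = %.4f, p = %.4g [%s]\n",
        x$r, x$n, x$t_standard, x$t_as_printed, x$p, x$formula))
    invisible(x)
}

#' Methylation-expression correlation across a gene panel
#'
#' For each gene with a methylation call, the Spearman correlation between
#' its per-sample percent methylation and its expression ratio to the
#' reference, over the samples shared by both inputs, with the t-based
#' significance test. Genes with fewer than 3 shared pairs, or constant
#' values, are reported untested with a reason.
#'
#' @param calls A `"GeneMethylationCalls"` object from [epityperReduce()],
#'   or a bare genes x samples percent matrix.
#' @param ratios An [ExpressionRatio-class].
#' @param formula Passed to [correlationTest()].
#' @return `data.frame`: `gene`, `n`, `spearman_r`, `t_standard`,
#'   `t_as_printed`, `p`, `tested`, `reason`.
#' @export
methylationExpressionPanel <- function(calls, ratios,
                                       formula = c("standard", "as_printed")) {
    formula <- match.arg(formula)
    meth <- if (inherits(calls, "GeneMethylationCalls")) calls$perSample
            else calls
    expr <- .upperRows(assay(ratios, "ratio"))
    rownames(meth) <- toupper(rownames(meth))
    samples <- intersect(colnames(meth), colnames(expr))
    genes <- sort(intersect(rownames(meth), rownames(expr)))
    if (!length(genes) || !length(samples))
        return(data.frame(gene = character(), n = integer(),
                          spearman_r = numeric(), t_standard = numeric(),
                          t_as_printed = numeric(), p = numeric(),
                          tested = logical(), reason = character()))
    res <- lapply(genes, function(g) {
        x <- meth[g, samples]
        y <- expr[g, samples]
        p <- .pairComplete(x, y)
        if (p$n < 3)
            return(data.frame(gene = g, n = p$n, spearman_r = NA_real_,
                              t_standard = NA_real_, t_as_printed = NA_real_,
                              p = NA_real_, tested = FALSE,
                              reason = "fewer than 3 paired samples"))
        r <- spearmanR(x, y)
        if (is.na(r))
            return(data.frame(gene = g, n = p$n, spearman_r = NA_real_,
                              t_standard = NA_real_, t_as_printed = NA_real_,
                              p = NA_real_, tested = FALSE,
                              reason = "constant input"))
        ct <- correlationTest(r, p$n, formula = formula)
        data.frame(gene = g, n = p$n, spearman_r = r,
                   t_standard = ct$t_standard, t_as_printed = ct$t_as_printed,
                   p = ct$p, tested = TRUE, reason = "")
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
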