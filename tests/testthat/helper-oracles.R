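# Independent brute-force oracles: scalar loops and first-principles
# formulas, deliberately sharing no code with the package internals.

oracle_beta <- function(M, U, offset = 0) {
    out <- numeric(length(M))
    for (i in seq_along(M)) {
        m <- if (M[i] > 0) M[i] else 0
        u <- if (U[i] > 0) U[i] else 0
        den <- m + u + offset
        out[i] <- if (den == 0) NA_real_ else 100 * m / den
    }
    out
}

oracle_delta <- function(beta, ref) {
    other <- setdiff(colnames(beta), ref)
    out <- matrix(NA_real_, nrow(beta), length(other),
                  dimnames = list(rownames(beta), other))
    for (g in rownames(beta))
        for (s in other)
            out[g, s] <- beta[g, s] - beta[g, ref]
    out
}

oracle_group_aggregate <- function(values, groups, fun) {
    gs <- sort(unique(groups))
    out <- matrix(NA_real_, length(gs), ncol(values),
                  dimnames = list(gs, colnames(values)))
    for (g in gs)
        for (j in seq_len(ncol(values))) {
            v <- values[groups == g, j]
            v <- v[!is.na(v)]
            if (length(v)) out[g, j] <- fun(v)
        }
    out
}

oracle_floor_log <- function(values, floor) {
    out <- values
    for (i in seq_along(out))
        if (!is.na(out[i])) out[i] <- log2(max(out[i], floor))
    out
}

oracle_median_center <- function(values) {
    out <- values
    for (j in seq_len(ncol(out)))
        out[, j] <- out[, j] - median(out[, j], na.rm = TRUE)
    for (i in seq_len(nrow(out)))
        out[i, ] <- out[i, ] - median(out[i, ], na.rm = TRUE)
    out
}

oracle_elementwise_div <- function(a, b) {
    out <- a
    for (i in seq_len(nrow(a)))
        for (j in seq_len(ncol(a)))
            out[i, j] <- a[i, j] / b[i, j]
    out
}

oracle_joint_filter <- function(delta, ratio, methMin, downregFold) {
    genes <- intersect(rownames(delta), rownames(ratio))
    samples <- intersect(colnames(delta), colnames(ratio))
    out <- list()
    for (g in genes) {
        qualifying <- character()
        for (s in samples) {
            d <- delta[g, s]; r <- ratio[g, s]
            if (!is.na(d) && !is.na(r) && d >= methMin &&
                r <= 1 / downregFold)
                qualifying <- c(qualifying, s)
        }
        out[[g]] <- qualifying
    }
    out
}

oracle_select_sites <- function(units, panelSamples, siteMin) {
    keys <- unique(paste(units$gene, units$amplicon_id, units$unit_index))
    keep <- character()
    for (k in keys) {
        rows <- paste(units$gene, units$amplicon_id, units$unit_index) == k &
            units$sample %in% panelSamples
        v <- units$meth_ratio_pct[rows]
        v <- v[!is.na(v)]
        if (length(v) && mean(v) >= siteMin) keep <- c(keep, k)
    }
    units[paste(units$gene, units$amplicon_id, units$unit_index) %in% keep, ]
}

# average ranks (ties share the mean rank) without rank()
oracle_avg_rank <- function(x) {
    out <- numeric(length(x))
    for (i in seq_along(x)) {
        less <- sum(x < x[i])
        eq <- sum(x == x[i])
        out[i] <- less + (eq + 1) / 2
    }
    out
}

# product-moment coefficient from raw sums
oracle_pearson <- function(x, y) {
    n <- length(x)
    sx <- sum(x); sy <- sum(y)
    num <- n * sum(x * y) - sx * sy
    den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
    num / den
}

oracle_spearman <- function(x, y)
    oracle_pearson(oracle_avg_rank(x), oracle_avg_rank(y))
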