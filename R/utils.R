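#' Percentage share of a count
#'
#' `round(100 * count / total, digits)` -- the operation behind summary
#' statements like "31 of 43 lines (72\%) had no expression". Vectorized.
#'
#' @param count,total Non-negative counts (`total > 0`).
#' @param digits Decimal places (default 0, whole percent as reported).
#' @return Numeric vector of percentages.
#' @examples
#' percentShare(31, 43)   # 72
#' percentShare(28, 31)   # 90
#' @export
percentShare <- function(count, total, digits = 0) {
    if (any(total <= 0)) stop("'total' must be > 0", call. = FALSE)
    if (any(count < 0)) stop("'count' must be >= 0", call. = FALSE)
    round(100 * count / total, digits)
}
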