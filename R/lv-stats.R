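#' @include utils.R
NULL

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples with midrank tie handling. The exact
#' null distribution is enumerated when the combined sample size is at most
#' 20 and there are no ties; otherwise the normal approximation with tie
#' correction and continuity correction is used. When every pooled value is
#' identical the statistic is n1*n2/2 and the p-value 1.
#'
#' @param x,y numeric samples (each non-empty).
#' @param alternative \code{"two_sided"} (default) or \code{"greater"}
#'   (x stochastically greater than y).
#' @return list with elements \code{u} (the U statistic, counting x-over-y
#'   pairs with ties as 1/2) and \code{p}.
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mannWhitney <- function(x, y, alternative = c("two_sided", "greater")) {
    alternative <- match.arg(alternative)
    if (length(x) < 1L || length(y) < 1L)
        stop("both samples must be non-empty")
    if (!all(is.finite(c(x, y))))
        stop("non-finite values")
    n1 <- length(x); n2 <- length(y)
    pooled <- c(x, y)
    if (length(unique(pooled)) == 1L)
        return(list(u = n1 * n2 / 2, p = 1))
    exact <- (n1 + n2 <= 20L) && !anyDuplicated(pooled)
    alt <- if (alternative == "two_sided") "two.sided" else "greater"
    wt <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = alt, exact = exact,
                           correct = TRUE))
    p <- wt$p.value
    if (!is.finite(p)) p <- 1
    list(u = unname(wt$statistic), p = min(p, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: after sorting ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1 and returned in
#' the original order.
#'
#' @param p numeric vector of p-values, all in (0, 1].
#' @return adjusted values, same length and order.
#' @export
bhAdjust <- function(p) {
    if (length(p) == 0L) return(numeric(0))
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Differential latent-variable analysis between two groups
#'
#' Per-LV two-sided Mann-Whitney comparison of LV scores between two sample
#' groups, with Benjamini-Hochberg correction restricted to the tested LV
#' subset and a direction call from the group medians.
#'
#' @param scores LVs x samples numeric matrix (e.g. the output of
#'   \code{\link{plierTransform}}).
#' @param labels vector of group labels aligned to the score columns; must
#'   take exactly two values. Group 1 is the first factor level.
#' @param lvSubset LV identifiers to test (default: all rows). Typically the
#'   interpretable set from \code{\link{interpretableLVs}}; the BH family is
#'   exactly this subset.
#' @return data.frame with columns lv, u_stat, p_value, fdr, direction
#'   (\code{higher_in_group1}/\code{higher_in_group2}/\code{none}),
#'   median_group1, median_group2.
#' @export
differentialLVAnalysis <- function(scores, labels, lvSubset = NULL) {
    scores <- as.matrix(scores)
    if (ncol(scores) != length(labels))
        stop("labels must align with the score columns")
    g <- factor(labels)
    if (nlevels(g) != 2L)
        stop("labels must define exactly two non-empty groups")
    if (is.null(lvSubset))
        lvSubset <- rownames(scores)
    if (is.null(lvSubset))
        lvSubset <- seq_len(nrow(scores))
    missing <- setdiff(as.character(lvSubset), rownames(scores))
    if (length(missing))
        stop("unknown LV(s): ", paste(missing, collapse = ", "))
    i1 <- g == levels(g)[1L]
    res <- lapply(lvSubset, function(lv) {
        x <- scores[lv, i1]
        y <- scores[lv, !i1]
        mw <- mannWhitney(x, y, "two_sided")
        m1 <- stats::median(x); m2 <- stats::median(y)
        dir <- if (m1 > m2) "higher_in_group1"
               else if (m2 > m1) "higher_in_group2" else "none"
        data.frame(lv = as.character(lv), u_stat = mw$u, p_value = mw$p,
                   direction = dir, median_group1 = m1, median_group2 = m2,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$fdr <- bhAdjust(out$p_value)
    rownames(out) <- NULL
    out[, c("lv", "u_stat", "p_value", "fdr", "direction",
            "median_group1", "median_group2")]
}
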