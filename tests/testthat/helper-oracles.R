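# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and the stats:: routines the package wraps).

# brute-force pair-counting AUC, ties counted 1/2
oracleAUC <- function(x, y) {
    wins <- 0
    for (xi in x) for (yj in y)
        wins <- wins + (xi > yj) + 0.5 * (xi == yj)
    wins / (length(x) * length(y))
}

# exact Mann-Whitney p-value by full enumeration of all C(n1+n2, n1)
# labelings; tie-free inputs only
oracleMWp <- function(x, y, alternative = c("two_sided", "greater")) {
    alternative <- match.arg(alternative)
    n1 <- length(x)
    pooled <- c(x, y)
    stopifnot(!anyDuplicated(pooled))
    uObs <- oracleAUC(x, y) * n1 * length(y)
    labelings <- utils::combn(length(pooled), n1)
    us <- apply(labelings, 2L, function(idx)
        oracleAUC(pooled[idx], pooled[-idx]) * n1 * length(y))
    if (alternative == "greater") {
        mean(us >= uObs)
    } else {
        # two-sided: double the smaller tail, capped at 1
        min(1, 2 * min(mean(us >= uObs), mean(us <= uObs)))
    }
}

# hand-coded Benjamini-Hochberg step-up
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    out
}

# tiny expression TSV fixture on disk; returns the path
writeExprFixture <- function(m, dir = NULL) {
    if (is.null(dir)) {
        dir <- tempfile("fixture")
        dir.create(dir)
    }
    path <- file.path(dir, "expr.tsv")
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

tinyTpm <- function() {
    matrix(c(0, 0.5, 1.5,
             2, 4, 8),
           nrow = 3,
           dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
}

tinyAtlas <- function() {
    SignatureAtlas(
        list(sigA = c("g1", "g2"), sigB = c("g2", "g3", "g9")),
        meta = data.frame(name = c("sigA", "sigB"),
                          author = c("a1", "a2"),
                          species = "human",
                          clinical_condition = "none",
                          cell_type = c("PT", "Non associated")))
}
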