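#' @include AllClasses.R
NULL

# timestamped structured log line on stderr
.log <- function(level, ...) {
    message(sprintf("[%s] %s %s", level,
                    format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    paste0(...)))
}

# write a numeric matrix as TSV with full double precision so that
# read/write round-trips are value-exact
.writeMatrixTSV <- function(m, path, idCol = "id") {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(paste(c(idCol, colnames(m)), collapse = "\t"), con)
    body <- vapply(seq_len(nrow(m)), function(i) {
        paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
    }, character(1))
    writeLines(body, con)
    invisible(path)
}

.readMatrixTSV <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(df[[1]])
    m
}

# rank-based AUC: P(random x > random y), ties counted 1/2.
# Equivalent to the Mann-Whitney U statistic divided by n1*n2.
.rankAUC <- function(x, y) {
    n1 <- length(x)
    n2 <- length(y)
    r <- rank(c(x, y))
    (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
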