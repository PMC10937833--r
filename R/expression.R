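#' @include AllClasses.R utils.R
NULL

#' Read an expression table
#'
#' Reads a tab- or comma-separated genes x samples table (first column gene
#' identifiers, header row sample identifiers) into an
#' \linkS4class{ExpressionMatrix}.
#'
#' @param path path to a TSV/CSV file.
#' @param scale declared scale of the stored values (\code{"tpm"} by
#'   default).
#' @param sep field separator; guessed from the header line when \code{NULL}
#'   (tab if the header contains a tab, comma otherwise).
#' @return an \linkS4class{ExpressionMatrix}.
#' @seealso \code{\link{writeExpression}}
#' @export
readExpression <- function(path, scale = c("tpm", "log2_tpm_half"),
                           sep = NULL) {
    scale <- match.arg(scale)
    if (!file.exists(path))
        stop("file not found: ", path)
    header <- readLines(path, n = 1L)
    if (length(header) == 0L)
        stop("empty expression table: ", path)
    if (is.null(sep))
        sep <- if (grepl("\t", header)) "\t" else ","
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "", comment.char = "")
    if (ncol(df) < 2L)
        stop("expression table needs a gene column plus >=1 sample column")
    genes <- as.character(df[[1]])
    if (anyDuplicated(genes))
        stop("duplicate gene identifiers: ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m))
        stop("non-numeric expression values in ", path)
    storage.mode(m) <- "double"
    rownames(m) <- genes
    ExpressionMatrix(m, scale)
}

#' Write an expression table
#'
#' Writes a full-precision TSV (first column \code{gene}) so that
#' \code{readExpression} round-trips value-exactly.
#'
#' @param em an \linkS4class{ExpressionMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(em, path) {
    stopifnot(is(em, "ExpressionMatrix"))
    .writeMatrixTSV(exprValues(em), path, idCol = "gene")
}

#' Log-transform TPM values
#'
#' Applies the variance-stabilizing transform \code{log2(TPM + 0.5)} used
#' throughout the framework; the half-count offset maps zero TPM to -1.
#'
#' @param em an \linkS4class{ExpressionMatrix} on the \code{tpm} scale.
#' @return an \linkS4class{ExpressionMatrix} on the \code{log2_tpm_half}
#'   scale.
#' @examples
#' m <- matrix(c(0, 0.5, 1.5, 2), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' exprValues(logTransform(ExpressionMatrix(m, "tpm")))
#' @export
logTransform <- function(em) {
    stopifnot(is(em, "ExpressionMatrix"))
    if (exprScale(em) != "tpm")
        stop("logTransform expects TPM-scale input")
    v <- exprValues(em)
    if (length(v) && min(v) < 0)
        stop("negative TPM values")
    ExpressionMatrix(log2(v + 0.5), "log2_tpm_half")
}

#' Filter genes prior to decomposition
#'
#' Drops genes with null variance across samples, genes whose fraction of
#' zero values exceeds \code{zeroFracMax} (strictly more than; a fraction
#' exactly equal to the threshold is kept), and genes absent from every
#' signature of the atlas. Both value-based filters are computed on the TPM
#' scale, where zeros are well defined. Gene order is preserved.
#'
#' @param em an \linkS4class{ExpressionMatrix} on the \code{tpm} scale.
#' @param atlas a \linkS4class{SignatureAtlas}; genes in no signature are
#'   removed. Pass \code{NULL} to skip the membership filter.
#' @param zeroFracMax maximum tolerated fraction of zero values (default
#'   0.95).
#' @return the filtered \linkS4class{ExpressionMatrix}.
#' @export
filterGenes <- function(em, atlas = NULL, zeroFracMax = 0.95) {
    stopifnot(is(em, "ExpressionMatrix"))
    if (exprScale(em) != "tpm")
        stop("filterGenes expects TPM-scale input (filters are defined on TPM)")
    v <- exprValues(em)
    vars <- apply(v, 1L, stats::var)
    zeroFrac <- rowMeans(v == 0)
    keep <- vars > 0 & zeroFrac <= zeroFracMax
    if (!is.null(atlas)) {
        stopifnot(is(atlas, "SignatureAtlas"))
        inSig <- rownames(v) %in% unique(unlist(geneSets(atlas),
                                                use.names = FALSE))
        keep <- keep & inSig
    }
    if (!any(keep))
        stop("all genes removed by filtering")
    ExpressionMatrix(v[keep, , drop = FALSE], "tpm")
}
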