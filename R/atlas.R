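#' @include AllClasses.R
NULL

#' Read a signature atlas from GMT
#'
#' Parses the standard GMT gene-set interchange format (one signature per
#' line: name, description, then tab-separated gene identifiers) and
#' optionally joins a metadata table keyed by signature name. Signatures
#' without metadata are classified as cell type \code{"Non associated"}.
#'
#' @param path path to a GMT file.
#' @param metadataPath optional path to a TSV with columns \code{name},
#'   \code{author}, \code{species}, \code{clinical_condition},
#'   \code{cell_type}. Rows naming unknown signatures raise a warning and
#'   are ignored.
#' @return a \linkS4class{SignatureAtlas}.
#' @seealso \code{\link{writeGMT}}
#' @export
readGMT <- function(path, metadataPath = NULL) {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L)
        stop("empty GMT file: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nm <- vapply(fields, `[`, character(1), 1L)
    if (anyDuplicated(nm))
        stop("duplicate signature names: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    geneSets <- lapply(fields, function(f) {
        g <- f[-(1:2)]
        g <- g[!is.na(g) & nzchar(g)]
        g
    })
    names(geneSets) <- nm
    empty <- vapply(geneSets, length, 1L) == 0L
    if (any(empty))
        stop("signature(s) with no genes: ",
             paste(nm[empty], collapse = ", "))
    meta <- NULL
    if (!is.null(metadataPath))
        meta <- utils::read.delim(metadataPath, stringsAsFactors = FALSE,
                                  check.names = FALSE)
    SignatureAtlas(geneSets, meta)
}

#' Write a signature atlas as GMT (plus optional metadata TSV)
#'
#' @param atlas a \linkS4class{SignatureAtlas}.
#' @param path output GMT path.
#' @param metadataPath optional output path for the metadata TSV.
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(atlas, path, metadataPath = NULL) {
    stopifnot(is(atlas, "SignatureAtlas"))
    gs <- geneSets(atlas)
    lines <- vapply(names(gs), function(n) {
        paste(c(n, "na", gs[[n]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    if (!is.null(metadataPath)) {
        meta <- signatureMeta(atlas)
        out <- cbind(name = rownames(meta), meta)
        utils::write.table(out, metadataPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' Build the binary prior-knowledge matrix
#'
#' Constructs the genes x signatures membership matrix C with
#' \code{C[i, s] = 1} iff gene i belongs to signature s, restricted to the
#' supplied gene universe. Signature genes outside the universe are dropped
#' with a warning; signatures left without any gene are dropped (also with a
#' warning).
#'
#' @param atlas a \linkS4class{SignatureAtlas}.
#' @param genes character vector: the ordered gene universe (typically the
#'   rownames of the filtered expression matrix).
#' @return numeric genes x signatures matrix of 0/1 values, with dimnames.
#' @export
buildPriorMatrix <- function(atlas, genes) {
    stopifnot(is(atlas, "SignatureAtlas"))
    genes <- as.character(genes)
    if (length(genes) == 0L)
        stop("empty gene universe")
    gs <- geneSets(atlas)
    C <- matrix(0, length(genes), length(gs),
                dimnames = list(genes, names(gs)))
    nDropped <- 0L
    for (s in names(gs)) {
        inU <- gs[[s]][gs[[s]] %in% genes]
        nDropped <- nDropped + (length(gs[[s]]) - length(inU))
        if (length(inU))
            C[inU, s] <- 1
    }
    if (nDropped > 0L)
        warning(nDropped,
                " signature gene(s) outside the universe were dropped")
    emptyCols <- colSums(C) == 0
    if (all(emptyCols))
        stop("no signature overlaps the gene universe")
    if (any(emptyCols)) {
        warning("signature(s) with no gene in the universe dropped: ",
                paste(colnames(C)[emptyCols], collapse = ", "))
        C <- C[, !emptyCols, drop = FALSE]
    }
    C
}
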