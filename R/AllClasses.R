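#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay
NULL

#' Expression matrix container
#'
#' A genes x samples expression matrix with an explicit scale flag, stored as
#' a \linkS4class{SummarizedExperiment} with a single assay named
#' \code{"expr"}. The scale is either \code{"tpm"} (raw transcripts per
#' million, nonnegative) or \code{"log2_tpm_half"} (values of
#' \code{log2(TPM + 0.5)}, bounded below by -1).
#'
#' @slot scale character, one of \code{"tpm"}, \code{"log2_tpm_half"}.
#' @export
setClass("ExpressionMatrix",
         contains = "SummarizedExperiment",
         representation(scale = "character"))

.validExpressionMatrix <- function(object) {
    msg <- NULL
    v <- SummarizedExperiment::assay(object, "expr")
    if (!is.numeric(v))
        msg <- c(msg, "assay 'expr' must be numeric")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "gene and sample identifiers are required")
    if (anyDuplicated(rownames(v)))
        msg <- c(msg, "duplicate gene identifiers")
    if (anyDuplicated(colnames(v)))
        msg <- c(msg, "duplicate sample identifiers")
    if (!all(is.finite(v)))
        msg <- c(msg, "expression values must be finite")
    if (length(object@scale) != 1L ||
        !object@scale %in% c("tpm", "log2_tpm_half"))
        msg <- c(msg, "scale must be 'tpm' or 'log2_tpm_half'")
    else if (object@scale == "tpm" && length(v) && min(v) < 0)
        msg <- c(msg, "TPM values must be nonnegative")
    else if (object@scale == "log2_tpm_half" && length(v) &&
             min(v) < -1 - 1e-8)
        msg <- c(msg, "log2(TPM+0.5) values must be >= -1")
    if (is.null(msg)) TRUE else msg
}
setValidity("ExpressionMatrix", .validExpressionMatrix)

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns (colnames = sample identifiers).
#' @param scale scale of the values: \code{"tpm"} or \code{"log2_tpm_half"}.
#' @return an \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(rexp(6), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' em <- ExpressionMatrix(m, "tpm")
#' @export
ExpressionMatrix <- function(values, scale = c("tpm", "log2_tpm_half")) {
    scale <- match.arg(scale)
    values <- as.matrix(values)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = values))
    new("ExpressionMatrix", se, scale = scale)
}

#' Signature atlas
#'
#' An ordered collection of named gene signatures with per-signature
#' metadata (author, species, clinical condition, cell type). Signatures
#' whose metadata is unknown carry cell type \code{"Non associated"}.
#'
#' @slot geneSets named list of character vectors (gene identifiers).
#' @slot meta data.frame with one row per signature (rownames = signature
#'   names) and columns author, species, clinical_condition, cell_type.
#' @export
setClass("SignatureAtlas",
         representation(geneSets = "list", meta = "data.frame"))

.metaCols <- c("author", "species", "clinical_condition", "cell_type")

.validSignatureAtlas <- function(object) {
    msg <- NULL
    gs <- object@geneSets
    if (length(gs) < 1L)
        msg <- c(msg, "atlas must contain at least one signature")
    if (is.null(names(gs)) || anyDuplicated(names(gs)) ||
        any(!nzchar(names(gs))))
        msg <- c(msg, "signature names must be unique and non-empty")
    if (any(vapply(gs, length, 1L) == 0L))
        msg <- c(msg, "every signature must contain at least one gene")
    if (!identical(rownames(object@meta), names(gs)))
        msg <- c(msg, "metadata rows must match signature names")
    if (!all(.metaCols %in% colnames(object@meta)))
        msg <- c(msg, paste("metadata must have columns",
                            paste(.metaCols, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
}
setValidity("SignatureAtlas", .validSignatureAtlas)

#' Construct a SignatureAtlas
#'
#' @param geneSets named list of character vectors of gene identifiers.
#' @param meta optional data.frame of signature metadata with a \code{name}
#'   column (or rownames) plus author, species, clinical_condition,
#'   cell_type. Signatures without a metadata row get \code{NA} fields and
#'   cell type \code{"Non associated"}.
#' @return a \linkS4class{SignatureAtlas}.
#' @export
SignatureAtlas <- function(geneSets, meta = NULL) {
    geneSets <- lapply(geneSets, function(g) unique(as.character(g)))
    nm <- names(geneSets)
    full <- data.frame(author = rep(NA_character_, length(nm)),
                       species = NA_character_,
                       clinical_condition = NA_character_,
                       cell_type = "Non associated",
                       row.names = nm, stringsAsFactors = FALSE)
    if (!is.null(meta)) {
        meta <- as.data.frame(meta, stringsAsFactors = FALSE)
        if ("name" %in% colnames(meta)) {
            rownames(meta) <- meta$name
            meta$name <- NULL
        }
        unknown <- setdiff(rownames(meta), nm)
        if (length(unknown))
            warning("metadata for unknown signature(s) ignored: ",
                    paste(unknown, collapse = ", "))
        keep <- intersect(rownames(meta), nm)
        for (cc in intersect(.metaCols, colnames(meta)))
            full[keep, cc] <- as.character(meta[keep, cc])
        full$cell_type[is.na(full$cell_type)] <- "Non associated"
    }
    new("SignatureAtlas", geneSets = geneSets, meta = full)
}

#' Fitted prior-guided decomposition model
#'
#' Holds the learned loadings Z (genes x LVs, nonnegative by default), the
#' score matrix B (LVs x samples), the sparse signature-weight matrix U
#' (signatures x LVs), the binary prior matrix C used in training, the
#' resolved configuration, the per-gene standardization statistics needed to
#' project new data, and the outer-iteration loss trace.
#'
#' @slot Z numeric matrix, genes x LVs.
#' @slot B numeric matrix, LVs x samples.
#' @slot U numeric matrix, signatures x LVs.
#' @slot prior numeric matrix, genes x signatures (binary; may be empty
#'   after deserialization, it is not needed for projection).
#' @slot config named list of resolved hyperparameters (k, lambda1, lambda2,
#'   lambda3, frac, maxIter, tol, seed, standardize, nonneg, innerSweeps).
#' @slot geneMeans,geneSds per-gene standardization statistics on the
#'   training data (zeros/ones when standardization is off).
#' @slot lossTrace numeric vector of outer-iteration loss values.
#' @export
setClass("PlierModel",
         representation(Z = "matrix", B = "matrix", U = "matrix",
                        prior = "matrix", config = "list",
                        geneMeans = "numeric", geneSds = "numeric",
                        lossTrace = "numeric"))

.validPlierModel <- function(object) {
    msg <- NULL
    k <- ncol(object@Z)
    if (nrow(object@B) != k)
        msg <- c(msg, "Z and B disagree on the number of LVs")
    if (ncol(object@U) != k && length(object@U))
        msg <- c(msg, "U and Z disagree on the number of LVs")
    if (length(object@geneMeans) != nrow(object@Z) ||
        length(object@geneSds) != nrow(object@Z))
        msg <- c(msg, "gene statistics must match the gene universe")
    if (isTRUE(object@config$nonneg)) {
        if (length(object@Z) && min(object@Z) < -1e-10)
            msg <- c(msg, "Z must be nonnegative")
        if (length(object@U) && min(object@U) < -1e-10)
            msg <- c(msg, "U must be nonnegative")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("PlierModel", .validPlierModel)

#' Latent-variable/signature association table
#'
#' One record per (LV, signature) pair receiving positive weight in the
#' hold-out refit, with the hold-out AUC, one-sided Mann-Whitney p-value,
#' Benjamini-Hochberg FDR and the signature's cell type. The interpretable
#' set contains the LVs with at least one record passing AUC > 0.7 and
#' FDR < 0.05 (both strict).
#'
#' @slot records data.frame with columns lv, signature, u_weight, auc,
#'   p_value, fdr, cell_type, interpretable.
#' @slot interpretableLVs character vector of interpretable LV identifiers.
#' @export
setClass("AssociationTable",
         representation(records = "data.frame",
                        interpretableLVs = "character"))
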