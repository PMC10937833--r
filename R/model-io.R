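#' @include plier-fit.R utils.R
NULL

#' Serialize a fitted model to a directory of plain-text files
#'
#' Writes \code{Z.tsv}, \code{B.tsv}, \code{U.tsv}, \code{gene_stats.tsv},
#' \code{loss_trace.tsv} and \code{config.yaml}. All numeric values are
#' written with full double precision so that
#' \code{\link{readPlierModel}} round-trips value-exactly.
#'
#' @param model a \linkS4class{PlierModel}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writePlierModel <- function(model, dir) {
    stopifnot(is(model, "PlierModel"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    .writeMatrixTSV(model@Z, file.path(dir, "Z.tsv"), "gene")
    .writeMatrixTSV(model@B, file.path(dir, "B.tsv"), "lv")
    .writeMatrixTSV(model@U, file.path(dir, "U.tsv"), "signature")
    gs <- cbind(mean = model@geneMeans, sd = model@geneSds)
    .writeMatrixTSV(gs, file.path(dir, "gene_stats.tsv"), "gene")
    lt <- matrix(model@lossTrace, ncol = 1,
                 dimnames = list(seq_along(model@lossTrace), "loss"))
    .writeMatrixTSV(lt, file.path(dir, "loss_trace.tsv"), "iteration")
    cfg <- model@config
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"), precision = 17L)
    invisible(dir)
}

#' Load a serialized model
#'
#' Counterpart of \code{\link{writePlierModel}}. The binary prior matrix C
#' is not part of the serialized form (it is not needed for projection); the
#' loaded model carries an empty C slot.
#'
#' @param dir directory written by \code{\link{writePlierModel}}.
#' @return a \linkS4class{PlierModel}.
#' @export
readPlierModel <- function(dir) {
    Z <- .readMatrixTSV(file.path(dir, "Z.tsv"))
    B <- .readMatrixTSV(file.path(dir, "B.tsv"))
    U <- .readMatrixTSV(file.path(dir, "U.tsv"))
    gs <- .readMatrixTSV(file.path(dir, "gene_stats.tsv"))
    lt <- .readMatrixTSV(file.path(dir, "loss_trace.tsv"))
    cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
    cfg$k <- as.integer(cfg$k)
    new("PlierModel", Z = Z, B = B, U = U,
        prior = matrix(0, 0, 0), config = cfg,
        geneMeans = stats::setNames(gs[, "mean"], rownames(gs)),
        geneSds = stats::setNames(gs[, "sd"], rownames(gs)),
        lossTrace = unname(lt[, 1]))
}
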