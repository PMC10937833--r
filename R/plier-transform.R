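#' @include plier-fit.R
NULL

.transformMatrix <- function(model, Yn) {
    genes <- rownames(model@Z)
    if (is.null(rownames(Yn)))
        stop("new data must carry gene identifiers as rownames")
    common <- intersect(genes, rownames(Yn))
    overlap <- length(common) / length(genes)
    if (overlap < 0.5)
        stop(sprintf("only %.1f%% of model genes present in the new data",
                     100 * overlap))
    if (overlap < 0.8)
        warning(sprintf(
            "only %.1f%% of model genes present; missing genes zero-filled",
            100 * overlap))
    else if (overlap < 1)
        .log("WARN", length(genes) - length(common),
             " model gene(s) absent from the new data; zero-filled")
    Ya <- matrix(0, length(genes), ncol(Yn),
                 dimnames = list(genes, colnames(Yn)))
    Ya[common, ] <- (Yn[common, , drop = FALSE] -
                         model@geneMeans[common]) / model@geneSds[common]
    Bp <- .ridgeScores(model@Z, Ya, model@config$lambda2)
    dimnames(Bp) <- list(colnames(model@Z), colnames(Yn))
    Bp
}

#' @describeIn plierTransform project an \linkS4class{ExpressionMatrix}
#'   (must be on the \code{log2_tpm_half} scale); returns the LVs x samples
#'   score matrix B', row-aligned to the training model's LVs. Genes are
#'   reordered to the model's gene universe; model genes absent from the new
#'   data are zero-filled after standardization (warning below 80% overlap,
#'   error below 50%).
#' @export
setMethod("plierTransform",
          signature(model = "PlierModel", newdata = "ExpressionMatrix"),
          function(model, newdata) {
    if (exprScale(newdata) != "log2_tpm_half")
        stop("plierTransform expects log2(TPM+0.5)-scale input")
    .transformMatrix(model, exprValues(newdata))
})

#' @describeIn plierTransform project a plain matrix with gene rownames.
#' @export
setMethod("plierTransform",
          signature(model = "PlierModel", newdata = "matrix"),
          function(model, newdata) {
    .transformMatrix(model, newdata)
})

#' Estimate the number of latent variables by permutation
#'
#' Parallel-analysis-style selection: singular values of the
#' row-standardized matrix are compared, component by component, with the
#' chosen quantile of the singular values obtained after independently
#' permuting the entries within each row. The returned k is the length of
#' the leading run of observed singular values exceeding their permutation
#' threshold.
#'
#' @param object an \linkS4class{ExpressionMatrix} or numeric matrix.
#' @param nPerm number of within-row permutations (default 20).
#' @param quantile permutation quantile used as the per-component threshold
#'   (default 0.95).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return the estimated number of latent variables (integer, >= 0).
#' @export
estimateNumLVs <- function(object, nPerm = 20L, quantile = 0.95, seed = 1L) {
    Y <- if (is(object, "ExpressionMatrix")) exprValues(object)
         else as.matrix(object)
    if (nrow(Y) < 2L || ncol(Y) < 2L)
        stop("need at least a 2 x 2 matrix")
    sds <- apply(Y, 1L, stats::sd)
    if (all(sds < 1e-12))
        stop("degenerate constant matrix")
    Ys <- (Y - rowMeans(Y)) / pmax(sds, 1e-12)
    dObs <- svd(Ys, nu = 0, nv = 0)$d
    set.seed(seed)
    dPerm <- vapply(seq_len(nPerm), function(i) {
        svd(.permuteWithinRows(Ys), nu = 0, nv = 0)$d
    }, numeric(length(dObs)))
    thr <- apply(dPerm, 1L, stats::quantile, probs = quantile)
    exceeds <- dObs > thr
    below <- which(!exceeds)
    if (length(below) == 0L) length(dObs) else below[1L] - 1L
}
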