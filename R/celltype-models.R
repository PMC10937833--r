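#' @include association.R utils.R
NULL

#' Extract the LVs most associated with a cell type
#'
#' Restricts the interpretable LVs to those labeled with the requested cell
#' type, ranks them by their maximum passing AUC (ties broken by lower FDR,
#' then higher u_weight) and truncates to \code{maxN}.
#'
#' @param assoc an \linkS4class{AssociationTable}.
#' @param cellType target cell-type category (after \code{categories}
#'   mapping).
#' @param maxN maximum number of LVs to return (default 4).
#' @param categories optional cell-type -> category mapping passed to
#'   \code{\link{labelLVs}}.
#' @return list with elements \code{cellType}, \code{lvs} (ordered, length
#'   <= maxN) and \code{rankingScores} (the per-LV maximum passing AUC).
#' @export
extractCellTypeLVs <- function(assoc, cellType, maxN = 4L,
                               categories = NULL) {
    labels <- labelLVs(assoc, categories = categories)
    lvs <- names(labels)[labels == cellType]
    if (length(lvs) == 0L)
        stop("no interpretable LV labeled '", cellType, "'")
    rec <- .recordsOf(assoc)
    pass <- rec[rec$auc > 0.7 & rec$fdr < 0.05 & rec$lv %in% lvs, ,
                drop = FALSE]
    pass <- .orderPassing(pass)
    best <- pass[!duplicated(pass$lv), , drop = FALSE]
    keep <- utils::head(seq_len(nrow(best)), maxN)
    list(cellType = cellType,
         lvs = best$lv[keep],
         rankingScores = stats::setNames(best$auc[keep], best$lv[keep]))
}

# stratified fold assignment: within each class, indices are shuffled and
# dealt cyclically, so per-class fold counts differ by at most one
.stratifiedFolds <- function(y, folds) {
    if (min(table(y)) < folds)
        stop("each fold must contain at least one sample of each class; ",
             "smallest class has ", min(table(y)), " samples for ", folds,
             " folds")
    fold <- integer(length(y))
    for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep(seq_len(folds), length.out = length(idx))
    }
    fold
}

.resolveModelSpec <- function(modelSpec) {
    if (is.list(modelSpec)) {
        stopifnot(is.function(modelSpec$fit), is.function(modelSpec$predict))
        return(modelSpec)
    }
    switch(match.arg(modelSpec, c("randomForest", "logistic")),
        randomForest = list(
            fit = function(X, y) randomForest::randomForest(x = X, y = y),
            predict = function(fit, X)
                stats::predict(fit, X, type = "prob")[, 2L]),
        logistic = list(
            fit = function(X, y) {
                df <- data.frame(X, check.names = FALSE)
                df$.y <- y
                suppressWarnings(
                    stats::glm(.y ~ ., data = df, family = stats::binomial()))
            },
            predict = function(fit, X)
                suppressWarnings(
                    stats::predict(fit, data.frame(X, check.names = FALSE),
                                   type = "response"))))
}

#' Repeated stratified cross-validated AUROC
#'
#' For each repetition a fresh stratified fold assignment is drawn, one
#' model is fitted per fold on the remaining folds, the out-of-fold
#' prediction scores are pooled across the repetition's folds, and a single
#' AUROC is computed from the pooled scores. The mean and standard deviation
#' over repetitions are reported. No hyperparameter tuning is performed; the
#' default model is a random forest with its library defaults.
#'
#' @param X samples x features matrix (or data.frame).
#' @param y binary labels aligned to the rows of X; coerced to a two-level
#'   factor, the second level being the positive class.
#' @param folds number of folds (default 10).
#' @param repeats number of repetitions (default 10).
#' @param modelSpec \code{"randomForest"} (default), \code{"logistic"}, or
#'   a list with functions \code{fit(X, y)} and \code{predict(fit, X)}
#'   returning a numeric score per row.
#' @param seed integer seed; the whole procedure is reproducible given the
#'   seed.
#' @return object of class \code{"cvResult"}: list with
#'   \code{perRepetitionAUROC}, \code{meanAUROC}, \code{sdAUROC},
#'   \code{predictions} (samples x repeats matrix of pooled out-of-fold
#'   scores) and \code{positiveClass}.
#' @export
repeatedCVAuroc <- function(X, y, folds = 10L, repeats = 10L,
                            modelSpec = "randomForest", seed = 1L) {
    X <- as.matrix(X)
    if (is.null(colnames(X)))
        colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
    y <- factor(y)
    if (nlevels(y) != 2L)
        stop("y must contain exactly two classes")
    if (nrow(X) != length(y))
        stop("X and y disagree on the number of samples")
    spec <- .resolveModelSpec(modelSpec)
    pos <- levels(y)[2L]
    set.seed(seed)
    preds <- matrix(NA_real_, nrow(X), repeats,
                    dimnames = list(rownames(X), NULL))
    aurocs <- numeric(repeats)
    for (r in seq_len(repeats)) {
        fold <- .stratifiedFolds(y, folds)
        sc <- numeric(nrow(X))
        for (f in seq_len(folds)) {
            tr <- fold != f
            fit <- spec$fit(X[tr, , drop = FALSE], droplevels(y[tr]))
            sc[!tr] <- spec$predict(fit, X[!tr, , drop = FALSE])
        }
        preds[, r] <- sc
        aurocs[r] <- .rankAUC(sc[y == pos], sc[y != pos])
    }
    structure(list(perRepetitionAUROC = aurocs,
                   meanAUROC = mean(aurocs),
                   sdAUROC = stats::sd(aurocs),
                   predictions = preds,
                   positiveClass = pos),
              class = "cvResult")
}

#' @export
print.cvResult <- function(x, ...) {
    cat(sprintf("cvResult: AUROC %.3f +/- %.3f over %d repetitions\n",
                x$meanAUROC, x$sdAUROC, length(x$perRepetitionAUROC)))
    invisible(x)
}

#' Exact Shapley-value attribution
#'
#' Computes exact Shapley values by full coalition enumeration. The value of
#' a coalition S for a sample is the mean model score over the background
#' rows with the sample's features substituted on S; the baseline is the
#' mean score over the background. Additivity (baseline + sum of
#' attributions = model score) holds exactly by construction. Feature counts
#' are limited to 12 (the cell-type models use at most 4 LVs).
#'
#' @param predictFn function mapping a samples x features matrix to a
#'   numeric score per row.
#' @param X samples x features matrix of instances to explain.
#' @param background samples x features matrix of reference rows.
#' @return list with \code{values} (samples x features matrix of Shapley
#'   values), \code{baseline} (mean background score) and
#'   \code{featureImportance} (per-feature mean absolute value, decreasing
#'   order of which ranks the features).
#' @export
shapleyAttribution <- function(predictFn, X, background) {
    X <- as.matrix(X)
    background <- as.matrix(background)
    d <- ncol(X)
    if (d < 1L || d > 12L)
        stop("exact enumeration supports 1 to 12 features")
    if (ncol(background) != d)
        stop("background must have the same features as X")
    n <- nrow(X); nb <- nrow(background)
    nMask <- bitwShiftL(1L, d)
    bits <- bitwShiftL(1L, seq_len(d) - 1L)
    # v[i, m+1] = value of coalition encoded by mask m for sample i
    v <- matrix(0, n, nMask)
    fullPred <- as.numeric(predictFn(X))
    base <- mean(as.numeric(predictFn(background)))
    for (m in 0:(nMask - 1L)) {
        S <- which(bitwAnd(m, bits) > 0L)
        if (length(S) == 0L) {
            v[, m + 1L] <- base
        } else if (length(S) == d) {
            v[, m + 1L] <- fullPred
        } else {
            big <- background[rep(seq_len(nb), n), , drop = FALSE]
            big[, S] <- X[rep(seq_len(n), each = nb), S, drop = FALSE]
            p <- as.numeric(predictFn(big))
            v[, m + 1L] <- colMeans(matrix(p, nrow = nb))
        }
    }
    sizes <- vapply(0:(nMask - 1L), function(m)
        sum(bitwAnd(m, bits) > 0L), 1L)
    w <- factorial(0:(d - 1L)) * factorial(d - 1L - 0:(d - 1L)) /
        factorial(d)
    phi <- matrix(0, n, d,
                  dimnames = list(rownames(X), colnames(X)))
    for (j in seq_len(d)) {
        without <- which(bitwAnd(0:(nMask - 1L), bits[j]) == 0L)
        for (m in without) {
            s <- sizes[m]
            phi[, j] <- phi[, j] + w[s + 1L] * (v[, m + bits[j]] - v[, m])
        }
    }
    list(values = phi, baseline = base,
         featureImportance = colMeans(abs(phi)))
}
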