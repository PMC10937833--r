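#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Configuration for the prior-guided decomposition
#'
#' Collects and validates the hyperparameters of the penalized
#' factorization. The loss being minimized is
#' \deqn{\|Y - ZB\|_F^2 + \lambda_1\|Z - CU\|_F^2 + \lambda_2\|B\|_F^2 +
#'   \lambda_3\sum|U|}
#' with Z (and U) constrained nonnegative by default.
#'
#' When \code{lambda1}/\code{lambda2} are \code{NULL} they default to the
#' noise level of the permutation scree of the row-standardized data (the
#' top singular value of a within-row permuted copy), the scale below which
#' singular values are indistinguishable from noise. When \code{lambda3} is
#' \code{NULL} it is calibrated so that the soft-threshold level equals the
#' \code{(1 - frac)} quantile of the nonzero unpenalized candidate
#' signature weights at initialization; smaller \code{frac} therefore
#' yields a sparser U.
#'
#' @param k number of latent variables (must satisfy k <= min(N, M) at fit
#'   time).
#' @param lambda1 weight of the Z ~ CU alignment term, or \code{NULL} for
#'   automatic calibration.
#' @param lambda2 L2 penalty on B, or \code{NULL} for automatic calibration.
#' @param lambda3 L1 penalty on U, or \code{NULL} for automatic calibration.
#' @param frac sparsity-control fraction in (0, 1] used by the automatic
#'   lambda3 calibration. Default 0.5.
#' @param maxIter maximum number of outer iterations (default 200).
#' @param tol relative loss-change stopping threshold (default 1e-6).
#' @param seed integer seed controlling the (single) random permutation used
#'   by the lambda calibration; the fit itself is deterministic.
#' @param standardize z-score each gene before fitting (default TRUE). The
#'   per-gene means/sds are stored in the model and reused when projecting
#'   new data.
#' @param nonneg constrain Z and U to be nonnegative (default TRUE).
#' @param innerSweeps coordinate-descent sweeps per outer iteration for the
#'   Z and U blocks (default 3).
#' @return a named list of class \code{"plierConfig"}.
#' @export
plierConfig <- function(k, lambda1 = NULL, lambda2 = NULL, lambda3 = NULL,
                        frac = 0.5, maxIter = 200L, tol = 1e-6, seed = 1L,
                        standardize = TRUE, nonneg = TRUE, innerSweeps = 3L) {
    stopifnot(length(k) == 1L, k >= 1, k == as.integer(k),
              is.null(lambda1) || lambda1 >= 0,
              is.null(lambda2) || lambda2 >= 0,
              is.null(lambda3) || lambda3 >= 0,
              frac > 0, frac <= 1, maxIter >= 1, tol > 0,
              innerSweeps >= 1)
    structure(list(k = as.integer(k), lambda1 = lambda1, lambda2 = lambda2,
                   lambda3 = lambda3, frac = frac,
                   maxIter = as.integer(maxIter), tol = tol,
                   seed = as.integer(seed),
                   standardize = isTRUE(standardize),
                   nonneg = isTRUE(nonneg),
                   innerSweeps = as.integer(innerSweeps)),
              class = "plierConfig")
}

# accept a plierConfig or a fitted model carrying its resolved config
.asPlierConfig <- function(x) {
    if (inherits(x, "plierConfig")) return(x)
    if (is(x, "PlierModel"))
        return(do.call(plierConfig, x@config[c(
            "k", "lambda1", "lambda2", "lambda3", "frac", "maxIter", "tol",
            "seed", "standardize", "nonneg", "innerSweeps")]))
    stop("expected a plierConfig or PlierModel")
}

#' Penalized factorization loss
#'
#' \eqn{\|Y - ZB\|_F^2 + \lambda_1\|Z - CU\|_F^2 + \lambda_2\|B\|_F^2 +
#' \lambda_3\sum|U|}.
#'
#' @param Y genes x samples matrix.
#' @param Z genes x LVs loadings.
#' @param B LVs x samples scores.
#' @param C genes x signatures binary prior.
#' @param U signatures x LVs weights.
#' @param lambda1,lambda2,lambda3 nonnegative penalty weights.
#' @return the (finite) loss value.
#' @export
plierLoss <- function(Y, Z, B, C, U, lambda1, lambda2, lambda3) {
    if (nrow(Z) != nrow(Y) || ncol(B) != ncol(Y) || ncol(Z) != nrow(B))
        stop("dimension mismatch between Y, Z and B")
    if (nrow(C) != nrow(Y) || ncol(C) != nrow(U) || ncol(U) != ncol(Z))
        stop("dimension mismatch between C, U and Z")
    val <- sum((Y - Z %*% B)^2) +
        lambda1 * sum((Z - C %*% U)^2) +
        lambda2 * sum(B^2) +
        lambda3 * sum(abs(U))
    if (!is.finite(val))
        stop("non-finite loss")
    val
}

# ridge solve B = (Z'Z + lambda2 I)^-1 Z'Y with a fallback jitter when the
# normal matrix is numerically singular (e.g. lambda2 = 0 and a collapsed
# loading column)
.ridgeScores <- function(Z, Y, lambda2) {
    k <- ncol(Z)
    G <- crossprod(Z) + diag(lambda2, k)
    H <- crossprod(Z, Y)
    ch <- tryCatch(chol(G), error = function(e) NULL)
    if (is.null(ch)) {
        G <- G + diag(1e-10 * (mean(diag(G)) + 1), k)
        ch <- chol(G)
    }
    backsolve(ch, backsolve(ch, H, transpose = TRUE))
}

# one block of exact column-wise coordinate descent for Z under
# ||Y - ZB||^2 + lambda1 ||Z - CU||^2, optionally clipped at zero
.updateZ <- function(Z, Y, B, CU, lambda1, nonneg, sweeps) {
    k <- ncol(Z)
    G <- tcrossprod(B) + diag(lambda1, k)
    diag(G) <- pmax(diag(G), 1e-12)
    H <- Y %*% t(B)
    if (lambda1 > 0)
        H <- H + lambda1 * CU
    if (!nonneg) {
        ch <- tryCatch(chol(G), error = function(e) NULL)
        if (is.null(ch)) {
            G <- G + diag(1e-10 * (mean(diag(G)) + 1), k)
            ch <- chol(G)
        }
        return(t(backsolve(ch, backsolve(ch, t(H), transpose = TRUE))))
    }
    for (sw in seq_len(sweeps)) {
        for (j in seq_len(k)) {
            zj <- (H[, j] - Z %*% G[, j] + Z[, j] * G[j, j]) / G[j, j]
            Z[, j] <- pmax(zj, 0)
        }
    }
    Z
}

# coordinate-wise (nonnegative) lasso updates for U under
# lambda1 ||Z - CU||^2 + lambda3 sum|U|; columns of U are independent and
# updated jointly, coordinates cycled over signatures
.updateU <- function(U, CtC, CtZ, lambda1, lambda3, nonneg, sweeps) {
    S <- nrow(U)
    thr <- lambda3 / (2 * lambda1)
    for (sw in seq_len(sweeps)) {
        for (s in seq_len(S)) {
            rho <- CtZ[s, ] - drop(CtC[s, ] %*% U) + CtC[s, s] * U[s, ]
            if (nonneg) {
                U[s, ] <- pmax(rho - thr, 0) / CtC[s, s]
            } else {
                U[s, ] <- sign(rho) * pmax(abs(rho) - thr, 0) / CtC[s, s]
            }
        }
    }
    U
}

# noise level of the scree from one seeded within-row permutation of the
# (standardized) matrix: the top permuted singular value. Penalties act on
# the singular-value scale, so this is the natural default weight.
.noiseScale <- function(Ys) {
    Yp <- .permuteWithinRows(Ys)
    svd(Yp, nu = 0, nv = 0)$d[1]
}

.permuteWithinRows <- function(Y) {
    t(apply(Y, 1L, sample))
}

.lvNames <- function(k) sprintf("LV%03d", seq_len(k))

# core fit on plain matrices; Y rows must already match C rows
.fitPlierMatrix <- function(Y, C, config) {
    stopifnot(inherits(config, "plierConfig"))
    N <- nrow(Y); M <- ncol(Y)
    if (!all(is.finite(Y)))
        stop("non-finite expression values")
    if (is.null(rownames(Y)))
        rownames(Y) <- sprintf("g%d", seq_len(N))
    if (!identical(rownames(Y), rownames(C)))
        stop("gene order of Y must equal the gene order of the prior matrix")
    k <- config$k
    if (k > min(N, M))
        stop("k = ", k, " exceeds min(N, M) = ", min(N, M))
    set.seed(config$seed)

    if (config$standardize) {
        mu <- rowMeans(Y)
        sds <- apply(Y, 1L, stats::sd)
        if (all(sds < 1e-12))
            stop("degenerate constant matrix")
        sds <- pmax(sds, 1e-12)
    } else {
        mu <- numeric(N)
        sds <- rep(1, N)
    }
    Ys <- (Y - mu) / sds

    # deterministic scale-aware initialization from the truncated SVD;
    # majority-negative loading columns are sign-flipped before clipping
    sv <- svd(Ys, nu = k, nv = k)
    d <- pmax(sv$d[seq_len(k)], 1e-12)
    Uk <- sv$u; Vk <- sv$v
    for (j in seq_len(k)) {
        if (mean(Uk[, j] < 0) > 0.5) {
            Uk[, j] <- -Uk[, j]
            Vk[, j] <- -Vk[, j]
        }
    }
    Z <- sweep(Uk, 2L, sqrt(d), "*")
    B <- sweep(t(Vk), 1L, sqrt(d), "*")
    if (config$nonneg) {
        Z <- pmax(Z, 0)
        for (j in seq_len(k)) # a fully clipped column would be degenerate
            if (max(Z[, j]) == 0)
                Z[, j] <- abs(Uk[, j]) * sqrt(d[j])
    }

    lambda1 <- config$lambda1
    lambda2 <- config$lambda2
    if (is.null(lambda1) || is.null(lambda2)) {
        s0 <- .noiseScale(Ys)
        if (is.null(lambda1)) lambda1 <- s0
        if (is.null(lambda2)) lambda2 <- s0
    }

    S <- ncol(C)
    CtC <- crossprod(C)
    diag(CtC) <- pmax(diag(CtC), 1)
    CtZ <- crossprod(C, Z)
    # unpenalized nonnegative candidate weights used only to calibrate the
    # soft threshold; frac is the retained fraction of their magnitudes
    lambda3 <- config$lambda3
    U0 <- tryCatch(pmax(solve(CtC + diag(1e-8, S), CtZ), 0),
                   error = function(e) pmax(CtZ / diag(CtC), 0))
    if (is.null(lambda3)) {
        cand <- U0[U0 > 0]
        if (length(cand)) {
            tq <- stats::quantile(cand, probs = 1 - config$frac,
                                  names = FALSE)
            lambda3 <- 2 * lambda1 * tq
        } else {
            lambda3 <- 1e-6
        }
    }

    U <- matrix(0, S, k, dimnames = list(colnames(C), NULL))
    CU <- matrix(0, N, k)
    trace <- plierLoss(Ys, Z, B, C, U, lambda1, lambda2, lambda3)
    prev <- trace
    for (it in seq_len(config$maxIter)) {
        B <- .ridgeScores(Z, Ys, lambda2)
        Z <- .updateZ(Z, Ys, B, CU, lambda1, config$nonneg,
                      config$innerSweeps)
        if (lambda1 > 0 && S > 0) {
            CtZ <- crossprod(C, Z)
            U <- .updateU(U, CtC, CtZ, lambda1, lambda3, config$nonneg,
                          config$innerSweeps)
            CU <- C %*% U
        }
        cur <- plierLoss(Ys, Z, B, C, U, lambda1, lambda2, lambda3)
        trace <- c(trace, cur)
        if (abs(prev - cur) <= config$tol * max(prev, 1e-12)) {
            prev <- cur
            break
        }
        prev <- cur
    }
    # final scores refresh so that stored B equals the projection of the
    # training data onto the final loadings
    B <- .ridgeScores(Z, Ys, lambda2)
    trace <- c(trace, plierLoss(Ys, Z, B, C, U, lambda1, lambda2, lambda3))

    lv <- .lvNames(k)
    dimnames(Z) <- list(rownames(Y), lv)
    dimnames(B) <- list(lv, colnames(Y))
    dimnames(U) <- list(colnames(C), lv)
    cfg <- unclass(config)
    cfg$lambda1 <- lambda1; cfg$lambda2 <- lambda2; cfg$lambda3 <- lambda3
    new("PlierModel", Z = Z, B = B, U = U, prior = C, config = cfg,
        geneMeans = stats::setNames(mu, rownames(Y)),
        geneSds = stats::setNames(sds, rownames(Y)),
        lossTrace = trace)
}

#' @describeIn fitPlier fit from an \linkS4class{ExpressionMatrix} (must be
#'   on the \code{log2_tpm_half} scale).
#' @export
setMethod("fitPlier", signature(object = "ExpressionMatrix"),
          function(object, prior, config) {
    if (exprScale(object) != "log2_tpm_half")
        stop("fitPlier expects log2(TPM+0.5)-scale input; see logTransform()")
    .fitPlierMatrix(exprValues(object), prior, config)
})

#' @describeIn fitPlier fit from a plain numeric matrix (rownames must match
#'   the prior's rownames).
#' @export
setMethod("fitPlier", signature(object = "matrix"),
          function(object, prior, config) {
    .fitPlierMatrix(object, prior, config)
})
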