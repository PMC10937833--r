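# shared small planted instance for the fit tests
smallSim <- function(seed = 2) {
    simulateDataset(nGenes = 400, nSamples = 40, nSignatures = 10,
                    signatureSize = 25, nActive = 3, seed = seed)
}

test_that("loss matches an elementwise recomputation and its degenerate limits", {
    set.seed(1)
    Y <- matrix(rnorm(4), 2, 2)
    Z <- matrix(abs(rnorm(4)), 2, 2)
    B <- matrix(rnorm(4), 2, 2)
    C <- matrix(c(1, 0, 1, 1), 2, 2)
    U <- matrix(abs(rnorm(4)), 2, 2)
    l1 <- 0.7; l2 <- 0.3; l3 <- 0.11
    # brute-force elementwise oracle
    R1 <- Y - Z %*% B; R2 <- Z - C %*% U
    expected <- sum(R1 * R1) + l1 * sum(R2 * R2) + l2 * sum(B * B) +
        l3 * sum(abs(U))
    expect_equal(plierLoss(Y, Z, B, C, U, l1, l2, l3), expected,
                 tolerance = 1e-12)

    # all-zero factors leave only the data term
    Z0 <- matrix(0, 2, 2); B0 <- matrix(0, 2, 2); U0 <- matrix(0, 2, 2)
    expect_equal(plierLoss(Y, Z0, B0, C, U0, l1, l2, l3), sum(Y^2))

    # exact factorization with no penalties is zero
    Yx <- Z %*% B; Zx <- C %*% U
    expect_equal(plierLoss(Yx, Zx, B, C, U, 1, 0, 0) -
                     sum((Yx - Zx %*% B)^2), 0, tolerance = 1e-12)
    expect_equal(plierLoss(Z %*% B, Z, B, C, U, 0, 0, 0), 0)

    expect_error(plierLoss(Y, Z, matrix(0, 3, 2), C, U, 1, 1, 1),
                 "dimension")
})

test_that("the outer-iteration loss trace is non-increasing", {
    sim <- smallSim()
    C <- buildPriorMatrix(sim$atlas, rownames(exprValues(sim$expr)))
    for (seed in 1:3) {
        cfg <- plierConfig(k = 5, seed = seed, maxIter = 50)
        m <- fitPlier(sim$expr, C, cfg)
        lt <- lossTrace(m)
        expect_true(all(diff(lt) <= 1e-8 * lt[-length(lt)]))
    }
})

test_that("with the alignment and L1 terms off, the fit attains the truncated-SVD error", {
    set.seed(42)
    N <- 120; M <- 40
    Zt <- matrix(abs(rnorm(N * 3)), N, 3)
    Y <- Zt %*% matrix(rnorm(3 * M), 3, M)
    rownames(Y) <- sprintf("g%03d", 1:N)
    colnames(Y) <- sprintf("s%02d", 1:M)
    C <- matrix(1, N, 1, dimnames = list(rownames(Y), "sig"))
    cfg <- plierConfig(k = 3, lambda1 = 0, lambda2 = 1e-6, lambda3 = 0,
                       seed = 1, standardize = FALSE)
    m <- fitPlier(Y, C, cfg)
    relErr <- norm(Y - plierLoadings(m) %*% plierScores(m), "F") /
        norm(Y, "F")
    # truncated-SVD oracle error is 0 for noiseless rank-3 data
    expect_lt(relErr, 0.01)
})

test_that("an overwhelming L1 penalty empties U and sparsity is monotone in lambda3", {
    sim <- smallSim()
    C <- buildPriorMatrix(sim$atlas, rownames(exprValues(sim$expr)))
    mBig <- fitPlier(sim$expr, C,
                     plierConfig(k = 5, lambda3 = 1e8, seed = 2))
    expect_true(all(signatureWeights(mBig) == 0))

    nnz <- vapply(c(0.5, 5, 50, 500), function(l3) {
        m <- fitPlier(sim$expr, C, plierConfig(k = 5, lambda3 = l3,
                                               seed = 2, maxIter = 60))
        sum(signatureWeights(m) > 0)
    }, 1)
    expect_true(all(diff(nnz) <= 0))
})

test_that("nonnegativity of Z and U holds and the fit is reproducible", {
    sim <- smallSim()
    C <- buildPriorMatrix(sim$atlas, rownames(exprValues(sim$expr)))
    cfg <- plierConfig(k = 5, seed = 9, maxIter = 40)
    m1 <- fitPlier(sim$expr, C, cfg)
    m2 <- fitPlier(sim$expr, C, cfg)
    expect_gte(min(plierLoadings(m1)), 0)
    expect_gte(min(signatureWeights(m1)), 0)
    expect_identical(plierLoadings(m1), plierLoadings(m2))
    expect_identical(plierScores(m1), plierScores(m2))
    expect_identical(lossTrace(m1), lossTrace(m2))
})

test_that("planted signature loadings are recovered on synthetic data", {
    sim <- smallSim(seed = 4)
    C <- buildPriorMatrix(sim$atlas, rownames(exprValues(sim$expr)))
    m <- fitPlier(sim$expr, C, plierConfig(k = 5, seed = 4))
    Z <- plierLoadings(m)
    for (a in seq_len(3)) {
        r <- max(stats::cor(sim$truth$Z[, a], Z))
        expect_gte(r, 0.8)
    }
})

test_that("fit preconditions are enforced", {
    sim <- smallSim()
    C <- buildPriorMatrix(sim$atlas, rownames(exprValues(sim$expr)))
    expect_error(fitPlier(sim$expr, C, plierConfig(k = 500, seed = 1)),
                 "exceeds")
    # gene order mismatch between Y and C
    Crev <- C[rev(seq_len(nrow(C))), ]
    expect_error(fitPlier(sim$expr, Crev, plierConfig(k = 3, seed = 1)),
                 "gene order")
    # TPM-scale input refused
    tpm <- ExpressionMatrix(2^exprValues(sim$expr) - 0.5 + 1, "tpm")
    expect_error(fitPlier(tpm, C, plierConfig(k = 3)), "log2")
})

test_that("model serialization round-trips value-exactly", {
    sim <- smallSim()
    C <- buildPriorMatrix(sim$atlas, rownames(exprValues(sim$expr)))
    m <- fitPlier(sim$expr, C, plierConfig(k = 4, seed = 2, maxIter = 30))
    dir <- tempfile("model")
    writePlierModel(m, dir)
    back <- readPlierModel(dir)
    expect_identical(plierLoadings(back), plierLoadings(m))
    expect_identical(plierScores(back), plierScores(m))
    expect_identical(signatureWeights(back), signatureWeights(m))
    expect_identical(lossTrace(back), lossTrace(m))
    expect_identical(back@geneMeans, m@geneMeans)
    # projection through the reloaded model matches the original
    expect_equal(plierTransform(back, sim$expr),
                 plierTransform(m, sim$expr), tolerance = 1e-12)
})
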