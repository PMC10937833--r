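assocFixture <- function() {
    data.frame(
        lv = c("LV1", "LV2", "LV3", "LV4", "LV5", "LV6", "LV7", "LV7"),
        signature = paste0("s", 1:8),
        u_weight = c(1, 1, 2, 1, 1, 1, 1, 1),
        auc = c(0.95, 0.92, 0.92, 0.9, 0.85, 0.8, 0.99, 0.6),
        fdr = c(0.01, 0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01),
        cell_type = c(rep("PT", 6), "End", "End"))
}

test_that("cell-type LV sets are ranked by passing AUC and truncated at four", {
    assoc <- assocFixture()
    pt <- extractCellTypeLVs(assoc, "PT")
    expect_identical(pt$lvs, c("LV1", "LV3", "LV2", "LV4"))
    expect_length(pt$lvs, 4L)
    # AUC tie between LV2 and LV3 broken by lower FDR
    expect_identical(pt$lvs[2], "LV3")

    # fewer candidates than maxN: all returned (endothelial case)
    en <- extractCellTypeLVs(assoc, "End")
    expect_identical(en$lvs, "LV7")
    expect_error(extractCellTypeLVs(assoc, "My"), "no interpretable")
})

test_that("repeated stratified CV separates planted clusters and stays null on permuted labels", {
    set.seed(50)
    n <- 100; d <- 4
    y <- rep(c(0, 1), each = n / 2)
    X <- matrix(rnorm(n * d), n, d) + 6 * y  # clusters 6 sd apart
    cv <- repeatedCVAuroc(X, y, folds = 10, repeats = 5, seed = 50)
    expect_gte(cv$meanAUROC, 0.95)
    expect_length(cv$perRepetitionAUROC, 5L)
    expect_gte(cv$sdAUROC, 0)

    set.seed(51)
    yPerm <- sample(y)
    # 5 repetitions keep this quick; the null band is wider than the
    # asymptotic one accordingly
    cvNull <- repeatedCVAuroc(X, yPerm, folds = 10, repeats = 5, seed = 51)
    expect_gte(cvNull$meanAUROC, 0.30)
    expect_lte(cvNull$meanAUROC, 0.70)
})

test_that("CV scoring is exact for a deterministic ranker and reproducible", {
    set.seed(52)
    n <- 40
    y <- rep(c(0, 1), each = n / 2)
    X <- cbind(score = ifelse(y == 1, 1, 0) + runif(n, 0, 0.1))
    rankSpec <- list(fit = function(X, y) NULL,
                     predict = function(fit, X) X[, "score"])
    cv <- repeatedCVAuroc(X, y, folds = 5, repeats = 3,
                          modelSpec = rankSpec, seed = 1)
    # all positives outrank all negatives -> AUROC 1 in every repetition
    expect_equal(cv$perRepetitionAUROC, rep(1, 3))

    # AUROC invariant to monotone transform of the scores
    expSpec <- list(fit = function(X, y) NULL,
                    predict = function(fit, X) exp(5 * X[, "score"]))
    cvT <- repeatedCVAuroc(X, y, folds = 5, repeats = 3,
                           modelSpec = expSpec, seed = 1)
    expect_equal(cvT$perRepetitionAUROC, cv$perRepetitionAUROC)

    # bit-reproducible under a fixed seed (random forest path)
    cvA <- repeatedCVAuroc(X, y, folds = 5, repeats = 2, seed = 7)
    cvB <- repeatedCVAuroc(X, y, folds = 5, repeats = 2, seed = 7)
    expect_identical(cvA$perRepetitionAUROC, cvB$perRepetitionAUROC)
    expect_identical(cvA$predictions, cvB$predictions)

    expect_error(repeatedCVAuroc(X, rep(0, n), seed = 1), "two classes")
    expect_error(repeatedCVAuroc(X[1:12, , drop = FALSE], y[c(1:10, 21:22)],
                                 folds = 10, seed = 1), "fold")
})

test_that("logistic model spec works as the secondary classifier", {
    set.seed(53)
    n <- 60
    y <- rep(c(0, 1), each = n / 2)
    X <- matrix(rnorm(n * 2), n, 2) + 4 * y
    cv <- repeatedCVAuroc(X, y, folds = 5, repeats = 2,
                          modelSpec = "logistic", seed = 2)
    expect_gte(cv$meanAUROC, 0.95)
})

test_that("exact Shapley values satisfy efficiency, dummy, symmetry and the additive closed form", {
    set.seed(60)
    for (d in 1:4) {
        X <- matrix(rnorm(6 * d), 6, d)
        bg <- matrix(rnorm(20 * d), 20, d)
        w <- rnorm(d)
        f <- function(m) as.numeric(m %*% w) + 3
        sh <- shapleyAttribution(f, X, bg)
        # efficiency: baseline + sum of attributions = prediction
        expect_equal(sh$baseline + rowSums(sh$values), f(X),
                     tolerance = 1e-8)
        # additive closed form: phi_j = w_j (x_j - mean(bg_j))
        closed <- sweep(sweep(X, 2, colMeans(bg)), 2, w, "*")
        expect_equal(sh$values, closed, tolerance = 1e-8,
                     ignore_attr = TRUE)
    }

    # single-feature model: attribution is prediction minus baseline
    X1 <- matrix(rnorm(5), 5, 1); bg1 <- matrix(rnorm(9), 9, 1)
    f1 <- function(m) sin(m[, 1])
    sh1 <- shapleyAttribution(f1, X1, bg1)
    expect_equal(sh1$values[, 1], f1(X1) - sh1$baseline, tolerance = 1e-10)

    # dummy: an ignored feature gets zero attribution
    X2 <- matrix(rnorm(12), 6, 2); bg2 <- matrix(rnorm(12), 6, 2)
    f2 <- function(m) m[, 1]^2
    sh2 <- shapleyAttribution(f2, X2, bg2)
    expect_equal(unname(sh2$values[, 2]), rep(0, 6), tolerance = 1e-10)

    # symmetry: duplicated features in a symmetric model share attribution
    X3 <- cbind(a = rnorm(6)); X3 <- cbind(X3, b = X3[, 1])
    bg3 <- cbind(a = rnorm(8)); bg3 <- cbind(bg3, b = bg3[, 1])
    f3 <- function(m) m[, 1] + m[, 2]
    sh3 <- shapleyAttribution(f3, X3, bg3)
    expect_equal(sh3$values[, 1], sh3$values[, 2], tolerance = 1e-10)

    expect_error(shapleyAttribution(f3, matrix(0, 2, 13), matrix(0, 2, 13)),
                 "12")
})

test_that("feature importance ranks by mean absolute attribution", {
    set.seed(61)
    X <- matrix(rnorm(40), 10, 4)
    bg <- matrix(rnorm(40), 10, 4)
    f <- function(m) 5 * m[, 3] + 0.5 * m[, 1]
    sh <- shapleyAttribution(f, X, bg)
    expect_identical(which.max(sh$featureImportance), 3L)
    expect_equal(sh$featureImportance, colMeans(abs(sh$values)))
})
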