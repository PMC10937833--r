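test_that("hold-out AUC equals brute-force pair counting across sizes and tie patterns", {
    expect_equal(holdoutAUC(c(0.9, 0.8), c(0.1, 0.2, 0.3)), 1)
    set.seed(20)
    for (n1 in 1:6) for (n2 in 1:6) {
        for (rep in 1:10) {
            # small integer alphabet forces frequent ties
            x <- sample(1:3, n1, replace = TRUE)
            y <- sample(1:3, n2, replace = TRUE)
            expect_equal(holdoutAUC(x, y), oracleAUC(x, y),
                         tolerance = 1e-12)
            # continuous, tie-free
            xc <- rnorm(n1); yc <- rnorm(n2)
            expect_equal(holdoutAUC(xc, yc), oracleAUC(xc, yc),
                         tolerance = 1e-12)
            # complement property for tie-free inputs
            expect_equal(holdoutAUC(xc, yc) + holdoutAUC(yc, xc), 1,
                         tolerance = 1e-12)
        }
    }
})

test_that("rank AUC agrees with an independent ROC implementation", {
    set.seed(77)
    for (rep in 1:10) {
        pos <- rnorm(15, mean = runif(1, 0, 2))
        neg <- rnorm(25)
        ref <- as.numeric(pROC::auc(
            response = c(rep(1, 15), rep(0, 25)),
            predictor = c(pos, neg), quiet = TRUE,
            direction = "<"))
        expect_equal(holdoutAUC(pos, neg), ref, tolerance = 1e-12)
    }
})

test_that("hold-out AUC is centred at 1/2 under the null", {
    set.seed(7)
    aucs <- replicate(200, holdoutAUC(rnorm(10), rnorm(50)))
    expect_gte(mean(aucs), 0.45)
    expect_lte(mean(aucs), 0.55)
})

test_that("interpretability selection applies both strict thresholds", {
    tab <- data.frame(
        lv = c("LV1", "LV2", "LV3", "LV4"),
        signature = paste0("s", 1:4),
        u_weight = 1,
        auc = c(0.9, 0.70, 0.9, 0.71),
        fdr = c(0.01, 0.01, 0.05, 0.049))
    sel <- selectInterpretable(tab)
    expect_identical(sel, c("LV1", "LV4"))  # 0.70 and 0.05 boundaries excluded
})

test_that("LV labeling follows the max-AUC record with FDR/u-weight tie-breaks", {
    tab <- data.frame(
        lv = c("LV1", "LV1", "LV2", "LV2", "LV3", "LV4"),
        signature = paste0("s", 1:6),
        u_weight = c(1, 1, 0.5, 2, 1, 1),
        auc = c(0.95, 0.80, 0.9, 0.9, 0.75, 0.6),
        fdr = c(0.01, 0.001, 0.02, 0.01, 0.01, 0.01),
        cell_type = c("proximal tubule", "tumor", "fibroblast",
                      "endothelium", "Non associated", "lymphoid"))
    lab <- labelLVs(tab, categories = c("proximal tubule" = "PT",
                                        "fibroblast" = "ST",
                                        "endothelium" = "End"))
    expect_identical(unname(lab["LV1"]), "PT")   # max AUC wins over tumor
    expect_identical(unname(lab["LV2"]), "End")  # AUC tie -> lower FDR
    expect_identical(unname(lab["LV3"]), "Rest") # Non associated -> Rest
    expect_false("LV4" %in% names(lab))          # no passing record
})

test_that("the scan recovers planted pairs, skips tiny signatures, and is seeded", {
    sim <- simulateDataset(nGenes = 400, nSamples = 40, nSignatures = 10,
                           signatureSize = 25, nActive = 3, seed = 12)
    C <- buildPriorMatrix(sim$atlas, rownames(exprValues(sim$expr)))
    cfg <- plierConfig(k = 5, seed = 12)
    scan <- associationScan(sim$expr, C, cfg, atlas = sim$atlas)
    rec <- associationRecords(scan)
    expect_true(all(rec$u_weight > 0))
    expect_true(all(rec$fdr >= rec$p_value))
    active <- sim$truth$activeSignatures$signature
    for (s in active) {
        rs <- rec[rec$signature == s, ]
        expect_gt(nrow(rs), 0)
        expect_gte(max(rs$auc), 0.9)
        expect_lt(rs$fdr[which.max(rs$auc)], 0.05)
    }
    # cell types joined from the atlas
    expect_true(all(rec$cell_type[rec$signature == active[1]] == "PT"))
    # determinism
    scan2 <- associationScan(sim$expr, C, cfg, atlas = sim$atlas)
    expect_identical(rec, associationRecords(scan2))

    # a 3-gene signature cannot be scanned and is skipped with a warning
    Cplus <- cbind(C, tiny = 0)
    Cplus[1:3, "tiny"] <- 1
    expect_warning(associationScan(sim$expr, Cplus, cfg), "skipped")
})

test_that("BH ordering of scan FDRs is a monotone transform of the p-values", {
    sim <- simulateDataset(nGenes = 300, nSamples = 30, nSignatures = 8,
                           signatureSize = 20, nActive = 2, seed = 3)
    C <- buildPriorMatrix(sim$atlas, rownames(exprValues(sim$expr)))
    rec <- associationRecords(
        associationScan(sim$expr, C, plierConfig(k = 4, seed = 3)))
    o <- order(rec$p_value)
    expect_true(all(diff(rec$fdr[o]) >= -1e-12))
})
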