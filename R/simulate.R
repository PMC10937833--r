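#' @include AllClasses.R
NULL

#' Simulate an expression dataset with planted signature-aligned structure
#'
#' Generates a log-scale expression matrix with planted low-rank structure
#' whose loading columns are supported on known gene signatures, plus
#' group-dependent LV shifts, so that every pipeline stage (filtering,
#' fitting, association scanning, differential testing, classification) can
#' be exercised against ground truth.
#'
#' Signatures are random gene sets; the first \code{nActive} are "active":
#' each contributes a loading column with value 1 on its genes plus small
#' positive noise (|N(0, 0.05)|) on a random 2\% of non-member genes. Sample
#' scores are standard normal; the first two active LVs are differential,
#' shifted by \code{groupEffect} in group 1. The data matrix is
#' \code{Z B + N(0, noiseSd)} on the log scale, then shifted so its minimum
#' is -1 (the log2(TPM+0.5) floor). Group labels are balanced. Remaining
#' signatures are decoys for association calibration.
#'
#' @param nGenes,nSamples,nSignatures,signatureSize,nActive dataset shape
#'   (defaults 2000, 80, 30, 50, 5).
#' @param noiseSd standard deviation of the additive log-scale noise
#'   (default 0.5).
#' @param groupEffect shift applied to the differential LVs' scores in group
#'   1 (default 1.0); 0 disables any group signal.
#' @param nDifferential number of active LVs carrying the group shift
#'   (default 2, capped at nActive).
#' @param seed integer seed; outputs are reproducible from it.
#' @return list with elements \code{expr} (an
#'   \linkS4class{ExpressionMatrix}, scale \code{log2_tpm_half}),
#'   \code{atlas} (a \linkS4class{SignatureAtlas}; active signatures carry
#'   cycling cell-type labels, decoys are "Non associated"), \code{labels}
#'   (integer 0/1 per sample) and \code{truth} (list: \code{Z}, \code{B},
#'   \code{activeSignatures} data.frame (signature, lv),
#'   \code{differentialLVs} data.frame (lv, effect), \code{noiseSd},
#'   \code{seed}).
#' @export
simulateDataset <- function(nGenes = 2000L, nSamples = 80L,
                            nSignatures = 30L, signatureSize = 50L,
                            nActive = 5L, noiseSd = 0.5,
                            groupEffect = 1.0, nDifferential = 2L,
                            seed = 1L) {
    stopifnot(nActive <= nSignatures, signatureSize <= nGenes,
              nSamples >= 2L, noiseSd >= 0)
    nDifferential <- min(nDifferential, nActive)
    set.seed(seed)
    genes <- sprintf("g%05d", seq_len(nGenes))
    samples <- sprintf("s%03d", seq_len(nSamples))
    sigNames <- sprintf("sig%02d", seq_len(nSignatures))
    sets <- lapply(seq_len(nSignatures), function(s)
        sort(sample(genes, signatureSize)))
    names(sets) <- sigNames

    cellTypes <- c("PT", "ST", "End", "Ly", "My")
    meta <- data.frame(
        name = sigNames, author = "synthetic", species = "synthetic",
        clinical_condition = "none",
        cell_type = c(rep(cellTypes, length.out = nActive),
                      rep("Non associated", nSignatures - nActive)),
        stringsAsFactors = FALSE)
    atlas <- SignatureAtlas(sets, meta)

    lvNames <- sprintf("trueLV%d", seq_len(nActive))
    Z <- matrix(0, nGenes, nActive, dimnames = list(genes, lvNames))
    for (a in seq_len(nActive)) {
        Z[sets[[a]], a] <- 1
        off <- setdiff(genes, sets[[a]])
        touched <- sample(off, max(1L, round(0.02 * length(off))))
        Z[touched, a] <- abs(stats::rnorm(length(touched), sd = 0.05))
    }

    labels <- rep(c(0L, 1L), length.out = nSamples)
    B <- matrix(stats::rnorm(nActive * nSamples), nActive, nSamples,
                dimnames = list(lvNames, samples))
    diffIdx <- seq_len(nDifferential)
    for (a in diffIdx)
        B[a, labels == 1L] <- B[a, labels == 1L] + groupEffect

    Y <- Z %*% B
    if (noiseSd > 0)
        Y <- Y + matrix(stats::rnorm(nGenes * nSamples, sd = noiseSd),
                        nGenes, nSamples)
    Y <- Y - min(Y) - 1  # log2(TPM+0.5) floor
    dimnames(Y) <- list(genes, samples)

    truth <- list(
        Z = Z, B = B,
        activeSignatures = data.frame(signature = sigNames[seq_len(nActive)],
                                      lv = lvNames,
                                      stringsAsFactors = FALSE),
        differentialLVs = data.frame(lv = lvNames[diffIdx],
                                     effect = groupEffect,
                                     stringsAsFactors = FALSE),
        noiseSd = noiseSd, seed = seed)
    list(expr = ExpressionMatrix(Y, "log2_tpm_half"),
         atlas = atlas,
         labels = stats::setNames(labels, samples),
         truth = truth)
}
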