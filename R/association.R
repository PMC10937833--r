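#' @include plier-fit.R lv-stats.R
NULL

#' Hold-out AUC
#'
#' Probability that a value drawn from \code{x} exceeds a value drawn from
#' \code{y}, ties counted 1/2 (the rank-sum AUC). In the association scan,
#' \code{x} are the loadings of a signature's held-out genes and \code{y}
#' the loadings of all genes outside the signature.
#'
#' @param x,y numeric samples (non-empty).
#' @return the AUC in [0, 1].
#' @examples
#' holdoutAUC(c(0.9, 0.8), c(0.1, 0.2, 0.3))  # 1: complete separation
#' @export
holdoutAUC <- function(x, y) {
    if (length(x) < 1L || length(y) < 1L)
        stop("both samples must be non-empty")
    .rankAUC(x, y)
}

#' Gene hold-out association scan
#'
#' Scores the association between each latent variable and each prior
#' signature by gene hold-out: a random fifth (by default) of each
#' signature's genes is zeroed in the prior matrix, the decomposition is
#' re-fit with the training hyperparameters, and for every (LV, signature)
#' pair with positive weight in the re-fit the held-out genes' loadings are
#' compared with the loadings of all genes outside the signature. The AUC is
#' the probability that a held-out gene outranks a non-member gene (ties
#' counted 1/2); the p-value is a one-sided Mann-Whitney test of the same
#' comparison, and FDRs are Benjamini-Hochberg across all scored pairs.
#'
#' @param expr \linkS4class{ExpressionMatrix} (\code{log2_tpm_half} scale)
#'   or plain matrix; the training data.
#' @param prior binary genes x signatures matrix (see
#'   \code{\link{buildPriorMatrix}}); rownames must match \code{expr}.
#' @param config the training \code{\link{plierConfig}}, or a fitted
#'   \linkS4class{PlierModel} whose resolved configuration is reused; the
#'   re-fit keeps the training k, lambdas and seed, differing only in the
#'   masked prior.
#' @param holdoutFrac fraction of each signature's genes to hold out
#'   (default 0.2); the hold-out count is \code{ceiling(holdoutFrac * n)}.
#' @param seed seed for the hold-out draw (default: the config seed).
#' @param replicates number of independent hold-out draws; when > 1 the AUCs
#'   are averaged and the median p-value retained per pair.
#' @param atlas optional \linkS4class{SignatureAtlas} supplying cell-type
#'   labels for the records.
#' @return an \linkS4class{AssociationTable}. Signatures with fewer than 5
#'   genes in the universe are skipped with a warning.
#' @export
associationScan <- function(expr, prior, config, holdoutFrac = 0.2,
                            seed = NULL, replicates = 1L, atlas = NULL) {
    Y <- if (is(expr, "ExpressionMatrix")) {
        if (exprScale(expr) != "log2_tpm_half")
            stop("associationScan expects log2(TPM+0.5)-scale input")
        exprValues(expr)
    } else as.matrix(expr)
    config <- .asPlierConfig(config)
    if (is.null(seed))
        seed <- config$seed
    sigNames <- colnames(prior)
    sizes <- colSums(prior != 0)
    small <- sizes < 5
    if (any(small))
        warning("signature(s) with < 5 genes in the universe skipped: ",
                paste(sigNames[small], collapse = ", "))
    if (all(small))
        stop("no signature large enough for a hold-out scan")

    reps <- vector("list", replicates)
    for (r in seq_len(replicates)) {
        set.seed(seed + r - 1L)
        held <- lapply(seq_along(sigNames), function(s) {
            if (small[s]) return(integer(0))
            mem <- which(prior[, s] != 0)
            sample(mem, ceiling(holdoutFrac * length(mem)))
        })
        Cmask <- prior
        for (s in seq_along(sigNames))
            if (length(held[[s]]))
                Cmask[held[[s]], s] <- 0
        refit <- .fitPlierMatrix(Y, Cmask, config)
        Z <- refit@Z
        U <- refit@U
        rows <- list()
        for (s in which(!small)) {
            nonMember <- which(prior[, s] == 0)
            hs <- held[[s]]
            for (k in which(U[s, ] > 0)) {
                x <- Z[hs, k]
                y <- Z[nonMember, k]
                mw <- mannWhitney(x, y, "greater")
                rows[[length(rows) + 1L]] <- data.frame(
                    lv = colnames(Z)[k], signature = sigNames[s],
                    u_weight = U[s, k], auc = .rankAUC(x, y),
                    p_value = mw$p, stringsAsFactors = FALSE)
            }
        }
        reps[[r]] <- do.call(rbind, rows)
    }
    rec <- do.call(rbind, reps)
    if (is.null(rec) || nrow(rec) == 0L)
        stop("no (LV, signature) pair received positive weight in the re-fit")
    if (replicates > 1L) {
        key <- paste(rec$lv, rec$signature, sep = "\r")
        agg <- lapply(split(rec, key), function(d) {
            data.frame(lv = d$lv[1L], signature = d$signature[1L],
                       u_weight = mean(d$u_weight), auc = mean(d$auc),
                       p_value = stats::median(d$p_value),
                       stringsAsFactors = FALSE)
        })
        rec <- do.call(rbind, agg)
        rownames(rec) <- NULL
    }
    rec$fdr <- bhAdjust(rec$p_value)
    ct <- rep("Non associated", nrow(rec))
    if (!is.null(atlas)) {
        meta <- signatureMeta(atlas)
        hit <- rec$signature %in% rownames(meta)
        ct[hit] <- meta[rec$signature[hit], "cell_type"]
        ct[is.na(ct)] <- "Non associated"
    }
    rec$cell_type <- ct
    rec$interpretable <- rec$auc > 0.7 & rec$fdr < 0.05
    rec <- rec[order(rec$lv, -rec$auc, rec$fdr), ]
    rownames(rec) <- NULL
    new("AssociationTable", records = rec,
        interpretableLVs = sort(unique(rec$lv[rec$interpretable])))
}

.recordsOf <- function(table) {
    if (is(table, "AssociationTable")) table@records
    else as.data.frame(table)
}

#' Select interpretable latent variables
#'
#' An LV is interpretable when at least one of its association records
#' satisfies AUC > 0.7 and FDR < 0.05 (both strict inequalities).
#'
#' @param table an \linkS4class{AssociationTable} or a data.frame with
#'   columns lv, auc, fdr.
#' @return character vector of interpretable LV identifiers (sorted).
#' @export
selectInterpretable <- function(table) {
    rec <- .recordsOf(table)
    pass <- rec$auc > 0.7 & rec$fdr < 0.05
    sort(unique(as.character(rec$lv[pass])))
}

# deterministic ordering of passing records: best AUC first, ties broken by
# lower FDR then higher u_weight
.orderPassing <- function(rec) {
    rec[order(-rec$auc, rec$fdr, -rec$u_weight), , drop = FALSE]
}

#' Label interpretable LVs with cell-type categories
#'
#' Each interpretable LV is labeled with the cell-type category of its
#' passing signatures; when the passing signatures span several cell types
#' the category of the record with the highest AUC wins (ties broken by
#' lower FDR, then higher u_weight). Signatures classified as
#' \code{"Non associated"} map to the category \code{"Rest"}.
#'
#' @param table an \linkS4class{AssociationTable} (or records data.frame
#'   with a cell_type column).
#' @param categories optional named character vector mapping raw cell-type
#'   strings to display categories (e.g. \code{c(fibroblast = "ST")});
#'   unmapped strings are kept as-is.
#' @return named character vector, LV identifier -> category. LVs with no
#'   passing record are absent.
#' @export
labelLVs <- function(table, categories = NULL) {
    rec <- .recordsOf(table)
    pass <- rec[rec$auc > 0.7 & rec$fdr < 0.05, , drop = FALSE]
    if (nrow(pass) == 0L)
        return(stats::setNames(character(0), character(0)))
    pass <- .orderPassing(pass)
    best <- pass[!duplicated(pass$lv), , drop = FALSE]
    lab <- best$cell_type
    if (!is.null(categories)) {
        mapped <- categories[lab]
        lab <- ifelse(is.na(mapped), lab, mapped)
    }
    lab[lab == "Non associated"] <- "Rest"
    stats::setNames(lab, best$lv)
}
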