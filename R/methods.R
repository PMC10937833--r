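#' @include AllGenerics.R
NULL

#' @describeIn ExpressionMatrix expression values
#' @param x,object an \linkS4class{ExpressionMatrix}.
#' @export
setMethod("exprValues", "ExpressionMatrix",
          function(x) SummarizedExperiment::assay(x, "expr"))

#' @describeIn ExpressionMatrix scale flag
#' @export
setMethod("exprScale", "ExpressionMatrix", function(x) x@scale)

#' @describeIn ExpressionMatrix compact display
#' @export
setMethod("show", "ExpressionMatrix", function(object) {
    cat("ExpressionMatrix:", nrow(object), "genes x", ncol(object),
        "samples, scale =", object@scale, "\n")
})

#' @describeIn SignatureAtlas gene sets
#' @param x,object a \linkS4class{SignatureAtlas}.
#' @export
setMethod("geneSets", "SignatureAtlas", function(x) x@geneSets)

#' @describeIn SignatureAtlas metadata table
#' @export
setMethod("signatureMeta", "SignatureAtlas", function(x) x@meta)

#' @describeIn SignatureAtlas number of signatures
#' @export
setMethod("length", "SignatureAtlas", function(x) length(x@geneSets))

#' @describeIn SignatureAtlas signature names
#' @export
setMethod("names", "SignatureAtlas", function(x) names(x@geneSets))

#' @describeIn SignatureAtlas compact display
#' @export
setMethod("show", "SignatureAtlas", function(object) {
    sizes <- vapply(object@geneSets, length, 1L)
    cat("SignatureAtlas:", length(object@geneSets), "signatures,",
        "gene-set sizes", min(sizes), "-", max(sizes), "\n")
    ct <- table(object@meta$cell_type)
    cat("  cell types:", paste(names(ct), ct, sep = ":", collapse = ", "),
        "\n")
})

#' @describeIn PlierModel loadings (genes x LVs)
#' @param object a \linkS4class{PlierModel}.
#' @export
setMethod("plierLoadings", "PlierModel", function(object) object@Z)

#' @describeIn PlierModel scores (LVs x samples)
#' @export
setMethod("plierScores", "PlierModel", function(object) object@B)

#' @describeIn PlierModel signature weights (signatures x LVs)
#' @export
setMethod("signatureWeights", "PlierModel", function(object) object@U)

#' @describeIn PlierModel outer-iteration loss values
#' @export
setMethod("lossTrace", "PlierModel", function(object) object@lossTrace)

#' @describeIn PlierModel resolved configuration list
#' @export
setMethod("modelConfig", "PlierModel", function(object) object@config)

#' @describeIn PlierModel compact display
#' @export
setMethod("show", "PlierModel", function(object) {
    cfg <- object@config
    cat("PlierModel:", nrow(object@Z), "genes,", ncol(object@Z), "LVs,",
        nrow(object@U), "signatures\n")
    cat(sprintf("  lambda1=%.4g lambda2=%.4g lambda3=%.4g frac=%.2f\n",
                cfg$lambda1, cfg$lambda2, cfg$lambda3, cfg$frac))
    cat(sprintf("  %d outer iterations, final loss %.6g, %d nonzero U\n",
                length(object@lossTrace),
                utils::tail(object@lossTrace, 1L),
                sum(object@U > 0)))
})

#' @describeIn AssociationTable association records
#' @param x,object an \linkS4class{AssociationTable}.
#' @export
setMethod("associationRecords", "AssociationTable", function(x) x@records)

#' @describeIn AssociationTable interpretable LV identifiers
#' @export
setMethod("interpretableLVs", "AssociationTable",
          function(x) x@interpretableLVs)

#' @describeIn AssociationTable compact display
#' @export
setMethod("show", "AssociationTable", function(object) {
    cat("AssociationTable:", nrow(object@records), "records,",
        length(object@interpretableLVs), "interpretable LVs\n")
})
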