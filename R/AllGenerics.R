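#' @include AllClasses.R
NULL

#' Extract the expression values of an ExpressionMatrix
#' @param x an \linkS4class{ExpressionMatrix}.
#' @return the genes x samples numeric matrix.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' Scale flag of an ExpressionMatrix
#' @param x an \linkS4class{ExpressionMatrix}.
#' @return \code{"tpm"} or \code{"log2_tpm_half"}.
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' Gene sets of a SignatureAtlas
#' @param x a \linkS4class{SignatureAtlas}.
#' @return named list of character vectors.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' Signature metadata of a SignatureAtlas
#' @param x a \linkS4class{SignatureAtlas}.
#' @return data.frame with columns author, species, clinical_condition,
#'   cell_type, one row per signature.
#' @export
setGeneric("signatureMeta", function(x) standardGeneric("signatureMeta"))

#' Loadings matrix (genes x LVs) of a fitted model
#' @param object a \linkS4class{PlierModel}.
#' @export
setGeneric("plierLoadings", function(object) standardGeneric("plierLoadings"))

#' Score matrix (LVs x samples) of a fitted model
#' @param object a \linkS4class{PlierModel}.
#' @export
setGeneric("plierScores", function(object) standardGeneric("plierScores"))

#' Signature weights (signatures x LVs) of a fitted model
#' @param object a \linkS4class{PlierModel}.
#' @export
setGeneric("signatureWeights",
           function(object) standardGeneric("signatureWeights"))

#' Outer-iteration loss trace of a fit
#' @param object a \linkS4class{PlierModel}.
#' @export
setGeneric("lossTrace", function(object) standardGeneric("lossTrace"))

#' Resolved configuration of a fitted model
#' @param object a \linkS4class{PlierModel}.
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))

#' Fit the prior-guided decomposition
#' @param object expression data (an \linkS4class{ExpressionMatrix} on the
#'   \code{log2_tpm_half} scale, or a plain numeric matrix).
#' @param prior binary genes x signatures prior matrix (see
#'   \code{\link{buildPriorMatrix}}).
#' @param config configuration list from \code{\link{plierConfig}}.
#' @export
setGeneric("fitPlier",
           function(object, prior, config) standardGeneric("fitPlier"))

#' Project expression data onto frozen loadings
#' @param model a fitted \linkS4class{PlierModel}.
#' @param newdata expression data preprocessed like the training data
#'   (\linkS4class{ExpressionMatrix} on the \code{log2_tpm_half} scale, or a
#'   plain matrix with gene rownames).
#' @export
setGeneric("plierTransform",
           function(model, newdata) standardGeneric("plierTransform"))

#' Association records
#' @param x an \linkS4class{AssociationTable}.
#' @return data.frame of per-(LV, signature) records.
#' @export
setGeneric("associationRecords",
           function(x) standardGeneric("associationRecords"))

#' Interpretable LVs of an association table
#' @param x an \linkS4class{AssociationTable}.
#' @return character vector of LV identifiers.
#' @export
setGeneric("interpretableLVs",
           function(x) standardGeneric("interpretableLVs"))
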