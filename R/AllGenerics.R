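#' @include AllClasses.R
NULL

#' @rdname RecurrenceCohort-class
#' @param object,x a \code{RecurrenceCohort}.
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))

#' @rdname RecurrenceCohort-class
#' @export
setGeneric("dfsMonths", function(x) standardGeneric("dfsMonths"))

#' @rdname RecurrenceCohort-class
#' @export
setGeneric("eventFlag", function(x) standardGeneric("eventFlag"))

#' @rdname RecurrenceCohort-class
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname GeneSignature-class
#' @param x a \code{GeneSignature} or \code{NearestMeanModel}.
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))

#' @rdname DiscoveryResult-class
#' @param x a \code{DiscoveryResult}.
#' @export
setGeneric("averagedRanking", function(x) standardGeneric("averagedRanking"))

#' @rdname DiscoveryResult-class
#' @export
setGeneric("pooledScores", function(x) standardGeneric("pooledScores"))

#' @rdname DiscoveryResult-class
#' @export
setGeneric("combinedAUCResult", function(x) standardGeneric("combinedAUCResult"))

## ---- accessors -------------------------------------------------------------

#' @rdname RecurrenceCohort-class
#' @export
setMethod("clinicalData", "RecurrenceCohort", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname RecurrenceCohort-class
#' @export
setMethod("dfsMonths", "RecurrenceCohort", function(x)
  SummarizedExperiment::colData(x)$dfs_months)

#' @rdname RecurrenceCohort-class
#' @export
setMethod("eventFlag", "RecurrenceCohort", function(x)
  SummarizedExperiment::colData(x)$event)

#' @rdname RecurrenceCohort-class
#' @export
setMethod("exprMatrix", "RecurrenceCohort", function(x)
  SummarizedExperiment::assay(x, "lratio"))

#' @rdname GeneSignature-class
#' @export
setMethod("signatureGenes", "GeneSignature", function(x) x@genes)

#' @rdname NearestMeanModel-class
#' @export
setMethod("signatureGenes", "NearestMeanModel", function(x) x@genes)

#' @rdname DiscoveryResult-class
#' @export
setMethod("averagedRanking", "DiscoveryResult", function(x) x@ranking)

#' @rdname DiscoveryResult-class
#' @export
setMethod("pooledScores", "DiscoveryResult", function(x) x@pooled)

#' @rdname DiscoveryResult-class
#' @export
setMethod("combinedAUCResult", "DiscoveryResult", function(x) x@auc)

## ---- show methods ----------------------------------------------------------

setMethod("show", "RiskRule", function(object) {
  cat(sprintf(
    "RiskRule: high risk = event at <= %g months; low risk = DFS > %g months\n",
    object@highMaxMonths, object@lowMinMonths))
})

setMethod("show", "NearestMeanModel", function(object) {
  cat(sprintf("NearestMeanModel: %d gene(s), trained on %d sample(s)\n",
              length(object@genes), length(object@trainingIds)))
})

setMethod("show", "DiscoveryResult", function(object) {
  cat(sprintf(
    "DiscoveryResult: %d iterations x %.0f%% draws, top-%d genes\n",
    object@config$iterations, 100 * object@config$fraction,
    object@config$top_k))
  cat(sprintf("  pooled out-of-fold scores: %d; combined AUC %.3f (95%% CI %.3f-%.3f)\n",
              nrow(object@pooled), object@auc$auc,
              object@auc$ci[1], object@auc$ci[2]))
})

setMethod("show", "GeneSignature", function(object) {
  cat(sprintf("GeneSignature of size %d (LOOCV accuracy %.3f)\n",
              object@size,
              object@accuracyCurve$accuracy[object@accuracyCurve$size ==
                                              object@size]))
  cat("  genes:", paste(head(object@genes, 10), collapse = ", "),
      if (object@size > 10) "..." else "", "\n")
})

setMethod("show", "ScoreRubric", function(object) {
  cat(sprintf("ScoreRubric '%s': %d criteria, high risk >= %g points\n",
              object@name, nrow(object@criteria), object@threshold))
})

setMethod("show", "TwoChannelArray", function(object) {
  cat(sprintf("TwoChannelArray %s (sample %s, %s): %d spots, %d tip groups\n",
              object@arrayId, object@sampleId, object@dyeOrientation,
              nrow(object@spots), length(unique(object@spots$printtip_group))))
})

setMethod("show", "NormalizedProfile", function(object) {
  cat(sprintf("NormalizedProfile %s (%s): %d genes\n", object@sampleId,
              object@dyeOrientation, nrow(object@values)))
})
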