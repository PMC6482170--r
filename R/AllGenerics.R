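#' @describeIn BipartiteNetwork-class ordered protein identifiers
#' @param x,object a `BipartiteNetwork` (or `EvalReport` where noted)
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @describeIn BipartiteNetwork-class ordered lncRNA identifiers
#' @export
setGeneric("lncrnaIds", function(x) standardGeneric("lncrnaIds"))

#' @describeIn BipartiteNetwork-class the binary interaction matrix
#' @export
setGeneric("interactionMatrix",
  function(x) standardGeneric("interactionMatrix"))

#' @describeIn BipartiteNetwork-class number of proteins (rows)
#' @export
setGeneric("nProteins", function(x) standardGeneric("nProteins"))

#' @describeIn BipartiteNetwork-class number of lncRNAs (columns)
#' @export
setGeneric("nLncrnas", function(x) standardGeneric("nLncrnas"))

#' @describeIn EvalReport-class area under the ROC curve
#' @param x an `EvalReport`
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @describeIn EvalReport-class area under the precision-recall curve
#' @export
setGeneric("aupr", function(x) standardGeneric("aupr"))

#' @describeIn EvalReport-class named scalar metric vector
#' @export
setGeneric("scalarMetrics", function(x) standardGeneric("scalarMetrics"))

setMethod("proteinIds", "BipartiteNetwork", function(x) x@proteinIds)
setMethod("lncrnaIds", "BipartiteNetwork", function(x) x@lncrnaIds)
setMethod("interactionMatrix", "BipartiteNetwork", function(x) x@I)
setMethod("nProteins", "BipartiteNetwork", function(x) length(x@proteinIds))
setMethod("nLncrnas", "BipartiteNetwork", function(x) length(x@lncrnaIds))

#' @export
setMethod("show", "BipartiteNetwork", function(object) {
  cat("BipartiteNetwork:", nProteins(object), "proteins x",
    nLncrnas(object), "lncRNAs,", sum(object@I), "interactions\n")
  cat("  protein degree range:",
    paste(range(rowSums(object@I)), collapse = "-"), "\n")
  cat("  lncRNA degree range:",
    paste(range(colSums(object@I)), collapse = "-"), "\n")
})

setMethod("auc", "EvalReport", function(x) x@auc)
setMethod("aupr", "EvalReport", function(x) x@aupr)
setMethod("scalarMetrics", "EvalReport", function(x) x@metrics)

#' @export
setMethod("show", "EvalReport", function(object) {
  cat("EvalReport:", object@method, "/", object@scheme, "\n")
  cat(sprintf("  %d scores (%d positives)\n", length(object@scores),
    sum(object@labels)))
  cat(sprintf("  AUC %.4f  AUPR %.4f\n", object@auc, object@aupr))
  m <- object@metrics
  cat(sprintf(
    "  at threshold %.4g: PRE %.4f SEN %.4f ACC %.4f F1 %.4f MCC %.4f\n",
    object@threshold, m[["pre"]], m[["sen"]], m[["acc"]], m[["f1"]],
    m[["mcc"]]))
  if (length(object@perFoldAuc)) {
    cat(sprintf("  per-fold AUC %.4f +/- %.4f (n=%d)\n",
      mean(object@perFoldAuc), stats::sd(object@perFoldAuc),
      length(object@perFoldAuc)))
  }
})

#' @export
setMethod("show", "PlantedBlockSpec", function(object) {
  cat("PlantedBlockSpec:", object@nProteins, "proteins x", object@nLncrnas,
    "lncRNAs in", object@nBlocks, "blocks\n")
  cat(sprintf("  pIn %.3g pOut %.3g | %d tissues, noise sd %.3g | seed %d\n",
    object@pIn, object@pOut, object@exprTissues, object@exprNoiseSd,
    object@seed))
})
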