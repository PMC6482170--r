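#' @import methods
NULL

#' Bipartite lncRNA-protein interaction network
#'
#' Container for a binary bipartite interaction network between a set of
#' proteins (rows) and a set of lncRNAs (columns). The interaction matrix
#' `I` holds 1 where an experimentally supported interaction is known and 0
#' elsewhere; both axes carry ordered, unique identifiers.
#'
#' @slot proteinIds character vector of unique protein identifiers (rows).
#' @slot lncrnaIds character vector of unique lncRNA identifiers (columns).
#' @slot I binary interaction matrix, `length(proteinIds)` rows by
#'   `length(lncrnaIds)` columns, with dimnames matching the id slots.
#'
#' @seealso [readInteractions()], [filterMinDegree()], [generateNetwork()]
#' @export
setClass("BipartiteNetwork",
  representation(
    proteinIds = "character",
    lncrnaIds = "character",
    I = "matrix"
  )
)

setValidity("BipartiteNetwork", function(object) {
  msgs <- character()
  if (anyDuplicated(object@proteinIds)) {
    msgs <- c(msgs, "duplicate protein ids")
  }
  if (anyDuplicated(object@lncrnaIds)) {
    msgs <- c(msgs, "duplicate lncRNA ids")
  }
  if (nrow(object@I) != length(object@proteinIds) ||
    ncol(object@I) != length(object@lncrnaIds)) {
    msgs <- c(msgs, "interaction matrix shape does not match id lists")
  }
  if (!all(object@I %in% c(0, 1))) {
    msgs <- c(msgs, "interaction matrix must contain only 0/1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a BipartiteNetwork from an edge table
#'
#' Duplicate edges are collapsed; axis order is first appearance in the edge
#' list, so the result is reproducible bit-for-bit from the same input.
#'
#' @param edges data.frame with columns `lncrna` and `protein` (character).
#' @return A [BipartiteNetwork-class] object.
#' @examples
#' net <- BipartiteNetwork(data.frame(
#'   lncrna = c("l1", "l1", "l2"),
#'   protein = c("p1", "p2", "p1")
#' ))
#' interactionMatrix(net)
#' @export
BipartiteNetwork <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("lncrna", "protein") %in% names(edges)))
  if (nrow(edges) == 0L) stop("no edges: cannot build an empty network")
  lnc <- as.character(edges$lncrna)
  pro <- as.character(edges$protein)
  lncIds <- unique(lnc)
  proIds <- unique(pro)
  I <- matrix(0, nrow = length(proIds), ncol = length(lncIds),
    dimnames = list(proIds, lncIds))
  I[cbind(match(pro, proIds), match(lnc, lncIds))] <- 1
  new("BipartiteNetwork", proteinIds = proIds, lncrnaIds = lncIds, I = I)
}

#' Planted-block synthetic data specification
#'
#' Parameters of the synthetic generator: proteins and lncRNAs are assigned
#' round-robin to `nBlocks` blocks; within-block pairs interact with
#' probability `pIn` and cross-block pairs with `pOut`. Expression profiles
#' and PPI scores are generated with matching block structure so that the
#' similarity signal the recommender exploits is actually present.
#'
#' @slot nProteins,nLncrnas,nBlocks positive integers.
#' @slot pIn,pOut interaction probabilities, `0 <= pOut < pIn <= 1`.
#' @slot exprTissues number of tissues/cell types in generated expression
#'   profiles.
#' @slot exprNoiseSd standard deviation of per-lncRNA noise around the block
#'   mean expression profile (block means are standard normal per tissue).
#' @slot ppiInScore scale of within-block PPI scores.
#' @slot ppiOutRate probability that a cross-block protein pair is listed
#'   (at lower scores) in the PPI table.
#' @slot seed integer seed; all generator randomness derives from it.
#'
#' @seealso [plantedBlockSpec()], [generateNetwork()]
#' @export
setClass("PlantedBlockSpec",
  representation(
    nProteins = "integer",
    nLncrnas = "integer",
    nBlocks = "integer",
    pIn = "numeric",
    pOut = "numeric",
    exprTissues = "integer",
    exprNoiseSd = "numeric",
    ppiInScore = "numeric",
    ppiOutRate = "numeric",
    seed = "integer"
  )
)

setValidity("PlantedBlockSpec", function(object) {
  msgs <- character()
  if (object@nProteins < 1L || object@nLncrnas < 1L || object@nBlocks < 1L) {
    msgs <- c(msgs, "nProteins, nLncrnas, nBlocks must be positive")
  }
  if (object@nBlocks > min(object@nProteins, object@nLncrnas)) {
    msgs <- c(msgs, "nBlocks must not exceed min(nProteins, nLncrnas)")
  }
  if (!(object@pOut >= 0 && object@pOut < object@pIn && object@pIn <= 1)) {
    msgs <- c(msgs, "need 0 <= pOut < pIn <= 1")
  }
  if (object@exprTissues < 1L) msgs <- c(msgs, "exprTissues must be positive")
  if (object@exprNoiseSd <= 0) msgs <- c(msgs, "exprNoiseSd must be positive")
  if (object@ppiInScore <= 0) msgs <- c(msgs, "ppiInScore must be positive")
  if (object@ppiOutRate < 0 || object@ppiOutRate > 1) {
    msgs <- c(msgs, "ppiOutRate must be in [0,1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Create a planted-block generator specification
#'
#' Defaults describe the benchmark network used throughout the package's
#' tests: 60 proteins and 200 lncRNAs in 4 blocks with within-block edge
#' probability 0.5 and cross-block probability 0.02, expression profiles
#' over 24 tissues.
#'
#' @param nProteins,nLncrnas,nBlocks block-model dimensions.
#' @param pIn,pOut within-/cross-block interaction probabilities.
#' @param exprTissues,exprNoiseSd expression generator parameters.
#' @param ppiInScore,ppiOutRate PPI score generator parameters.
#' @param seed integer seed.
#' @return A [PlantedBlockSpec-class] object.
#' @export
plantedBlockSpec <- function(nProteins = 60L, nLncrnas = 200L, nBlocks = 4L,
                             pIn = 0.5, pOut = 0.02,
                             exprTissues = 24L, exprNoiseSd = 0.5,
                             ppiInScore = 1, ppiOutRate = 0.05,
                             seed = 1L) {
  new("PlantedBlockSpec",
    nProteins = as.integer(nProteins), nLncrnas = as.integer(nLncrnas),
    nBlocks = as.integer(nBlocks), pIn = pIn, pOut = pOut,
    exprTissues = as.integer(exprTissues), exprNoiseSd = exprNoiseSd,
    ppiInScore = ppiInScore, ppiOutRate = ppiOutRate,
    seed = as.integer(seed))
}

#' Cross-validation evaluation report
#'
#' Pooled test scores and labels from a cross-validation run, together with
#' ROC/PR curves and the scalar metric suite (precision, sensitivity,
#' accuracy, F1, Matthews correlation coefficient) at a chosen threshold.
#'
#' @slot method scoring method name.
#' @slot scheme `"loocv"` or `"kfold"`.
#' @slot scores numeric vector of pooled prediction scores.
#' @slot labels integer vector of 0/1 labels aligned with `scores`.
#' @slot auc,aupr areas under the ROC and precision-recall curves.
#' @slot metrics named numeric vector: `pre`, `sen`, `acc`, `f1`, `mcc`.
#' @slot threshold score threshold at which `metrics` were computed.
#' @slot perFoldAuc per-fold AUC (k-fold only; empty for LOOCV).
#' @slot curves list with `roc` and `pr` curve data.frames.
#' @export
setClass("EvalReport",
  representation(
    method = "character",
    scheme = "character",
    scores = "numeric",
    labels = "integer",
    auc = "numeric",
    aupr = "numeric",
    metrics = "numeric",
    threshold = "numeric",
    perFoldAuc = "numeric",
    curves = "list"
  )
)

setValidity("EvalReport", function(object) {
  msgs <- character()
  if (length(object@scores) != length(object@labels)) {
    msgs <- c(msgs, "scores and labels differ in length")
  }
  if (!all(object@labels %in% c(0L, 1L))) {
    msgs <- c(msgs, "labels must be 0/1")
  }
  if (length(object@auc) == 1 && (object@auc < 0 || object@auc > 1)) {
    msgs <- c(msgs, "auc outside [0,1]")
  }
  if (length(object@aupr) == 1 && (object@aupr < 0 || object@aupr > 1)) {
    msgs <- c(msgs, "aupr outside [0,1]")
  }
  if (length(msgs)) msgs else TRUE
})
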