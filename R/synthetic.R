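# Planted-block synthetic data: a bipartite network with community
# structure, plus expression profiles and PPI scores that carry the same
# block signal, so the similarity-weighted recommender has a real (and
# known) signal to recover. All randomness derives from the spec seed;
# the three generators use fixed offsets of it so each output is
# reproducible independently of call order.

.blockLabels <- function(n, nBlocks) rep_len(seq_len(nBlocks), n)

#' Generate a planted-block bipartite network
#'
#' Proteins and lncRNAs are assigned round-robin to blocks; each
#' within-block (protein, lncRNA) pair interacts with probability `pIn` and
#' each cross-block pair with `pOut`. The raw network is then cleaned with
#' [filterMinDegree()] at degree 2, and block labels of the surviving nodes
#' are returned as ground truth.
#'
#' @param spec a [PlantedBlockSpec-class].
#' @return list with `network` (a [BipartiteNetwork-class]),
#'   `proteinBlocks` and `lncrnaBlocks` (named integer vectors over the
#'   surviving nodes).
#' @export
generateNetwork <- function(spec) {
  stopifnot(is(spec, "PlantedBlockSpec"))
  np <- spec@nProteins
  nl <- spec@nLncrnas
  pb <- .blockLabels(np, spec@nBlocks)
  lb <- .blockLabels(nl, spec@nBlocks)
  prob <- ifelse(outer(pb, lb, "=="), spec@pIn, spec@pOut)
  I <- withr::with_seed(spec@seed,
    matrix(stats::rbinom(np * nl, 1, prob), np, nl))
  dimnames(I) <- list(sprintf("p%03d", seq_len(np)),
    sprintf("l%03d", seq_len(nl)))
  names(pb) <- rownames(I)
  names(lb) <- colnames(I)
  raw <- new("BipartiteNetwork", proteinIds = rownames(I),
    lncrnaIds = colnames(I), I = I)
  net <- tryCatch(filterMinDegree(raw, 2L), error = function(e) {
    stop("degree filtering emptied the generated network; ",
      "increase pIn or the network size", call. = FALSE)
  })
  list(
    network = net,
    proteinBlocks = pb[proteinIds(net)],
    lncrnaBlocks = lb[lncrnaIds(net)]
  )
}

#' Generate block-structured lncRNA expression profiles
#'
#' Each block draws a mean profile (standard normal per tissue); each
#' lncRNA's profile is its block mean plus independent Gaussian noise with
#' sd `exprNoiseSd`. Within-block pairs therefore share a mean and are more
#' strongly correlated (in absolute Pearson correlation) than cross-block
#' pairs.
#'
#' @param spec a [PlantedBlockSpec-class].
#' @param lncrnaBlocks named block assignment from [generateNetwork()].
#' @return Numeric matrix, one row per lncRNA in `lncrnaBlocks`, with
#'   `spec@exprTissues` tissue columns.
#' @export
generateExpression <- function(spec, lncrnaBlocks) {
  stopifnot(is(spec, "PlantedBlockSpec"))
  nT <- spec@exprTissues
  nl <- length(lncrnaBlocks)
  withr::with_seed(spec@seed + 1L, {
    means <- matrix(stats::rnorm(spec@nBlocks * nT), spec@nBlocks, nT)
    E <- means[lncrnaBlocks, , drop = FALSE] +
      matrix(stats::rnorm(nl * nT, sd = spec@exprNoiseSd), nl, nT)
  })
  dimnames(E) <- list(names(lncrnaBlocks),
    sprintf("tissue%02d", seq_len(nT)))
  E
}

#' Generate block-structured PPI scores
#'
#' Every within-block protein pair is listed with score
#' `ppiInScore * u`, `u ~ U(0.5, 1]`; each cross-block pair is listed with
#' probability `ppiOutRate` at a lower score `ppiInScore * v`,
#' `v ~ U(0.05, 0.5)`. The table is symmetric by construction (each
#' unordered pair appears once).
#'
#' @param spec a [PlantedBlockSpec-class].
#' @param proteinBlocks named block assignment from [generateNetwork()].
#' @return data.frame with columns `a`, `b`, `score` (one row per listed
#'   unordered pair); materialize with [ppiMatrix()].
#' @export
generatePPI <- function(spec, proteinBlocks) {
  stopifnot(is(spec, "PlantedBlockSpec"))
  ids <- names(proteinBlocks)
  np <- length(ids)
  pairs <- which(upper.tri(matrix(0, np, np)), arr.ind = TRUE)
  same <- proteinBlocks[pairs[, 1]] == proteinBlocks[pairs[, 2]]
  withr::with_seed(spec@seed + 2L, {
    listed <- ifelse(same, TRUE,
      stats::runif(nrow(pairs)) < spec@ppiOutRate)
    score <- ifelse(same,
      spec@ppiInScore * stats::runif(nrow(pairs), 0.5, 1),
      spec@ppiInScore * stats::runif(nrow(pairs), 0.05, 0.5))
  })
  data.frame(
    a = ids[pairs[listed, 1]],
    b = ids[pairs[listed, 2]],
    score = score[listed],
    stringsAsFactors = FALSE
  )
}

#' Materialize a PPI score table as a symmetric matrix
#'
#' @param ppiTable data.frame from [generatePPI()] (columns a, b, score).
#' @param net the network whose protein axis orders the matrix.
#' @return Symmetric numeric matrix over `proteinIds(net)`.
#' @export
ppiMatrix <- function(ppiTable, net) {
  ids <- proteinIds(net)
  AP <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  keep <- ppiTable$a %in% ids & ppiTable$b %in% ids
  t <- ppiTable[keep, , drop = FALSE]
  AP[cbind(t$a, t$b)] <- t$score
  AP[cbind(t$b, t$a)] <- t$score
  AP
}

#' Generate the full synthetic dataset
#'
#' Runs the three generators in sequence and returns everything the
#' pipeline consumes: the cleaned network, the expression matrix, the PPI
#' score matrix, and the ground-truth block labels.
#'
#' @param spec a [PlantedBlockSpec-class].
#' @return list with `network`, `expression`, `ppi` (matrix), `ppiTable`,
#'   `proteinBlocks`, `lncrnaBlocks`.
#' @export
simulateDataset <- function(spec = plantedBlockSpec()) {
  gen <- generateNetwork(spec)
  expr <- generateExpression(spec, gen$lncrnaBlocks)
  ppiTab <- generatePPI(spec, gen$proteinBlocks)
  list(
    network = gen$network,
    expression = expr,
    ppi = ppiMatrix(ppiTab, gen$network),
    ppiTable = ppiTab,
    proteinBlocks = gen$proteinBlocks,
    lncrnaBlocks = gen$lncrnaBlocks
  )
}
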