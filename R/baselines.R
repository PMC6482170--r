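# Reference predictors used for comparison with the resource-allocation
# recommender. All three share the score-matrix contract of ibnraScores().

#' Collaborative filtering baseline
#'
#' Memory-based CF: each protein's score for a lncRNA is the
#' similarity-weighted vote of all proteins over that lncRNA's known
#' interactions, normalized by total similarity:
#' `score(i,j) = sum_k SimP(i,k) I(k,j) / sum_k SimP(i,k)`. Unlike
#' [proteinSideScores()] the result is not restricted to known edges.
#'
#' @param I binary interaction matrix.
#' @param simP protein similarity matrix.
#' @return `np x nl` score matrix.
#' @export
cfPredict <- function(I, simP) {
  stopifnot(nrow(simP) == nrow(I), ncol(simP) == nrow(I))
  rs <- rowSums(simP)
  inv <- ifelse(rs > 0, 1 / rs, 0)
  out <- (simP %*% I) * inv
  dimnames(out) <- dimnames(I)
  out
}

#' Random walk with restart on the protein similarity network
#'
#' For each lncRNA, the walker restarts at its known interacting proteins
#' (uniform over them) and steps through the column-normalized protein
#' similarity network with probability `1 - restartProb`:
#' `p <- (1 - r) M p + r p0`, iterated until the L1 change drops below
#' `tol`. The diagonal of the similarity is zeroed before normalization so
#' self-loops do not dampen propagation. A lncRNA with no training edges
#' has no restart distribution; its column is 0 with a warning.
#'
#' @param I binary interaction matrix.
#' @param simP protein similarity matrix.
#' @param restartProb restart probability `r` in `(0, 1]`; default 0.5.
#' @param tol L1 convergence tolerance; default 1e-8.
#' @param maxIter iteration cap; default 1000.
#' @return `np x nl` matrix of stationary probabilities.
#' @export
rwrPredict <- function(I, simP, restartProb = 0.5, tol = 1e-8,
                       maxIter = 1000L) {
  stopifnot(restartProb > 0, restartProb <= 1, tol > 0, maxIter >= 1)
  M <- simP
  diag(M) <- 0
  cs <- colSums(M)
  M <- sweep(M, 2, ifelse(cs > 0, cs, 1), "/")
  M[, cs == 0] <- 0
  colMass <- colSums(I)
  empty <- colMass == 0
  if (any(empty)) {
    warning(sum(empty), " lncRNA(s) with no training interactions: ",
      "their score columns are 0")
  }
  P0 <- sweep(I, 2, ifelse(empty, 1, colMass), "/")
  P0[, empty] <- 0
  P <- P0
  r <- restartProb
  for (it in seq_len(maxIter)) {
    Pnew <- (1 - r) * (M %*% P) + r * P0
    if (max(colSums(abs(Pnew - P))) < tol) {
      P <- Pnew
      break
    }
    P <- Pnew
  }
  dimnames(P) <- dimnames(I)
  P
}

#' Unweighted bipartite network inference baseline
#'
#' Classical two-round allocation on the binary network alone (no
#' similarities): `W_bin(i,j) = (1/deg(p_j)) sum_k I(i,k) I(j,k) / deg(l_k)`
#' and `scores = W_bin I`. Identical to the recommender with identity
#' similarity matrices and `alpha = 0`.
#'
#' @param I binary interaction matrix.
#' @return `np x nl` score matrix.
#' @export
lpbniPredict <- function(I) {
  stopifnot(all(I %in% c(0, 1)))
  finalScores(weightMatrix(I), I)
}
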