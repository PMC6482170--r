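# Resource allocation on the bipartite network: the recommender proper.
#
# The initial resource matrix Sini lives on the known-interaction support;
# a two-round spread (protein -> lncRNA -> protein) is equivalent to the
# protein-protein weight matrix W applied to each column of Sini, and
# replacing W by W + alpha W^2 (alpha in (-1, 0]) subtracts the redundancy
# of proteins connected both through a shared lncRNA and through
# intermediary proteins.

#' Protein-similarity-weighted resource scores
#'
#' For each known interaction (i,j), the fraction of protein i's total
#' similarity carried by proteins that interact with lncRNA j:
#' `SP(i,j) = sum_k SimP(i,k) I(k,j) / sum_k SimP(i,k)` where `I(i,j) = 1`,
#' and 0 elsewhere (support equals the known-interaction support).
#'
#' @param I binary interaction matrix.
#' @param simP integrated protein similarity (unit diagonal).
#' @return Matrix `SP`, same shape as `I`, entries in `[0,1]`.
#' @export
proteinSideScores <- function(I, simP) {
  stopifnot(nrow(simP) == nrow(I), ncol(simP) == nrow(I))
  rs <- rowSums(simP)
  if (any(rs == 0)) stop("zero protein similarity row sum")
  SP <- (simP %*% I) / rs
  SP[I == 0] <- 0
  dimnames(SP) <- dimnames(I)
  SP
}

#' LncRNA-similarity-weighted resource scores
#'
#' For each known interaction (i,j), the similarity-weighted share of
#' protein i's interaction profile relative to the target lncRNA:
#' `SL(i,j) = sum_k I(i,k) SimL(k,j) / sum_k SimL(k,j)` where `I(i,j) = 1`,
#' 0 elsewhere. The denominator normalizes over the scored lncRNA `j`; a
#' zero denominator (impossible with a unit-diagonal similarity) yields 0
#' with a warning.
#'
#' @param I binary interaction matrix.
#' @param simL integrated lncRNA similarity (unit diagonal).
#' @return Matrix `SL`, same shape as `I`, entries in `[0,1]`.
#' @export
lncrnaSideScores <- function(I, simL) {
  stopifnot(nrow(simL) == ncol(I), ncol(simL) == ncol(I))
  den <- colSums(simL)
  zero <- den == 0
  if (any(zero)) {
    warning(sum(zero), " lncRNA(s) with zero similarity column sum; ",
      "their scores are set to 0")
    den[zero] <- 1
  }
  SL <- sweep(I %*% simL, 2, den, "/")
  SL[, zero] <- 0
  SL[I == 0] <- 0
  dimnames(SL) <- dimnames(I)
  SL
}

#' Combine the two resource score matrices
#'
#' `Sini = gamma * SP + (1 - gamma) * SL`; `gamma` in `[0,1]` balances the
#' protein-similarity and lncRNA-similarity contributions (0.5 weighs them
#' equally, the default).
#'
#' @param SP,SL matrices from [proteinSideScores()] / [lncrnaSideScores()].
#' @param gamma mixing weight in `[0,1]`.
#' @return The initial resource score matrix `Sini`.
#' @export
initialScores <- function(SP, SL, gamma = 0.5) {
  if (!is.numeric(gamma) || gamma < 0 || gamma > 1) {
    stop("gamma must lie in [0,1]")
  }
  if (!identical(dim(SP), dim(SL))) stop("shape mismatch: SP vs SL")
  gamma * SP + (1 - gamma) * SL
}

#' Protein-protein resource-allocation weight matrix
#'
#' Vectorized form of the two-round allocation:
#' `W(i,j) = (1/d(p_j)) sum_k Sini(i,k) Sini(j,k) / d(l_k)`, with
#' `d(p_j) = sum_k Sini(j,k)` and `d(l_k) = sum_y Sini(y,k)`. Terms with
#' `d(l_k) = 0` contribute 0 and columns with `d(p_j) = 0` are all-zero.
#' Restricted to proteins with positive degree, columns of `W` sum to 1.
#'
#' @param Sini non-negative initial resource score matrix.
#' @return `np x np` weight matrix `W`.
#' @export
weightMatrix <- function(Sini) {
  if (any(Sini < 0)) stop("Sini must be non-negative")
  dl <- colSums(Sini)
  dp <- rowSums(Sini)
  invDl <- ifelse(dl > 0, 1 / dl, 0)
  invDp <- ifelse(dp > 0, 1 / dp, 0)
  W <- tcrossprod(sweep(Sini, 2, invDl, "*"), Sini)
  W <- sweep(W, 2, invDp, "*")
  dimnames(W) <- list(rownames(Sini), rownames(Sini))
  W
}

#' Two-round resource allocation for one lncRNA (iterative form)
#'
#' Reference implementation of the spread as explicit loops: the resource of
#' lncRNA `k` starts on its interacting proteins (`s0(p_i) = Sini(i,k)`),
#' flows to all lncRNAs proportionally to each protein's scores
#' (`s1(l) = sum_j Sini(j,l) s0(j)/d(p_j)`), and flows back
#' (`s2(i) = sum_l Sini(i,l) s1(l)/d(l)`). Zero-degree proteins and lncRNAs
#' contribute and receive nothing. The production path is the matrix product
#' `W %*% Sini` ([weightMatrix()]); this iterative form exists to verify it.
#'
#' @param Sini non-negative initial resource score matrix.
#' @param k lncRNA column index.
#' @return Numeric vector of length `nrow(Sini)`: the reallocated scores.
#' @export
twoRoundAllocation <- function(Sini, k) {
  stopifnot(k >= 1, k <= ncol(Sini))
  np <- nrow(Sini)
  nl <- ncol(Sini)
  dp <- rowSums(Sini)
  dl <- colSums(Sini)
  s0 <- Sini[, k]
  s1 <- numeric(nl)
  for (l in seq_len(nl)) {
    acc <- 0
    for (j in seq_len(np)) {
      if (dp[j] > 0) acc <- acc + Sini[j, l] * s0[j] / dp[j]
    }
    s1[l] <- acc
  }
  s2 <- numeric(np)
  for (i in seq_len(np)) {
    acc <- 0
    for (l in seq_len(nl)) {
      if (dl[l] > 0) acc <- acc + Sini[i, l] * s1[l] / dl[l]
    }
    s2[i] <- acc
  }
  names(s2) <- rownames(Sini)
  s2
}

#' Second-order correlation elimination
#'
#' `W' = W + alpha W^2` (matrix square). Proteins sharing a lncRNA are also
#' correlated indirectly through intermediary proteins; with `alpha < 0` the
#' squared term subtracts that redundancy. At `alpha = 0` the weight matrix
#' is unchanged; column sums over positive-degree proteins become
#' `1 + alpha`, so entries of `W'` (and of the final scores) can be
#' negative — ranking uses them as-is.
#'
#' @param W weight matrix from [weightMatrix()].
#' @param alpha elimination strength in `(-1, 0]`; default -0.7.
#' @return The adjusted weight matrix `W'`.
#' @export
eliminateSecondOrder <- function(W, alpha = -0.7) {
  if (!is.numeric(alpha) || alpha <= -1 || alpha > 0) {
    stop("alpha must lie in (-1, 0]")
  }
  W + alpha * (W %*% W)
}

#' Final prediction scores
#'
#' `Sfin' = W' %*% Sini`: every column of the initial resource matrix is
#' reallocated through the (redundancy-corrected) weight matrix. With
#' `alpha = 0` this is the plain weighted two-round allocation `W Sini`.
#'
#' @param Wprime adjusted weight matrix ([eliminateSecondOrder()]).
#' @param Sini initial resource score matrix.
#' @return `np x nl` score matrix.
#' @export
finalScores <- function(Wprime, Sini) {
  if (ncol(Wprime) != nrow(Sini)) stop("shape mismatch: Wprime vs Sini")
  Wprime %*% Sini
}

#' Rank candidate proteins for one lncRNA
#'
#' Sorts proteins by descending final score for lncRNA `k`; ties are broken
#' by protein id lexicographically (stable). With `excludeKnown`, proteins
#' already known to interact with `k` are omitted, leaving the novel
#' candidates.
#'
#' @param scores final score matrix (`np x nl`).
#' @param net the [BipartiteNetwork-class] (ids and known edges).
#' @param k lncRNA column index or id.
#' @param excludeKnown omit known interaction partners (default TRUE).
#' @return data.frame with columns protein, score, rank.
#' @export
rankCandidates <- function(scores, net, k, excludeKnown = TRUE) {
  if (is.character(k)) k <- match(k, lncrnaIds(net))
  stopifnot(!is.na(k), k >= 1, k <= nLncrnas(net))
  pid <- proteinIds(net)
  keep <- if (excludeKnown) {
    which(interactionMatrix(net)[, k] == 0)
  } else {
    seq_along(pid)
  }
  sc <- unname(scores[keep, k])
  ord <- order(-sc, pid[keep], method = "radix")
  data.frame(protein = pid[keep][ord], score = sc[ord],
    rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Full recommender pipeline on one interaction matrix
#'
#' Builds the integrated similarities from `I` (plus optional PPI scores
#' and expression profiles), forms `Sini`, the weight matrix, applies
#' second-order elimination, and returns the final score matrix. This is
#' the scoring core shared by prediction and cross-validation. When
#' `alpha` is a vector, a named list of score matrices is returned (the
#' weight matrix does not depend on `alpha`, so scoring is cheap per value).
#'
#' @param I binary interaction matrix (training edges only).
#' @param ppi optional PPI score matrix.
#' @param expression optional expression profile matrix.
#' @param gamma mixing weight for [initialScores()].
#' @param alpha elimination strength(s) for [eliminateSecondOrder()].
#' @param betaPrimeProtein,betaPrimeLncrna kernel bandwidth coefficients.
#' @param simP,simL optional precomputed similarity matrices (override the
#'   kernel construction; used by the evaluation harness).
#' @return Score matrix, or named list of score matrices when `alpha` has
#'   length > 1.
#' @export
ibnraScores <- function(I, ppi = NULL, expression = NULL, gamma = 0.5,
                        alpha = -0.7, betaPrimeProtein = 1,
                        betaPrimeLncrna = 1, simP = NULL, simL = NULL) {
  if (is.null(simP) || is.null(simL)) {
    sims <- buildSimilarities(I, ppi, expression, betaPrimeProtein,
      betaPrimeLncrna)
    if (is.null(simP)) simP <- sims$simP
    if (is.null(simL)) simL <- sims$simL
  }
  SP <- proteinSideScores(I, simP)
  SL <- lncrnaSideScores(I, simL)
  Sini <- initialScores(SP, SL, gamma)
  W <- weightMatrix(Sini)
  if (length(alpha) == 1L) {
    return(finalScores(eliminateSecondOrder(W, alpha), Sini))
  }
  out <- lapply(alpha, function(a) {
    finalScores(eliminateSecondOrder(W, a), Sini)
  })
  names(out) <- as.character(alpha)
  out
}
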