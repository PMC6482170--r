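# Independent reference implementations used to cross-check the package.
# These deliberately use naive loops and closed forms, never the package's
# own production code paths.

# The 2x2 hand-traceable fixture: p2 interacts only with l2.
tinyNet <- function() {
  BipartiteNetwork(data.frame(
    lncrna = c("l1", "l2", "l2"),
    protein = c("p1", "p1", "p2")
  ))
}

# Random binary interaction matrix with ids, optionally guaranteed to have
# no zero rows/columns.
randomBinaryI <- function(np, nl, p = 0.5, noZeroDegrees = TRUE) {
  repeat {
    I <- matrix(rbinom(np * nl, 1, p), np, nl,
      dimnames = list(paste0("p", seq_len(np)), paste0("l", seq_len(nl))))
    if (!noZeroDegrees || (all(rowSums(I) > 0) && all(colSums(I) > 0))) {
      return(I)
    }
  }
}

# Random non-negative resource matrix with sparse support.
randomSini <- function(np, nl, density = 0.6) {
  S <- matrix(runif(np * nl) * (runif(np * nl) < density), np, nl,
    dimnames = list(paste0("p", seq_len(np)), paste0("l", seq_len(nl))))
  S
}

# Classical unweighted two-round (ProbS) projection weight matrix,
# written as explicit loops over the definition.
probsOracle <- function(I) {
  np <- nrow(I)
  nl <- ncol(I)
  degP <- rowSums(I)
  degL <- colSums(I)
  W <- matrix(0, np, np)
  for (i in seq_len(np)) {
    for (j in seq_len(np)) {
      if (degP[j] == 0) next
      acc <- 0
      for (k in seq_len(nl)) {
        if (degL[k] > 0) acc <- acc + I[i, k] * I[j, k] / degL[k]
      }
      W[i, j] <- acc / degP[j]
    }
  }
  W
}

# AUC by brute-force enumeration of positive-negative pairs
# (ties count one half).
aucPairOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# AUPR by brute-force enumeration of all distinct score cutoffs, step-wise
# (non-interpolated) summation in decreasing threshold order.
auprEnumOracle <- function(scores, labels) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  area <- 0
  prevRecall <- 0
  for (t in thresholds) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    recall <- tp / P
    precision <- tp / (tp + fp)
    area <- area + (recall - prevRecall) * precision
    prevRecall <- recall
  }
  area
}

# Stationary RWR distribution by direct linear solve.
rwrClosedForm <- function(M, p0, r) {
  solve(diag(nrow(M)) - (1 - r) * M, r * p0)
}

writeTempTsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
    .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
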