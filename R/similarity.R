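.checkSymmetric <- function(M, label, tol = 1e-10) {
  if (nrow(M) != ncol(M) || max(abs(M - t(M))) > tol) {
    stop(label, " must be symmetric")
  }
}

#' Degree-normalize a PPI score matrix
#'
#' Normalizes a symmetric non-negative protein-protein score matrix `AP` by
#' the geometric mean of row sums: `AP'(i,j) = AP(i,j) / sqrt(R(i) R(j))`
#' with `R(i) = sum_j AP(i,j)`. Proteins with zero total score keep zero
#' entries (no division by zero).
#'
#' @param AP symmetric non-negative numeric matrix.
#' @return The normalized similarity matrix `AP'`, same dimnames.
#' @export
normalizePPI <- function(AP) {
  .checkSymmetric(AP, "PPI score matrix")
  if (any(AP < 0)) stop("PPI scores must be non-negative")
  R <- rowSums(AP)
  inv <- ifelse(R > 0, 1 / sqrt(R), 0)
  out <- AP * tcrossprod(inv)
  dimnames(out) <- dimnames(AP)
  out
}

#' Gaussian interaction-profile kernel similarity
#'
#' Similarity between two nodes' binary interaction profiles:
#' `K(i,j) = exp(-beta * ||X_i - X_j||^2)`, where profiles `X` are rows of
#' the interaction matrix (protein axis) or columns (lncRNA axis), and the
#' bandwidth is normalized by the mean squared profile norm:
#' `beta = betaPrime / mean_i ||X_i||^2`. Nodes with identical profiles get
#' similarity 1; the diagonal is exactly 1.
#'
#' @param I binary interaction matrix (proteins x lncRNAs).
#' @param axis `"protein"` (rows as profiles) or `"lncrna"` (columns).
#' @param betaPrime positive bandwidth adjustment coefficient; default 1.
#' @return Symmetric kernel matrix with unit diagonal, entries in (0, 1].
#' @export
gaussianProfileKernel <- function(I, axis = c("protein", "lncrna"),
                                  betaPrime = 1) {
  axis <- match.arg(axis)
  stopifnot(betaPrime > 0)
  X <- if (axis == "protein") I else t(I)
  sq <- rowSums(X^2)
  msn <- mean(sq)
  if (msn == 0) stop("bandwidth undefined: all interaction profiles are zero")
  beta <- betaPrime / msn
  # squared Euclidean distances via the Gram matrix
  G <- tcrossprod(X)
  D2 <- outer(sq, sq, "+") - 2 * G
  D2[D2 < 0] <- 0
  K <- exp(-beta * D2)
  diag(K) <- 1
  ids <- if (axis == "protein") rownames(I) else colnames(I)
  dimnames(K) <- list(ids, ids)
  K
}

#' Expression-profile similarity (absolute Pearson correlation)
#'
#' `AL(i,j) = |PCC(E(i), E(j))|` between the tissue expression profiles of
#' two lncRNAs. A constant profile has undefined correlation; its similarity
#' to every other lncRNA is set to 0 (the least-informative choice) while
#' the diagonal is forced to 1.
#'
#' @param E numeric matrix, lncRNAs in rows, tissues in columns (`T >= 2`).
#' @return Symmetric matrix of absolute correlations with unit diagonal.
#' @export
expressionSimilarity <- function(E) {
  stopifnot(ncol(E) >= 2)
  AL <- suppressWarnings(abs(stats::cor(t(E))))
  AL[is.na(AL)] <- 0
  diag(AL) <- 1
  dimnames(AL) <- list(rownames(E), rownames(E))
  AL
}

#' Integrate protein similarities
#'
#' Entrywise: the mean of normalized PPI similarity and kernel similarity
#' where a PPI-derived value exists (`AP' != 0`), and the kernel similarity
#' alone where it does not. The test is per entry.
#'
#' @param APn normalized PPI similarity ([normalizePPI()] output).
#' @param KP protein Gaussian profile kernel.
#' @return Integrated protein similarity matrix `SimP`.
#' @export
integrateProteinSimilarity <- function(APn, KP) {
  if (!identical(dim(APn), dim(KP))) stop("shape mismatch: APn vs KP")
  out <- ifelse(APn != 0, (APn + KP) / 2, KP)
  dimnames(out) <- dimnames(KP)
  out
}

#' Integrate lncRNA similarities
#'
#' Unconditional entrywise average of expression similarity and the lncRNA
#' Gaussian profile kernel.
#'
#' @param AL expression similarity ([expressionSimilarity()] output).
#' @param KL lncRNA Gaussian profile kernel.
#' @return Integrated lncRNA similarity matrix `SimL`.
#' @export
integrateLncrnaSimilarity <- function(AL, KL) {
  if (!identical(dim(AL), dim(KL))) stop("shape mismatch: AL vs KL")
  out <- (AL + KL) / 2
  dimnames(out) <- dimnames(KL)
  out
}

#' Build both integrated similarity matrices for a network
#'
#' Convenience wrapper: computes the Gaussian profile kernels from the given
#' interaction matrix (which, during cross-validation, must be the masked
#' training matrix — the kernels depend on the interaction profiles and
#' would otherwise leak test edges), and integrates them with the optional
#' PPI and expression similarities. With `ppi = NULL` the protein similarity
#' is the kernel alone; with `expression = NULL` the lncRNA similarity is
#' the kernel alone.
#'
#' @param I binary interaction matrix (training edges only).
#' @param ppi optional symmetric PPI score matrix ([readPPIScores()]).
#' @param expression optional expression profile matrix ([readExpression()]).
#' @param betaPrimeProtein,betaPrimeLncrna kernel bandwidth coefficients.
#' @return list with elements `simP` and `simL`.
#' @export
buildSimilarities <- function(I, ppi = NULL, expression = NULL,
                              betaPrimeProtein = 1, betaPrimeLncrna = 1) {
  KP <- gaussianProfileKernel(I, "protein", betaPrimeProtein)
  KL <- gaussianProfileKernel(I, "lncrna", betaPrimeLncrna)
  simP <- if (is.null(ppi)) KP else {
    integrateProteinSimilarity(normalizePPI(ppi), KP)
  }
  simL <- if (is.null(expression)) KL else {
    integrateLncrnaSimilarity(expressionSimilarity(expression), KL)
  }
  list(simP = simP, simL = simL)
}
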