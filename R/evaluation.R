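# Cross-validation harness and ranking metrics.
#
# Scores are pooled over folds: each held-out edge contributes a positive,
# and every non-edge (in the full network) of a lncRNA holding a test edge
# in that fold contributes a negative. Similarities are rebuilt from the
# masked training matrix in every fold, so no test edge can leak through
# the interaction-profile kernels.

# Group scores by decreasing value and accumulate confusion counts at each
# distinct threshold. Shared backbone of the ROC and PR curves: tied scores
# collapse to one threshold, which makes curve integration match the
# Mann-Whitney statistic (ties contribute 1/2) exactly.
.thresholdCounts <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # indices of the last element of each tie group
  grpEnd <- which(diff(c(s, -Inf)) != 0)
  list(
    threshold = s[grpEnd],
    tp = cumsum(y)[grpEnd],
    fp = cumsum(1 - y)[grpEnd],
    P = sum(y),
    N = sum(1 - y)
  )
}

#' ROC curve and area under it
#'
#' Computes the ROC curve over all score thresholds (tied scores form a
#' single threshold) and its area by trapezoidal integration, which equals
#' the Mann-Whitney rank statistic with ties contributing one half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (both classes must be present).
#' @return list with `curve` (data.frame: threshold, fpr, tpr) and `auc`.
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("ROC undefined: labels contain a single class")
  }
  tc <- .thresholdCounts(scores, labels)
  tpr <- c(0, tc$tp / tc$P)
  fpr <- c(0, tc$fp / tc$N)
  aucVal <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(
    curve = data.frame(threshold = c(Inf, tc$threshold), fpr = fpr,
      tpr = tpr),
    auc = aucVal
  )
}

#' Precision-recall curve and area under it
#'
#' Non-interpolated step-wise summation: the area is
#' `sum_i (R_i - R_{i-1}) * P_i` over distinct thresholds in decreasing
#' score order. With all scores equal this degenerates to a single point
#' and the area equals the positive prevalence.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (at least one positive required).
#' @return list with `curve` (data.frame: threshold, recall, precision)
#'   and `aupr`.
#' @export
prAupr <- function(scores, labels) {
  labels <- as.integer(labels)
  if (sum(labels) == 0) stop("PR undefined: no positive labels")
  tc <- .thresholdCounts(scores, labels)
  recall <- tc$tp / tc$P
  precision <- tc$tp / (tc$tp + tc$fp)
  auprVal <- sum(diff(c(0, recall)) * precision)
  list(
    curve = data.frame(threshold = tc$threshold, recall = recall,
      precision = precision),
    aupr = auprVal
  )
}

.confusion <- function(scores, labels, threshold) {
  pred <- scores >= threshold
  c(
    tp = sum(pred & labels == 1), fp = sum(pred & labels == 0),
    fn = sum(!pred & labels == 1), tn = sum(!pred & labels == 0)
  )
}

.metricsFromCounts <- function(cn) {
  tp <- cn[["tp"]]; fp <- cn[["fp"]]; fn <- cn[["fn"]]; tn <- cn[["tn"]]
  safe <- function(num, den) if (den == 0) 0 else num / den
  mccDen <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  c(
    pre = safe(tp, tp + fp),
    sen = safe(tp, tp + fn),
    acc = safe(tp + tn, tp + fp + fn + tn),
    f1 = safe(2 * tp, 2 * tp + fp + fn),
    mcc = if (mccDen == 0) 0 else (tp * tn - fp * fn) / mccDen
  )
}

#' Threshold-based classification metrics
#'
#' Precision, sensitivity, accuracy, F1 and the Matthews correlation
#' coefficient (`MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`)
#' at a threshold chosen by rule: `"max_f1"` (default) maximizes F1 over
#' all observed score values, `"youden"` maximizes TPR - FPR, and
#' `"fixed:x"` (or a numeric) uses the given cutoff. A metric with a
#' degenerate (zero) denominator is reported as 0 and listed in the
#' `degenerate` attribute.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (both classes must be present).
#' @param thresholdRule `"max_f1"`, `"youden"`, `"fixed:x"`, or a number.
#' @return Named numeric vector (pre, sen, acc, f1, mcc, threshold) with a
#'   `counts` attribute holding the confusion counts.
#' @export
binaryMetrics <- function(scores, labels, thresholdRule = "max_f1") {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("metrics undefined: labels contain a single class")
  }
  if (is.numeric(thresholdRule)) {
    thr <- thresholdRule
  } else if (startsWith(thresholdRule, "fixed:")) {
    thr <- as.numeric(sub("^fixed:", "", thresholdRule))
    if (is.na(thr)) stop("unparseable fixed threshold: ", thresholdRule)
  } else {
    rule <- match.arg(thresholdRule, c("max_f1", "youden"))
    tc <- .thresholdCounts(scores, labels)
    objective <- if (rule == "max_f1") {
      2 * tc$tp / (2 * tc$tp + tc$fp + (tc$P - tc$tp))
    } else {
      tc$tp / tc$P - tc$fp / tc$N
    }
    thr <- tc$threshold[which.max(objective)]
  }
  cn <- .confusion(scores, labels, thr)
  m <- .metricsFromCounts(cn)
  degenerate <- character()
  if (cn[["tp"]] + cn[["fp"]] == 0) degenerate <- c(degenerate, "pre")
  out <- c(m, threshold = thr)
  attr(out, "counts") <- cn
  attr(out, "degenerate") <- degenerate
  out
}

#' Build a cross-validation fold plan over the known edges
#'
#' Shuffles the known interactions with the given seed and splits them into
#' disjoint folds: one edge per fold for LOOCV, `k` near-equal folds
#' otherwise. The same seed always yields the same plan.
#'
#' @param net a [BipartiteNetwork-class].
#' @param scheme `"kfold"` or `"loocv"`.
#' @param k number of folds (ignored for LOOCV); default 10.
#' @param seed integer seed for the shuffle.
#' @return A fold plan: list with `scheme`, `k`, `seed`, and `folds`, a
#'   list of integer vectors of linear indices into the interaction matrix.
#' @export
makeFolds <- function(net, scheme = c("kfold", "loocv"), k = 10L,
                      seed = 1L) {
  scheme <- match.arg(scheme)
  edges <- which(interactionMatrix(net) == 1)
  nE <- length(edges)
  if (scheme == "kfold" && k > nE) {
    stop("k = ", k, " exceeds the number of known edges (", nE, ")")
  }
  shuffled <- withr::with_seed(seed, sample(edges))
  folds <- if (scheme == "loocv") {
    as.list(shuffled)
  } else {
    split(shuffled, rep_len(seq_len(k), nE))
  }
  list(scheme = scheme, k = if (scheme == "loocv") nE else as.integer(k),
    seed = as.integer(seed), folds = unname(folds))
}

.baselineScorers <- c("cf", "rwr", "lpbni")

#' Run cross-validated evaluation of a predictor
#'
#' For every fold: the fold's test edges are zeroed in the interaction
#' matrix, all interaction-profile kernels (and hence similarities, resource
#' scores and weight matrices) are recomputed from the masked matrix, the
#' chosen method scores the network, and the scores of the test edges
#' (label 1) plus all full-network non-edges of the lncRNAs holding a test
#' edge in this fold (label 0) are pooled into the report. The PPI- and
#' expression-derived similarity components do not depend on the
#' interaction matrix and are computed once.
#'
#' Every matrix entering the scorer is asserted to carry 0 at the fold's
#' test-edge positions, so held-out information cannot reach the model.
#'
#' @param net a [BipartiteNetwork-class] (the full known network).
#' @param plan a fold plan from [makeFolds()].
#' @param method `"ibnra"`, `"cf"`, `"rwr"`, `"lpbni"`, or a function
#'   `f(Itrain, simP, simL)` returning a score matrix (for oracle and null
#'   scorers in tests).
#' @param ppi optional PPI score matrix ([readPPIScores()]).
#' @param expression optional expression matrix ([readExpression()]).
#' @param gamma,alpha recommender parameters; `alpha` may be a vector, in
#'   which case a named list of reports is returned (one per alpha; the
#'   weight matrix is alpha-independent and reused).
#' @param betaPrimeProtein,betaPrimeLncrna kernel bandwidth coefficients.
#' @param restartProb,rwrTol,rwrMaxIter RWR baseline parameters.
#' @param thresholdRule threshold rule for [binaryMetrics()].
#' @return An [EvalReport-class], or a named list of them for vector
#'   `alpha`.
#' @export
runCV <- function(net, plan, method = "ibnra", ppi = NULL,
                  expression = NULL, gamma = 0.5, alpha = -0.7,
                  betaPrimeProtein = 1, betaPrimeLncrna = 1,
                  restartProb = 0.5, rwrTol = 1e-8, rwrMaxIter = 1000L,
                  thresholdRule = "max_f1") {
  I <- interactionMatrix(net)
  isFun <- is.function(method)
  if (!isFun) method <- match.arg(method, c("ibnra", .baselineScorers))
  multiAlpha <- !isFun && method == "ibnra" && length(alpha) > 1L
  alphas <- if (multiAlpha) alpha else alpha[1]
  APn <- if (is.null(ppi)) NULL else normalizePPI(ppi)
  AL <- if (is.null(expression)) NULL else expressionSimilarity(expression)
  needSims <- isFun || method %in% c("ibnra", "cf", "rwr")

  nA <- length(alphas)
  pool <- replicate(nA, list(scores = list(), labels = list()),
    simplify = FALSE)
  perFold <- replicate(nA, numeric(0), simplify = FALSE)

  for (f in seq_along(plan$folds)) {
    test <- plan$folds[[f]]
    Itrain <- I
    Itrain[test] <- 0
    stopifnot(all(Itrain[test] == 0))
    simP <- simL <- NULL
    if (needSims) {
      KP <- gaussianProfileKernel(Itrain, "protein", betaPrimeProtein)
      simP <- if (is.null(APn)) KP else integrateProteinSimilarity(APn, KP)
      if (isFun || method == "ibnra") {
        KL <- gaussianProfileKernel(Itrain, "lncrna", betaPrimeLncrna)
        simL <- if (is.null(AL)) KL else integrateLncrnaSimilarity(AL, KL)
      }
    }
    scoreList <- if (isFun) {
      list(method(Itrain, simP, simL))
    } else if (method == "ibnra") {
      SP <- proteinSideScores(Itrain, simP)
      SL <- lncrnaSideScores(Itrain, simL)
      Sini <- initialScores(SP, SL, gamma)
      stopifnot(all(Sini[test] == 0)) # support confined to training edges
      W <- weightMatrix(Sini)
      lapply(alphas, function(a) {
        finalScores(eliminateSecondOrder(W, a), Sini)
      })
    } else if (method == "cf") {
      list(cfPredict(Itrain, simP))
    } else if (method == "rwr") {
      list(rwrPredict(Itrain, simP, restartProb, rwrTol, rwrMaxIter))
    } else {
      list(lpbniPredict(Itrain))
    }

    idx <- arrayInd(test, dim(I))
    for (j in unique(idx[, 2])) {
      posRows <- idx[idx[, 2] == j, 1]
      negRows <- which(I[, j] == 0)
      for (a in seq_len(nA)) {
        S <- scoreList[[a]]
        pool[[a]]$scores[[length(pool[[a]]$scores) + 1L]] <-
          c(S[posRows, j], S[negRows, j])
        pool[[a]]$labels[[length(pool[[a]]$labels) + 1L]] <-
          c(rep(1L, length(posRows)), rep(0L, length(negRows)))
      }
    }
    if (plan$scheme == "kfold") {
      for (a in seq_len(nA)) {
        S <- scoreList[[a]]
        fs <- fl <- numeric(0)
        for (j in unique(idx[, 2])) {
          posRows <- idx[idx[, 2] == j, 1]
          negRows <- which(I[, j] == 0)
          fs <- c(fs, S[posRows, j], S[negRows, j])
          fl <- c(fl, rep(1, length(posRows)), rep(0, length(negRows)))
        }
        if (length(unique(fl)) == 2) {
          perFold[[a]] <- c(perFold[[a]], rocAuc(fs, fl)$auc)
        }
      }
    }
  }

  methodName <- if (isFun) "custom" else method
  reports <- lapply(seq_len(nA), function(a) {
    sc <- unlist(pool[[a]]$scores, use.names = FALSE)
    lb <- as.integer(unlist(pool[[a]]$labels, use.names = FALSE))
    roc <- rocAuc(sc, lb)
    pr <- prAupr(sc, lb)
    m <- binaryMetrics(sc, lb, thresholdRule)
    new("EvalReport",
      method = methodName, scheme = plan$scheme, scores = sc, labels = lb,
      auc = roc$auc, aupr = pr$aupr,
      metrics = m[c("pre", "sen", "acc", "f1", "mcc")],
      threshold = m[["threshold"]], perFoldAuc = perFold[[a]],
      curves = list(roc = roc$curve, pr = pr$curve))
  })
  if (multiAlpha) {
    names(reports) <- as.character(alphas)
    reports
  } else {
    reports[[1]]
  }
}

#' AUC as a function of the elimination strength alpha
#'
#' Runs one cross-validation per the plan, rescoring every fold for each
#' `alpha` (the weight matrix is alpha-independent, so the sweep costs
#' little more than a single run), and tabulates AUC and AUPR per value.
#'
#' @param net,plan,... passed to [runCV()] with `method = "ibnra"`.
#' @param alphas vector of elimination strengths in `(-1, 0]`.
#' @return data.frame with columns alpha, auc, aupr.
#' @export
sweepAlpha <- function(net, plan, alphas = seq(-0.9, 0, by = 0.1), ...) {
  reports <- runCV(net, plan, method = "ibnra", alpha = alphas, ...)
  if (is(reports, "EvalReport")) reports <- list(reports)
  data.frame(
    alpha = alphas,
    auc = vapply(reports, auc, 0),
    aupr = vapply(reports, aupr, 0)
  )
}

#' Serialize an evaluation report
#'
#' Writes `<prefix>_summary.json` (scalar metrics and parameters) and
#' `<prefix>_roc.tsv` / `<prefix>_pr.tsv` (curve points) into `dir`.
#'
#' @param report an [EvalReport-class].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix; default the method name.
#' @return Invisibly, the summary file path.
#' @export
writeEvalReport <- function(report, dir, prefix = report@method) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(
    method = report@method, scheme = report@scheme,
    n_scores = length(report@scores), n_positive = sum(report@labels),
    auc = report@auc, aupr = report@aupr,
    metrics = as.list(report@metrics), threshold = report@threshold,
    per_fold_auc = report@perFoldAuc
  )
  jsonPath <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE, digits = NA)
  utils::write.table(report@curves$roc,
    file.path(dir, paste0(prefix, "_roc.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report@curves$pr,
    file.path(dir, paste0(prefix, "_pr.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(jsonPath)
}
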