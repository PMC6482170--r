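test_that("ROC area equals brute-force pair counting", {
  r <- rocAuc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(r$auc, 0.75)

  expect_equal(rocAuc(c(3, 2, 1), c(1, 1, 0))$auc, 1)

  withr::with_seed(61, {
    for (rep in 1:50) {
      n <- sample(10:40, 1)
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # many ties
      labels <- rbinom(n, 1, 0.4)
      if (length(unique(labels)) < 2) next
      expect_equal(rocAuc(scores, labels)$auc,
        aucPairOracle(scores, labels), tolerance = 1e-12)
    }
  })

  expect_error(rocAuc(1:3, c(1, 1, 1)), "single class")
})

test_that("ROC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(62, {
    scores <- runif(200)
    labels <- rbinom(200, 1, 0.3)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
      direction = "<")))
    expect_equal(rocAuc(scores, labels)$auc, ref, tolerance = 1e-10)
  })
})

test_that("PR area uses step-wise summation over thresholds", {
  expect_equal(prAupr(c(3, 2, 1), c(1, 1, 0))$aupr, 1)

  # all scores equal: single threshold, area = positive prevalence
  expect_equal(prAupr(rep(0.5, 10), c(rep(1, 3), rep(0, 7)))$aupr, 0.3)

  fourPoint <- prAupr(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(fourPoint$aupr,
    auprEnumOracle(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)))

  withr::with_seed(63, {
    for (rep in 1:30) {
      n <- sample(10:40, 1)
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
      labels <- rbinom(n, 1, 0.4)
      if (sum(labels) == 0) next
      expect_equal(prAupr(scores, labels)$aupr,
        auprEnumOracle(scores, labels), tolerance = 1e-12)
    }
  })

  expect_error(prAupr(1:3, c(0, 0, 0)), "no positive")
})

test_that("AUC and AUPR are invariant to monotone score transforms", {
  withr::with_seed(64, {
    scores <- runif(100)
    labels <- rbinom(100, 1, 0.3)
    trans <- exp(3 * scores) - 1
    expect_equal(rocAuc(trans, labels)$auc, rocAuc(scores, labels)$auc,
      tolerance = 1e-12)
    expect_equal(prAupr(trans, labels)$aupr, prAupr(scores, labels)$aupr,
      tolerance = 1e-12)
  })
})

test_that("threshold metrics match the confusion-count definitions", {
  # 3 positives scoring (0.9, 0.8, 0.3), 7 negatives with one at 0.7:
  # at threshold 0.5 -> TP=2, FP=1, FN=1, TN=6
  scores <- c(0.9, 0.8, 0.3, 0.7, rep(0.2, 6))
  labels <- c(1, 1, 1, rep(0, 7))
  m <- binaryMetrics(scores, labels, "fixed:0.5")
  expect_equal(attr(m, "counts"),
    c(tp = 2, fp = 1, fn = 1, tn = 6))
  expect_equal(m[["pre"]], 2 / 3)
  expect_equal(m[["sen"]], 2 / 3)
  expect_equal(m[["acc"]], 0.8)
  expect_equal(m[["f1"]], 2 / 3)
  expect_equal(m[["mcc"]], 11 / 21)

  # perfect classifier at the max-F1 threshold
  perfect <- binaryMetrics(c(0.9, 0.8, 0.1), c(1, 1, 0))
  expect_equal(unname(perfect[c("pre", "sen", "acc", "f1", "mcc")]),
    rep(1, 5))

  # all-negative predictions: degenerate precision flagged as 0
  allneg <- binaryMetrics(scores, labels, "fixed:2")
  expect_equal(allneg[["sen"]], 0)
  expect_equal(allneg[["pre"]], 0)
  expect_true("pre" %in% attr(allneg, "degenerate"))

  # youden rule picks the TPR - FPR maximizer: threshold 0.3 gives
  # TPR = 1, FPR = 1/7
  y <- binaryMetrics(scores, labels, "youden")
  expect_equal(y[["threshold"]], 0.3)
  expect_equal(y[["sen"]], 1)
})

test_that("fold plans partition the known edges reproducibly", {
  data <- simulateDataset(plantedBlockSpec(nProteins = 10, nLncrnas = 20,
    nBlocks = 2, seed = 65))
  net <- data$network
  nE <- sum(interactionMatrix(net))

  plan <- makeFolds(net, "kfold", k = 5, seed = 9)
  expect_length(plan$folds, 5)
  sizes <- lengths(plan$folds)
  expect_true(max(sizes) - min(sizes) <= 1)
  allIdx <- sort(unlist(plan$folds))
  expect_equal(allIdx, sort(which(interactionMatrix(net) == 1)))

  # ten edges, five folds of two
  small <- BipartiteNetwork(data.frame(
    lncrna = rep(paste0("l", 1:5), each = 2),
    protein = paste0("p", c(1:2, 2:3, 3:4, 4:5, c(5, 1)))))
  expect_equal(unname(lengths(makeFolds(small, "kfold", 5, 1)$folds)),
    rep(2L, 5))

  loo <- makeFolds(net, "loocv", seed = 9)
  expect_length(loo$folds, nE)
  expect_true(all(lengths(loo$folds) == 1))

  expect_identical(makeFolds(net, "kfold", 5, seed = 9),
    makeFolds(net, "kfold", 5, seed = 9))
  expect_error(makeFolds(small, "kfold", k = 99), "exceeds")
})

test_that("cross-validation recovers a planted oracle and rejects noise", {
  data <- simulateDataset(plantedBlockSpec(nProteins = 20, nLncrnas = 50,
    nBlocks = 2, seed = 66))
  net <- data$network
  plan <- makeFolds(net, "kfold", k = 5, seed = 66)

  # an oracle scoring straight from the ground-truth adjacency is perfect
  oracle <- function(Itrain, simP, simL) interactionMatrix(net)
  expect_equal(auc(runCV(net, plan, method = oracle)), 1)

  # uniform random scores sit at chance
  withr::with_seed(66, {
    noise <- function(Itrain, simP, simL) {
      matrix(runif(length(Itrain)), nrow(Itrain))
    }
    expect_lt(abs(auc(runCV(net, plan, method = noise)) - 0.5), 0.08)
  })
})

test_that("LOOCV tests every edge exactly once", {
  data <- simulateDataset(plantedBlockSpec(nProteins = 8, nLncrnas = 16,
    nBlocks = 2, seed = 67))
  net <- data$network
  plan <- makeFolds(net, "loocv", seed = 2)
  report <- runCV(net, plan, method = "lpbni")
  expect_equal(sum(report@labels), sum(interactionMatrix(net)))
})

test_that("fold models never see held-out edges", {
  data <- simulateDataset(plantedBlockSpec(nProteins = 12, nLncrnas = 24,
    nBlocks = 3, seed = 68))
  net <- data$network
  I <- interactionMatrix(net)
  plan <- makeFolds(net, "kfold", k = 4, seed = 68)
  APn <- normalizePPI(data$ppi)
  AL <- expressionSimilarity(data$expression)
  for (test in plan$folds) {
    Itrain <- I
    Itrain[test] <- 0
    expect_true(all(Itrain[test] == 0))
    sims <- list(
      simP = integrateProteinSimilarity(APn,
        gaussianProfileKernel(Itrain, "protein")),
      simL = integrateLncrnaSimilarity(AL,
        gaussianProfileKernel(Itrain, "lncrna")))
    SP <- proteinSideScores(Itrain, sims$simP)
    SL <- lncrnaSideScores(Itrain, sims$simL)
    Sini <- initialScores(SP, SL)
    # every matrix entering the scorer is 0 at the held-out positions
    expect_true(all(SP[test] == 0))
    expect_true(all(SL[test] == 0))
    expect_true(all(Sini[test] == 0))
  }
  # the production CV path runs the same assertions internally
  expect_s4_class(
    runCV(net, plan, "ibnra", ppi = data$ppi,
      expression = data$expression), "EvalReport")
})

test_that("evaluation reports serialize to JSON and TSV", {
  data <- simulateDataset(plantedBlockSpec(nProteins = 10, nLncrnas = 20,
    nBlocks = 2, seed = 69))
  plan <- makeFolds(data$network, "kfold", k = 3, seed = 69)
  report <- runCV(data$network, plan, "lpbni")
  dir <- withr::local_tempdir()
  writeEvalReport(report, dir)
  parsed <- jsonlite::read_json(file.path(dir, "lpbni_summary.json"))
  expect_equal(parsed$auc, auc(report))
  roc <- read.delim(file.path(dir, "lpbni_roc.tsv"))
  expect_true(all(c("fpr", "tpr") %in% names(roc)))
})
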