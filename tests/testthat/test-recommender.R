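test_that("protein-side resource scores match direct evaluation", {
  I <- rbind(c(1, 1), c(0, 1))
  expect_equal(proteinSideScores(I, diag(2)), I)

  simP <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  SP <- proteinSideScores(I, simP)
  expect_equal(SP[1, 1], 2 / 3)
  expect_equal(SP[2, 1], 0) # zero outside the known-interaction support
  expect_true(all(SP >= 0 & SP <= 1))
})

test_that("lncRNA-side resource scores match direct evaluation", {
  I <- rbind(c(1, 1), c(0, 1))
  expect_equal(lncrnaSideScores(I, diag(2)), I)

  simL <- matrix(c(1, 0.2, 0.2, 1), 2, 2)
  SL <- lncrnaSideScores(I, simL)
  expect_equal(SL[1, 1], (1 + 0.2) / 1.2)
  expect_equal(SL[2, 1], 0)
  expect_true(all(SL >= 0 & SL <= 1))
})

test_that("initial scores interpolate between the two sides", {
  SP <- matrix(0.4, 2, 2)
  SL <- matrix(0.6, 2, 2)
  expect_equal(initialScores(SP, SL, gamma = 1), SP)
  expect_equal(initialScores(SP, SL, gamma = 0), SL)
  expect_equal(initialScores(SP, SL, 0.5), matrix(0.5, 2, 2))
  expect_error(initialScores(SP, SL, 1.5), "gamma")
  expect_error(initialScores(SP, SL, -0.1), "gamma")
})

test_that("weight matrix reproduces the hand-traced fixture", {
  Sini <- rbind(c(1, 1), c(0, 1))
  W <- weightMatrix(Sini)
  expect_equal(unname(W), rbind(c(0.75, 0.5), c(0.25, 0.5)),
    tolerance = 1e-12)

  # each protein owning one exclusive lncRNA with unit score: W = identity
  expect_equal(unname(weightMatrix(diag(3))), diag(3))
})

test_that("weight matrix columns over positive-degree proteins sum to one", {
  withr::with_seed(41, {
    for (rep in 1:20) {
      Sini <- randomSini(sample(2:8, 1), sample(2:8, 1))
      W <- weightMatrix(Sini)
      dp <- rowSums(Sini)
      if (any(dp > 0)) {
        expect_equal(unname(colSums(W)[dp > 0]),
          rep(1, sum(dp > 0)), tolerance = 1e-10)
      }
      expect_true(all(colSums(W)[dp == 0] == 0))
    }
  })
})

test_that("iterative two-round allocation agrees with the matrix form", {
  Sini <- rbind(c(1, 1), c(0, 1))
  expect_equal(unname(twoRoundAllocation(Sini, 1)), c(0.75, 0.25))

  withr::with_seed(42, {
    for (rep in 1:10) {
      Sini <- randomSini(sample(2:8, 1), sample(2:8, 1))
      W <- weightMatrix(Sini)
      for (k in seq_len(ncol(Sini))) {
        expect_equal(unname(twoRoundAllocation(Sini, k)),
          unname((W %*% Sini)[, k]), tolerance = 1e-10)
      }
      # conservation when every degree is positive
      if (all(rowSums(Sini) > 0) && all(colSums(Sini) > 0)) {
        for (k in seq_len(ncol(Sini))) {
          expect_equal(sum(twoRoundAllocation(Sini, k)), sum(Sini[, k]),
            tolerance = 1e-10)
        }
      }
    }
  })
})

test_that("second-order elimination matches hand matrix algebra", {
  W <- rbind(c(0.75, 0.5), c(0.25, 0.5))
  expect_equal(eliminateSecondOrder(W, 0), W)
  Wp <- eliminateSecondOrder(W, -0.7)
  expect_equal(Wp, rbind(c(0.26875, 0.0625), c(0.03125, 0.2375)),
    tolerance = 1e-12)
  expect_equal(colSums(Wp), rep(1 - 0.7, 2), tolerance = 1e-12)
  expect_error(eliminateSecondOrder(W, -1), "alpha")
  expect_error(eliminateSecondOrder(W, 0.1), "alpha")
})

test_that("final score mass scales by 1 + alpha when degrees are positive", {
  withr::with_seed(43, {
    for (rep in 1:10) {
      Sini <- randomSini(5, 7, density = 1)
      W <- weightMatrix(Sini)
      for (a in c(0, -0.3, -0.7)) {
        Sfin <- finalScores(eliminateSecondOrder(W, a), Sini)
        expect_equal(sum(Sfin), (1 + a) * sum(Sini), tolerance = 1e-10)
        expect_true(all(is.finite(Sfin)))
      }
    }
  })
  expect_error(finalScores(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("identity similarities reduce the recommender to classical ProbS", {
  withr::with_seed(44, {
    for (rep in 1:10) {
      I <- randomBinaryI(sample(3:6, 1), sample(3:6, 1), p = 0.5)
      simP <- diag(nrow(I))
      simL <- diag(ncol(I))
      SP <- proteinSideScores(I, simP)
      SL <- lncrnaSideScores(I, simL)
      Sini <- initialScores(SP, SL, 0.5)
      expect_equal(unname(Sini), unname(I))
      expect_equal(unname(weightMatrix(Sini)), probsOracle(I),
        tolerance = 1e-12)
    }
  })
})

test_that("scores are continuous in alpha and exact at alpha = 0", {
  I <- withr::with_seed(45, randomBinaryI(5, 8, 0.5))
  Sini <- I
  W <- weightMatrix(Sini)
  alphas <- seq(-0.9, 0, by = 0.05)
  runs <- lapply(alphas, function(a) {
    finalScores(eliminateSecondOrder(W, a), Sini)
  })
  steps <- vapply(seq_along(runs)[-1], function(i) {
    max(abs(runs[[i]] - runs[[i - 1]]))
  }, 0)
  expect_true(all(steps < 0.05 * max(abs(W %*% Sini)) + 0.05))
  expect_identical(runs[[length(runs)]], W %*% Sini)
})

test_that("permuting protein ids permutes prediction rows identically", {
  data <- simulateDataset(plantedBlockSpec(nProteins = 10, nLncrnas = 25,
    nBlocks = 2, seed = 46))
  I <- interactionMatrix(data$network)
  scores <- ibnraScores(I, data$ppi, data$expression)
  perm <- withr::with_seed(46, sample(nrow(I)))
  scoresPerm <- ibnraScores(I[perm, ], data$ppi[perm, perm],
    data$expression)
  expect_equal(unname(scoresPerm), unname(scores[perm, ]),
    tolerance = 1e-12)
})

test_that("candidate ranking sorts, excludes, and breaks ties by id", {
  net <- BipartiteNetwork(data.frame(
    lncrna = c("l1", "l1", "l2"),
    protein = c("p1", "p2", "p3")
  ))
  scores <- matrix(c(0.1, 0.9, 0.5, 0.3, 0.3, 0.2), 3, 2,
    dimnames = list(proteinIds(net), lncrnaIds(net)))

  ranked <- rankCandidates(scores, net, "l1", excludeKnown = FALSE)
  expect_equal(ranked$protein, c("p2", "p3", "p1"))
  expect_equal(ranked$rank, 1:3)

  novel <- rankCandidates(scores, net, "l1", excludeKnown = TRUE)
  expect_false(any(c("p1", "p2") %in% novel$protein))

  # tie between p1 (0.3) and p2 (0.3) on l2: lexicographic order wins
  tiebreak <- rankCandidates(scores, net, "l2", excludeKnown = FALSE)
  expect_equal(tiebreak$protein, c("p1", "p2", "p3"))
})
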