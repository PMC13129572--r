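test_that("presets pin the fitting hyperparameters", {
  m <- boostConfig("moderate")
  expect_equal(m@learningRate, 0.3)
  expect_equal(m@maxDepth, 6L)
  expect_equal(m@earlyStoppingRounds, 3L)
  u <- boostConfig("underfit")
  expect_equal(u@learningRate, 0.1)
  expect_equal(u@maxDepth, 3L)
  o <- boostConfig("overfit")
  expect_true(is.na(o@earlyStoppingRounds))
  expect_equal(o@maxRounds, 50L)
  expect_error(boostConfig("moderate", learningRate = -1), "learningRate")
})

test_that("constant response yields a constant model", {
  X <- matrix(sample(c(-1, 0, 1), 120, TRUE), 40, 3)
  y <- rep(2.5, 40)
  ens <- fitEnsemble(X, y, validX = X[1:10, ], validY = y[1:10],
                     config = boostConfig("moderate"))
  expect_equal(predict(ens, X), rep(2.5, 40), tolerance = 1e-6)
})

test_that("a single informative marker is fitted nearly perfectly", {
  withr::with_seed(21, {
    X <- matrix(sample(c(-1, 0, 1), 300, TRUE), 100, 3)
    y <- as.numeric(X[, 2])
    tr <- 1:70
    ens <- fitEnsemble(X[tr, ], y[tr], validX = X[-tr, ], validY = y[-tr],
                       config = boostConfig("moderate"))
    r2 <- 1 - mean((predict(ens, X[tr, ]) - y[tr])^2) / var(y[tr])
    expect_gt(r2, 0.9)
  })
})

test_that("the overfit preset boosts exactly 50 rounds", {
  withr::with_seed(22, {
    X <- matrix(rnorm(200), 50, 4)
    y <- rnorm(50)
    ens <- fitEnsemble(X, y, config = boostConfig("overfit"))
    expect_equal(nTrees(ens), 50L)
  })
})

test_that("early stopping requires a validation set", {
  X <- matrix(rnorm(100), 25, 4)
  expect_error(fitEnsemble(X, rnorm(25), config = boostConfig("moderate")),
               "validation")
  expect_error(fitEnsemble(X[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("extracted structure reproduces the library's predictions", {
  for (s in 1:5) {
    fx <- randomFittedEnsemble(400 + s, n = 80, p = 6, depth = 4,
                               rounds = 5)
    Xn <- fx$X
    colnames(Xn) <- fx$ens@featureNames
    expect_lt(max(abs(predict(fx$ens, fx$X) -
                      as.numeric(predict(fx$ens@booster, Xn)))), 1e-6)
  }
  # early-stopped fit: the dump is truncated to the trees predict() uses
  withr::with_seed(31, {
    X <- matrix(sample(c(-1, 0, 1), 600, TRUE), 100, 6)
    y <- X[, 1] + 0.5 * X[, 2] * X[, 3] + rnorm(100, 0, 0.3)
    tr <- 1:70
    ens <- fitEnsemble(X[tr, ], y[tr], validX = X[-tr, ], validY = y[-tr],
                       config = boostConfig("moderate"))
    Xn <- X
    colnames(Xn) <- ens@featureNames
    expect_lt(max(abs(predict(ens, X) -
                      as.numeric(predict(ens@booster, Xn)))), 1e-6)
  })
})

test_that("tree dumps conserve cover and carry a sensible base", {
  fx <- randomFittedEnsemble(77, n = 90, p = 5)
  for (tr in fx$ens@trees) {
    internal <- which(!is.na(tr$feature))
    expect_equal(tr$cover[internal],
                 tr$cover[tr$yes[internal]] + tr$cover[tr$no[internal]])
    expect_equal(tr$cover[1], 90)   # root cover = training weight
  }
  expect_equal(basePrediction(fx$ens), mean(fx$y), tolerance = 1e-6)
  # stump dump: one tree, three nodes
  withr::with_seed(5, {
    X <- matrix(sample(c(-1, 1), 50, TRUE), 50, 1)
    st <- fitEnsemble(X, as.numeric(X[, 1]),
                      config = boostConfig("overfit", maxDepth = 1,
                                           maxRounds = 1))
    expect_equal(nTrees(st), 1L)
    expect_equal(nrow(st@trees[[1]]), 3L)
  })
})

test_that("training fit quality orders overfit >= moderate >= underfit", {
  withr::with_seed(91, {
    sc <- simulateScenario(1, seed = 911)
    y <- phenotypes(sc$phen)
    tr <- 1:150
    r2 <- vapply(c("underfit", "moderate", "overfit"), function(p) {
      ens <- fitEnsemble(sc$X[tr, ], y[tr], validX = sc$X[-tr, ],
                         validY = y[-tr], config = boostConfig(p))
      1 - mean((predict(ens, sc$X[tr, ]) - y[tr])^2) / var(y[tr])
    }, 0)
    expect_true(r2["overfit"] >= r2["moderate"] - 1e-8)
    expect_true(r2["moderate"] >= r2["underfit"] - 1e-8)
  })
})
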