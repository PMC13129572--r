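# Frozen oracle values for the stump fixtures were derived by hand from the
# subset-enumeration definition: on a balanced stump over feature 1 only
# that feature changes any conditional expectation, so phi_1 equals the
# prediction minus the cover-weighted mean and every other phi is 0.

test_that("conditional expectations route and average as defined", {
  ens <- handEnsemble(list(stumpTree(1L, 0, -1, 1)), nFeatures = 3)
  x <- c(1, 0, 0)
  expect_equal(conditionalExpectation(ens, x, 1:3), predict(ens, x))
  expect_equal(conditionalExpectation(ens, x, integer(0)), 0)  # balanced
  expect_equal(conditionalExpectation(ens, x, S = 1L), 1)
  # unbalanced covers weight the unconditioned average
  ens2 <- handEnsemble(list(stumpTree(1L, 0, -1, 1, cYes = 75, cNo = 25)),
                       nFeatures = 2)
  expect_equal(conditionalExpectation(ens2, c(1, 0), integer(0)),
               0.25 * 1 + 0.75 * (-1))
})

test_that("exact Shapley values on stumps match hand enumeration", {
  ens <- handEnsemble(list(stumpTree(1L, 0, -1, 1)), nFeatures = 3,
                      base = 0.5)
  sv <- shapleyExact(ens, c(1, 0, 0))
  expect_equal(sv$phi, c(1, 0, 0))
  expect_equal(sv$baseValue, 0.5)
  # additivity over trees: two stumps on different features
  ens2 <- handEnsemble(list(stumpTree(1L, 0, -1, 1),
                            stumpTree(2L, 0, -2, 2)), nFeatures = 3)
  sv2 <- shapleyExact(ens2, c(1, -1, 0))
  expect_equal(sv2$phi, c(1, -2, 0))
  expect_error(shapleyExact(handEnsemble(list(), 20), rep(0, 20)),
               "guard")
})

test_that("XOR interaction is pure: zero mains, nonzero pair value", {
  ens <- handEnsemble(list(xorTree()), nFeatures = 3)
  for (x in list(c(1, 1, 0), c(-1, 1, 0), c(1, -1, 0))) {
    si <- shapleyInteractionsExact(ens, x)
    expect_equal(si$phiMatrix[1, 1], 0, tolerance = 1e-12)
    expect_equal(si$phiMatrix[2, 2], 0, tolerance = 1e-12)
    expect_gt(abs(si$phiMatrix[1, 2]), 0.1)
    expect_equal(si$phiMatrix, t(si$phiMatrix))
    # feature 3 never splits: zero row and column (missingness)
    expect_equal(si$phiMatrix[3, ], rep(0, 3))
    expect_equal(si$phi[3], 0)
  }
  # single-feature ensemble has no off-diagonal interaction
  st <- handEnsemble(list(stumpTree(1L, 0, -1, 1)), nFeatures = 2)
  m <- shapleyInteractionsExact(st, c(1, 1))$phiMatrix
  expect_equal(m[1, 2], 0)
})

test_that("fast Tree SHAP equals the enumeration oracle", {
  for (s in 1:8) {
    fx <- randomFittedEnsemble(500 + s)
    Xt <- fx$X[1:3, , drop = FALSE]
    fast <- treeShap(fx$ens, Xt, method = "r")
    del <- treeShap(fx$ens, Xt, method = "booster")
    for (r in 1:3) {
      ex <- shapleyExact(fx$ens, Xt[r, ])
      expect_equal(fast$phi[r, ], ex$phi, tolerance = 1e-6)
      expect_equal(del$phi[r, ], ex$phi, tolerance = 1e-6)
      # local accuracy
      expect_equal(ex$baseValue + sum(ex$phi),
                   predict(fx$ens, Xt[r, , drop = FALSE]),
                   tolerance = 1e-6)
    }
  }
})

test_that("fast interaction values equal the oracle and decompose phi", {
  for (s in 1:5) {
    fx <- randomFittedEnsemble(600 + s, rounds = 2)
    x <- fx$X[1, , drop = FALSE]
    ex <- shapleyInteractionsExact(fx$ens, x[1, ])
    fi <- treeShapInteractions(fx$ens, x, method = "r")
    bi <- treeShapInteractions(fx$ens, x, method = "booster")
    expect_equal(fi$phiArray[1, , ], ex$phiMatrix, tolerance = 1e-6)
    expect_equal(bi$phiArray[1, , ], ex$phiMatrix, tolerance = 1e-6)
    # row sums give back the SHAP values; matrix total = pred - base
    expect_equal(rowSums(ex$phiMatrix), ex$phi, tolerance = 1e-9)
    expect_equal(sum(fi$phiArray[1, , ]),
                 predict(fx$ens, x) - fi$baseValue[1], tolerance = 1e-6)
  }
})

test_that("constant ensembles attribute nothing", {
  leafOnly <- data.frame(feature = NA_integer_, split = NA_real_,
                         yes = NA_integer_, no = NA_integer_,
                         value = 3, cover = 100)
  ens <- handEnsemble(list(leafOnly), nFeatures = 4, base = 1)
  ts <- treeShap(ens, matrix(0, 2, 4), method = "r")
  expect_equal(ts$phi, matrix(0, 2, 4))
  expect_equal(ts$baseValue, c(4, 4))
})
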