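test_that("marker labels honour the window edge and chromosome bounds", {
  map <- new("GeneticMap",
             chromosomes = data.frame(chrom = 1:2, length_cM = c(100, 100)),
             markers = data.frame(
               marker = c("a", "b", "c", "d", "e"),
               chrom = c(1L, 1L, 1L, 1L, 2L),
               pos_cM = c(30, 40, 40.1, 95, 30)))
  lay <- layoutAt(chrom = c(1L, 1L, 1L, 2L, 2L),
                  pos = c(30, 30, 30, 90, 90),
                  pairs = c(1, 2, 1, 3, 2, 3, 4, 5, 1, 4))
  lab <- labelMarkers(map, lay)
  expect_true(lab[["a"]])    # exactly at a QTL
  expect_true(lab[["b"]])    # 10 cM away: boundary is inclusive
  expect_false(lab[["c"]])   # 10.1 cM away
  expect_false(lab[["d"]])   # near a QTL position but wrong chromosome? no:
                             # 95 vs QTL at 90 on chrom 2 -> chrom 1 marker
  expect_false(lab[["e"]])   # 60 cM from chrom-2 QTL
})

test_that("pair labels need two distinct interacting QTLs", {
  map <- new("GeneticMap",
             chromosomes = data.frame(chrom = 1:2, length_cM = c(100, 100)),
             markers = data.frame(marker = c("a1", "a2", "b1", "far"),
                                  chrom = c(1L, 1L, 2L, 2L),
                                  pos_cM = c(18, 22, 50, 95)))
  # QTLs: q1 at (1, 20), q2 at (2, 50); only pair (1,2) interacts
  lay <- layoutAt(chrom = c(1L, 2L, 1L, 1L, 2L),
                  pos = c(20, 50, 80, 99, 99),
                  pairs = c(1, 2, 3, 4, 3, 5, 4, 5, 2, 3))
  lp <- labelPairs(map, lay)
  key <- paste(lp$markerA, lp$markerB)
  expect_true(lp$positive[key == "a1 b1"])
  expect_true(lp$positive[key == "a2 b1"])
  # both markers tag the same single QTL: negative
  expect_false(lp$positive[key == "a1 a2"])
  expect_false(lp$positive[key == "a1 far"])
  expect_equal(nrow(lp), choose(4, 2))
})

test_that("pair labels match a brute-force double loop", {
  withr::with_seed(10, {
    map <- makeMap(4, 120, 8)
    lay <- placeQtls(makeMap(5, 120, 4, seed = 1), 1, seed = 2)
    # reuse 4-chromosome map: rebuild a valid 5-QTL layout on it
    lay <- new("QTLLayout",
               qtl = data.frame(chrom = sample(1:4, 5, TRUE),
                                pos_cM = runif(5, 0, 120)),
               pairs = lay@pairs)
  })
  win <- 10
  lp <- labelPairs(map, lay, win)
  got <- setNames(lp$positive, paste(lp$markerA, lp$markerB))
  mk <- markerInfo(map)
  tag <- function(m, q) mk$chrom[m] == lay@qtl$chrom[q] &
    abs(mk$pos_cM[m] - lay@qtl$pos_cM[q]) <= win
  nBad <- 0L
  for (a in 1:(nrow(mk) - 1)) for (b in (a + 1):nrow(mk)) {
    want <- FALSE
    for (k in 1:nrow(lay@pairs)) {
      q <- lay@pairs[k, 1]; r <- lay@pairs[k, 2]
      want <- want || (tag(a, q) && tag(b, r)) || (tag(a, r) && tag(b, q))
    }
    if (!identical(unname(got[[paste(mk$marker[a], mk$marker[b])]]), want))
      nBad <- nBad + 1L
  }
  expect_identical(nBad, 0L)
  expect_equal(nrow(lp), choose(nrow(mk), 2))
})

test_that("AUC equals the all-pairs comparison probability", {
  # frozen example: 3 of the 4 positive-negative comparisons are wins
  r <- rocAuc(c(0.9, 0.8, 0.3, 0.1), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(auc(r), 0.75)
  expect_equal(auc(rocAuc(c(5, 4, 3, 1), c(TRUE, TRUE, FALSE, FALSE))), 1)
  expect_equal(auc(rocAuc(rep(2, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE,
                                       FALSE))), 0.5)
  # property: agreement with the brute-force U-statistic, ties included
  for (s in 1:20) {
    withr::with_seed(700 + s, {
      sc <- sample(seq(0, 1, by = 0.1), 30, TRUE)
      lb <- sample(c(TRUE, FALSE), 30, TRUE, prob = c(0.3, 0.7))
    })
    if (!any(lb) || all(lb)) next
    expect_equal(auc(rocAuc(sc, lb)), bruteAuc(sc, lb), tolerance = 1e-12)
  }
  expect_error(rocAuc(1:3, c(TRUE, TRUE, TRUE)), "undefined")
  # curve is monotone
  cv <- rocCurve(rocAuc(runif(20), rep(c(TRUE, FALSE), 10)))
  expect_false(is.unsorted(cv$fpr))
  expect_false(is.unsorted(cv$tpr))
})

test_that("the scenario harness chains simulation, mapping and scoring", {
  tab <- runScenario(1, nReps = 1, seed = 5, nBoot = 2)
  expect_equal(nrow(tab), 1L)
  expect_true(tab$aucMain > 0 && tab$aucMain < 1)
  expect_true(tab$aucInteraction > 0 && tab$aucInteraction < 1)
  expect_true(tab$realizedVA > 0)
  # reproducible end to end
  tab2 <- runScenario(1, nReps = 1, seed = 5, nBoot = 2)
  expect_identical(tab, tab2)
})

test_that("dependency data exposes one row per line with coded genotypes", {
  withr::with_seed(8, {
    map <- makeMap(2, 100, 4)
    pop <- simulateF2(map, NULL, 40)
    X <- codeGenotypes(markerGenotypes(pop), "additive")
    y <- 3 * X[, 1] * X[, 5] + rnorm(40, 0, 0.3)
  })
  res <- runShapXgb(X, y, nBoot = 5, seed = 8)
  dd <- dependencyData(res, X, colnames(X)[1], colnames(X)[5])
  expect_equal(nrow(dd), 40L)
  expect_equal(anyDuplicated(dd$lineId), 0L)
  expect_true(all(dd$genoA %in% c(-1, 0, 1)))
  # planted sign flip: the interaction value trend in genoA inverts with genoB
  upp <- dd$genoB == 1 & dd$genoA != 0
  dwn <- dd$genoB == -1 & dd$genoA != 0
  if (sum(upp) > 5 && sum(dwn) > 5) {
    expect_gt(cor(dd$genoA[upp], dd$interactionValue[upp]), 0)
    expect_lt(cor(dd$genoA[dwn], dd$interactionValue[dwn]), 0)
  }
  expect_error(dependencyData(res, X, "m1", "m1"), "distinct")
  expect_error(dependencyData(res, X, "nope", colnames(X)[1]), "unknown")
})
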