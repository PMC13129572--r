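test_that("maps have the requested layout and uniform marker positions", {
  map <- makeMap(8, 120, 20, seed = 1)
  expect_equal(nMarkers(map), 160L)
  mk <- markerInfo(map)
  expect_true(all(mk$pos_cM >= 0 & mk$pos_cM <= 120))
  # sorted within chromosomes
  for (ch in 1:8)
    expect_false(is.unsorted(mk$pos_cM[mk$chrom == ch]))

  tiny <- makeMap(1, 120, 2, seed = 2)
  expect_equal(nMarkers(tiny), 2L)
  expect_false(is.unsorted(markerInfo(tiny)$pos_cM))

  # goodness of fit of pooled positions against Uniform(0, 120)
  pos <- unlist(lapply(1:50, function(s)
    markerInfo(makeMap(1, 120, 200, seed = 100 + s))$pos_cM))
  cnt <- table(cut(pos, breaks = seq(0, 120, by = 12)))
  gof <- chisq.test(cnt, p = rep(0.1, 10))
  expect_gt(gof$p.value, 1e-4)

  expect_error(makeMap(0, 120, 20), "nChr")
  expect_error(makeMap(2, 120, 1), "markersPerChr")
})

test_that("maps and crosses are reproducible from their seed", {
  m1 <- makeMap(5, 120, 10, seed = 7)
  m2 <- makeMap(5, 120, 10, seed = 7)
  expect_identical(markerInfo(m1), markerInfo(m2))
  lay <- placeQtls(m1, 1, seed = 8)
  p1 <- simulateF2(m1, lay, 50, seed = 9)
  p2 <- simulateF2(m1, lay, 50, seed = 9)
  expect_identical(genotypes(p1), genotypes(p2))
  r1 <- simulateRil(m1, lay, 50, seed = 10)
  r2 <- simulateRil(m1, lay, 50, seed = 10)
  expect_identical(genotypes(r1), genotypes(r2))
})

test_that("random QTL layouts use 5 chromosomes and 5 interacting pairs", {
  map <- makeMap(8, 120, 20, seed = 3)
  lay <- placeQtls(map, 1, seed = 4)
  q <- qtlPositions(lay)
  expect_equal(nrow(q), 5L)
  expect_equal(length(unique(q$chrom)), 5L)
  expect_equal(nrow(interactingPairs(lay)), 5L)
  expect_error(placeQtls(map, 10), "scenario")
  expect_error(placeQtls(makeMap(3, 120, 5, seed = 1), 1), "chromosomes")
})

test_that("scenario 9 layouts are linked islands with exact 30 cM spacing", {
  map <- makeMap(8, 120, 20, seed = 5)
  for (s in 1:10) {
    lay <- placeQtls(map, 9, seed = s)
    q <- qtlPositions(lay)
    triple <- q[1:3, ]
    expect_equal(length(unique(triple$chrom)), 1L)
    expect_equal(sort(dist(triple$pos_cM)[1:3]), c(30, 30, 60))
    duo <- q[4:5, ]
    expect_equal(length(unique(duo$chrom)), 1L)
    expect_false(duo$chrom[1] == triple$chrom[1])
    expect_equal(abs(diff(duo$pos_cM)), 30)
    pr <- interactingPairs(lay)
    expect_equal(nrow(pr), 5L)
    # 3 within-triple, 1 within-duo, exactly 1 cross pair
    side <- function(i) ifelse(i <= 3, "A", "B")
    kinds <- paste0(side(pr[, 1]), side(pr[, 2]))
    expect_equal(sum(kinds == "AA"), 3L)
    expect_equal(sum(kinds == "BB"), 1L)
    expect_equal(sum(kinds == "AB"), 1L)
  }
})

test_that("F2 genotypes segregate 1:2:1 and obey exact linkage at 0 cM", {
  map <- tinyMap(pos = c(20, 20, 80))
  pop <- simulateF2(map, NULL, 4000, seed = 6)
  g <- genotypes(pop)
  frq <- as.vector(table(g[, 1]) / nrow(g))
  expect_equal(frq, c(0.25, 0.5, 0.25), tolerance = 0.1)
  # two loci at identical positions carry identical dosages
  expect_identical(g[, 1], g[, 2])
})

test_that("F2 recombination matches the Haldane map function", {
  map <- new("GeneticMap",
             chromosomes = data.frame(chrom = 1L, length_cM = 120),
             markers = data.frame(marker = c("a", "b"), chrom = 1L,
                                  pos_cM = c(30, 40)))
  g <- simulateGametes(map, 20000, seed = 7)
  rhat <- mean(g[, 1] != g[, 2])
  r <- haldane(10)
  expect_equal(r, (1 - exp(-0.2)) / 2)
  expect_lt(abs(rhat - r), 3 * sqrt(r * (1 - r) / 20000))
})

test_that("RIL lines are homozygous, balanced, and switch at 2r/(1+2r)", {
  expect_equal(rilSwitchProb(0), 0)
  expect_equal(rilSwitchProb(0.5), 0.5)
  map <- tinyMap(pos = c(10, 40), len = 100)
  ril <- simulateRil(map, NULL, 20000, seed = 8)
  g <- genotypes(ril)
  expect_true(all(g %in% c(0L, 2L)))
  expect_equal(mean(g[, 1] == 2L), 0.5, tolerance = 0.02)
  rs <- rilSwitchProb(haldane(30))
  sh <- mean(g[, 1] != g[, 2])
  expect_lt(abs(sh - rs), 3 * sqrt(rs * (1 - rs) / 20000))
})

test_that("splitMarkers partitions columns losslessly", {
  map <- makeMap(8, 120, 20, seed = 9)
  lay <- placeQtls(map, 1, seed = 10)
  pop <- simulateF2(map, lay, 30, seed = 11)
  parts <- splitMarkers(pop)
  expect_equal(ncol(parts$markers), 160L)
  expect_equal(ncol(parts$qtl), 5L)
  # reassembling in locus order reproduces the genotype matrix
  lo <- locusInfo(pop)
  rebuilt <- matrix(0L, nrow(genotypes(pop)), nrow(lo))
  rebuilt[, which(lo$is_marker)] <- parts$markers
  rebuilt[, which(!lo$is_marker)] <- parts$qtl
  expect_equal(unname(rebuilt), unname(genotypes(pop)))

  noQtl <- simulateF2(map, NULL, 10, seed = 12)
  expect_equal(ncol(splitMarkers(noQtl)$qtl), 0L)
})
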