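# Shared fixtures: hand-built tree ensembles and tiny maps.

# A single split node with two leaves (rows: root, yes-leaf, no-leaf).
stumpTree <- function(feature, split, vYes, vNo, cYes = 50, cNo = 50) {
  data.frame(feature = c(as.integer(feature), NA, NA),
             split = c(split, NA, NA),
             yes = c(2L, NA, NA), no = c(3L, NA, NA),
             value = c(NA, vYes, vNo),
             cover = c(cYes + cNo, cYes, cNo))
}

# Depth-2 XOR-style tree on features f1, f2 with thresholds at 0:
# sign of the leaf equals the product of the two +/-1 codings, covers equal,
# so both main effects vanish by symmetry and only the interaction remains.
xorTree <- function(f1 = 1L, f2 = 2L, amp = 1) {
  data.frame(
    feature = c(f1, f2, f2, NA, NA, NA, NA),
    split = c(0, 0, 0, NA, NA, NA, NA),
    yes = c(2L, 4L, 6L, NA, NA, NA, NA),
    no = c(3L, 5L, 7L, NA, NA, NA, NA),
    value = c(NA, NA, NA, amp, -amp, -amp, amp),
    cover = c(100, 50, 50, 25, 25, 25, 25))
}

handEnsemble <- function(trees, nFeatures, base = 0) {
  new("TreeEnsemble", trees = trees, basePrediction = base,
      nFeatures = as.integer(nFeatures),
      featureNames = sprintf("f%d", seq_len(nFeatures)), booster = NULL)
}

# Random small fitted ensemble for oracle-equivalence sweeps.
randomFittedEnsemble <- function(seed, n = 60L, p = 5L, depth = 3L,
                                 rounds = 3L) {
  withr::with_seed(seed, {
    X <- matrix(sample(c(-1, 0, 1), n * p, TRUE), n, p)
    y <- stats::rnorm(n) + X[, 1] * X[, 2] + 0.5 * X[, min(3L, p)]
    list(ens = fitEnsemble(X, y,
                           config = boostConfig("overfit", maxDepth = depth,
                                                maxRounds = rounds)),
         X = X, y = y)
  })
}

# Two-marker, one-chromosome toy map.
tinyMap <- function(pos = c(10, 50), len = 100) {
  new("GeneticMap",
      chromosomes = data.frame(chrom = 1L, length_cM = len),
      markers = data.frame(marker = sprintf("m%d", seq_along(pos)),
                           chrom = 1L, pos_cM = pos))
}

# Layout builder for label tests (pads/truncates to the 5-QTL invariant is
# not wanted here, so build directly with validity off where needed).
layoutAt <- function(chrom, pos, pairs) {
  new("QTLLayout", qtl = data.frame(chrom = chrom, pos_cM = pos),
      pairs = matrix(as.integer(pairs), ncol = 2, byrow = TRUE,
                     dimnames = list(NULL, c("q1", "q2"))))
}

# Brute-force AUC: all positive-negative comparisons, ties half credit.
bruteAuc <- function(scores, labels) {
  sp <- scores[labels]
  sn <- scores[!labels]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
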