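#' Bootstrap SHAP-assisted gradient-boosting QTL scan
#'
#' The core mapping algorithm. For each of `nBoot` replicates: draw a
#' bootstrap sample of lines (in-bag = training set, out-of-bag = held-out
#' set for early stopping), fit a boosted tree ensemble, and compute SHAP
#' values and SHAP interaction values for all original lines under that
#' model. The per-line values are averaged across replicates, then global
#' importance scores are formed as means over lines of absolute values:
#' the compound score `mean |phi_i|` per marker, the pure score
#' `mean |phi_ii|` per marker, and the global interaction score
#' `mean |2 phi_ij|` per marker pair.
#'
#' Bootstrap replicates with an empty out-of-bag set are redrawn (counted
#' in the result); replicate seeds are derived deterministically from the
#' master seed as `seed + replicate`.
#'
#' @param X numeric n x p matrix of coded marker genotypes (n >= 20,
#'   p >= 2).
#' @param y numeric phenotype vector (finite).
#' @param config a [BoostConfig-class]; the default is the moderate preset.
#' @param nBoot number of bootstrap replicates (default 100).
#' @param seed master integer seed.
#' @param interactions compute SHAP interaction values as well (the n x p x
#'   p averaging dominates run time and memory; disable when only marker
#'   main scores are needed).
#' @return a [ShapXgbResult-class].
#' @examples
#' sc <- simulateScenario(1, seed = 1)
#' \donttest{
#' res <- runShapXgb(sc$X, phenotypes(sc$phen), nBoot = 5, seed = 1)
#' head(sort(scoreMode(res, "compound"), decreasing = TRUE))
#' }
#' @export
runShapXgb <- function(X, y, config = boostConfig(), nBoot = 100L,
                       seed = NULL, interactions = TRUE) {
  n <- nrow(X)
  p <- ncol(X)
  stopIf(n < 20L, "need at least 20 lines")
  stopIf(p < 2L, "need at least 2 markers")
  stopIf(length(y) != n, "y must match the rows of X")
  stopIf(!all(is.finite(y)), "non-finite phenotype values")
  if (is.null(colnames(X))) colnames(X) <- sprintf("M%d", seq_len(p))
  nBoot <- as.integer(nBoot)
  sumPhi <- matrix(0, n, p)
  sumMain <- matrix(0, n, p)
  sumInt <- if (interactions) array(0, dim = c(n, p, p)) else NULL
  sumBase <- 0
  sumPred <- numeric(n)
  redraws <- 0L
  for (b in seq_len(nBoot)) {
    repl <- withSeed(if (is.null(seed)) NULL else seed + b, {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), unique(idx))
        if (length(oob) > 0L) break
        redraws <- redraws + 1L
        message("bootstrap replicate with empty out-of-bag set; redrawing")
      }
      ens <- fitEnsemble(X[idx, , drop = FALSE], y[idx],
                         validX = X[oob, , drop = FALSE], validY = y[oob],
                         config = config)
      bst <- ens@booster
      ct <- stats::predict(bst, X, predcontrib = TRUE)
      out <- list(phi = ct[, seq_len(p), drop = FALSE],
                  base = ct[1L, p + 1L],
                  pred = stats::predict(bst, X))
      if (interactions) {
        it <- stats::predict(bst, X, predinteraction = TRUE)
        out$int <- it[, seq_len(p), seq_len(p), drop = FALSE]
      }
      out
    })
    sumPhi <- sumPhi + repl$phi
    sumBase <- sumBase + repl$base
    sumPred <- sumPred + repl$pred
    if (interactions) {
      sumInt <- sumInt + repl$int
      dg <- vapply(seq_len(p), function(j) repl$int[, j, j], numeric(n))
      sumMain <- sumMain + dg
    }
  }
  meanPhi <- sumPhi / nBoot
  meanMain <- sumMain / nBoot
  meanInt <- if (interactions) sumInt / nBoot else NULL
  gInt <- NULL
  if (interactions) {
    gInt <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
    for (j in seq_len(p)) gInt[, j] <- colMeans(abs(2 * meanInt[, , j]))
    diag(gInt) <- 0
  }
  dimnames(meanPhi) <- list(rownames(X), colnames(X))
  dimnames(meanMain) <- list(rownames(X), colnames(X))
  new("ShapXgbResult",
      meanPhi = meanPhi, meanPhiMain = meanMain, meanPhiInt = meanInt,
      globalCompound = stats::setNames(colMeans(abs(meanPhi)), colnames(X)),
      globalPure = stats::setNames(colMeans(abs(meanMain)), colnames(X)),
      globalInteraction = gInt,
      meanBase = sumBase / nBoot, meanPrediction = sumPred / nBoot,
      nBoot = nBoot, seed = asSeed(seed), redraws = redraws,
      markerNames = colnames(X))
}

#' Select the global score used for main-effect mapping
#'
#' The compound score (`mean |phi_i|`) folds interaction contributions into
#' each marker's score; the pure score (`mean |phi_ii|`) strips them.
#'
#' @param result a [ShapXgbResult-class].
#' @param mode `"compound"` or `"pure"`.
#' @return named numeric vector of p global scores.
#' @export
scoreMode <- function(result, mode = c("compound", "pure")) {
  mode <- match.arg(mode)
  if (mode == "compound") result@globalCompound else result@globalPure
}

#' Global SHAP interaction scores per marker pair
#'
#' Flattens the upper triangle of the global interaction matrix into a
#' ranked pair table.
#'
#' @param result a [ShapXgbResult-class] computed with
#'   `interactions = TRUE`.
#' @return data.frame with columns `markerA`, `markerB` (A before B in
#'   marker order) and `score`, sorted by decreasing score.
#' @export
pairScores <- function(result) {
  stopIf(is.null(result@globalInteraction),
         "result was computed without interactions")
  g <- result@globalInteraction
  p <- ncol(g)
  ij <- which(upper.tri(g), arr.ind = TRUE)
  out <- data.frame(markerA = result@markerNames[ij[, 1L]],
                    markerB = result@markerNames[ij[, 2L]],
                    score = g[ij])
  out[order(-out$score), , drop = FALSE]
}
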