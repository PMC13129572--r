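#' Positive-marker labels around QTL windows
#'
#' A marker is positive when it lies within `windowCM` centiMorgans of at
#' least one QTL on the same chromosome (the boundary counts: distance
#' `<= windowCM`); windows never cross chromosomes.
#'
#' @param map a [GeneticMap-class].
#' @param layout a [QTLLayout-class].
#' @param windowCM half-window in cM (default 10, i.e. a 20 cM window).
#' @return named logical vector over markers, in map order.
#' @export
labelMarkers <- function(map, layout, windowCM = 10) {
  stopIf(windowCM < 0, "windowCM must be nonnegative")
  mk <- map@markers
  lab <- rep(FALSE, nrow(mk))
  q <- layout@qtl
  for (k in seq_len(nrow(q))) {
    hit <- mk$chrom == q$chrom[k] & abs(mk$pos_cM - q$pos_cM[k]) <= windowCM
    lab <- lab | hit
  }
  stats::setNames(lab, mk$marker)
}

# markers tagging each QTL (within the window, same chromosome)
qtlTags <- function(map, layout, windowCM) {
  mk <- map@markers
  lapply(seq_len(nrow(layout@qtl)), function(k)
    which(mk$chrom == layout@qtl$chrom[k] &
          abs(mk$pos_cM - layout@qtl$pos_cM[k]) <= windowCM))
}

#' Positive labels for marker pairs
#'
#' An unordered marker pair is positive when, for some interacting QTL pair
#' `(q, r)`, one marker lies within the window of `q` and the other within
#' the window of `r` (both orientations accepted). Two markers tagging the
#' same single QTL do not form a positive pair.
#'
#' @inheritParams labelMarkers
#' @return data.frame with columns `markerA`, `markerB` (upper-triangle
#'   enumeration in map order) and logical `positive`.
#' @export
labelPairs <- function(map, layout, windowCM = 10) {
  stopIf(windowCM < 0, "windowCM must be nonnegative")
  p <- nrow(map@markers)
  tags <- qtlTags(map, layout, windowCM)
  pos <- matrix(FALSE, p, p)
  pr <- layout@pairs
  for (k in seq_len(nrow(pr))) {
    a <- tags[[pr[k, 1L]]]
    b <- tags[[pr[k, 2L]]]
    if (length(a) && length(b)) {
      pos[a, b] <- TRUE
      pos[b, a] <- TRUE
    }
  }
  ij <- which(upper.tri(pos), arr.ind = TRUE)
  data.frame(markerA = map@markers$marker[ij[, 1L]],
             markerB = map@markers$marker[ij[, 2L]],
             positive = pos[ij])
}

#' ROC curve and AUC from scores and labels
#'
#' Ranks scores against binary labels; the AUC equals the Mann-Whitney
#' U-statistic form `P(score_pos > score_neg) + P(tie)/2`. Computation is
#' delegated to pROC (trapezoidal rule over the ranked curve, which
#' realises the midrank tie convention).
#'
#' @param scores numeric scores, higher = more likely positive.
#' @param labels logical (or 0/1) labels; both classes must occur.
#' @return an [ROCResult-class].
#' @examples
#' auc(rocAuc(c(0.9, 0.8, 0.3, 0.1), c(TRUE, FALSE, TRUE, FALSE))) # 0.75
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopIf(length(scores) != length(labels), "scores and labels must align")
  stopIf(!any(labels) || all(labels),
         "AUC undefined: need at least one positive and one negative")
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  curve <- data.frame(fpr = rev(1 - r$specificities),
                      tpr = rev(r$sensitivities))
  new("ROCResult", curve = curve, auc = as.numeric(r$auc))
}

#' Run replicated scenario experiments end to end
#'
#' For each replicate: simulate a scenario dataset ([simulateScenario()]),
#' run the bootstrap SHAP pipeline ([runShapXgb()]), label markers and
#' marker pairs around the true QTLs, and score detection with ROC AUC for
#' main effects (global score of `scoreMode`) and for interactions (global
#' SHAP interaction scores). Replicate seeds derive from `seed` as
#' `seed + 1000 * replicate`.
#'
#' @param scenario integer in 1..9.
#' @param nReps number of replicates (default 10).
#' @param seed master integer seed.
#' @param config a [BoostConfig-class].
#' @param nBoot bootstrap replicates per pipeline run.
#' @param mode score used for main-effect mapping (`"compound"` or
#'   `"pure"`).
#' @param windowCM positive-label half-window in cM.
#' @param interactions also compute interaction AUCs (default TRUE).
#' @return data.frame with one row per replicate: `replicate`, `scenario`,
#'   `aucMain`, `aucInteraction` (NA when `interactions = FALSE`),
#'   `realizedVA`, `realizedVI`.
#' @export
runScenario <- function(scenario, nReps = 10L, seed = NULL,
                        config = boostConfig(), nBoot = 100L,
                        mode = c("compound", "pure"), windowCM = 10,
                        interactions = TRUE) {
  mode <- match.arg(mode)
  out <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    repSeed <- if (is.null(seed)) NULL else seed + 1000L * r
    sc <- simulateScenario(scenario, seed = repSeed)
    res <- runShapXgb(sc$X, phenotypes(sc$phen), config = config,
                      nBoot = nBoot, seed = repSeed,
                      interactions = interactions)
    labM <- labelMarkers(sc$map, sc$layout, windowCM)
    aucMain <- auc(rocAuc(scoreMode(res, mode), labM))
    aucInt <- NA_real_
    if (interactions) {
      labP <- labelPairs(sc$map, sc$layout, windowCM)
      ps <- pairScores(res)
      key <- function(a, b) paste(a, b, sep = "||")
      sc_map <- stats::setNames(ps$score, key(ps$markerA, ps$markerB))
      scores <- sc_map[key(labP$markerA, labP$markerB)]
      aucInt <- auc(rocAuc(scores, labP$positive))
    }
    out[[r]] <- data.frame(replicate = r, scenario = scenario,
                           aucMain = aucMain, aucInteraction = aucInt,
                           realizedVA = realizedVA(sc$phen),
                           realizedVI = realizedVI(sc$phen))
  }
  do.call(rbind, out)
}

#' Per-line SHAP interaction values for one marker pair
#'
#' Extracts the data behind a dependency plot: for every line, the coded
#' genotypes at the two markers of interest and the bootstrap-averaged SHAP
#' interaction value of the pair. Scatter the interaction value against
#' `genoA`, coloured by `genoB`, to visualise how the effect of one locus
#' depends on the genotype at the other.
#'
#' @param result a [ShapXgbResult-class] with interactions.
#' @param X the coded genotype matrix the pipeline was run on.
#' @param markerA,markerB marker names (distinct).
#' @return data.frame with columns `lineId`, `genoA`, `genoB`,
#'   `interactionValue` (one row per line).
#' @export
dependencyData <- function(result, X, markerA, markerB) {
  stopIf(is.null(result@meanPhiInt),
         "result was computed without interactions")
  stopIf(identical(markerA, markerB), "markers must be distinct")
  a <- match(markerA, result@markerNames)
  b <- match(markerB, result@markerNames)
  stopIf(is.na(a) || is.na(b), "unknown marker name")
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("L%03d", seq_len(nrow(X)))
  data.frame(lineId = ids, genoA = X[, a], genoB = X[, b],
             interactionValue = result@meanPhiInt[, a, b])
}

#' Dependency plot for a marker pair
#'
#' Genotype-coloured scatter of per-line SHAP interaction values with one
#' linear fit (and confidence band) per genotype class of `markerB`.
#' Requires ggplot2.
#'
#' @inheritParams dependencyData
#' @return a ggplot object.
#' @export
plotDependency <- function(result, X, markerA, markerB) {
  stopIf(!requireNamespace("ggplot2", quietly = TRUE),
         "plotDependency requires ggplot2")
  dd <- dependencyData(result, X, markerA, markerB)
  dd$genoB <- factor(dd$genoB)
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$genoA,
                                   y = .data$interactionValue,
                                   colour = .data$genoB)) +
    ggplot2::geom_jitter(width = 0.05, height = 0, alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.6) +
    ggplot2::labs(x = markerA, y = sprintf("SHAP interaction (%s : %s)",
                                           markerA, markerB),
                  colour = markerB) +
    ggplot2::theme_minimal()
}
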