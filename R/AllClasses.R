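#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("arrayOrNULL", c("array", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' GeneticMap: chromosomes and ordered marker positions
#'
#' Holds a linkage map: a set of chromosomes with lengths in centiMorgans
#' (cM) and markers placed at cM positions along them. Marker rows are kept
#' strictly ordered by (chromosome, position) and marker names are unique.
#'
#' @slot chromosomes data.frame with columns `chrom` (integer id) and
#'   `length_cM` (numeric chromosome length).
#' @slot markers data.frame with columns `marker` (character), `chrom`
#'   (integer) and `pos_cM` (numeric position in `[0, length_cM]`).
#'
#' @seealso [makeMap()], [readMap()]
#' @exportClass GeneticMap
setClass("GeneticMap",
  representation(chromosomes = "data.frame", markers = "data.frame"))

setValidity("GeneticMap", function(object) {
  ch <- object@chromosomes
  mk <- object@markers
  if (!all(c("chrom", "length_cM") %in% names(ch)))
    return("chromosomes needs columns chrom, length_cM")
  if (!all(c("marker", "chrom", "pos_cM") %in% names(mk)))
    return("markers needs columns marker, chrom, pos_cM")
  if (anyDuplicated(ch$chrom)) return("duplicated chromosome ids")
  if (any(ch$length_cM <= 0)) return("chromosome lengths must be positive")
  if (anyDuplicated(mk$marker)) return("marker names must be unique")
  if (!all(mk$chrom %in% ch$chrom)) return("marker on unknown chromosome")
  len <- ch$length_cM[match(mk$chrom, ch$chrom)]
  if (any(mk$pos_cM < 0 | mk$pos_cM > len))
    return("marker positions must lie in [0, length_cM]")
  ord <- order(match(mk$chrom, ch$chrom), mk$pos_cM)
  if (!identical(ord, seq_len(nrow(mk))))
    return("markers must be sorted by (chrom, pos_cM)")
  TRUE
})

#' QTLLayout: QTL positions and interacting pairs
#'
#' Positions of the simulated QTLs and which unordered QTL pairs carry an
#' epistatic interaction effect. Layouts always hold five QTLs and five of
#' the ten possible pairs, matching the simulated genetic architectures.
#'
#' @slot qtl data.frame with columns `chrom` and `pos_cM`, one row per QTL.
#' @slot pairs integer matrix with two columns; each row is an unordered
#'   pair of QTL indices (row `i < j`) that interact.
#'
#' @seealso [placeQtls()]
#' @exportClass QTLLayout
setClass("QTLLayout", representation(qtl = "data.frame", pairs = "matrix"))

setValidity("QTLLayout", function(object) {
  q <- object@qtl
  p <- object@pairs
  if (!all(c("chrom", "pos_cM") %in% names(q)))
    return("qtl needs columns chrom, pos_cM")
  if (nrow(q) != 5L) return("exactly 5 QTLs are required")
  if (ncol(p) != 2L || nrow(p) != 5L)
    return("exactly 5 interacting pairs are required")
  if (any(p < 1L | p > nrow(q))) return("pair index out of range")
  if (any(p[, 1L] >= p[, 2L])) return("pairs must satisfy i < j")
  key <- paste(p[, 1L], p[, 2L])
  if (anyDuplicated(key)) return("duplicated interacting pair")
  TRUE
})

#' CrossPopulation: simulated genotypes at markers and hidden QTL loci
#'
#' Raw allele-dosage genotypes (count of parent-A alleles, 0/1/2) for an F2
#' or recombinant inbred line (RIL) population at every locus of the merged
#' marker + QTL locus set. RIL lines are fully homozygous (no dosage 1).
#'
#' @slot popType `"F2"` or `"RIL"`.
#' @slot genotypes integer matrix, lines x loci, entries in `{0,1,2}`.
#' @slot loci data.frame with columns `locus`, `chrom`, `pos_cM`,
#'   `is_marker` describing the columns of `genotypes`, ordered like the map.
#' @slot seed integer seed used for the simulation (NA if none supplied).
#'
#' @seealso [simulateF2()], [simulateRil()], [splitMarkers()]
#' @exportClass CrossPopulation
setClass("CrossPopulation",
  representation(popType = "character", genotypes = "matrix",
                 loci = "data.frame", seed = "integer"))

setValidity("CrossPopulation", function(object) {
  if (!object@popType %in% c("F2", "RIL")) return("popType must be F2 or RIL")
  g <- object@genotypes
  if (nrow(g) < 1L) return("population must have at least one line")
  if (!all(g %in% c(0L, 1L, 2L))) return("dosages must be in {0,1,2}")
  if (object@popType == "RIL" && any(g == 1L))
    return("RIL genotypes must be homozygous (no dosage 1)")
  if (!all(c("locus", "chrom", "pos_cM", "is_marker") %in% names(object@loci)))
    return("loci needs columns locus, chrom, pos_cM, is_marker")
  if (ncol(g) != nrow(object@loci))
    return("genotype columns must match the locus set")
  TRUE
})

#' QTLModel: gene action and effect sizes of the simulated QTLs
#'
#' @slot layout a [QTLLayout-class].
#' @slot action gene action: `"additive"`, `"complete_dominance"` or
#'   `"overdominance"`; fixes the genotype coding used for the QTLs.
#' @slot mainEffects numeric(5), main effect per QTL (may contain zeros).
#' @slot interactionEffects numeric(5), one effect per interacting pair, in
#'   the row order of `layout@pairs`.
#' @slot mainSd,interactionSd standard deviations the effects were drawn
#'   with.
#'
#' @seealso [drawEffects()], [geneticValues()]
#' @exportClass QTLModel
setClass("QTLModel",
  representation(layout = "QTLLayout", action = "character",
                 mainEffects = "numeric", interactionEffects = "numeric",
                 mainSd = "numeric", interactionSd = "numeric"))

setValidity("QTLModel", function(object) {
  if (!object@action %in% c("additive", "complete_dominance", "overdominance"))
    return("unknown gene action")
  if (length(object@mainEffects) != 5L) return("need 5 main effects")
  if (length(object@interactionEffects) != nrow(object@layout@pairs))
    return("one interaction effect per interacting pair")
  TRUE
})

#' PhenotypeSet: genetic values, residuals and realized variance shares
#'
#' Phenotypes decompose elementwise as
#' `phenotypes = mainValues + interactionValues + residuals`. Realized
#' variance proportions are sample variances (n - 1 denominator) of the
#' components divided by the sample variance of the phenotypes.
#'
#' @slot mainValues,interactionValues,residuals,phenotypes numeric(n).
#' @slot H2Target targeted broad-sense heritability in (0, 1].
#' @slot realizedVA,realizedVI realized additive / epistatic variance
#'   proportions.
#'
#' @seealso [addNoise()]
#' @exportClass PhenotypeSet
setClass("PhenotypeSet",
  representation(mainValues = "numeric", interactionValues = "numeric",
                 residuals = "numeric", phenotypes = "numeric",
                 H2Target = "numeric", realizedVA = "numeric",
                 realizedVI = "numeric"))

setValidity("PhenotypeSet", function(object) {
  n <- length(object@phenotypes)
  if (length(object@mainValues) != n || length(object@interactionValues) != n ||
      length(object@residuals) != n)
    return("component vectors must share one length")
  if (max(abs(object@phenotypes -
              (object@mainValues + object@interactionValues +
               object@residuals))) > 1e-8)
    return("phenotypes must equal main + interaction + residuals")
  if (object@H2Target <= 0 || object@H2Target > 1)
    return("H2Target must be in (0, 1]")
  TRUE
})

#' BoostConfig: gradient-boosting hyperparameters and fitting presets
#'
#' Three presets control the degree of fit: `"moderate"` (library defaults,
#' learning rate 0.3 and depth 6, early stopping after 3 non-improving
#' rounds), `"underfit"` (rate 0.1, depth 3, early stopping 3) and
#' `"overfit"` (defaults, exactly 50 rounds, no early stopping).
#'
#' @slot preset `"moderate"`, `"underfit"` or `"overfit"`.
#' @slot learningRate boosting shrinkage (eta).
#' @slot maxDepth maximum tree depth.
#' @slot earlyStoppingRounds rounds without validation improvement before
#'   stopping; `NA` disables early stopping.
#' @slot maxRounds cap on boosting iterations.
#' @slot basePrediction model intercept; `NA` means "use the training mean".
#'
#' @seealso [boostConfig()], [fitEnsemble()]
#' @exportClass BoostConfig
setClass("BoostConfig",
  representation(preset = "character", learningRate = "numeric",
                 maxDepth = "integer", earlyStoppingRounds = "integer",
                 maxRounds = "integer", basePrediction = "numeric"))

setValidity("BoostConfig", function(object) {
  if (!object@preset %in% c("moderate", "underfit", "overfit"))
    return("unknown preset")
  if (object@learningRate <= 0) return("learningRate must be positive")
  if (object@maxDepth < 1L) return("maxDepth must be >= 1")
  if (!is.na(object@earlyStoppingRounds) && object@earlyStoppingRounds < 1L)
    return("earlyStoppingRounds must be >= 1 or NA")
  if (object@maxRounds < 1L) return("maxRounds must be >= 1")
  TRUE
})

#' TreeEnsemble: boosted regression trees as explicit structure
#'
#' A sum-of-trees regression model: `prediction(x) = basePrediction +
#' sum_k tree_k(x)`. Each tree is a node table (row 1 = root) with split
#' feature, threshold, children, leaf value and cover (training-weight mass
#' reaching the node). Routing is strictly-less-than: `x[feature] <
#' threshold` goes to the `yes` child. Internal nodes conserve cover:
#' a node's cover equals the sum of its children's covers.
#'
#' @slot trees list of data.frames with columns `feature` (1-based integer,
#'   `NA` at leaves), `split`, `yes`, `no` (row indices, `NA` at leaves),
#'   `value` (leaf weight, `NA` internal) and `cover`.
#' @slot basePrediction numeric intercept added to every prediction.
#' @slot nFeatures number of input features.
#' @slot featureNames character feature names (length `nFeatures`).
#' @slot booster the fitted `xgb.Booster` the structure was extracted from,
#'   or `NULL` for hand-built ensembles.
#'
#' @seealso [fitEnsemble()], [extractStructure()], [treeShap()]
#' @exportClass TreeEnsemble
setClass("TreeEnsemble",
  representation(trees = "list", basePrediction = "numeric",
                 nFeatures = "integer", featureNames = "character",
                 booster = "ANY"))

setValidity("TreeEnsemble", function(object) {
  for (tr in object@trees) {
    need <- c("feature", "split", "yes", "no", "value", "cover")
    if (!all(need %in% names(tr))) return("tree table misses columns")
    leaf <- is.na(tr$feature)
    if (any(leaf & is.na(tr$value))) return("leaves must carry values")
    if (any(!leaf & (is.na(tr$yes) | is.na(tr$no) | is.na(tr$split))))
      return("internal nodes must carry split, yes, no")
    if (any(!leaf & (tr$feature < 1L | tr$feature > object@nFeatures)))
      return("split feature index out of range")
    kid <- c(tr$yes[!leaf], tr$no[!leaf])
    if (any(kid < 1L | kid > nrow(tr))) return("child index out of range")
    if (any(tr$cover < 0)) return("covers must be nonnegative")
    bad <- abs(tr$cover[!leaf] - (tr$cover[tr$yes[!leaf]] +
                                  tr$cover[tr$no[!leaf]]))
    if (length(bad) && any(bad > 1e-6 * pmax(1, tr$cover[!leaf])))
      return("cover must be conserved at internal nodes")
  }
  if (length(object@featureNames) &&
      length(object@featureNames) != object@nFeatures)
    return("featureNames length must match nFeatures")
  TRUE
})

#' ShapXgbResult: bootstrap-averaged SHAP decomposition and global scores
#'
#' Per-line SHAP values, their main/interaction decomposition and the global
#' importance scores of the bootstrap pipeline. Global scores are means over
#' lines of absolute averaged values: `globalCompound[j] = mean_i
#' |meanPhi[i,j]|`, `globalPure[j] = mean_i |meanPhiMain[i,j]|`, and
#' `globalInteraction[j,k] = mean_i |2 * meanPhiInt[i,j,k]|` (diagonal 0).
#'
#' @slot meanPhi n x p matrix, bootstrap-averaged SHAP value per line and
#'   marker.
#' @slot meanPhiMain n x p matrix of averaged main-effect values (phi_ii).
#' @slot meanPhiInt n x p x p array of averaged interaction values
#'   (phi_ij), or NULL if interactions were not computed.
#' @slot globalCompound,globalPure numeric(p) global SHAP scores.
#' @slot globalInteraction p x p symmetric matrix of global SHAP interaction
#'   scores (NULL if not computed).
#' @slot meanBase,meanPrediction bootstrap means of the model base value and
#'   of the model prediction per line.
#' @slot nBoot number of bootstrap replicates; @slot seed master seed (NA if
#'   none); @slot redraws bootstrap draws discarded for an empty out-of-bag
#'   set.
#' @slot markerNames feature names (length p).
#'
#' @seealso [runShapXgb()], [scoreMode()], [pairScores()]
#' @exportClass ShapXgbResult
setClass("ShapXgbResult",
  representation(meanPhi = "matrix", meanPhiMain = "matrix",
                 meanPhiInt = "arrayOrNULL", globalCompound = "numeric",
                 globalPure = "numeric", globalInteraction = "matrixOrNULL",
                 meanBase = "numeric", meanPrediction = "numeric",
                 nBoot = "integer", seed = "integer", redraws = "integer",
                 markerNames = "character"))

setValidity("ShapXgbResult", function(object) {
  p <- ncol(object@meanPhi)
  if (ncol(object@meanPhiMain) != p) return("meanPhiMain dimension mismatch")
  if (length(object@globalCompound) != p || length(object@globalPure) != p)
    return("global score length mismatch")
  if (!is.null(object@meanPhiInt) &&
      !identical(dim(object@meanPhiInt)[2:3], c(p, p)))
    return("meanPhiInt dimension mismatch")
  if (object@nBoot < 1L) return("nBoot must be >= 1")
  TRUE
})

#' ROCResult: ranked ROC curve and area under it
#'
#' @slot curve data.frame with columns `fpr`, `tpr` tracing the ROC curve.
#' @slot auc area under the curve; equals the Mann-Whitney probability that
#'   a random positive outscores a random negative (ties counted 1/2).
#'
#' @seealso [rocAuc()]
#' @exportClass ROCResult
setClass("ROCResult", representation(curve = "data.frame", auc = "numeric"))

setValidity("ROCResult", function(object) {
  if (!all(c("fpr", "tpr") %in% names(object@curve)))
    return("curve needs fpr, tpr")
  if (object@auc < 0 || object@auc > 1) return("auc must be in [0,1]")
  TRUE
})
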