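# Generics and accessors. Slot access from user code goes through these.

#' @rdname GeneticMap-class
#' @param object,x a shapQTL object
#' @export
setGeneric("nMarkers", function(object) standardGeneric("nMarkers"))
#' @rdname GeneticMap-class
#' @export
setGeneric("markerNames", function(object) standardGeneric("markerNames"))
#' @rdname GeneticMap-class
#' @export
setGeneric("markerInfo", function(object) standardGeneric("markerInfo"))
#' @rdname GeneticMap-class
#' @export
setGeneric("chromosomes", function(object) standardGeneric("chromosomes"))

#' @rdname QTLLayout-class
#' @export
setGeneric("qtlPositions", function(object) standardGeneric("qtlPositions"))
#' @rdname QTLLayout-class
#' @export
setGeneric("interactingPairs",
           function(object) standardGeneric("interactingPairs"))

#' @rdname CrossPopulation-class
#' @export
setGeneric("popType", function(object) standardGeneric("popType"))
#' @rdname CrossPopulation-class
#' @export
setGeneric("genotypes", function(object) standardGeneric("genotypes"))
#' @rdname CrossPopulation-class
#' @export
setGeneric("locusInfo", function(object) standardGeneric("locusInfo"))
#' @rdname CrossPopulation-class
#' @export
setGeneric("markerGenotypes",
           function(object) standardGeneric("markerGenotypes"))
#' @rdname CrossPopulation-class
#' @export
setGeneric("qtlGenotypes", function(object) standardGeneric("qtlGenotypes"))

#' @rdname QTLModel-class
#' @export
setGeneric("mainEffects", function(object) standardGeneric("mainEffects"))
#' @rdname QTLModel-class
#' @export
setGeneric("interactionEffects",
           function(object) standardGeneric("interactionEffects"))
#' @rdname QTLModel-class
#' @export
setGeneric("geneAction", function(object) standardGeneric("geneAction"))

#' @rdname PhenotypeSet-class
#' @export
setGeneric("phenotypes", function(object) standardGeneric("phenotypes"))
#' @rdname PhenotypeSet-class
#' @export
setGeneric("realizedVA", function(object) standardGeneric("realizedVA"))
#' @rdname PhenotypeSet-class
#' @export
setGeneric("realizedVI", function(object) standardGeneric("realizedVI"))

#' @rdname TreeEnsemble-class
#' @export
setGeneric("nTrees", function(object) standardGeneric("nTrees"))
#' @rdname TreeEnsemble-class
#' @export
setGeneric("basePrediction",
           function(object) standardGeneric("basePrediction"))

#' @rdname ShapXgbResult-class
#' @export
setGeneric("meanShap", function(object) standardGeneric("meanShap"))
#' @rdname ShapXgbResult-class
#' @export
setGeneric("meanShapMain", function(object) standardGeneric("meanShapMain"))
#' @rdname ShapXgbResult-class
#' @export
setGeneric("meanShapInteraction",
           function(object) standardGeneric("meanShapInteraction"))

#' @rdname ROCResult-class
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))
#' @rdname ROCResult-class
#' @export
setGeneric("rocCurve", function(object) standardGeneric("rocCurve"))

# ---- methods -------------------------------------------------------------

#' @rdname GeneticMap-class
#' @export
setMethod("nMarkers", "GeneticMap", function(object) nrow(object@markers))
#' @rdname GeneticMap-class
#' @export
setMethod("markerNames", "GeneticMap", function(object) object@markers$marker)
#' @rdname GeneticMap-class
#' @export
setMethod("markerInfo", "GeneticMap", function(object) object@markers)
#' @rdname GeneticMap-class
#' @export
setMethod("chromosomes", "GeneticMap", function(object) object@chromosomes)

#' @rdname QTLLayout-class
#' @export
setMethod("qtlPositions", "QTLLayout", function(object) object@qtl)
#' @rdname QTLLayout-class
#' @export
setMethod("interactingPairs", "QTLLayout", function(object) object@pairs)

#' @rdname CrossPopulation-class
#' @export
setMethod("popType", "CrossPopulation", function(object) object@popType)
#' @rdname CrossPopulation-class
#' @export
setMethod("genotypes", "CrossPopulation", function(object) object@genotypes)
#' @rdname CrossPopulation-class
#' @export
setMethod("locusInfo", "CrossPopulation", function(object) object@loci)
#' @rdname CrossPopulation-class
#' @export
setMethod("markerGenotypes", "CrossPopulation", function(object)
  object@genotypes[, object@loci$is_marker, drop = FALSE])
#' @rdname CrossPopulation-class
#' @export
setMethod("qtlGenotypes", "CrossPopulation", function(object)
  object@genotypes[, !object@loci$is_marker, drop = FALSE])

#' @rdname QTLModel-class
#' @export
setMethod("mainEffects", "QTLModel", function(object) object@mainEffects)
#' @rdname QTLModel-class
#' @export
setMethod("interactionEffects", "QTLModel",
          function(object) object@interactionEffects)
#' @rdname QTLModel-class
#' @export
setMethod("geneAction", "QTLModel", function(object) object@action)
#' @rdname QTLModel-class
#' @export
setMethod("interactingPairs", "QTLModel",
          function(object) object@layout@pairs)

#' @rdname PhenotypeSet-class
#' @export
setMethod("phenotypes", "PhenotypeSet", function(object) object@phenotypes)
#' @rdname PhenotypeSet-class
#' @export
setMethod("realizedVA", "PhenotypeSet", function(object) object@realizedVA)
#' @rdname PhenotypeSet-class
#' @export
setMethod("realizedVI", "PhenotypeSet", function(object) object@realizedVI)

#' @rdname TreeEnsemble-class
#' @export
setMethod("nTrees", "TreeEnsemble", function(object) length(object@trees))
#' @rdname TreeEnsemble-class
#' @export
setMethod("basePrediction", "TreeEnsemble",
          function(object) object@basePrediction)

#' @rdname ShapXgbResult-class
#' @export
setMethod("meanShap", "ShapXgbResult", function(object) object@meanPhi)
#' @rdname ShapXgbResult-class
#' @export
setMethod("meanShapMain", "ShapXgbResult", function(object) object@meanPhiMain)
#' @rdname ShapXgbResult-class
#' @export
setMethod("meanShapInteraction", "ShapXgbResult",
          function(object) object@meanPhiInt)

#' @rdname ROCResult-class
#' @export
setMethod("auc", "ROCResult", function(object) object@auc)
#' @rdname ROCResult-class
#' @export
setMethod("rocCurve", "ROCResult", function(object) object@curve)

# ---- show ----------------------------------------------------------------

setMethod("show", "GeneticMap", function(object) {
  cat(sprintf("GeneticMap: %d chromosomes, %d markers\n",
              nrow(object@chromosomes), nrow(object@markers)))
  cat(sprintf("  lengths (cM): %s\n",
              paste(format(object@chromosomes$length_cM), collapse = ", ")))
})

setMethod("show", "QTLLayout", function(object) {
  cat("QTLLayout: 5 QTLs\n")
  print(object@qtl)
  cat("interacting pairs (QTL indices):\n")
  apply(object@pairs, 1L, function(p) cat(sprintf("  %d -- %d\n", p[1], p[2])))
  invisible(NULL)
})

setMethod("show", "CrossPopulation", function(object) {
  cat(sprintf("CrossPopulation (%s): %d lines, %d loci (%d markers, %d QTLs)\n",
              object@popType, nrow(object@genotypes), nrow(object@loci),
              sum(object@loci$is_marker), sum(!object@loci$is_marker)))
})

setMethod("show", "QTLModel", function(object) {
  cat(sprintf("QTLModel (%s gene action)\n", object@action))
  cat("  main effects:        ",
      paste(format(object@mainEffects, digits = 3), collapse = " "), "\n")
  cat("  interaction effects: ",
      paste(format(object@interactionEffects, digits = 3), collapse = " "),
      "\n")
})

setMethod("show", "PhenotypeSet", function(object) {
  cat(sprintf(
    "PhenotypeSet: %d lines, H2 target %.2f, realized VA %.3f, VI %.3f\n",
    length(object@phenotypes), object@H2Target, object@realizedVA,
    object@realizedVI))
})

setMethod("show", "BoostConfig", function(object) {
  cat(sprintf(
    "BoostConfig (%s): eta %.2f, depth %d, early stopping %s, max rounds %d\n",
    object@preset, object@learningRate, object@maxDepth,
    ifelse(is.na(object@earlyStoppingRounds), "off",
           as.character(object@earlyStoppingRounds)), object@maxRounds))
})

setMethod("show", "TreeEnsemble", function(object) {
  cat(sprintf("TreeEnsemble: %d trees, %d features, base %.4f%s\n",
              length(object@trees), object@nFeatures, object@basePrediction,
              if (is.null(object@booster)) "" else " (booster attached)"))
})

setMethod("show", "ShapXgbResult", function(object) {
  cat(sprintf(
    "ShapXgbResult: %d lines x %d markers, %d bootstrap replicates%s\n",
    nrow(object@meanPhi), ncol(object@meanPhi), object@nBoot,
    if (is.null(object@meanPhiInt)) " (no interactions)" else ""))
  top <- order(object@globalCompound, decreasing = TRUE)[1:min(5, ncol(object@meanPhi))]
  cat("  top compound scores:\n")
  for (j in top)
    cat(sprintf("    %s  %.4f\n", object@markerNames[j],
                object@globalCompound[j]))
})

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult: AUC = %.4f (%d curve points)\n", object@auc,
              nrow(object@curve)))
})
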