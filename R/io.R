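# CSV interfaces. One canonical dialect: RFC-4180-style, UTF-8, header row.
# Numeric output keeps 17 significant digits so write/read round trips are
# bit-faithful.

fmtNum <- function(x) sprintf("%.17g", x)

checkNoMissing <- function(m, what, path) {
  if (anyNA(m))
    stop(sprintf("missing values in %s file '%s' are not supported", what,
                 path), call. = FALSE)
}

#' Read and write genotype matrices
#'
#' Genotype CSV: header row, first column `line_id`, one column per marker,
#' one row per line. Values are validated against the declared coding:
#' `"raw"` allele dosages in `{0,1,2}`, `"additive"` codes in `{-1,0,1}`,
#' or `"dominance"` codes in `{0,1}` — the coding is declared explicitly
#' because the numeric ranges overlap.
#'
#' @param path CSV file path.
#' @param coding declared genotype coding.
#' @return numeric matrix with line ids as rownames and markers as columns.
#' @export
readGenotypes <- function(path, coding = c("raw", "additive", "dominance")) {
  coding <- match.arg(coding)
  df <- utils::read.csv(path, check.names = FALSE)
  stopIf(ncol(df) < 2L, "genotype file '%s' has no marker columns", path)
  stopIf(nrow(df) == 0L, "genotype file '%s' has no data rows", path)
  ids <- as.character(df[[1L]])
  stopIf(anyDuplicated(ids) > 0L, "duplicate line ids in '%s'", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  stopIf(!is.numeric(m), "non-numeric genotype cells in '%s'", path)
  checkNoMissing(m, "genotype", path)
  allowed <- switch(coding, raw = c(0, 1, 2), additive = c(-1, 0, 1),
                    dominance = c(0, 1))
  bad <- !m %in% allowed
  if (any(bad)) {
    w <- which(bad, arr.ind = FALSE)[1L]
    stop(sprintf(
      "genotype value %g at line '%s', marker '%s' not allowed under %s coding",
      m[w], ids[(w - 1L) %% nrow(m) + 1L],
      colnames(m)[(w - 1L) %/% nrow(m) + 1L], coding), call. = FALSE)
  }
  rownames(m) <- ids
  m
}

#' @rdname readGenotypes
#' @param genotypes numeric matrix with rownames as line ids.
#' @export
writeGenotypes <- function(genotypes, path) {
  df <- data.frame(line_id = rownames(genotypes), genotypes,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write genetic maps
#'
#' Map CSV: columns `marker`, `chrom`, `pos_cM` (header required). Rows not
#' sorted by (chrom, pos_cM) are sorted on read with a warning. Chromosome
#' lengths are not part of the format; the largest observed position per
#' chromosome is used as its length.
#'
#' @param path CSV file path.
#' @return a [GeneticMap-class].
#' @export
readMap <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopIf(!all(c("marker", "chrom", "pos_cM") %in% names(df)),
         "map file '%s' needs columns marker, chrom, pos_cM", path)
  checkNoMissing(df$pos_cM, "map", path)
  chroms <- unique(df$chrom)
  ord <- order(match(df$chrom, chroms), df$pos_cM)
  if (!identical(ord, seq_len(nrow(df)))) {
    warning(sprintf("map file '%s' was not sorted; sorting on read", path))
    df <- df[ord, , drop = FALSE]
  }
  len <- tapply(df$pos_cM, factor(df$chrom, levels = chroms), max)
  new("GeneticMap",
      chromosomes = data.frame(chrom = chroms, length_cM = as.numeric(len)),
      markers = data.frame(marker = as.character(df$marker),
                           chrom = df$chrom, pos_cM = df$pos_cM))
}

#' @rdname readMap
#' @param map a [GeneticMap-class].
#' @export
writeMap <- function(map, path) {
  mk <- map@markers
  df <- data.frame(marker = mk$marker, chrom = mk$chrom,
                   pos_cM = fmtNum(mk$pos_cM))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write phenotypes
#'
#' Phenotype CSV: columns `line_id`, `phenotype`. Phenotypes are matched to
#' genotypes by line id (key), never by row order; use
#' `matchPhenotypes()` to align.
#'
#' @param path CSV file path.
#' @return named numeric vector of phenotypes.
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopIf(!all(c("line_id", "phenotype") %in% names(df)),
         "phenotype file '%s' needs columns line_id, phenotype", path)
  y <- df$phenotype
  stopIf(!is.numeric(y), "non-numeric phenotypes in '%s'", path)
  checkNoMissing(y, "phenotype", path)
  ids <- as.character(df$line_id)
  stopIf(anyDuplicated(ids) > 0L, "duplicate line ids in '%s'", path)
  stats::setNames(as.numeric(y), ids)
}

#' @rdname readPhenotypes
#' @param y named numeric phenotype vector.
#' @export
writePhenotypes <- function(y, path) {
  df <- data.frame(line_id = names(y), phenotype = fmtNum(y))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align phenotypes to a genotype matrix by line id
#'
#' @param genotypes matrix with line ids as rownames.
#' @param y named phenotype vector.
#' @return numeric vector ordered like `rownames(genotypes)`.
#' @export
matchPhenotypes <- function(genotypes, y) {
  ids <- rownames(genotypes)
  stopIf(is.null(ids), "genotype matrix has no line ids")
  miss <- setdiff(ids, names(y))
  stopIf(length(miss) > 0L, "no phenotype for line(s): %s",
         paste(utils::head(miss, 5L), collapse = ", "))
  unname(y[ids])
}

#' Write global marker scores, pair scores and per-line SHAP matrices
#'
#' `writeScores()` writes one row per marker (with map positions when a map
#' is supplied); `writePairs()` writes the ranked pair table of
#' [pairScores()]; `writeShap()` writes a per-line matrix (`line_id` then
#' one column per marker).
#'
#' @param scores named numeric vector of global scores.
#' @param path output CSV path.
#' @param map optional [GeneticMap-class] to attach `chrom`, `pos_cM`.
#' @export
writeScores <- function(scores, path, map = NULL) {
  df <- data.frame(marker = names(scores), score = fmtNum(scores))
  if (!is.null(map)) {
    mk <- map@markers
    i <- match(df$marker, mk$marker)
    stopIf(anyNA(i), "score marker(s) missing from the map")
    df <- data.frame(marker = df$marker, chrom = mk$chrom[i],
                     pos_cM = fmtNum(mk$pos_cM[i]), score = df$score)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeScores
#' @param pairs data.frame from [pairScores()].
#' @export
writePairs <- function(pairs, path) {
  df <- data.frame(marker_a = pairs$markerA, marker_b = pairs$markerB,
                   score = fmtNum(pairs$score))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeScores
#' @param shap per-line matrix (lines x markers), e.g. [meanShap()].
#' @export
writeShap <- function(shap, path) {
  ids <- rownames(shap)
  if (is.null(ids)) ids <- sprintf("L%03d", seq_len(nrow(shap)))
  df <- data.frame(line_id = ids,
                   apply(shap, 2L, fmtNum), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records the run configuration, seeds and package versions needed to
#' reproduce a run bit for bit, as JSON.
#'
#' @param config named list of run parameters (paths, preset, seeds, ...).
#' @param path output JSON path.
#' @export
writeManifest <- function(config, path) {
  manifest <- list(
    format_version = "1.0",
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    r_version = as.character(getRversion()),
    package_versions = list(
      shapQTL = as.character(utils::packageVersion("shapQTL")),
      xgboost = as.character(utils::packageVersion("xgboost")),
      pROC = as.character(utils::packageVersion("pROC"))),
    config = config)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
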