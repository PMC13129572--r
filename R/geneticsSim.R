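#' Haldane map function and selfed-RIL map expansion
#'
#' `haldane()` converts a map distance in centiMorgans to the recombination
#' fraction under no crossover interference,
#' `r = (1 - exp(-2 d / 100)) / 2`. `rilSwitchProb()` converts an F2
#' recombination fraction to the parental-origin switch probability of a
#' selfed recombinant inbred line, `r* = 2 r / (1 + 2 r)`.
#'
#' @param d map distance in cM (vectorised).
#' @param r F2 recombination fraction in `[0, 0.5]` (vectorised).
#' @return numeric vector of recombination fractions / switch probabilities.
#' @examples
#' haldane(10)            # ~0.0906
#' rilSwitchProb(0.5)     # 0.5: unlinked loci stay unlinked
#' @export
haldane <- function(d) {
  stopIf(any(d < 0), "map distances must be nonnegative")
  (1 - exp(-2 * d / 100)) / 2
}

#' @rdname haldane
#' @export
rilSwitchProb <- function(r) {
  stopIf(any(r < 0 | r > 0.5), "recombination fractions must be in [0, 0.5]")
  2 * r / (1 + 2 * r)
}

#' Generate a random genetic map
#'
#' Draws `markersPerChr` marker positions independently and uniformly on
#' `[0, chrLenCM]` for each of `nChr` chromosomes and sorts them. Markers
#' are named `D<chrom>M<index>` in map order.
#'
#' @param nChr number of chromosomes (>= 1).
#' @param chrLenCM chromosome length in cM (> 0); recycled over chromosomes.
#' @param markersPerChr markers per chromosome (>= 2).
#' @param seed optional integer seed (the caller's RNG state is preserved).
#' @return a [GeneticMap-class].
#' @examples
#' makeMap(8, 120, 20, seed = 1)   # the standard simulated map
#' @export
makeMap <- function(nChr, chrLenCM, markersPerChr, seed = NULL) {
  stopIf(nChr < 1, "nChr must be >= 1")
  stopIf(markersPerChr < 2, "markersPerChr must be >= 2")
  stopIf(any(chrLenCM <= 0), "chrLenCM must be positive")
  len <- rep_len(chrLenCM, nChr)
  withSeed(seed, {
    mk <- do.call(rbind, lapply(seq_len(nChr), function(ch) {
      pos <- sort(stats::runif(markersPerChr, 0, len[ch]))
      data.frame(marker = sprintf("D%dM%d", ch, seq_len(markersPerChr)),
                 chrom = ch, pos_cM = pos)
    }))
    new("GeneticMap",
        chromosomes = data.frame(chrom = seq_len(nChr), length_cM = len),
        markers = mk)
  })
}

#' Place QTLs on a map for a simulation scenario
#'
#' Scenarios 1-8 place one QTL on each of five randomly chosen chromosomes
#' at uniform-random positions, and pick five of the ten QTL pairs at random
#' as interacting. Scenario 9 places three linked QTLs spaced exactly 30 cM
#' on one random chromosome and two spaced 30 cM on another; the interacting
#' pairs are the three within-triple pairs, the within-duo pair, and one
#' cross-chromosome pair chosen uniformly among the six candidates.
#'
#' @param map a [GeneticMap-class] with enough chromosomes (>= 5 for
#'   scenarios 1-8, >= 2 for scenario 9).
#' @param scenario integer scenario id in 1..9.
#' @param seed optional integer seed.
#' @return a [QTLLayout-class].
#' @examples
#' map <- makeMap(8, 120, 20, seed = 1)
#' placeQtls(map, scenario = 1, seed = 2)
#' @export
placeQtls <- function(map, scenario = 1L, seed = NULL) {
  stopIf(!scenario %in% 1:9, "scenario must be in 1..9")
  ch <- map@chromosomes
  withSeed(seed, {
    if (scenario != 9L) {
      stopIf(nrow(ch) < 5, "need >= 5 chromosomes for scenarios 1-8")
      sel <- sort(sample(ch$chrom, 5L))
      pos <- stats::runif(5L, 0, ch$length_cM[match(sel, ch$chrom)])
      qtl <- data.frame(chrom = sel, pos_cM = pos)
      all_pairs <- t(utils::combn(5L, 2L))
      pairs <- all_pairs[sort(sample(nrow(all_pairs), 5L)), , drop = FALSE]
    } else {
      stopIf(nrow(ch) < 2, "need >= 2 chromosomes for scenario 9")
      stopIf(any(ch$length_cM < 60), "scenario 9 needs >= 60 cM chromosomes")
      two <- sample(ch$chrom, 2L)
      lenA <- ch$length_cM[match(two[1L], ch$chrom)]
      lenB <- ch$length_cM[match(two[2L], ch$chrom)]
      startA <- stats::runif(1L, 0, lenA - 60)
      startB <- stats::runif(1L, 0, lenB - 30)
      qtl <- data.frame(
        chrom = c(rep(two[1L], 3L), rep(two[2L], 2L)),
        pos_cM = c(startA, startA + 30, startA + 60, startB, startB + 30))
      cross <- as.matrix(expand.grid(1:3, 4:5))
      pick <- cross[sample(nrow(cross), 1L), ]
      pairs <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L), c(4L, 5L),
                     sort(pick))
    }
    storage.mode(pairs) <- "integer"
    colnames(pairs) <- c("q1", "q2")
    new("QTLLayout", qtl = qtl, pairs = pairs)
  })
}

# merged, ordered locus set of markers plus (hidden) QTL loci
lociWithQtls <- function(map, qtls = NULL) {
  mk <- map@markers
  loci <- data.frame(locus = mk$marker, chrom = mk$chrom, pos_cM = mk$pos_cM,
                     is_marker = TRUE)
  if (!is.null(qtls)) {
    q <- qtls@qtl
    loci <- rbind(loci, data.frame(
      locus = sprintf("QTL%d", seq_len(nrow(q))),
      chrom = q$chrom, pos_cM = q$pos_cM, is_marker = FALSE))
  }
  loci[order(match(loci$chrom, map@chromosomes$chrom), loci$pos_cM), ,
       drop = FALSE]
}

# one chromosome's worth of gametes: n x L matrix of parent-A indicators.
# Crossovers: Poisson(length/100) count, uniform positions (Haldane model).
gametesOneChrom <- function(n, pos, chromLen) {
  L <- length(pos)
  start <- stats::rbinom(n, 1L, 0.5)
  ncross <- stats::rpois(n, chromLen / 100)
  out <- matrix(0L, n, L)
  xo <- stats::runif(sum(ncross), 0, chromLen)
  at <- 0L
  for (g in seq_len(n)) {
    k <- ncross[g]
    if (k == 0L) {
      out[g, ] <- start[g]
    } else {
      cuts <- sort(xo[(at + 1L):(at + k)])
      out[g, ] <- (start[g] + findInterval(pos, cuts)) %% 2L
      at <- at + k
    }
  }
  out
}

#' Simulate meioses: gametes from an F1 parent
#'
#' Simulates `n` gametes over all loci of `map` (plus hidden QTL loci if a
#' layout is given). Each chromosome receives a Poisson-distributed number
#' of crossovers (`length/100` expected) at uniform positions, i.e. the
#' Haldane no-interference model; the returned entries indicate the
#' parent-A allele.
#'
#' @param map a [GeneticMap-class].
#' @param n number of gametes.
#' @param qtls optional [QTLLayout-class]; QTL loci are simulated jointly
#'   with the markers on the same gamete (exact linkage).
#' @param seed optional integer seed.
#' @return integer matrix `n x L` of 0/1 parent-A indicators, with locus
#'   names as column names.
#' @export
simulateGametes <- function(map, n, qtls = NULL, seed = NULL) {
  stopIf(n < 1, "n must be >= 1")
  loci <- lociWithQtls(map, qtls)
  withSeed(seed, {
    cols <- lapply(map@chromosomes$chrom, function(ch) {
      i <- loci$chrom == ch
      if (!any(i)) return(NULL)
      gametesOneChrom(n, loci$pos_cM[i],
                      map@chromosomes$length_cM[map@chromosomes$chrom == ch])
    })
    g <- do.call(cbind, cols)
    colnames(g) <- loci$locus
    g
  })
}

#' Simulate an F2 biparental population
#'
#' Each F2 individual is the union of two independent F1 gametes
#' ([simulateGametes()]); the stored genotype is the allele dosage (count of
#' parent-A alleles, 0/1/2) at every marker and hidden QTL locus.
#'
#' @param map a [GeneticMap-class].
#' @param qtls optional [QTLLayout-class] of hidden QTL loci.
#' @param n population size (>= 1).
#' @param seed optional integer seed.
#' @return a [CrossPopulation-class] with `popType = "F2"`.
#' @examples
#' map <- makeMap(8, 120, 20, seed = 1)
#' lay <- placeQtls(map, 1, seed = 2)
#' pop <- simulateF2(map, lay, n = 200, seed = 3)
#' table(markerGenotypes(pop)[, 1])   # ~ 1:2:1
#' @export
simulateF2 <- function(map, qtls = NULL, n, seed = NULL) {
  stopIf(n < 1, "n must be >= 1")
  loci <- lociWithQtls(map, qtls)
  g <- withSeed(seed, simulateGametes(map, 2L * n, qtls) )
  dos <- g[seq_len(n), , drop = FALSE] + g[n + seq_len(n), , drop = FALSE]
  rownames(dos) <- sprintf("L%03d", seq_len(n))
  new("CrossPopulation", popType = "F2", genotypes = dos, loci = loci,
      seed = asSeed(seed))
}

#' Simulate a selfed recombinant inbred line (RIL) population
#'
#' Each line is fully homozygous. Along a chromosome the parental origin is
#' a Markov chain: the switch probability across an adjacent-locus interval
#' is the selfed-RIL map expansion `r* = 2r/(1+2r)` of the Haldane F2
#' recombination fraction `r` for that interval.
#'
#' @inheritParams simulateF2
#' @return a [CrossPopulation-class] with `popType = "RIL"` and dosages in
#'   `{0, 2}`.
#' @export
simulateRil <- function(map, qtls = NULL, n, seed = NULL) {
  stopIf(n < 1, "n must be >= 1")
  loci <- lociWithQtls(map, qtls)
  withSeed(seed, {
    cols <- lapply(map@chromosomes$chrom, function(ch) {
      i <- loci$chrom == ch
      if (!any(i)) return(NULL)
      pos <- loci$pos_cM[i]
      L <- length(pos)
      A <- matrix(0L, n, L)
      A[, 1L] <- stats::rbinom(n, 1L, 0.5)
      if (L > 1L) {
        rstar <- rilSwitchProb(haldane(diff(pos)))
        for (k in 2:L) {
          sw <- stats::rbinom(n, 1L, rstar[k - 1L])
          A[, k] <- (A[, k - 1L] + sw) %% 2L
        }
      }
      A
    })
    A <- do.call(cbind, cols)
    dos <- 2L * A
    colnames(dos) <- loci$locus
    rownames(dos) <- sprintf("L%03d", seq_len(n))
    new("CrossPopulation", popType = "RIL", genotypes = dos, loci = loci,
        seed = asSeed(seed))
  })
}

#' Split a population into marker and QTL genotype matrices
#'
#' Partitions the genotype columns of a [CrossPopulation-class] by the
#' `is_marker` flag, preserving locus order. Binding the two blocks back in
#' locus order reproduces the input matrix.
#'
#' @param pop a [CrossPopulation-class].
#' @return list with elements `markers` (n x p dosage matrix) and `qtl`
#'   (n x #QTL dosage matrix, zero columns if the population has no hidden
#'   QTL loci).
#' @export
splitMarkers <- function(pop) {
  stopIf(!is(pop, "CrossPopulation"), "pop must be a CrossPopulation")
  list(markers = markerGenotypes(pop), qtl = qtlGenotypes(pop))
}
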