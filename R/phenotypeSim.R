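#' Genotype coding maps for the three gene actions
#'
#' Converts raw allele dosages (0/1/2 copies of the parent-A allele) to the
#' coded genotypes used as model features and QTL genotypes: additive
#' `(0,1,2) -> (-1,0,1)`, complete dominance `(0,1,2) -> (0,1,1)`,
#' overdominance `(0,1,2) -> (0,1,0)`.
#'
#' @param action `"additive"`, `"complete_dominance"` or `"overdominance"`.
#' @return named numeric vector mapping dosage `"0"`, `"1"`, `"2"` to codes.
#' @export
geneActionCoding <- function(action = c("additive", "complete_dominance",
                                        "overdominance")) {
  action <- match.arg(action)
  switch(action,
         additive = c(`0` = -1, `1` = 0, `2` = 1),
         complete_dominance = c(`0` = 0, `1` = 1, `2` = 1),
         overdominance = c(`0` = 0, `1` = 1, `2` = 0))
}

#' Code a dosage matrix under a gene action
#'
#' @param dosages matrix with entries in `{0,1,2}`.
#' @inheritParams geneActionCoding
#' @return numeric matrix of the same shape with the coding applied
#'   elementwise.
#' @examples
#' codeGenotypes(matrix(0:2, 1), "additive")   # -1 0 1
#' @export
codeGenotypes <- function(dosages, action = c("additive",
                                              "complete_dominance",
                                              "overdominance")) {
  stopIf(!all(dosages %in% c(0, 1, 2)), "dosage entries must be in {0,1,2}")
  cmap <- geneActionCoding(action)
  out <- matrix(cmap[as.character(dosages)], nrow(dosages), ncol(dosages),
                dimnames = dimnames(dosages))
  out
}

#' Draw QTL main and interaction effects
#'
#' Main effects are independent `N(0, mainSd^2)` draws for the QTLs with
#' nonzero effects (a uniformly random subset when `nNonzeroMain < 5`, the
#' remaining effects are exactly zero) and one `N(0, interactionSd^2)` draw
#' is made per interacting pair. With the default standard deviations of 1
#' the effects follow the standard normal distribution.
#'
#' @param layout a [QTLLayout-class].
#' @param action gene action, stored for downstream coding.
#' @param mainSd,interactionSd effect standard deviations (> 0).
#' @param nNonzeroMain number of QTLs with nonzero main effects (2 or 5).
#' @param seed optional integer seed.
#' @return a [QTLModel-class].
#' @export
drawEffects <- function(layout, action = "additive", mainSd = 1,
                        interactionSd = 1, nNonzeroMain = 5L, seed = NULL) {
  stopIf(!nNonzeroMain %in% c(2L, 5L), "nNonzeroMain must be 2 or 5")
  stopIf(mainSd <= 0 || interactionSd <= 0, "effect sds must be positive")
  withSeed(seed, {
    main <- stats::rnorm(5L, 0, mainSd)
    if (nNonzeroMain < 5L)
      main[sample(5L, 5L - nNonzeroMain)] <- 0
    int <- stats::rnorm(nrow(layout@pairs), 0, interactionSd)
    new("QTLModel", layout = layout, action = action, mainEffects = main,
        interactionEffects = int, mainSd = mainSd,
        interactionSd = interactionSd)
  })
}

#' Genetic values from coded QTL genotypes
#'
#' Main values are `sum_q a_q z_iq`; interaction values are additive-by-
#' additive (or dominance-by-dominance, depending on the coding) products
#' `sum_(q,r) b_qr z_iq z_ir` over the interacting pairs.
#'
#' @param codedQtl n x 5 matrix of QTL genotypes coded under the model's
#'   gene action (see [codeGenotypes()]).
#' @param model a [QTLModel-class].
#' @return list with numeric vectors `main` and `interaction` of length n.
#' @export
geneticValues <- function(codedQtl, model) {
  stopIf(ncol(codedQtl) != length(model@mainEffects),
         "codedQtl must have one column per QTL")
  main <- unname(drop(codedQtl %*% model@mainEffects))
  pr <- model@layout@pairs
  interaction <- rep(0, nrow(codedQtl))
  for (k in seq_len(nrow(pr)))
    interaction <- interaction + model@interactionEffects[k] *
      codedQtl[, pr[k, 1L]] * codedQtl[, pr[k, 2L]]
  list(main = main, interaction = unname(interaction))
}

#' Add residual noise at a target broad-sense heritability
#'
#' Residuals are drawn `N(0, sigma_e^2)` with `sigma_e^2 = Var(g) (1 -
#' H2) / H2`, where `g = main + interaction` and `Var` is the sample
#' variance (n - 1 denominator) of the replicate at hand, so the realized
#' heritability targets `H2` per replicate. Realized variance proportions
#' are `Var(main) / Var(phenotypes)` and `Var(interaction) /
#' Var(phenotypes)`.
#'
#' @param main,interaction numeric genetic-value vectors (same length).
#' @param H2 target broad-sense heritability in (0, 1].
#' @param seed optional integer seed.
#' @return a [PhenotypeSet-class].
#' @examples
#' addNoise(c(-1, 0, 1), c(0, 0, 0), H2 = 1)   # zero residuals
#' @export
addNoise <- function(main, interaction, H2 = 0.8, seed = NULL) {
  stopIf(H2 <= 0 || H2 > 1, "H2 must be in (0, 1]")
  g <- main + interaction
  vg <- stats::var(g)
  stopIf(!is.finite(vg) || vg <= 0,
         "genetic values are constant; cannot scale residual variance")
  sigma2 <- vg * (1 - H2) / H2
  withSeed(seed, {
    res <- if (sigma2 > 0) stats::rnorm(length(g), 0, sqrt(sigma2))
           else rep(0, length(g))
    y <- g + res
    new("PhenotypeSet", mainValues = main, interactionValues = interaction,
        residuals = res, phenotypes = y, H2Target = H2,
        realizedVA = stats::var(main) / stats::var(y),
        realizedVI = stats::var(interaction) / stats::var(y))
  })
}

#' Settings of the nine simulation scenarios
#'
#' Returns the study conditions of a scenario: population type (`F2` or
#' `RIL`), gene action, population size, interaction-effect standard
#' deviation (4 in scenario 5, i.e. variance 16; otherwise 1), number of
#' QTLs with nonzero main effects (2 in scenario 6, else 5), and whether
#' the QTLs are linked (scenario 9).
#'
#' @param scenario integer in 1..9.
#' @return list with elements `popType`, `action`, `n`, `interactionSd`,
#'   `nNonzeroMain`, `linked`.
#' @export
scenarioSettings <- function(scenario) {
  stopIf(!scenario %in% 1:9, "scenario must be in 1..9")
  list(
    popType = if (scenario %in% c(2L, 8L)) "RIL" else "F2",
    action = switch(as.character(scenario), `3` = "complete_dominance",
                    `4` = "overdominance", "additive"),
    n = if (scenario %in% c(7L, 8L)) 400L else 200L,
    interactionSd = if (scenario == 5L) 4 else 1,
    nNonzeroMain = if (scenario == 6L) 2L else 5L,
    linked = scenario == 9L)
}

#' Run one full scenario replicate of the simulator
#'
#' Chains map generation (8 chromosomes x 120 cM, 20 markers each), QTL
#' placement, cross simulation, effect drawing, genotype coding and
#' phenotype generation at broad-sense heritability `H2` for one replicate
#' of a simulation scenario.
#'
#' @param scenario integer in 1..9.
#' @param seed optional integer seed for the whole replicate.
#' @param H2 target broad-sense heritability.
#' @param nChr,chrLenCM,markersPerChr map dimensions.
#' @param n population size override (default: the scenario's size).
#' @return list with components `map`, `layout`, `pop`, `model`, `phen`
#'   (a [PhenotypeSet-class]), `X` (coded marker matrix used as features)
#'   and `settings`.
#' @examples
#' rep1 <- simulateScenario(1, seed = 1)
#' realizedVA(rep1$phen)
#' @export
simulateScenario <- function(scenario, seed = NULL, H2 = 0.8, nChr = 8L,
                             chrLenCM = 120, markersPerChr = 20L, n = NULL) {
  st <- scenarioSettings(scenario)
  if (!is.null(n)) st$n <- as.integer(n)
  withSeed(seed, {
    map <- makeMap(nChr, chrLenCM, markersPerChr)
    layout <- placeQtls(map, scenario)
    pop <- if (st$popType == "RIL") simulateRil(map, layout, st$n)
           else simulateF2(map, layout, st$n)
    model <- drawEffects(layout, action = st$action,
                         interactionSd = st$interactionSd,
                         nNonzeroMain = st$nNonzeroMain)
    parts <- splitMarkers(pop)
    gv <- geneticValues(codeGenotypes(parts$qtl, st$action), model)
    phen <- addNoise(gv$main, gv$interaction, H2 = H2)
    X <- codeGenotypes(parts$markers, st$action)
    list(map = map, layout = layout, pop = pop, model = model, phen = phen,
         X = X, settings = st)
  })
}
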