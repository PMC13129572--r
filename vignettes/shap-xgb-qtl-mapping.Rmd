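---
title: "Mapping QTLs and epistasis with gradient tree boosting and SHAP"
author: "shapQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping QTLs and epistasis with gradient tree boosting and SHAP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapQTL)
```

## The problem

In a biparental cross (F2 or recombinant inbred lines), quantitative trait
locus (QTL) mapping asks which markers are associated with a quantitative
phenotype. Epistasis — the statistical interaction between loci — is harder:
classical linear scans test markers one or two at a time and lose power for
interactions. Gradient-boosted regression trees capture interactions
natively, but a fitted ensemble does not expose per-marker effects.
shapQTL turns a boosted ensemble into mapping signals via Shapley additive
explanations (SHAP): per line (instance) $i$ and marker $j$ the SHAP value
$\phi_j$ is the Shapley value of a cooperative game whose players are
markers and whose payoff is the model output,

$$\phi_j=\sum_{S\subseteq N\setminus\{j\}}
\frac{|S|!\,(M-|S|-1)!}{M!}\bigl[v(S\cup\{j\})-v(S)\bigr],$$

with $v(S)=E[f(x)\mid x_S]$ the path-dependent conditional expectation of
the tree ensemble (follow the instance's branch when the split feature is
in $S$, otherwise average the children weighted by their training cover).
The pairwise Shapley interaction index $\phi_{jk}$ decomposes each
$\phi_j$ into a main part $\phi_{jj}$ and interaction parts:
$\phi_j=\phi_{jj}+\sum_{k\ne j}\phi_{jk}$, with $\phi_{jk}=\phi_{kj}$, so a
pair's total effect is $2\phi_{jk}$.

## The mapping pipeline

`runShapXgb()` implements the bootstrap algorithm:

1. draw a bootstrap sample of lines; the in-bag lines train a squared-error
   xgboost model, the out-of-bag lines drive early stopping (3
   non-improving rounds by default);
2. compute SHAP values and SHAP interaction values for *all* original
   lines under that model;
3. repeat (100 times by default) and average per line;
4. aggregate to global scores: compound $\;\mathrm{mean}_i\,|\phi_j|$,
   pure $\;\mathrm{mean}_i\,|\phi_{jj}|$, and pair scores
   $\;\mathrm{mean}_i\,|2\phi_{jk}|$.

Step 2 evaluates SHAP for all lines rather than only the in-bag sample:
that choice gives every line the same weight in every replicate and makes
the average well defined; the alternative (in-bag only) would weight lines
by their bootstrap multiplicity.

Compound scores fold interaction contributions into a marker's main-effect
signal; pure scores strip them. Compound is the default for mapping main
effects — it gains a little power when epistatic variance is large, at the
price of slightly more false positives when an interacting QTL has no main
effect.

```{r quick-example}
sc <- simulateScenario(1, seed = 11)
res <- runShapXgb(sc$X, phenotypes(sc$phen), nBoot = 10, seed = 11)
head(sort(scoreMode(res, "compound"), decreasing = TRUE), 3)
head(pairScores(res), 3)
```

(10 bootstrap replicates keep this chunk quick; analyses should use the
default 100.)

## Two routes to every Shapley quantity

The package computes each SHAP quantity twice, by independent routes:

* **Enumeration oracle.** `shapleyExact()` and
  `shapleyInteractionsExact()` evaluate the defining sums over all feature
  subsets, with the conditional expectation evaluated by tree traversal.
  Features the ensemble never splits on are dummy players; the oracle
  enumerates subsets of the used features and aggregates the Shapley
  weights of the unused ones in closed form, so it stays exact while
  guarded to 15 (values) / 12 (interactions) features.
* **Fast path.** `treeShap(..., method = "r")` implements the
  path-dependent Tree SHAP recursion (the EXTEND/UNWIND bookkeeping over
  the unique-feature path), and `treeShapInteractions()` obtains
  $\phi_{jk}$ from the conditioning identity
  $\phi_{jk}=\tfrac12(\phi_k^{(+j)}-\phi_k^{(-j)})$, where $(+j)$/$(-j)$
  force marker $j$ to be always followed / always averaged out.

The test suite asserts three-way agreement — oracle, in-package recursion,
and the boosting library's compiled implementation — to $10^{-6}$ on
randomized small ensembles, along with local accuracy
($\phi_0+\sum_j\phi_j$ equals the prediction), symmetry, and the
$\phi_j=\sum_k\phi_{jk}$ decomposition. Inside the bootstrap pipeline the
compiled implementation is used for speed; its agreement with the oracle
is what licenses that delegation.

## The simulator

The synthetic populations reproduce the standard evaluation conditions:

* **Map**: 8 chromosomes of 120 cM, 20 markers per chromosome at
  uniform-random positions (`makeMap(8, 120, 20)`).
* **Crossovers**: Poisson count with mean length/100 and uniform
  positions — the Haldane no-interference model, so the recombination
  fraction over $d$ cM is $r=(1-e^{-2d/100})/2$ in closed form, which the
  tests verify against simulated gametes at 3 Monte-Carlo standard
  errors. QTL loci are simulated jointly with markers on the same gametes
  (exact linkage) and then hidden.
* **RILs**: simulated directly as the asymptotic selfed-RIL Markov chain
  with switch probability $r^*=2r/(1+2r)$ per interval, rather than by
  iterating selfing generations; lines are fully homozygous.
* **Architecture**: 5 QTLs (one per random chromosome; scenario 9 instead
  places a linked triple spaced 30 cM and a linked duo spaced 30 cM, at a
  random island start), 5 of the 10 QTL pairs interacting. Main and
  interaction effects are standard normal (scenario 5 raises the
  interaction SD to 4, i.e. variance 16; scenario 6 zeroes a random 3 of
  5 main effects). Gene action codes dosages (0,1,2) as additive
  $(-1,0,1)$, complete dominance $(0,1,1)$ or overdominance $(0,1,0)$,
  and interactions are products of coded genotypes.
* **Phenotypes**: residuals are Gaussian with variance
  $\mathrm{Var}(g)(1-H^2)/H^2$ scaled to each replicate's realized sample
  genetic variance (n−1 denominator), so every replicate targets
  broad-sense heritability $H^2=0.8$ exactly in expectation. Realized
  variance proportions are component sample variances over the phenotype
  sample variance, ignoring the (zero-mean) covariance terms — the
  convention under which the published shares sum to ≈ 0.8.

What the generator does *not* emulate: crossover interference, missing or
erroneous genotypes, segregation distortion, multi-environment (G×E)
structure, and non-Gaussian residuals. Passing simulation tests therefore
demonstrates correctness of the machinery under idealized meiosis, not
robustness to those real-data features.

Note that the realized variance shares are ratios of
$\chi^2_5$-distributed effect sums, so they vary strongly between
replicates and 10-replicate means (the standard evaluation protocol)
still scatter considerably around the generator's center; comparisons of
such means are only meaningful with multi-standard-error bands.

## Detection power evaluation

`labelMarkers()` marks a marker positive when it lies within ±10 cM of a
QTL on the same chromosome (boundary inclusive; the window never crosses a
chromosome); `labelPairs()` marks a marker pair positive when its members
tag the two distinct QTLs of an interacting pair, in either orientation —
two markers tagging the same QTL are negative. `rocAuc()` ranks global
scores against these labels (midrank tie handling, so the AUC is the
Mann-Whitney probability that a positive outscores a negative), and
`runScenario()` chains the whole loop. On Scenario-1-scale data the
moderate preset reaches mean main-effect AUCs well above 0.7.

## Fitting presets and numerical choices

* `moderate`: learning rate 0.3, depth 6 (library defaults, pinned
  explicitly with L2 penalty 1, gamma 0, no subsampling), early stopping
  after 3 non-improving validation rounds, RMSE metric. `underfit`: rate
  0.1, depth 3, same stopping. `overfit`: defaults, exactly 50 rounds, no
  early stopping. Under- and over-fitting deflate and inflate the SHAP
  values, but ROC/AUC depends only on relative marker rankings, which the
  acceptance tests confirm move by < 0.05 AUC across presets.
* The model intercept is the training-phenotype mean (not the 0.5 many
  libraries default to, which would distort regression base values); it
  is configurable via `boostConfig(basePrediction = )`.
* Split routing is strictly-less-than everywhere (prediction, conditional
  expectation, Tree SHAP), matching the fitting library. Coded genotypes
  are integers, so threshold ties cannot arise in practice.
* Early-stopped ensembles are truncated to the best validation iteration
  before structure extraction, so the dumped trees are exactly the trees
  the model predicts with.
* Leaf values cross a 32-bit float representation inside the fitting
  library; round-trip and cross-implementation agreements are therefore
  asserted at $10^{-6}$ absolute, and exact enumeration guards
  (15/12 features) keep the oracle in the seconds range.
* Degenerate inputs fail loudly: constant genetic values (no variance to
  scale residuals against), single-class ROC labels, missing genotypes,
  and dosage values outside the declared coding are all errors, not
  warnings.

## Design decisions on open points

* **Bootstrap SHAP evaluation set**: all lines, for the equal-weighting
  reason above.
* **Scenario 9 cross-chromosome interaction**: read as exactly one pair
  chosen uniformly among the 3×2 triple-duo candidates, in addition to
  the four within-chromosome pairs.
* **Positions** are continuous cM on a per-chromosome axis starting at 0;
  QTLs need not coincide with markers.
* **Exact equivariance caveat**: global scores are equivariant to marker
  permutation through the attribution stage, but the boosting library
  breaks exact equivariance when two candidate splits tie on gain (the
  first column wins). Pipeline outputs are therefore permutation-invariant
  in distribution, not bit-for-bit; the tests pin the attribution-stage
  invariance.
* **Adjacent-marker interactions**: linked neighbouring markers can soak
  up interaction score that is really a main effect in disguise;
  `pairScores()` reports all pairs and leaves any minimum-distance
  filtering to the analyst (compound scores are unaffected).

## Problem sizes used by the shipped checks

The acceptance suite runs the oracle sweep on 50 random ensembles with up
to 10 features and depth 3; variance-share and window-count checks use the
published protocol of 10 replicates; simulator calibration uses $10^5$
gametes; and the pipeline behaviour checks run Scenario-1/Scenario-5-scale
data (200 lines × 160 markers) with 25 bootstrap replicates and 5
simulation replicates, with interaction tensors computed only where pair
scores are needed. These sizes were chosen so the whole suite documents
the method's behaviour at realistic scale while remaining routine to run;
production analyses should prefer the default `nBoot = 100`.

## Known limitations

* Linkage disequilibrium between dense markers dilutes per-marker SHAP
  values (the conditional expectation assumes feature independence);
  scores shrink toward zero as marker density grows, and pure scores can
  leak main effect into neighbour interactions.
* No significance thresholds are provided — scores rank markers; deciding
  a cutoff (e.g. by permutation) is outside the package's scope.
* Memory for interaction tensors grows as $n\,p^2$; interaction scoring at
  GWAS scale would need marker pre-screening.
* Only two-way interactions are scored.
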