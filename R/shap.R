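# Shapley engine for tree ensembles.
#
# Two routes to the same quantities:
#  * an exact subset-enumeration oracle (shapleyExact /
#    shapleyInteractionsExact) evaluating the cover-weighted conditional
#    expectation for every feature subset, guarded to small p;
#  * a fast path-dependent Tree SHAP (treeShap / treeShapInteractions)
#    using the EXTEND/UNWIND path-weight recursion, linear-ish in tree
#    size, which must agree with the oracle to 1e-6.
# The value function is the path-dependent conditional expectation: at a
# node splitting on a feature in S the instance's branch is followed; at a
# node splitting on a feature outside S the cover-weighted average of both
# children is taken.

# E[f|x_S] of one tree, S given as logical mask over features
condExpTree <- function(tr, x, inS) {
  rec <- function(j) {
    f <- tr$feature[j]
    if (is.na(f)) return(tr$value[j])
    if (inS[f]) {
      if (x[f] < tr$split[j]) rec(tr$yes[j]) else rec(tr$no[j])
    } else {
      (tr$cover[tr$yes[j]] * rec(tr$yes[j]) +
       tr$cover[tr$no[j]] * rec(tr$no[j])) / tr$cover[j]
    }
  }
  rec(1L)
}

#' Conditional expectation of a tree ensemble given a feature subset
#'
#' Evaluates `E[f(x) | x_S]` with cover-weighted (path-dependent)
#' averaging: at a node splitting on a feature in `S` the instance's branch
#' is followed; otherwise both children are averaged with weights
#' proportional to their covers. With `S` = all features this is exactly
#' the prediction; with `S` empty it is the model's expected output (the
#' SHAP base value).
#'
#' @param ensemble a [TreeEnsemble-class].
#' @param x numeric feature vector (length `nFeatures`).
#' @param S integer vector of feature indices conditioned on (may be
#'   empty).
#' @return scalar conditional expectation.
#' @export
conditionalExpectation <- function(ensemble, x, S = integer(0)) {
  stopIf(length(x) != ensemble@nFeatures, "x must have nFeatures entries")
  stopIf(length(S) && (any(S < 1L) || any(S > ensemble@nFeatures)),
         "S must index features")
  inS <- rep(FALSE, ensemble@nFeatures)
  inS[S] <- TRUE
  ensemble@basePrediction +
    sum(vapply(ensemble@trees, condExpTree, 0, x = x, inS = inS))
}

# memoised value table v(mask) over all 2^p subsets encoded as bitmasks.
# Only features actually used by the ensemble branch the expectation, so
# the table is computed on the used features and shared by the oracles.
valueTable <- function(ensemble, x) {
  p <- ensemble@nFeatures
  used <- sort(unique(stats::na.omit(unlist(
    lapply(ensemble@trees, function(tr) tr$feature)))))
  u <- length(used)
  v <- numeric(2^u)
  inS <- rep(FALSE, p)
  for (mask in 0:(2^u - 1)) {
    inS[] <- FALSE
    inS[used[bitwAnd(mask, bitwShiftL(1L, seq_len(u) - 1L)) != 0L]] <- TRUE
    v[mask + 1L] <- ensemble@basePrediction +
      sum(vapply(ensemble@trees, condExpTree, 0, x = x, inS = inS))
  }
  list(used = used, v = v)
}

# v(S) lookup for S a subset of 1..p given the used-feature table
lookupV <- function(vt, S) {
  idx <- match(intersect(S, vt$used), vt$used)
  mask <- sum(bitwShiftL(1L, idx - 1L))
  vt$v[mask + 1L]
}

#' Exact Shapley values by subset enumeration
#'
#' Computes the SHAP value of every feature for one instance by full
#' enumeration: `phi_i = sum_{S subseteq N \ {i}} |S|! (M-|S|-1)! / M!
#' [E(f|x_{S+i}) - E(f|x_S)]`, with the conditional expectation of
#' [conditionalExpectation()] as value function. Serves as the oracle the
#' fast algorithm is validated against; refuses more than `guard` features.
#'
#' @param ensemble a [TreeEnsemble-class].
#' @param x numeric feature vector.
#' @param guard enumeration guard on the number of features (default 15).
#' @return list with `phi` (numeric p) and `baseValue` (`E[f]`, the empty-
#'   subset expectation); `baseValue + sum(phi)` equals the prediction.
#' @export
shapleyExact <- function(ensemble, x, guard = 15L) {
  p <- ensemble@nFeatures
  stopIf(p > guard,
         "p = %d exceeds the enumeration guard (%d); use treeShap()", p,
         guard)
  vt <- valueTable(ensemble, x)
  used <- vt$used
  u <- length(used)
  phi <- numeric(p)
  M <- p
  # features never split on are dummies: phi = 0 (missingness); for the
  # rest, dummies do not change marginal contributions, so enumerating
  # subsets of the used features with full-M Shapley weights aggregated
  # over the unused features is exact. Aggregation: a subset T of used
  # features stands for all S with S-cap-used = T; summing the weights
  # |S|!(M-|S|-1)!/M! over the (M-u choose k) ways to add k unused
  # features gives the collapsed weight below.
  wcol <- function(t) { # t = |T|, collapsed weight for subsets of used
    k <- 0:(M - u)
    sum(choose(M - u, k) * factorial(t + k) *
        factorial(M - (t + k) - 1) / factorial(M))
  }
  wt <- if (u > 0L) vapply(0:(u - 1), wcol, 0) else numeric(0)
  for (ii in seq_len(u)) {
    i <- used[ii]
    bit_i <- bitwShiftL(1L, ii - 1L)
    for (mask in 0:(2^u - 1)) {
      if (bitwAnd(mask, bit_i) != 0L) next
      t <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(u - 1))) != 0L)
      phi[i] <- phi[i] + wt[t + 1L] *
        (vt$v[bitwOr(mask, bit_i) + 1L] - vt$v[mask + 1L])
    }
  }
  list(phi = phi, baseValue = vt$v[1L])
}

#' Exact Shapley interaction values by subset enumeration
#'
#' Off-diagonal entries follow the Shapley interaction index
#' `phi_ij = sum_{S subseteq N \ {i,j}} |S|! (M-|S|-2)! / (2 (M-1)!)
#' delta_ij(S)` with `delta_ij(S) = f(S+ij) - f(S+i) - f(S+j) + f(S)`; the
#' matrix is symmetric and the diagonal is defined by the decomposition
#' `phi_ii = phi_i - sum_{j != i} phi_ij`, so every row sums to the
#' feature's SHAP value.
#'
#' @inheritParams shapleyExact
#' @param guard enumeration guard (default 12).
#' @return list with `phiMatrix` (p x p), `phi` (numeric p) and
#'   `baseValue`.
#' @export
shapleyInteractionsExact <- function(ensemble, x, guard = 12L) {
  p <- ensemble@nFeatures
  stopIf(p > guard,
         "p = %d exceeds the enumeration guard (%d); use treeShapInteractions()",
         p, guard)
  vt <- valueTable(ensemble, x)
  used <- vt$used
  u <- length(used)
  M <- p
  mat <- matrix(0, p, p)
  if (u >= 2L) {
    # collapsed interaction weights over unused (dummy) features, as in
    # shapleyExact but for the (M-2)-player coefficient
    wcol2 <- function(t) {
      k <- 0:(M - u)
      sum(choose(M - u, k) * factorial(t + k) *
          factorial(M - (t + k) - 2) / (2 * factorial(M - 1)))
    }
    wt2 <- vapply(0:max(0, u - 2), wcol2, 0)
    for (ii in seq_len(u - 1L)) for (jj in (ii + 1L):u) {
      i <- used[ii]; j <- used[jj]
      bi <- bitwShiftL(1L, ii - 1L); bj <- bitwShiftL(1L, jj - 1L)
      acc <- 0
      for (mask in 0:(2^u - 1)) {
        if (bitwAnd(mask, bi) != 0L || bitwAnd(mask, bj) != 0L) next
        t <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(u - 1))) != 0L)
        delta <- vt$v[bitwOr(mask, bitwOr(bi, bj)) + 1L] -
          vt$v[bitwOr(mask, bi) + 1L] - vt$v[bitwOr(mask, bj) + 1L] +
          vt$v[mask + 1L]
        acc <- acc + wt2[t + 1L] * delta
      }
      mat[i, j] <- acc
      mat[j, i] <- acc
    }
  }
  sv <- shapleyExact(ensemble, x, guard = guard)
  diag(mat) <- sv$phi - rowSums(mat)
  list(phiMatrix = mat, phi = sv$phi, baseValue = sv$baseValue)
}

# ---- fast path-dependent Tree SHAP --------------------------------------

# One tree's contribution to phi for instance x.
# m is the unique-feature path: parallel vectors d (feature), z (zero
# fraction), o (one fraction), w (permutation weight); element 1 is a
# dummy. forcePresent / forceAbsent features never enter the path: present
# means "always follow x's branch", absent means "always cover-average"
# (scaling accumulated in q).
treeShapOne <- function(tr, x, phi, forcePresent = integer(0),
                        forceAbsent = integer(0)) {
  extend <- function(d, z, o, w, pz, po, pi) {
    l <- length(w)
    d <- c(d, pi); z <- c(z, pz); o <- c(o, po)
    w <- c(w, if (l == 0L) 1 else 0)
    if (l > 0L) for (i in l:1) {
      w[i + 1L] <- w[i + 1L] + po * w[i] * i / (l + 1L)
      w[i] <- pz * w[i] * (l + 1L - i) / (l + 1L)
    }
    list(d = d, z = z, o = o, w = w)
  }
  # removes path entry i; weights stay positional for the surviving l-1
  # elements (the inverse of extend)
  unwind <- function(m, i) {
    l <- length(m$w)
    nn <- m$w[l]
    w <- numeric(l - 1L)
    if (m$o[i] != 0) {
      for (j in (l - 1L):1) {
        t <- m$w[j]
        w[j] <- nn * l / (j * m$o[i])
        nn <- t - w[j] * m$z[i] * (l - j) / l
      }
    } else {
      for (j in (l - 1L):1) w[j] <- m$w[j] * l / (m$z[i] * (l - j))
    }
    keep <- setdiff(seq_len(l), i)
    list(d = m$d[keep], z = m$z[keep], o = m$o[keep], w = w)
  }
  unwoundSum <- function(m, i) sum(unwind(m, i)$w)
  rec <- function(j, m, pz, po, pi, q) {
    if (is.na(pi)) {
      # forced feature on the incoming edge: no path extension
    } else {
      m <- extend(m$d, m$z, m$o, m$w, pz, po, pi)
    }
    f <- tr$feature[j]
    if (is.na(f)) {
      l <- length(m$w)
      if (l >= 2L) for (i in 2:l) {
        phi[m$d[i]] <<- phi[m$d[i]] +
          q * unwoundSum(m, i) * (m$o[i] - m$z[i]) * tr$value[j]
      }
      return(invisible(NULL))
    }
    hot <- if (x[f] < tr$split[j]) tr$yes[j] else tr$no[j]
    cold <- if (hot == tr$yes[j]) tr$no[j] else tr$yes[j]
    if (f %in% forcePresent) {
      rec(hot, m, 1, 1, NA, q)
      return(invisible(NULL))
    }
    if (f %in% forceAbsent) {
      rec(tr$yes[j], m, 1, 1, NA, q * tr$cover[tr$yes[j]] / tr$cover[j])
      rec(tr$no[j], m, 1, 1, NA, q * tr$cover[tr$no[j]] / tr$cover[j])
      return(invisible(NULL))
    }
    iz <- 1; io <- 1
    k <- match(f, m$d[-1L])
    if (!is.na(k)) {
      k <- k + 1L
      iz <- m$z[k]; io <- m$o[k]
      m <- unwind(m, k)
    }
    rec(hot, m, iz * tr$cover[hot] / tr$cover[j], io, f, q)
    rec(cold, m, iz * tr$cover[cold] / tr$cover[j], 0, f, q)
    invisible(NULL)
  }
  m0 <- list(d = numeric(0), z = numeric(0), o = numeric(0), w = numeric(0))
  rec(1L, m0, 1, 1, 0, 1)
  phi
}

treeShapR <- function(ensemble, X, forcePresent = integer(0),
                      forceAbsent = integer(0)) {
  p <- ensemble@nFeatures
  phi <- matrix(0, nrow(X), p)
  base <- numeric(nrow(X))
  for (r in seq_len(nrow(X))) {
    x <- X[r, ]
    acc <- numeric(p)
    for (tr in ensemble@trees)
      acc <- treeShapOne(tr, x, acc, forcePresent, forceAbsent)
    phi[r, ] <- acc
    # base value under the forcing: conditional expectation with S =
    # forcePresent (forced-absent features are averaged out anyway)
    base[r] <- conditionalExpectation(ensemble, x, S = forcePresent)
  }
  list(phi = phi, baseValue = base)
}

#' Fast SHAP values for a tree ensemble
#'
#' Path-dependent Tree SHAP: per-tree recursion over the unique-feature
#' path with the EXTEND/UNWIND permutation-weight bookkeeping, summed over
#' trees. Agrees with [shapleyExact()] to 1e-6 wherever the enumeration
#' guard allows. For ensembles fitted in-package the computation can be
#' delegated to the attached booster (`method = "booster"`), which runs the
#' same algorithm in compiled code; `method = "auto"` does so when a
#' booster is attached.
#'
#' @param ensemble a [TreeEnsemble-class].
#' @param X numeric matrix of instances (rows).
#' @param method `"auto"`, `"r"` (in-package recursion) or `"booster"`.
#' @return list with `phi` (n x p matrix) and `baseValue` (numeric n);
#'   `baseValue + rowSums(phi)` equals the prediction for every row (local
#'   accuracy).
#' @export
treeShap <- function(ensemble, X, method = c("auto", "r", "booster")) {
  method <- match.arg(method)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  stopIf(ncol(X) != ensemble@nFeatures, "X must have nFeatures columns")
  if (method == "auto")
    method <- if (!is.null(ensemble@booster)) "booster" else "r"
  if (method == "booster") {
    stopIf(is.null(ensemble@booster), "no booster attached to this ensemble")
    Xn <- X
    colnames(Xn) <- ensemble@featureNames
    ct <- stats::predict(ensemble@booster, Xn, predcontrib = TRUE)
    p <- ensemble@nFeatures
    return(list(phi = unname(ct[, seq_len(p), drop = FALSE]),
                baseValue = unname(ct[, p + 1L])))
  }
  treeShapR(ensemble, X)
}

#' Fast SHAP interaction values for a tree ensemble
#'
#' Off-diagonal interaction values are obtained from the conditioning
#' identity `phi_ij = (phi_j with i always present - phi_j with i always
#' absent) / 2`, each term a Tree SHAP run on the ensemble with feature `i`
#' fixed into or averaged out of every tree; the diagonal completes the
#' decomposition `phi_ii = phi_i - sum_{j != i} phi_ij`. Agrees with
#' [shapleyInteractionsExact()] to 1e-6. With `method = "booster"` the
#' attached booster's compiled implementation is used.
#'
#' @inheritParams treeShap
#' @return list with `phiArray` (n x p x p, symmetric in the last two
#'   dimensions), `phi` (n x p) and `baseValue` (numeric n).
#' @export
treeShapInteractions <- function(ensemble, X,
                                 method = c("auto", "r", "booster")) {
  method <- match.arg(method)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  stopIf(ncol(X) != ensemble@nFeatures, "X must have nFeatures columns")
  if (method == "auto")
    method <- if (!is.null(ensemble@booster)) "booster" else "r"
  p <- ensemble@nFeatures
  n <- nrow(X)
  if (method == "booster") {
    stopIf(is.null(ensemble@booster), "no booster attached to this ensemble")
    Xn <- X
    colnames(Xn) <- ensemble@featureNames
    it <- stats::predict(ensemble@booster, Xn, predinteraction = TRUE)
    ct <- stats::predict(ensemble@booster, Xn, predcontrib = TRUE)
    return(list(phiArray = unname(it[, seq_len(p), seq_len(p), drop = FALSE]),
                phi = unname(ct[, seq_len(p), drop = FALSE]),
                baseValue = unname(ct[, p + 1L])))
  }
  plain <- treeShapR(ensemble, X)
  arr <- array(0, dim = c(n, p, p))
  for (i in seq_len(p)) {
    pres <- treeShapR(ensemble, X, forcePresent = i)
    abs_ <- treeShapR(ensemble, X, forceAbsent = i)
    for (j in seq_len(p)) {
      if (j == i) next
      arr[, i, j] <- (pres$phi[, j] - abs_$phi[, j]) / 2
    }
  }
  # enforce exact symmetry (the two conditioning orders agree analytically)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i < j) {
      s <- (arr[, i, j] + arr[, j, i]) / 2
      arr[, i, j] <- s
      arr[, j, i] <- s
    }
  }
  for (i in seq_len(p))
    arr[, i, i] <- plain$phi[, i] - apply(arr[, i, , drop = FALSE], 1, sum)
  list(phiArray = arr, phi = plain$phi, baseValue = plain$baseValue)
}
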