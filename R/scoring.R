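#' Construct a Boolean network model
#'
#' @param tfs ordered node names (at most 60).
#' @param rules named list of [LogicRule-class], one per TF. Missing rules
#'   default to self-maintenance.
#' @param clamp TF names held active (over-expressed) throughout the
#'   simulation.
#' @return a [BooleanNetworkModel-class].
#' @export
BooleanNetworkModel <- function(tfs, rules = list(), clamp = character()) {
  missingRules <- setdiff(tfs, names(rules))
  for (tf in missingRules) rules[[tf]] <- buildLogicRule(tf)
  new("BooleanNetworkModel", tfs = tfs, rules = rules[tfs],
      clamp = unique(clamp))
}

#' Build a Boolean network model from a core GRN
#'
#' @param grn a [CoreGRN-class] with compiled rules.
#' @param clamp over-expressed TF set.
#' @return a [BooleanNetworkModel-class].
#' @export
asBooleanNetwork <- function(grn, clamp = character()) {
  stopifnot(is(grn, "CoreGRN"))
  if (!length(grn@rules)) stop("core GRN has no compiled logic rules")
  BooleanNetworkModel(networkTFs(grn), grn@rules, clamp)
}

setMethod("show", "BooleanNetworkModel", function(object) {
  cat("BooleanNetworkModel:", length(object@tfs), "TFs,",
      length(object@clamp), "clamped\n")
})

#' Prior model over initial network states
#'
#' Product-form prior: each TF is independently active with its empirical
#' activation probability; clamped (over-expressed) TFs have their marginal
#' forced to 1, modelling the discrete 0-to-1 switch at the start of the
#' conversion.
#'
#' @param marginals named numeric vector of per-TF activation
#'   probabilities in `[0, 1]`.
#' @param perturbation TF set whose marginals are forced to 1.
#' @return an object of class `PriorModel`.
#' @export
priorModel <- function(marginals, perturbation = character()) {
  stopifnot(all(marginals >= 0 & marginals <= 1), !is.null(names(marginals)))
  m <- marginals
  m[intersect(perturbation, names(m))] <- 1
  structure(list(marginals = m, perturbation = perturbation),
            class = "PriorModel")
}

#' Probability of a network state under the product prior
#'
#' Product over TFs of the marginal (active bit) or its complement
#' (inactive bit), after clamped marginals are forced to 1; any state with
#' a clamped TF inactive therefore has probability 0.
#'
#' @param state named logical/0-1 vector over the prior's TFs.
#' @param prior a [priorModel()].
#' @return probability in `[0, 1]`.
#' @export
statePrior <- function(state, prior) {
  m <- prior$marginals
  s <- as.logical(state[names(m)])
  if (anyNA(s)) stop("state must assign every TF of the prior")
  prod(ifelse(s, m, 1 - m))
}

#' Synchronous successor of a network state
#'
#' Every non-clamped TF takes the value of its logic rule evaluated on the
#' current state; clamped TFs remain active; self-maintaining nodes keep
#' their value. Dynamics are deterministic: each state has exactly one
#' successor.
#'
#' @param state named logical vector over the model's TFs.
#' @param model a [BooleanNetworkModel-class].
#' @return the successor state (named logical).
#' @export
synchronousSuccessor <- function(state, model) {
  stopifnot(is(model, "BooleanNetworkModel"))
  s <- as.logical(state[model@tfs])
  names(s) <- model@tfs
  if (anyNA(s)) stop("state must assign every model TF")
  nxt <- vapply(model@tfs, function(tf)
    evaluateRule(model@rules[[tf]], s), logical(1))
  nxt[model@clamp] <- TRUE
  nxt
}

#' Steps until the all-active state is reached
#'
#' Follows the deterministic synchronous trajectory from `state` and
#' returns the number of steps until the all-active state is first
#' reached, or `Inf` when a previously visited state recurs (the
#' trajectory has entered a cycle) without reaching it.
#'
#' @param state named logical vector.
#' @param model a [BooleanNetworkModel-class].
#' @param maxSteps safety cap on steps (default `2^n`, the state-space
#'   size, which guarantees cycle detection).
#' @return integer number of steps, or `Inf`.
#' @export
distanceToFullActivation <- function(state, model,
                                     maxSteps = 2^length(model@tfs)) {
  s <- as.logical(state[model@tfs])
  names(s) <- model@tfs
  seen <- new.env(hash = TRUE, parent = emptyenv())
  d <- 0L
  repeat {
    if (all(s)) return(d)
    key <- paste(as.integer(s), collapse = "")
    if (!is.null(seen[[key]])) return(Inf)
    seen[[key]] <- TRUE
    if (d >= maxSteps) return(Inf)
    s <- synchronousSuccessor(s, model)
    d <- d + 1L
  }
}

## ---- vectorized exact dynamics ---------------------------------------------

# Enumerate the clamped subspace: all 2^m states over the free (non-clamped)
# TFs with clamped TFs held active. Returns the state matrix, the successor
# index of every state, and the distance of every state to the all-active
# state (Inf when unreachable), computed by reverse BFS over the functional
# graph.
enumerateDynamics <- function(model) {
  tfs <- model@tfs
  n <- length(tfs)
  free <- setdiff(tfs, model@clamp)
  m <- length(free)
  if (m > 22L)
    stop("exact enumeration is capped at 22 free TFs (",
         m, " requested); use mode = 'monte_carlo'")
  nStates <- 2L^m
  S <- matrix(TRUE, nrow = nStates, ncol = n, dimnames = list(NULL, tfs))
  if (m > 0L) {
    for (j in seq_len(m)) {
      S[, free[j]] <- bitwAnd(seq_len(nStates) - 1L, bitwShiftL(1L, j - 1L)) > 0L
    }
  }
  evalClauseMat <- function(clusters) {
    if (!length(clusters)) return(rep(TRUE, nStates))
    val <- rep(FALSE, nStates)
    for (cl in clusters) {
      if (length(cl) == 1L) val <- val | S[, cl]
      else val <- val | (rowSums(S[, cl, drop = FALSE]) == length(cl))
    }
    val
  }
  Snext <- S
  for (tf in free) {
    rule <- model@rules[[tf]]
    if (rule@selfMaintain) {
      Snext[, tf] <- S[, tf]
    } else {
      pv <- evalClauseMat(rule@promoter)
      ev <- if (!length(rule@enhancers)) rep(TRUE, nStates) else {
        acc <- rep(FALSE, nStates)
        for (cl in rule@enhancers) acc <- acc | evalClauseMat(cl)
        acc
      }
      Snext[, tf] <- pv & ev
    }
  }
  encode <- function(M) {
    idx <- rep(0, nrow(M))
    if (m > 0L) for (j in seq_len(m))
      idx <- idx + as.numeric(M[, free[j]]) * 2^(j - 1L)
    idx + 1
  }
  succ <- encode(Snext)
  dist <- rep(Inf, nStates)
  target <- nStates  # all free TFs active (clamped are always active)
  dist[target] <- 0
  preds <- split(seq_len(nStates), succ)
  frontier <- target
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unlist(preds[as.character(frontier)], use.names = FALSE)
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  list(states = S, free = free, succ = succ, dist = dist)
}

statePriorVec <- function(S, free, prior) {
  m <- prior$marginals
  p <- rep(1, nrow(S))
  for (tf in free) {
    if (!tf %in% names(m)) stop("prior lacks a marginal for TF: ", tf)
    p <- p * ifelse(S[, tf], m[[tf]], 1 - m[[tf]])
  }
  p
}

#' Transcriptional score of a perturbation
#'
#' The prior-weighted measure of eventually reaching the all-active
#' network state under clamped synchronous dynamics. Two variants are
#' shipped: `"reachability"` (default) scores
#' `T = sum_s pi(s) * 1[d(s) < Inf]`, the probability that the network is
#' eventually fully activated; `"distance_weighted"` additionally rewards
#' shorter paths, `T = sum_s pi(s) * 1[d(s) < Inf] * (1 - d(s)/(dmax+1))`
#' with `dmax` the largest finite distance observed. Exact mode enumerates
#' the clamped subspace (at most 22 free TFs); Monte-Carlo mode draws
#' initial states from the prior and averages the indicator/weight,
#' reporting a standard error.
#'
#' @param model a [BooleanNetworkModel-class]; its `clamp` slot defines
#'   the perturbation.
#' @param prior a [priorModel()]; clamped marginals are forced to 1
#'   automatically.
#' @param mode `"exact"` or `"monte_carlo"`.
#' @param variant `"reachability"` or `"distance_weighted"`.
#' @param nSamples Monte-Carlo sample count (default 10000).
#' @param seed seed for Monte-Carlo sampling (required in that mode).
#' @return list with `T`, `variant`, `mode`, and for Monte-Carlo runs
#'   `se`, `n_samples`, `seed`.
#' @export
transcriptionalScore <- function(model, prior,
                                 mode = c("exact", "monte_carlo"),
                                 variant = c("reachability",
                                             "distance_weighted"),
                                 nSamples = 10000, seed = NULL) {
  stopifnot(is(model, "BooleanNetworkModel"))
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  prior <- priorModel(prior$marginals, union(prior$perturbation, model@clamp))
  if (mode == "exact") {
    dyn <- enumerateDynamics(model)
    p <- statePriorVec(dyn$states, dyn$free, prior)
    fin <- is.finite(dyn$dist)
    tval <- if (variant == "reachability") sum(p[fin]) else {
      dmax <- if (any(fin)) max(dyn$dist[fin]) else 0
      sum(p[fin] * (1 - dyn$dist[fin] / (dmax + 1)))
    }
    return(list(T = min(max(tval, 0), 1), variant = variant, mode = mode))
  }
  if (is.null(seed)) stop("monte_carlo mode requires a seed")
  stopifnot(nSamples >= 1)
  tfs <- model@tfs
  free <- setdiff(tfs, model@clamp)
  marg <- prior$marginals
  if (!all(free %in% names(marg)))
    stop("prior lacks marginals for some model TFs")
  memo <- new.env(hash = TRUE, parent = emptyenv())
  distOf <- function(s) {
    key <- paste(as.integer(s[free]), collapse = "")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    d <- distanceToFullActivation(s, model)
    memo[[key]] <- d
    d
  }
  vals <- withr::with_seed(seed, {
    draws <- matrix(stats::runif(nSamples * length(free)) <
                      rep(marg[free], each = nSamples),
                    nrow = nSamples,
                    dimnames = list(NULL, free))
    ds <- vapply(seq_len(nSamples), function(i) {
      s <- stats::setNames(rep(TRUE, length(tfs)), tfs)
      s[free] <- draws[i, ]
      distOf(s)
    }, numeric(1))
    if (variant == "reachability") as.numeric(is.finite(ds)) else {
      fin <- is.finite(ds)
      dmax <- if (any(fin)) max(ds[fin]) else 0
      ifelse(fin, 1 - ds / (dmax + 1), 0)
    }
  })
  list(T = mean(vals), se = stats::sd(vals) / sqrt(nSamples),
       variant = variant, mode = mode, n_samples = nSamples, seed = seed)
}

#' Epigenetic score of a perturbation
#'
#' For every network TF, the fraction of its target-active regulatory
#' regions that are already active in the initial cell type (matched by
#' region id with at least 1 bp of coordinate overlap between the active
#' segments). The fraction is set to 1 for over-expressed TFs — their
#' remodeling is bypassed — and for TFs without target-active regions. The
#' epigenetic score is the product of the fractions, measuring the
#' remodeling still required to reach the target epigenome.
#'
#' @param initialRegions named list (by TF/gene) of `GRanges` of regions
#'   active in the initial cell type (metadata `region_id`).
#' @param targetRegions named list of `GRanges` active in the target cell
#'   type, keyed by the network TFs.
#' @param perturbation over-expressed TF set.
#' @return list with `E` and `per_tf` (named fractions).
#' @export
epigeneticScore <- function(initialRegions, targetRegions,
                            perturbation = character()) {
  fr <- vapply(names(targetRegions), function(tf) {
    if (tf %in% perturbation) return(1)
    tgt <- targetRegions[[tf]]
    if (is.null(tgt) || !length(tgt)) return(1)
    ini <- initialRegions[[tf]]
    if (is.null(ini) || !length(ini)) return(0)
    shared <- vapply(seq_along(tgt), function(i) {
      rid <- S4Vectors::mcols(tgt)$region_id[i]
      j <- which(S4Vectors::mcols(ini)$region_id == rid)
      if (!length(j)) return(FALSE)
      any(GenomicRanges::countOverlaps(tgt[i], ini[j], minoverlap = 1L,
                                       ignore.strand = TRUE) > 0L)
    }, logical(1))
    mean(shared)
  }, numeric(1))
  list(E = prod(fr), per_tf = fr)
}

#' Combined surrogate efficiency
#'
#' The arithmetic mean of the transcriptional and epigenetic scores.
#'
#' @param T,E scores in `[0, 1]`.
#' @return `(T + E) / 2`.
#' @export
combinedScore <- function(T, E) {
  if (is.na(T) || is.na(E) || T < 0 || T > 1 || E < 0 || E > 1)
    stop("T and E must lie in [0, 1]")
  (T + E) / 2
}

#' Score one perturbation of a core GRN
#'
#' Convenience wrapper combining [transcriptionalScore()],
#' [epigeneticScore()] and [combinedScore()] into a
#' [ScoreBreakdown-class].
#'
#' @param grn a [CoreGRN-class] with compiled rules.
#' @param perturbation over-expressed TF set.
#' @param marginals named activation probabilities for the network TFs in
#'   the initial cell type.
#' @param initialRegions,targetRegions per-TF active region sets (see
#'   [epigeneticScore()]).
#' @param mode,variant,nSamples,seed passed to [transcriptionalScore()].
#' @return a [ScoreBreakdown-class].
#' @export
scorePerturbation <- function(grn, perturbation, marginals, initialRegions,
                              targetRegions, mode = "exact",
                              variant = "reachability", nSamples = 10000,
                              seed = NULL) {
  model <- asBooleanNetwork(grn, clamp = perturbation)
  ts <- transcriptionalScore(model, priorModel(marginals, perturbation),
                             mode = mode, variant = variant,
                             nSamples = nSamples, seed = seed)
  es <- epigeneticScore(initialRegions, targetRegions, perturbation)
  new("ScoreBreakdown", transcriptional = ts$T, epigenetic = es$E,
      combined = combinedScore(ts$T, es$E), perTF = es$per_tf,
      mode = mode, variant = variant,
      nSamples = if (mode == "exact") NA_real_ else nSamples,
      seed = if (is.null(seed)) NA_real_ else seed)
}

setMethod("show", "ScoreBreakdown", function(object) {
  cat(sprintf("ScoreBreakdown: T = %.4f, E = %.4f, combined = %.4f (%s, %s)\n",
              object@transcriptional, object@epigenetic, object@combined,
              object@mode, object@variant))
})

#' Rank all size-k combinations of instructive factors
#'
#' Scores every size-`k` subset of network TFs (or an explicit candidate
#' list) as a perturbation and ranks by combined score, descending, with a
#' deterministic lexicographic tie-break on the sorted, comma-joined TF
#' names. Exhaustive enumeration is refused above 1e6 combinations.
#'
#' @inheritParams scorePerturbation
#' @param k combination size.
#' @param candidates optional list of candidate combinations (each a
#'   character vector of size `k`); mandatory when `choose(n, k) > 1e6`.
#' @return data.frame with columns `combination`, `T`, `E`, `combined`,
#'   `rank`.
#' @export
rankCombinations <- function(grn, k, marginals, initialRegions,
                             targetRegions, candidates = NULL,
                             mode = "exact", variant = "reachability",
                             nSamples = 10000, seed = NULL) {
  tfs <- networkTFs(grn)
  n <- length(tfs)
  if (k < 1 || k > n) stop("k must lie between 1 and ", n)
  if (is.null(candidates)) {
    if (choose(n, k) > 1e6)
      stop("more than 1e6 combinations; supply an explicit candidate list")
    candidates <- utils::combn(tfs, k, simplify = FALSE)
  }
  rows <- lapply(candidates, function(comb) {
    comb <- sort(comb)
    sb <- scorePerturbation(grn, comb, marginals, initialRegions,
                            targetRegions, mode = mode, variant = variant,
                            nSamples = nSamples, seed = seed)
    data.frame(combination = paste(comb, collapse = ","),
               T = sb@transcriptional, E = sb@epigenetic,
               combined = sb@combined, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$combined, res$combination), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

## ---- ranking concordance ----------------------------------------------------

allPermutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(k - 1L)
  out <- matrix(0L, nrow = k * nrow(sub), ncol = k)
  r <- 0L
  for (pos in seq_len(k)) {
    block <- cbind(sub, k)
    if (pos < k) {
      block <- sub
      block <- cbind(block[, seq_len(pos - 1L), drop = FALSE], k,
                     block[, pos:(k - 1L), drop = FALSE])
    }
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Concordance p-value between predicted and experimental rankings
#'
#' Computes the Euclidean distance `D` between the two rank vectors and
#' the tail probability, under the uniform null over all `k!` orderings,
#' of a distance to the experimental ranking at most `D`:
#' `p = #\{permutations with distance <= D\} / k!`. Exhaustive for
#' `k <= 8`; beyond that a seeded Monte-Carlo estimate over at least 1e5
#' permutation draws is used.
#'
#' @param predicted,experimental integer vectors, each a permutation of
#'   `1..k`.
#' @param nDraws Monte-Carlo draws for `k > 8` (minimum 1e5).
#' @param seed seed for Monte-Carlo sampling.
#' @return p-value in `(0, 1]`.
#' @export
rankingConcordancePvalue <- function(predicted, experimental,
                                     nDraws = 1e5, seed = 1L) {
  k <- length(predicted)
  if (length(experimental) != k)
    stop("rankings must have equal length")
  isPerm <- function(x) identical(sort(as.integer(x)), seq_len(k))
  if (!isPerm(predicted) || !isPerm(experimental))
    stop("both rankings must be permutations of 1..k")
  if (k == 1L) return(1)
  D <- sqrt(sum((predicted - experimental)^2))
  if (k <= 8L) {
    perms <- allPermutations(k)
    dists <- sqrt(rowSums((perms -
      matrix(experimental, nrow(perms), k, byrow = TRUE))^2))
    return(sum(dists <= D + 1e-9) / nrow(perms))
  }
  nDraws <- max(nDraws, 1e5)
  withr::with_seed(seed, {
    hits <- vapply(seq_len(nDraws), function(i) {
      sqrt(sum((sample.int(k) - experimental)^2)) <= D + 1e-9
    }, logical(1))
    mean(hits)
  })
}
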