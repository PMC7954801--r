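# Independent oracles and generators used across the suite.

gr1 <- function(chrom, start1, end1) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start1, end = end1))
}

# explicit per-base index set of a single interval
baseSet <- function(gr) {
  paste(as.character(GenomicRanges::seqnames(gr)),
        seq(GenomicRanges::start(gr), GenomicRanges::end(gr)))
}

# direct base-2 Jensen-Shannon divergence by the textbook formula
jsdOracle <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / m[i]))
  }
  (kl(p) + kl(q)) / 2
}

# random Boolean network with positive-literal rules; every node gets a
# promoter clause, some get enhancer clauses, some self-maintain
makeRandomModel <- function(n, seed, clamp = character()) {
  withr::with_seed(seed, {
    tfs <- sprintf("N%02d", seq_len(n))
    randClusters <- function(maxRegs) {
      regs <- sample(tfs, sample.int(maxRegs, 1L))
      grp <- sample.int(length(regs), length(regs), replace = TRUE)
      unname(lapply(split(regs, grp), sort))
    }
    rules <- lapply(tfs, function(tf) {
      if (stats::runif(1) < 0.15) return(buildLogicRule(tf))
      prom <- randClusters(min(3L, n))
      enh <- list()
      if (stats::runif(1) < 0.4) {
        enh <- lapply(seq_len(sample.int(2L, 1L)), function(i)
          randClusters(min(2L, n)))
      }
      buildLogicRule(tf, prom, enh)
    })
    names(rules) <- tfs
    BooleanNetworkModel(tfs, rules, clamp = clamp)
  })
}

randomMarginals <- function(model, seed) {
  withr::with_seed(seed,
    stats::setNames(stats::runif(length(model@tfs)), model@tfs))
}

# Brute-force transcriptional score: enumerate every free-TF state, follow
# the scalar trajectory (memoized over the functional graph), weight the
# reached/not-reached indicator by the product prior.
oracleTranscriptional <- function(model, marginals, variant = "reachability") {
  tfs <- model@tfs
  free <- setdiff(tfs, model@clamp)
  m <- length(free)
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  colnames(grid) <- free
  dist <- new.env(hash = TRUE, parent = emptyenv())
  keyOf <- function(s) paste(as.integer(s[free]), collapse = "")
  resolve <- function(s0) {
    path <- character(); s <- s0
    repeat {
      k <- keyOf(s)
      known <- dist[[k]]
      if (!is.null(known)) { base <- known; break }
      if (all(s)) { base <- 0; dist[[k]] <- 0; break }
      if (k %in% path) {  # entered a cycle without reaching the target
        for (pk in path) dist[[pk]] <- Inf
        base <- Inf
        break
      }
      path <- c(path, k)
      s <- synchronousSuccessor(s, model)
    }
    if (length(path)) {
      for (i in seq_along(path)) {
        if (is.null(dist[[path[i]]]))
          dist[[path[i]]] <- base + (length(path) - i + 1L)
      }
    }
    dist[[keyOf(s0)]]
  }
  ds <- numeric(nrow(grid))
  pr <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    s <- stats::setNames(rep(TRUE, length(tfs)), tfs)
    s[free] <- grid[i, ]
    ds[i] <- resolve(s)
    pr[i] <- prod(ifelse(grid[i, ], marginals[free], 1 - marginals[free]))
  }
  fin <- is.finite(ds)
  if (variant == "reachability") return(sum(pr[fin]))
  dmax <- if (any(fin)) max(ds[fin]) else 0
  sum(pr[fin] * (1 - ds[fin] / (dmax + 1)))
}

# exhaustive permutation enumeration by recursion over insert positions,
# independent of the package's generator
oraclePermutations <- function(k) {
  if (k == 1L) return(list(1L))
  shorter <- oraclePermutations(k - 1L)
  out <- list()
  for (p in shorter) {
    for (pos in 0:(k - 1L)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos)
    }
  }
  out
}

# random per-TF region sets for score-law checks: target regions plus an
# initial set sharing a random subset of them
makeRandomRegionSets <- function(tfs, seed) {
  withr::with_seed(seed, {
    tgt <- list(); ini <- list()
    for (tf in tfs) {
      k <- sample.int(4L, 1L)
      starts <- sort(sample.int(100000L, k)) * 10L
      rg <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(start = starts, width = 200L))
      S4Vectors::mcols(rg)$region_id <- paste0(tf, "_R", seq_len(k))
      tgt[[tf]] <- rg
      keep <- stats::runif(k) < 0.6
      ini[[tf]] <- rg[keep]
    }
    list(target = tgt, initial = ini)
  })
}

# small cached conversion scenario shared across test files
scenarioCache <- new.env(parent = emptyenv())
cachedScenario <- function(seed = 7, nTfs = 12) {
  key <- paste0("s", seed, "_", nTfs)
  if (is.null(scenarioCache[[key]])) {
    scenarioCache[[key]] <-
      generateConversionScenario(fixtureConfig(nTfs = nTfs, seed = seed))
  }
  scenarioCache[[key]]
}

scenarioMarginals <- function(bundle, grn) {
  tfs <- networkTFs(grn)
  vals <- exprValues(bundle$compendium)
  stats::setNames(vapply(tfs, function(tf)
    activationProbability(bundle$initialProfile[[tf]], vals[tf, ]),
    numeric(1)), tfs)
}
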