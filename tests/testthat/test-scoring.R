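swapModel <- function(clamp = character()) {
  BooleanNetworkModel(c("X", "Y"),
    list(X = buildLogicRule("X", list("Y")),
         Y = buildLogicRule("Y", list("X"))), clamp = clamp)
}

test_that("the product prior behaves as a probability distribution", {
  pr <- priorModel(c(X = 0.5, Y = 0.5))
  for (sx in c(0, 1)) for (sy in c(0, 1))
    expect_equal(statePrior(c(X = sx, Y = sy), pr), 0.25)
  # perturbed TF forces its marginal to 1
  prX <- priorModel(c(X = 0.3, Y = 0.5), perturbation = "X")
  expect_equal(statePrior(c(X = 0, Y = 1), prX), 0)
  expect_equal(statePrior(c(X = 1, Y = 1), prX), 0.5)
  # normalization over all 2^n states
  withr::with_seed(51, {
    for (n in c(3, 6, 9, 12)) {
      tfs <- sprintf("T%02d", 1:n)
      pr <- priorModel(setNames(runif(n), tfs))
      grid <- as.matrix(expand.grid(rep(list(0:1), n)))
      colnames(grid) <- tfs
      tot <- sum(apply(grid, 1, statePrior, prior = pr))
      expect_equal(tot, 1)
    }
  })
})

test_that("synchronous dynamics are deterministic; clamping holds TFs active", {
  m <- swapModel()
  expect_equal(synchronousSuccessor(c(X = TRUE, Y = FALSE), m),
               c(X = FALSE, Y = TRUE))
  mc <- swapModel(clamp = "X")
  expect_equal(synchronousSuccessor(c(X = TRUE, Y = FALSE), mc),
               c(X = TRUE, Y = TRUE))
  # the all-active state is a fixed point of every compiled model
  withr::with_seed(52, {
    for (rep in 1:10) {
      model <- makeRandomModel(sample(3:8, 1), seed = 5200 + rep)
      ones <- setNames(rep(TRUE, length(model@tfs)), model@tfs)
      expect_equal(synchronousSuccessor(ones, model), ones)
    }
  })
})

test_that("distance to full activation detects cycles and counts steps", {
  mc <- swapModel(clamp = "X")
  expect_equal(distanceToFullActivation(c(X = TRUE, Y = TRUE), mc), 0L)
  expect_equal(distanceToFullActivation(c(X = TRUE, Y = FALSE), mc), 1L)
  m <- swapModel()
  expect_equal(distanceToFullActivation(c(X = FALSE, Y = TRUE), m), Inf)
})

test_that("transcriptional score handles the degenerate priors", {
  mc <- swapModel(clamp = c("X", "Y"))
  # all prior mass on the target state
  expect_equal(transcriptionalScore(mc, priorModel(c(X = 1, Y = 1)))$T, 1)
  m <- swapModel()
  # X=0,Y=1 <-> X=1,Y=0 cycles forever: no mass reaches the target
  pr <- priorModel(c(X = 0, Y = 1))
  expect_equal(transcriptionalScore(m, pr)$T, 0)
  expect_equal(transcriptionalScore(m, pr,
                                    variant = "distance_weighted")$T, 0)
})

test_that("Monte-Carlo estimation agrees with exact enumeration within 3 SE", {
  model <- makeRandomModel(8, seed = 53, clamp = "N01")
  marg <- randomMarginals(model, 530)
  pr <- priorModel(marg, "N01")
  for (variant in c("reachability", "distance_weighted")) {
    ex <- transcriptionalScore(model, pr, variant = variant)$T
    mcr <- transcriptionalScore(model, pr, mode = "monte_carlo",
                                variant = variant, nSamples = 10000,
                                seed = 99)
    expect_lt(abs(mcr$T - ex), 3 * max(mcr$se, 1e-3))
  }
  expect_error(transcriptionalScore(model, pr, mode = "monte_carlo"),
               "seed")
})

test_that("epigenetic score counts shared target regions, clamps to 1", {
  mkRegions <- function(ids, starts) {
    rg <- GenomicRanges::GRanges("chrT",
      IRanges::IRanges(start = starts, width = 100))
    S4Vectors::mcols(rg)$region_id <- ids
    rg
  }
  tgt <- list(A = mkRegions(paste0("A", 1:4), c(100, 300, 500, 700)),
              B = mkRegions(paste0("B", 1:4), c(1100, 1300, 1500, 1700)))
  iniHalf <- list(A = mkRegions(paste0("A", 1:2), c(100, 300)),
                  B = mkRegions(paste0("B", 1:2), c(1100, 1300)))
  es <- epigeneticScore(iniHalf, tgt)
  expect_equal(unname(es$per_tf), c(0.5, 0.5))
  expect_equal(es$E, 0.25)
  # all network TFs perturbed -> E = 1
  expect_equal(epigeneticScore(iniHalf, tgt, c("A", "B"))$E, 1)
  # identical epigenomes -> E = 1
  expect_equal(epigeneticScore(tgt, tgt)$E, 1)
  # a region id only counts as shared when the coordinates still overlap
  iniShift <- list(A = mkRegions(c("A1", "A2"), c(5000, 300)),
                   B = tgt$B)
  expect_equal(unname(epigeneticScore(iniShift, tgt)$per_tf), c(0.25, 1))
})

test_that("combined score is the arithmetic mean with range checks", {
  expect_equal(combinedScore(1, 0.25), 0.625)
  expect_equal(combinedScore(0.4, 0.4), 0.4)
  expect_equal(combinedScore(0, 0), 0)
  expect_error(combinedScore(1.2, 0), "0, 1")
})

test_that("score laws hold on randomized models", {
  withr::with_seed(55, {
    for (rep in 1:15) {
      n <- sample(4:7, 1)
      model <- makeRandomModel(n, seed = 5500 + rep)
      tfs <- model@tfs
      marg <- randomMarginals(model, 5600 + rep)
      sets <- makeRandomRegionSets(tfs, 5700 + rep)
      pert <- sample(tfs, sample.int(n - 1L, 1L))
      modelP <- BooleanNetworkModel(tfs, model@rules, clamp = pert)
      ts <- transcriptionalScore(modelP, priorModel(marg, pert))$T
      es <- epigeneticScore(sets$initial, sets$target, pert)
      expect_gte(ts, 0); expect_lte(ts, 1)
      expect_gte(es$E, 0); expect_lte(es$E, 1)
      expect_equal(combinedScore(ts, es$E), (ts + es$E) / 2)
      # adding a TF to the perturbation never decreases E
      extra <- sample(setdiff(tfs, pert), 1L)
      es2 <- epigeneticScore(sets$initial, sets$target, c(pert, extra))
      expect_gte(es2$E, es$E)
      expect_equal(epigeneticScore(sets$initial, sets$target, tfs)$E, 1)
    }
  })
})

test_that("scores are invariant under node relabeling", {
  model <- makeRandomModel(6, seed = 56, clamp = "N02")
  marg <- randomMarginals(model, 560)
  relabel <- setNames(sprintf("Z%02d", 6:1), model@tfs)
  renameCl <- function(cls) lapply(cls, function(cl) unname(relabel[cl]))
  rules2 <- lapply(model@rules, function(r) {
    if (r@selfMaintain) return(buildLogicRule(unname(relabel[r@target])))
    buildLogicRule(unname(relabel[r@target]), renameCl(r@promoter),
                   lapply(r@enhancers, renameCl))
  })
  names(rules2) <- unname(relabel[names(model@rules)])
  model2 <- BooleanNetworkModel(unname(relabel[model@tfs]), rules2,
                                clamp = unname(relabel[model@clamp]))
  marg2 <- setNames(unname(marg), unname(relabel[names(marg)]))
  t1 <- transcriptionalScore(model, priorModel(marg, model@clamp))$T
  t2 <- transcriptionalScore(model2, priorModel(marg2, model2@clamp))$T
  expect_equal(t1, t2)
})

test_that("ranking enumerates all size-k subsets with deterministic ties", {
  b <- cachedScenario(seed = 9, nTfs = 10)
  res <- reconstructFromBundle(b)
  g <- res$grn
  marg <- scenarioMarginals(b, g)
  ini <- activeRegionSets(networkTFs(g), b$genome$promoterAnnotation,
                          b$genome$enhancerMap, b$initialPeaks$h3k4me3,
                          b$initialPeaks$h3k27ac, params = b$params)
  tgt <- regionSets(g)
  rk <- rankCombinations(g, k = 4, marginals = marg, initialRegions = ini,
                         targetRegions = tgt)
  expect_equal(nrow(rk), choose(length(networkTFs(g)), 4))
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_true(all(diff(rk$combined) <= 0))
  # ties broken lexicographically on the combination label
  tied <- split(rk$combination, rk$combined)
  for (grp in tied) expect_equal(grp, sort(grp))
  expect_error(rankCombinations(g, k = 99, marg, ini, tgt), "between")
  # k = n: the single all-TF combination has E = 1
  all_k <- rankCombinations(g, k = length(networkTFs(g)), marginals = marg,
                            initialRegions = ini, targetRegions = tgt)
  expect_equal(nrow(all_k), 1L)
  expect_equal(all_k$E, 1)
})

test_that("concordance p-values match the k! permutation null", {
  expect_equal(rankingConcordancePvalue(1L, 1L), 1)
  expect_equal(rankingConcordancePvalue(1:4, 1:4), 1 / factorial(4))
  expect_equal(rankingConcordancePvalue(4:1, 1:4), 1)
  expect_error(rankingConcordancePvalue(1:3, 1:4), "equal length")
  expect_error(rankingConcordancePvalue(c(1L, 1L, 3L), 1:3), "permutations")
})
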