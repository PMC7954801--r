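makeCompendium <- function(values, phen = rep("p", ncol(values))) {
  ExpressionCompendium(values, phen)
}

test_that("correlation cutoff calibration separates planted classes", {
  withr::with_seed(11, {
    centroid <- runif(60, 1, 100)
    pos <- sapply(1:8, function(i) centroid * exp(rnorm(60, 0, 0.02)))
    neg <- sapply(1:12, function(i) runif(60, 1, 100))
    vals <- cbind(pos, neg)
    dimnames(vals) <- list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:20))
    comp <- makeCompendium(vals)
    labels <- c(rep(TRUE, 8), rep(FALSE, 12))
    cut <- calibrateCorrelationCutoff(comp, labels)
    lv <- log2(vals + 1)
    r <- apply(lv, 2, cor, y = rowMeans(lv[, 1:8]))
    expect_gt(cut, max(r[!labels]))
    expect_lte(cut, min(r[labels]))  # F1 = 1 at the returned cutoff
    expect_error(calibrateCorrelationCutoff(comp, rep(TRUE, 20)),
                 "both classes")
  })
  expect_equal(calibrateCorrelationCutoff(NULL), 0.75)
})

test_that("correlated background samples are excluded, others retained", {
  withr::with_seed(12, {
    genes <- sprintf("g%02d", 1:50)
    query <- setNames(runif(50, 1, 200), genes)
    dup <- sapply(1:10, function(i) query * exp(rnorm(50, 0, 0.01)))
    indep <- sapply(1:90, function(i) runif(50, 1, 200))
    vals <- cbind(dup, indep)
    dimnames(vals) <- list(genes, sprintf("s%03d", 1:100))
    comp <- makeCompendium(vals)
    filt <- filterCorrelatedSamples(query, comp, 0.75)
    expect_setequal(colnames(exprValues(filt)), sprintf("s%03d", 11:100))
    # idempotent
    filt2 <- filterCorrelatedSamples(query, filt, 0.75)
    expect_identical(exprValues(filt2), exprValues(filt))
    # anti-correlated sample retained
    anti <- setNames(max(query) - query + 1, genes)
    vals2 <- cbind(vals[, 11:100], anti = anti)
    filt3 <- filterCorrelatedSamples(query, makeCompendium(vals2), 0.75)
    expect_true("anti" %in% colnames(exprValues(filt3)))
  })
  expect_error(
    filterCorrelatedSamples(c(a = 1), makeCompendium(
      matrix(1, 1, 2, dimnames = list("a", c("x", "y")))), 0.75),
    "fewer than 2")
})

test_that("JSD specificity is 1 for exclusive expression and matches the formula", {
  vals <- matrix(0, nrow = 2, ncol = 3,
                 dimnames = list(c("tfA", "tfB"), c("s1", "s2", "s3")))
  vals["tfB", ] <- 5
  comp <- makeCompendium(vals)
  query <- c(tfA = 10, tfB = 5)
  expect_equal(specificityScore("tfA", query, comp), 1)
  # uniform over query + 3 background samples: 1 - sqrt(JSD(delta, unif4))
  expected <- 1 - sqrt(jsdOracle(c(1, 0, 0, 0), rep(0.25, 4)))
  expect_equal(specificityScore("tfB", query, comp), expected)
  expect_error(specificityScore("tfA", c(tfA = 0, tfB = 1),
                                makeCompendium(vals * 0)), "all-zero")
})

test_that("specificity is minimal when mass sits on a background sample", {
  n <- 5
  specAt <- sapply(0:n, function(pos) {
    vals <- matrix(0, 1, n, dimnames = list("tf", sprintf("s%d", 1:n)))
    q <- c(tf = 0)
    if (pos == 0) q["tf"] <- 7 else vals["tf", pos] <- 7
    specificityScore("tf", q, makeCompendium(vals))
  })
  expect_equal(specAt[1], 1)
  expect_true(all(specAt[-1] < specAt[1]))
  expect_equal(min(specAt), min(specAt[-1]))
})

test_that("identity-TF selection takes the top-n with lexicographic ties", {
  vals <- matrix(0, 4, 3,
                 dimnames = list(c("b", "a", "d", "c"), c("s1", "s2", "s3")))
  vals["d", ] <- 3  # uniform -> low specificity
  comp <- makeCompendium(vals)
  query <- c(b = 10, a = 10, d = 3, c = 0)
  res <- selectIdentityTFs(query, comp, n = 2)
  # a and b both score 1; both selected ahead of d
  expect_equal(res$tf, c("a", "b"))
  expect_equal(res$rank, 1:2)
  expect_warning(res4 <- selectIdentityTFs(query, comp, n = 10), "only")
  expect_equal(nrow(res4), 3)  # c is unscorable (all-zero)
})

test_that("identity selection is invariant to sample ordering", {
  b <- cachedScenario()
  comp <- b$compendium
  vals <- exprValues(comp)
  perm <- rev(seq_len(ncol(vals)))
  shuffled <- ExpressionCompendium(vals[, perm],
                                   unname(phenotypes(comp))[perm])
  r1 <- selectIdentityTFs(b$query, comp, n = 10)
  r2 <- selectIdentityTFs(b$query, shuffled, n = 10)
  expect_equal(r1$tf, r2$tf)
  expect_equal(r1$specificity, r2$specificity)
})

test_that("activity p-values and activation probabilities follow the counting rules", {
  bg <- 1:99
  expect_equal(activityPvalue(100, bg), 1 / 100)
  expect_lt(activityPvalue(100, bg), 0.1)   # active at the default alpha
  expect_equal(activityPvalue(50, bg), (1 + 50) / 100)  # at the median
  expect_gt(activityPvalue(50, bg), 0.1)
  expect_equal(activationProbability(0, bg), 0)
  expect_equal(activationProbability(1000, bg), 1)
  bg40 <- c(1:30, 101:110)
  expect_equal(activationProbability(31, bg40), 0.75)
  expect_error(activityPvalue(1, numeric()), "empty")
  expect_error(activationProbability(1, numeric()), "empty")
  # monotonicity
  xs <- seq(0, 120, by = 5)
  p <- sapply(xs, activityPvalue, background = bg)
  m <- sapply(xs, activationProbability, background = bg)
  expect_true(all(diff(p) <= 0))
  expect_true(all(diff(m) >= 0))
})

test_that("co-factor rank z-scores handle the boundary and degenerate cases", {
  z <- cofactorRankZscore("x", 5, rep(c(20, 80), 10))
  expect_equal(z$z, (5 - 50) / sd(rep(c(20, 80), 10)))
  # background with mean 50 and sd exactly 30: rank 5 gives z = -1.5,
  # which is eligible (boundary included)
  a <- 30 / sqrt(2)
  zb <- cofactorRankZscore("x", 5, c(50 - a, 50 + a))
  expect_equal(zb$z, -1.5)
  expect_true(zb$eligible)
  degSame <- cofactorRankZscore("x", 7, c(7, 7, 7))
  expect_equal(degSame$z, 0)
  expect_false(degSame$eligible)
  degBelow <- cofactorRankZscore("x", 2, c(7, 7, 7))
  expect_equal(degBelow$z, -Inf)
  expect_true(degBelow$eligible)
  above <- cofactorRankZscore("x", 90, c(40, 60))
  expect_gt(above$z, 0)
  expect_false(above$eligible)
  expect_error(cofactorRankZscore("x", 1, 5), "at least 2")
})
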