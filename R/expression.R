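#' Construct an ExpressionCompendium
#'
#' @param values numeric gene x sample matrix of non-negative abundances
#'   (TPM-like), with unique rownames (genes) and colnames (samples).
#' @param phenotype character vector of phenotype labels, one per sample;
#'   defaults to `"unknown"`.
#' @return an [ExpressionCompendium-class].
#' @export
ExpressionCompendium <- function(values,
                                 phenotype = rep("unknown", ncol(values))) {
  new("ExpressionCompendium", values = values, phenotype = phenotype)
}

#' @describeIn ExpressionCompendium the abundance matrix.
#' @param x an `ExpressionCompendium`.
#' @export
exprValues <- function(x) {
  stopifnot(is(x, "ExpressionCompendium"))
  x@values
}

#' @describeIn ExpressionCompendium sample phenotype labels (named by sample).
#' @export
phenotypes <- function(x) {
  stopifnot(is(x, "ExpressionCompendium"))
  stats::setNames(x@phenotype, colnames(x@values))
}

setMethod("show", "ExpressionCompendium", function(object) {
  cat("ExpressionCompendium:", nrow(object@values), "genes x",
      ncol(object@values), "samples (",
      length(unique(object@phenotype)), "phenotypes )\n")
})

#' @describeIn ExpressionCompendium dimensions of the abundance matrix.
#' @export
setMethod("dim", "ExpressionCompendium", function(x) dim(x@values))

subsetSamples <- function(compendium, keep) {
  new("ExpressionCompendium",
      values = compendium@values[, keep, drop = FALSE],
      phenotype = compendium@phenotype[keep])
}

#' Read an expression compendium from TSV
#'
#' The matrix TSV has gene ids in the first column and sample ids in the
#' header. An optional companion metadata TSV carries columns `sample` and
#' `phenotype`.
#'
#' @param path matrix TSV.
#' @param metadata optional metadata TSV.
#' @return an [ExpressionCompendium-class].
#' @export
readCompendium <- function(path, metadata = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           check.names = FALSE, row.names = 1L)
  values <- as.matrix(tab)
  phen <- rep("unknown", ncol(values))
  if (!is.null(metadata)) {
    md <- utils::read.table(metadata, sep = "\t", header = TRUE, quote = "",
                            stringsAsFactors = FALSE)
    phen <- md$phenotype[match(colnames(values), md$sample)]
  }
  ExpressionCompendium(values, phen)
}

#' Read a query expression profile (2-column TSV: gene, value)
#'
#' @param path TSV path.
#' @return named numeric vector.
#' @export
readQueryProfile <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2L]]), tab[[1L]])
}

## ---- correlation filtering -------------------------------------------------

log2p1 <- function(x) log2(x + 1)

#' Calibrate the background-exclusion correlation cutoff
#'
#' Sweeps cutoffs on a 0.01 grid over `[0, 1]` and returns the value
#' maximizing the F1 score of classifying samples as in-class by Pearson
#' correlation (on `log2(x+1)` values) to the in-class centroid. Ties are
#' broken toward the larger cutoff. Without labels the shipped default of
#' 0.75 is returned.
#'
#' @param compendium an [ExpressionCompendium-class].
#' @param labels logical per sample (`TRUE` = in-class), or `NULL` to use
#'   the default cutoff.
#' @return cutoff in `(0, 1)`.
#' @export
calibrateCorrelationCutoff <- function(compendium, labels = NULL) {
  if (is.null(labels)) return(0.75)
  stopifnot(is(compendium, "ExpressionCompendium"))
  labels <- as.logical(labels)
  if (length(labels) != ncol(compendium@values))
    stop("one label per sample is required")
  if (all(labels) || !any(labels))
    stop("labels must contain both classes")
  lv <- log2p1(compendium@values)
  centroid <- rowMeans(lv[, labels, drop = FALSE])
  r <- apply(lv, 2L, stats::cor, y = centroid)
  grid <- round(seq(0, 1, by = 0.01), 2)
  f1 <- vapply(grid, function(cut) {
    pred <- r >= cut
    tp <- sum(pred & labels)
    if (tp == 0L) return(0)
    prec <- tp / sum(pred)
    rec <- tp / sum(labels)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  best <- max(f1)
  grid[max(which(f1 >= best - 1e-12))]
}

#' Exclude background samples correlated with the query
#'
#' Removes every compendium sample whose Pearson correlation with the query
#' profile, computed on `log2(x+1)`-transformed shared genes, exceeds the
#' cutoff. The remaining samples form the background used for specificity
#' and co-factor ranking.
#'
#' @param query named numeric expression vector.
#' @param compendium an [ExpressionCompendium-class]; the query gene set
#'   must be contained in the compendium gene set.
#' @param cutoff correlation cutoff (default 0.75).
#' @return the filtered [ExpressionCompendium-class].
#' @export
filterCorrelatedSamples <- function(query, compendium, cutoff = 0.75) {
  stopifnot(is(compendium, "ExpressionCompendium"))
  shared <- intersect(names(query), rownames(compendium@values))
  if (length(shared) < 2L)
    stop("fewer than 2 genes shared between query and compendium")
  q <- log2p1(query[shared])
  lv <- log2p1(compendium@values[shared, , drop = FALSE])
  r <- apply(lv, 2L, function(col) {
    if (stats::sd(col) == 0 || stats::sd(q) == 0) return(0)
    stats::cor(col, q)
  })
  subsetSamples(compendium, r <= cutoff)
}

## ---- Jensen-Shannon specificity --------------------------------------------

# base-2 Jensen-Shannon divergence of two discrete distributions
jsDivergence <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Jensen-Shannon specificity of a TF for the query sample
#'
#' Normalizes the TF's expression over the query plus the filtered
#' background to a probability distribution, computes the base-2
#' Jensen-Shannon divergence against the idealized point mass sitting
#' entirely on the query sample, and returns `1 - sqrt(JSD)`. A TF
#' expressed exclusively in the query scores exactly 1.
#'
#' @param tf gene identifier.
#' @param query named numeric expression vector containing `tf`.
#' @param filtered the correlation-filtered [ExpressionCompendium-class].
#' @return specificity score in `[0, 1]`.
#' @export
specificityScore <- function(tf, query, filtered) {
  stopifnot(is(filtered, "ExpressionCompendium"))
  if (!tf %in% names(query)) stop("TF absent from query profile: ", tf)
  if (!tf %in% rownames(filtered@values))
    stop("TF absent from compendium: ", tf)
  x <- c(query[[tf]], as.numeric(filtered@values[tf, ]))
  tot <- sum(x)
  if (tot <= 0) stop("all-zero expression for TF: ", tf)
  q <- x / tot
  ideal <- c(1, rep(0, length(x) - 1L))
  1 - sqrt(jsDivergence(ideal, q))
}

# Specificity of every gene for every sample of a compendium, treating each
# sample in turn as the query position of the ideal distribution. Because
# JSD(delta_j, q) depends on q only through q_j, this reduces to a closed
# form in the per-sample mass and vectorizes over the whole matrix.
specificityMatrix <- function(values) {
  tot <- rowSums(values)
  ok <- tot > 0
  q <- values
  q[ok, ] <- values[ok, , drop = FALSE] / tot[ok]
  qj <- q
  term <- function(z) ifelse(z > 0, z * log2(2 * z / (1 + z)), 0)
  jsd <- (log2(2 / (1 + qj)) + (1 - qj) + term(qj)) / 2
  spec <- 1 - sqrt(pmax(jsd, 0))
  spec[!ok, ] <- NA_real_
  spec
}

#' Select identity TFs by specificity
#'
#' Scores every candidate TF with [specificityScore()] against the filtered
#' background and returns the top `n`, ranked by decreasing specificity with
#' a deterministic lexicographic tie-break on gene id.
#'
#' @param query named numeric expression vector.
#' @param filtered the correlation-filtered [ExpressionCompendium-class].
#' @param n number of identity TFs (default 10).
#' @param candidates candidate TF ids; defaults to all compendium genes
#'   present in the query.
#' @return data.frame with columns `tf`, `specificity`, `rank`.
#' @export
selectIdentityTFs <- function(query, filtered, n = 10, candidates = NULL) {
  stopifnot(is(filtered, "ExpressionCompendium"), n >= 1)
  if (is.null(candidates))
    candidates <- intersect(names(query), rownames(filtered@values))
  candidates <- sort(unique(candidates))
  spec <- vapply(candidates, function(tf) {
    tot <- query[[tf]] + sum(filtered@values[tf, ])
    if (tot <= 0) return(NA_real_)
    specificityScore(tf, query, filtered)
  }, numeric(1))
  keep <- !is.na(spec)
  candidates <- candidates[keep]; spec <- spec[keep]
  ord <- order(-spec, candidates)
  res <- data.frame(tf = candidates[ord], specificity = spec[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  if (n > nrow(res)) {
    warning("requested ", n, " identity TFs but only ", nrow(res),
            " candidates are scorable; returning all")
    n <- nrow(res)
  }
  res[seq_len(n), , drop = FALSE]
}

## ---- activity discretization -----------------------------------------------

#' Empirical p-value for the null hypothesis that a gene is inactive
#'
#' One-sided empirical p-value `(1 + #\{background >= x\}) / (1 + N)`; the
#' gene is called active when `p < alpha` (default 0.1). The `+1`
#' correction keeps p strictly positive.
#'
#' @param x observed expression value.
#' @param background numeric vector of background values for the gene.
#' @return p-value in `(0, 1]`.
#' @export
activityPvalue <- function(x, background) {
  if (!length(background)) stop("empty background distribution")
  (1 + sum(background >= x)) / (1 + length(background))
}

#' Empirical probability that a gene is active
#'
#' Empirical CDF of the background at `x`: the fraction of background
#' values strictly below the observed expression. Feeds the product-form
#' prior over network states.
#'
#' @inheritParams activityPvalue
#' @return probability in `[0, 1]`.
#' @export
activationProbability <- function(x, background) {
  if (!length(background)) stop("empty background distribution")
  sum(background < x) / length(background)
}

#' Activity calls for a set of genes
#'
#' Applies [activityPvalue()] and [activationProbability()] gene-wise, using
#' the compendium rows as background distributions.
#'
#' @param query named numeric expression vector.
#' @param compendium an [ExpressionCompendium-class] (unfiltered background).
#' @param genes genes to call; defaults to all shared genes.
#' @param alpha significance level (default 0.1).
#' @return data.frame with columns `gene`, `p_inactive`, `active`,
#'   `p_active_marginal`.
#' @export
activityCalls <- function(query, compendium, genes = NULL, alpha = 0.1) {
  stopifnot(is(compendium, "ExpressionCompendium"))
  if (is.null(genes))
    genes <- intersect(names(query), rownames(compendium@values))
  genes <- genes[genes %in% rownames(compendium@values) &
                 genes %in% names(query)]
  p <- vapply(genes, function(g)
    activityPvalue(query[[g]], compendium@values[g, ]), numeric(1))
  marg <- vapply(genes, function(g)
    activationProbability(query[[g]], compendium@values[g, ]), numeric(1))
  data.frame(gene = genes, p_inactive = p, active = p < alpha,
             p_active_marginal = marg, stringsAsFactors = FALSE,
             row.names = NULL)
}

## ---- co-factor rank z-scores -----------------------------------------------

#' Rank z-score of a candidate co-factor
#'
#' Compares a TF's specificity rank in the query against the distribution
#' of its ranks across background samples: `z = (rank_query - mean) / sd`.
#' The TF is eligible as a co-factor when `z <= -1.5`. With a degenerate
#' background (`sd = 0`) z is 0 (never eligible) unless the query rank lies
#' strictly below the constant mean, in which case z is `-Inf` (eligible).
#'
#' @param tf TF identifier.
#' @param rankQuery the TF's rank in the query sample.
#' @param rankBackground integer vector of the TF's ranks across background
#'   samples (at least 2).
#' @return data.frame with columns `tf`, `rank_query`, `rank_mean`,
#'   `rank_sd`, `z`, `eligible`.
#' @export
cofactorRankZscore <- function(tf, rankQuery, rankBackground) {
  if (length(rankBackground) < 2L)
    stop("at least 2 background rank observations are required")
  m <- mean(rankBackground)
  s <- stats::sd(rankBackground)
  z <- if (s > 0) (rankQuery - m) / s
       else if (rankQuery < m) -Inf else 0
  data.frame(tf = tf, rank_query = rankQuery, rank_mean = m, rank_sd = s,
             z = z, eligible = z <= -1.5, stringsAsFactors = FALSE)
}

#' Co-factor rank z-scores for all candidate TFs
#'
#' Ranks candidates by specificity for the query and, treating each
#' background sample in turn as the query position, for every background
#' sample; then applies [cofactorRankZscore()] per TF. Ties in any ranking
#' are broken lexicographically on gene id.
#'
#' @param query named numeric expression vector.
#' @param filtered the correlation-filtered [ExpressionCompendium-class].
#' @param candidates candidate TF ids (default: shared genes).
#' @return data.frame, one row per candidate.
#' @export
cofactorZscores <- function(query, filtered, candidates = NULL) {
  stopifnot(is(filtered, "ExpressionCompendium"))
  if (is.null(candidates))
    candidates <- intersect(names(query), rownames(filtered@values))
  candidates <- sort(unique(
    candidates[candidates %in% rownames(filtered@values) &
               candidates %in% names(query)]))
  if (ncol(filtered@values) < 2L)
    stop("at least 2 background samples are required")
  rankVec <- function(spec) {
    ord <- order(-spec, candidates)
    r <- integer(length(spec)); r[ord] <- seq_along(ord)
    r
  }
  # query ranking over {query} + background
  qspec <- vapply(candidates, function(tf) {
    tot <- query[[tf]] + sum(filtered@values[tf, ])
    if (tot <= 0) return(-Inf)
    specificityScore(tf, query, filtered)
  }, numeric(1))
  qrank <- rankVec(qspec)
  # per-background-sample rankings over the background matrix
  specMat <- specificityMatrix(filtered@values[candidates, , drop = FALSE])
  specMat[is.na(specMat)] <- -Inf
  bgRanks <- apply(specMat, 2L, rankVec)  # candidates x samples
  out <- do.call(rbind, lapply(seq_along(candidates), function(i)
    cofactorRankZscore(candidates[i], qrank[i], bgRanks[i, ])))
  rownames(out) <- NULL
  out
}
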