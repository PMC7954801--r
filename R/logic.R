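#' Read an undirected PPI pair list
#'
#' 2-column TSV of gene symbols (header optional but recommended:
#' `tf_a`, `tf_b`). Pairs are unordered.
#'
#' @param path TSV path.
#' @return data.frame with columns `tf_a`, `tf_b`.
#' @export
readPPI <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("PPI file must have 2 columns")
  data.frame(tf_a = tab[[1L]], tf_b = tab[[2L]], stringsAsFactors = FALSE)
}

ppiKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Cooperativity model: PPI evidence plus a reciprocal-overlap threshold
#'
#' TF pairs are considered cooperative (joined by a Boolean AND) when their
#' ChIP peaks in a region reciprocally overlap by at least
#' `overlapThreshold` *and* a protein-protein interaction is on record.
#' The shipped default threshold of 0.6243 reflects the separation of
#' interacting from non-interacting TF pairs by average reciprocal peak
#' overlap.
#'
#' @param ppi data.frame with columns `tf_a`, `tf_b` (unordered pairs).
#' @param overlapThreshold fraction in `[0, 1]` (default 0.6243).
#' @return an object of class `CooperativityModel` (a list with the pair
#'   key set and the threshold).
#' @export
cooperativityModel <- function(ppi = NULL, overlapThreshold = 0.6243) {
  stopifnot(overlapThreshold >= 0, overlapThreshold <= 1)
  keys <- if (is.null(ppi) || !nrow(ppi)) character()
          else unique(ppiKey(ppi$tf_a, ppi$tf_b))
  structure(list(pairs = keys, overlapThreshold = overlapThreshold),
            class = "CooperativityModel")
}

#' Calibrate the cooperative-overlap threshold
#'
#' Sweeps thresholds in steps of 1e-4 over `[0, 1]` and returns the value
#' maximizing the balanced accuracy of separating reciprocal overlaps of
#' interacting (positive) from non-interacting (negative) TF pairs,
#' predicting "interacting" when overlap >= threshold. Ties are broken
#' toward the larger threshold. When the classes are inseparable
#' (balanced accuracy ~ 0.5) a warning is issued.
#'
#' @param positive numeric vector of reciprocal overlaps of interacting
#'   pairs.
#' @param negative numeric vector for non-interacting pairs.
#' @return list with `threshold` and `balanced_accuracy`.
#' @export
calibrateOverlapThreshold <- function(positive, negative) {
  if (!length(positive) || !length(negative))
    stop("both positive and negative pairs are required")
  grid <- round(seq(0, 1, by = 1e-4), 4)
  # balanced accuracy = (TPR + TNR)/2; vectorized via counts above threshold
  tpr <- 1 - vapply(grid, function(t) mean(positive < t), numeric(1))
  tnr <- vapply(grid, function(t) mean(negative < t), numeric(1))
  bacc <- (tpr + tnr) / 2
  best <- max(bacc)
  thr <- grid[max(which(bacc >= best - 1e-12))]
  if (best <= 0.5 + 1e-9)
    warning("positive and negative overlaps are inseparable; ",
            "balanced accuracy ", signif(best, 3))
  list(threshold = thr, balanced_accuracy = best)
}

#' Cluster the TFs binding one region into AND-clusters
#'
#' Builds an undirected graph over the TFs with binding events in a single
#' region: an edge joins A and B when their maximal pairwise reciprocal
#' peak overlap within the region reaches the model threshold and the pair
#' has a recorded PPI. The connected components of this graph are the
#' AND-clusters of the region clause; all clusters combine by OR.
#'
#' @param events data.frame of binding events sharing one `region_id`
#'   (columns as in [callBindingEvents()]).
#' @param model a [cooperativityModel()].
#' @return list with `region_id` and `clusters` (list of sorted character
#'   vectors, sorted by first member).
#' @export
clusterRegionTFs <- function(events, model) {
  if (!nrow(events)) return(list(region_id = NA_character_, clusters = list()))
  rid <- unique(events$region_id)
  if (length(rid) != 1L) stop("all events must share one region_id")
  tfs <- sort(unique(events$tf))
  if (length(tfs) == 1L)
    return(list(region_id = rid, clusters = list(tfs)))
  peaksOf <- lapply(tfs, function(tf) {
    e <- events[events$tf == tf, , drop = FALSE]
    GenomicRanges::GRanges(e$peak_chrom,
      IRanges::IRanges(start = e$peak_start, end = e$peak_end))
  })
  names(peaksOf) <- tfs
  edges <- character()
  for (i in seq_along(tfs)[-length(tfs)]) {
    for (j in seq((i + 1L), length(tfs))) {
      if (!ppiKey(tfs[i], tfs[j]) %in% model$pairs) next
      maxOv <- 0
      for (pa in seq_along(peaksOf[[i]])) {
        for (pb in seq_along(peaksOf[[j]])) {
          maxOv <- max(maxOv,
                       reciprocalOverlap(peaksOf[[i]][pa], peaksOf[[j]][pb]))
        }
      }
      if (maxOv >= model$overlapThreshold)
        edges <- c(edges, tfs[i], tfs[j])
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(tfs)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  clusters <- split(tfs, comp$membership[tfs])
  clusters <- lapply(unname(clusters), sort)
  clusters <- clusters[order(vapply(clusters, `[`, character(1), 1L))]
  list(region_id = rid, clusters = clusters)
}

#' Build the Boolean logic rule of a target TF
#'
#' Combines the promoter clause and the enhancer clauses: the rule is
#' `promoter AND (enhancer_1 OR enhancer_2 OR ...)`. With no active
#' enhancer the promoter clause stands alone; with no promoter binding the
#' enhancer disjunction stands alone; a target with no regulators at all is
#' self-maintaining.
#'
#' @param target target TF id.
#' @param promoterClusters list of AND-clusters (character vectors) of the
#'   promoter clause; empty list when no TF binds the promoter.
#' @param enhancerClauses list of enhancer clauses, each a list of
#'   AND-clusters.
#' @param hasActivePromoter must be `TRUE`: nodes without an active
#'   promoter are dropped before rule compilation.
#' @return a [LogicRule-class].
#' @export
buildLogicRule <- function(target, promoterClusters = list(),
                           enhancerClauses = list(),
                           hasActivePromoter = TRUE) {
  if (!isTRUE(hasActivePromoter))
    stop("target '", target, "' lacks an active promoter; ",
         "such nodes are dropped upstream")
  enhancerClauses <- enhancerClauses[
    vapply(enhancerClauses, length, integer(1)) > 0L]
  selfMaint <- !length(promoterClusters) && !length(enhancerClauses)
  new("LogicRule", target = target, promoter = promoterClusters,
      enhancers = enhancerClauses, selfMaintain = selfMaint)
}

# all TFs appearing in a rule's clauses
ruleRegulators <- function(rule) {
  sort(unique(c(unlist(rule@promoter, use.names = FALSE),
                unlist(rule@enhancers, use.names = FALSE))))
}

evalClause <- function(clusters, state) {
  if (!length(clusters)) return(TRUE)
  for (cl in clusters) if (all(state[cl])) return(TRUE)
  FALSE
}

#' Evaluate a logic rule on a network state
#'
#' Clause value = OR over AND-clusters; rule value = promoter clause AND
#' disjunction of enhancer clauses (absent parts are vacuously true). A
#' self-maintaining rule returns the target's current state.
#'
#' @param rule a [LogicRule-class].
#' @param state named logical vector assigning every TF referenced by the
#'   rule (and, for self-maintenance, the target itself).
#' @return logical scalar.
#' @export
evaluateRule <- function(rule, state) {
  stopifnot(is(rule, "LogicRule"))
  need <- if (rule@selfMaintain) rule@target else ruleRegulators(rule)
  miss <- setdiff(need, names(state))
  if (length(miss))
    stop("state does not assign TF(s): ", paste(miss, collapse = ", "))
  if (anyNA(state[need])) stop("state assigns NA to a referenced TF")
  if (rule@selfMaintain) return(as.logical(state[[rule@target]]))
  pv <- evalClause(rule@promoter, state)
  ev <- if (!length(rule@enhancers)) TRUE else
    any(vapply(rule@enhancers, evalClause, logical(1), state = state))
  pv && ev
}

#' Compile logic rules for every node of a core GRN
#'
#' Groups the core GRN's binding events (restricted to regulators that are
#' network nodes) by target and region, clusters each region's TFs with
#' [clusterRegionTFs()], and assembles one [LogicRule-class] per node via
#' [buildLogicRule()]. The compiled rules are stored in the returned
#' network.
#'
#' @param grn a [CoreGRN-class].
#' @param events binding-event data.frame (from the scaffold).
#' @param model a [cooperativityModel()].
#' @return the [CoreGRN-class] with its `rules` slot populated.
#' @export
compileLogicRules <- function(grn, events, model) {
  stopifnot(is(grn, "CoreGRN"))
  nodes <- networkTFs(grn)
  md <- S4Vectors::mcols(grn@regions)
  ev <- events[events$tf %in% nodes & events$target_gene %in% nodes &
               events$region_id %in% md$region_id, , drop = FALSE]
  rules <- lapply(nodes, function(node) {
    nev <- ev[ev$target_gene == node, , drop = FALSE]
    prom <- nev[nev$kind == "promoter", , drop = FALSE]
    promClusters <- if (nrow(prom))
      clusterRegionTFs(prom, model)$clusters else list()
    enh <- nev[nev$kind == "enhancer", , drop = FALSE]
    enhClauses <- list()
    if (nrow(enh)) {
      rids <- sort(unique(enh$region_id))
      enhClauses <- lapply(rids, function(rid)
        clusterRegionTFs(enh[enh$region_id == rid, , drop = FALSE],
                         model)$clusters)
    }
    buildLogicRule(node, promClusters, enhClauses)
  })
  names(rules) <- nodes
  grn@rules <- rules
  validObject(grn)
  grn
}

## ---- rule text serialization -----------------------------------------------

clauseText <- function(clusters) {
  paste(vapply(clusters, paste, character(1), collapse = " & "),
        collapse = " | ")
}

#' Serialize a logic rule as text
#'
#' Grammar: `target <- (A & B | C) & ((D) | (E & F))` — the promoter
#' clause first (written `(1)` when no TF binds the promoter), then the
#' parenthesized enhancer clauses joined by `|` and wrapped in one outer
#' pair of parentheses; the enhancer part is omitted when there is none.
#' `&` binds tighter than `|`. Self-maintenance serializes as
#' `target <- target`. [parseRuleText()] round-trips this format.
#'
#' @param rule a [LogicRule-class].
#' @return a single string.
#' @export
ruleToText <- function(rule) {
  stopifnot(is(rule, "LogicRule"))
  if (rule@selfMaintain)
    return(paste(rule@target, "<-", rule@target))
  promTxt <- if (length(rule@promoter))
    paste0("(", clauseText(rule@promoter), ")") else "(1)"
  parts <- promTxt
  if (length(rule@enhancers)) {
    enh <- paste(vapply(rule@enhancers, function(cl)
      paste0("(", clauseText(cl), ")"), character(1)), collapse = " | ")
    parts <- c(parts, paste0("(", enh, ")"))
  }
  paste(rule@target, "<-", paste(parts, collapse = " & "))
}

parseClause <- function(txt) {
  lapply(strsplit(txt, "|", fixed = TRUE)[[1L]], function(cl)
    sort(trimws(strsplit(cl, "&", fixed = TRUE)[[1L]])))
}

#' Parse a logic rule from its text form
#'
#' Inverse of [ruleToText()]. A rule of the form `target <- target` is
#' parsed as self-maintenance. The first top-level parenthesized group is
#' taken as the promoter clause and the second (if present) as the
#' enhancer disjunction.
#'
#' @param txt rule text.
#' @return a [LogicRule-class].
#' @export
parseRuleText <- function(txt) {
  sides <- strsplit(txt, "<-", fixed = TRUE)[[1L]]
  if (length(sides) != 2L) stop("malformed rule text: ", txt)
  target <- trimws(sides[1L])
  rhs <- trimws(sides[2L])
  if (identical(rhs, target))
    return(buildLogicRule(target))
  groups <- splitTopLevel(rhs, "&")
  promTxt <- stripOuterParens(groups[[1L]])
  promoter <- if (identical(promTxt, "1")) list() else parseClause(promTxt)
  enhancers <- list()
  if (length(groups) >= 2L) {
    enhTxt <- stripOuterParens(groups[[2L]])
    enhancers <- lapply(splitTopLevel(enhTxt, "|"), function(g)
      parseClause(stripOuterParens(g)))
  }
  buildLogicRule(target, promoter, enhancers)
}

# split a parenthesized expression on a top-level operator
splitTopLevel <- function(txt, op) {
  chars <- strsplit(txt, "")[[1L]]
  depth <- 0L; cur <- character(); out <- character()
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == op && depth == 0L) {
      out <- c(out, paste(cur, collapse = "")); cur <- character()
    } else cur <- c(cur, ch)
  }
  trimws(c(out, paste(cur, collapse = "")))
}

stripOuterParens <- function(txt) {
  txt <- trimws(txt)
  while (startsWith(txt, "(") && endsWith(txt, ")")) {
    inner <- substr(txt, 2L, nchar(txt) - 1L)
    depth <- 0L; balanced <- TRUE
    for (ch in strsplit(inner, "")[[1L]]) {
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") depth <- depth - 1L
      if (depth < 0L) { balanced <- FALSE; break }
    }
    if (!balanced) break
    txt <- trimws(inner)
  }
  txt
}
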