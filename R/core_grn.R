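#' Build the GRN scaffold from binding events
#'
#' A directed edge (A -> B) is created when at least one binding event of
#' active TF A lies in an active region of active gene B. Edges are
#' annotated with the kinds of supporting regions (comma-separated) and the
#' number of supporting events. TFs or targets that failed the activity
#' call contribute no edges.
#'
#' @param events data.frame from [callBindingEvents()].
#' @param activity data.frame from [activityCalls()].
#' @param regionIds character vector of known region ids; events referring
#'   to unknown regions raise an error. Defaults to the ids present in
#'   `events`.
#' @return list with elements `nodes` (active TF ids appearing in edges),
#'   `edges` (data.frame `regulator`, `target`, `kinds`, `n_events`) and
#'   `events` (the retained events).
#' @export
buildScaffold <- function(events, activity, regionIds = NULL) {
  if (!is.null(regionIds)) {
    unknown <- setdiff(events$region_id, regionIds)
    if (length(unknown))
      stop("binding event references unknown region: ", unknown[1L])
  }
  activeSet <- activity$gene[activity$active]
  keep <- events$tf %in% activeSet & events$target_gene %in% activeSet
  ev <- events[keep, , drop = FALSE]
  if (!nrow(ev)) {
    return(list(nodes = character(),
                edges = data.frame(regulator = character(),
                                   target = character(), kinds = character(),
                                   n_events = integer(),
                                   stringsAsFactors = FALSE),
                events = ev))
  }
  key <- paste(ev$tf, ev$target_gene, sep = "\r")
  kinds <- vapply(split(ev$kind, key), function(k)
    paste(sort(unique(k)), collapse = ","), character(1))
  nev <- vapply(split(ev$kind, key), length, integer(1))
  parts <- strsplit(names(kinds), "\r", fixed = TRUE)
  edges <- data.frame(
    regulator = vapply(parts, `[`, character(1), 1L),
    target = vapply(parts, `[`, character(1), 2L),
    kinds = unname(kinds), n_events = unname(nev),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = sort(unique(c(edges$regulator, edges$target))),
       edges = edges, events = ev)
}

#' Select co-factors of the identity TFs
#'
#' A TF qualifies as a co-factor when it (i) passed the activity call,
#' (ii) is rank-enriched in the query (`z <= -1.5`), (iii) regulates at
#' least one identity TF and (iv) is regulated by at least one identity TF
#' in the scaffold. Both promoter- and enhancer-mediated edges count. No
#' cap is placed on the number of co-factors.
#'
#' @param scaffold list from [buildScaffold()].
#' @param identity character vector of identity TF ids; those absent from
#'   the scaffold are dropped with a warning.
#' @param activity data.frame from [activityCalls()].
#' @param zscores data.frame from [cofactorZscores()].
#' @return character vector of co-factor TF ids (sorted).
#' @export
selectCofactors <- function(scaffold, identity, activity, zscores) {
  missing <- setdiff(identity, scaffold$nodes)
  if (length(missing))
    warning("identity TFs absent from scaffold: ",
            paste(missing, collapse = ", "))
  identity <- intersect(identity, scaffold$nodes)
  ed <- scaffold$edges
  activeSet <- activity$gene[activity$active]
  eligible <- zscores$tf[zscores$eligible]
  cand <- setdiff(intersect(activeSet, eligible), identity)
  regulatesId <- unique(ed$regulator[ed$target %in% identity])
  regulatedById <- unique(ed$target[ed$regulator %in% identity])
  sort(intersect(cand, intersect(regulatesId, regulatedById)))
}

#' Assemble the core GRN
#'
#' Restricts the scaffold to the node-induced subgraph over identity TFs
#' and co-factors and attaches each node's active regulatory regions.
#' Nodes lacking an active promoter are dropped with a warning: under the
#' logic semantics they can never be induced.
#'
#' @param scaffold list from [buildScaffold()].
#' @param identity character vector of identity TF ids.
#' @param cofactors character vector of co-factor TF ids.
#' @param regions `GRanges` of regulatory regions (active and inactive)
#'   carrying metadata `region_id`, `gene`, `kind`, `active`.
#' @return a [CoreGRN-class] (rules not yet compiled).
#' @export
assembleCoreGRN <- function(scaffold, identity, cofactors, regions) {
  nodes <- unique(c(identity, cofactors))
  if (!length(nodes)) stop("empty node set for core GRN")
  md <- S4Vectors::mcols(regions)
  promOK <- unique(md$gene[md$kind == "promoter" & md$active])
  dropped <- setdiff(nodes, promOK)
  if (length(dropped)) {
    warning("dropping nodes without an active promoter: ",
            paste(sort(dropped), collapse = ", "))
    nodes <- setdiff(nodes, dropped)
  }
  if (!length(nodes)) stop("no core-GRN node has an active promoter")
  ed <- scaffold$edges
  ed <- ed[ed$regulator %in% nodes & ed$target %in% nodes, , drop = FALSE]
  rownames(ed) <- NULL
  keepRegions <- regions[md$gene %in% nodes & md$active]
  new("CoreGRN",
      identity = sort(intersect(identity, nodes)),
      cofactors = sort(intersect(cofactors, nodes)),
      edges = ed, regions = keepRegions, rules = list())
}

#' @describeIn assembleCoreGRN node names of a core GRN.
#' @param grn a [CoreGRN-class].
#' @export
networkTFs <- function(grn) {
  stopifnot(is(grn, "CoreGRN"))
  sort(c(grn@identity, grn@cofactors))
}

#' @describeIn assembleCoreGRN edge table of a core GRN.
#' @export
networkEdges <- function(grn) {
  stopifnot(is(grn, "CoreGRN"))
  grn@edges
}

#' @describeIn assembleCoreGRN active regulatory regions of a core GRN.
#' @export
networkRegions <- function(grn) {
  stopifnot(is(grn, "CoreGRN"))
  grn@regions
}

#' @describeIn assembleCoreGRN compiled logic rules of a core GRN.
#' @export
networkRules <- function(grn) {
  stopifnot(is(grn, "CoreGRN"))
  grn@rules
}

setMethod("show", "CoreGRN", function(object) {
  cat("CoreGRN:", length(object@identity), "identity TFs,",
      length(object@cofactors), "co-factors,",
      nrow(object@edges), "edges,",
      length(object@regions), "active regions\n")
  if (length(object@rules))
    cat("  logic rules compiled for", length(object@rules), "nodes\n")
})

#' Compare an inferred edge list to a gold standard
#'
#' Both lists are first restricted to TFs present in both node sets (the
#' shared-TF rule); then matching, mismatching and newly inferred
#' interaction counts are computed by set algebra, and the overall
#' validated percentage is `100 * matching / gs_interactions`.
#'
#' @param inferred data.frame with columns `regulator`, `target` (extra
#'   columns ignored).
#' @param goldStandard data.frame with columns `regulator`, `target`.
#' @return data.frame with one row: `gs_interactions`,
#'   `inferred_interactions`, `matching`, `mismatching`, `newly_inferred`,
#'   `overall_validated`.
#' @export
compareToGoldStandard <- function(inferred, goldStandard) {
  infNodes <- unique(c(inferred$regulator, inferred$target))
  gsNodes <- unique(c(goldStandard$regulator, goldStandard$target))
  shared <- intersect(infNodes, gsNodes)
  if (!length(shared)) stop("no TFs shared between inferred and gold standard")
  restrict <- function(df) {
    keep <- df$regulator %in% shared & df$target %in% shared
    unique(paste(df$regulator[keep], df$target[keep], sep = "->"))
  }
  gs <- restrict(goldStandard)
  inf <- restrict(inferred)
  matching <- length(intersect(gs, inf))
  data.frame(
    gs_interactions = length(gs),
    inferred_interactions = length(inf),
    matching = matching,
    mismatching = length(setdiff(gs, inf)),
    newly_inferred = length(setdiff(inf, gs)),
    overall_validated = if (length(gs)) 100 * matching / length(gs) else NA_real_)
}

#' Export a core GRN as a TSV edge list and a JSON bundle
#'
#' @param grn a [CoreGRN-class].
#' @param edgePath TSV output path (regulator, target, kinds, n_events), or
#'   `NULL` to skip.
#' @param jsonPath JSON output path bundling nodes, regions, edges and rule
#'   texts, or `NULL` to skip.
#' @return invisibly, the list written as JSON.
#' @export
exportCoreGRN <- function(grn, edgePath = NULL, jsonPath = NULL) {
  stopifnot(is(grn, "CoreGRN"))
  if (!is.null(edgePath))
    utils::write.table(grn@edges, edgePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  md <- S4Vectors::mcols(grn@regions)
  bundle <- list(
    identity = grn@identity,
    cofactors = grn@cofactors,
    edges = grn@edges,
    regions = data.frame(
      region_id = md$region_id, gene = md$gene, kind = md$kind,
      chrom = as.character(GenomicRanges::seqnames(grn@regions)),
      start = GenomicRanges::start(grn@regions) - 1L,
      end = GenomicRanges::end(grn@regions),
      stringsAsFactors = FALSE),
    rules = vapply(grn@rules, ruleToText, character(1)))
  if (!is.null(jsonPath))
    jsonlite::write_json(bundle, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(bundle)
}
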