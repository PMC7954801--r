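#' @import methods
#' @importFrom GenomicRanges GRanges seqnames granges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

#' PeakSet: a labelled collection of genomic intervals
#'
#' A `PeakSet` wraps a [GenomicRanges::GRanges] with an assay label
#' (`"H3K4me3"`, `"H3K27ac"`, `"DNase"`, `"TF-binding:<tf>"` or `"other"`)
#' and free-text provenance. Coordinates are held 1-based closed as usual for
#' `GRanges`; BED input/output is converted at the reader/writer boundary.
#'
#' @slot ranges `GRanges` of peak intervals.
#' @slot assay single assay label.
#' @slot source free-text provenance.
#' @export
setClass("PeakSet",
  slots = c(ranges = "GRanges", assay = "character", source = "character"))

setValidity("PeakSet", function(object) {
  msg <- character()
  if (length(object@assay) != 1L || !nzchar(object@assay))
    msg <- c(msg, "'assay' must be a single non-empty label")
  if (length(object@source) != 1L)
    msg <- c(msg, "'source' must be a single string")
  if (length(object@ranges) &&
      any(GenomicRanges::width(object@ranges) < 1L))
    msg <- c(msg, "all intervals must have width >= 1")
  if (length(msg)) msg else TRUE
})

#' Expression compendium: gene x sample non-negative abundance matrix
#'
#' Holds a gene-by-sample matrix of non-negative abundances (TPM-like) and a
#' phenotype label per sample. Used as the background for specificity
#' scoring, activity discretization, activation probabilities and co-factor
#' rank z-scores.
#'
#' @slot values numeric matrix, genes in rows, samples in columns.
#' @slot phenotype character vector of free-text phenotype labels, one per
#'   sample.
#' @export
setClass("ExpressionCompendium",
  slots = c(values = "matrix", phenotype = "character"))

setValidity("ExpressionCompendium", function(object) {
  v <- object@values
  msg <- character()
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "gene identifiers (rownames) must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "sample identifiers (colnames) must be present and unique")
  if (anyNA(v) || any(v < 0))
    msg <- c(msg, "abundances must be non-negative and non-missing")
  if (length(object@phenotype) != ncol(v))
    msg <- c(msg, "'phenotype' must have one label per sample")
  if (length(msg)) msg else TRUE
})

#' Boolean logic rule for one target TF
#'
#' Encodes the update rule of a target TF: a promoter clause AND a
#' disjunction of enhancer clauses. Each clause is an OR over AND-clusters
#' (character vectors of cooperating regulator TFs). All literals are
#' positive. A rule with no regulators at all is self-maintaining: the
#' target keeps its current state.
#'
#' An absent promoter clause (no TF bound in the active promoter) and an
#' absent enhancer disjunction are each treated as vacuously true, so a
#' purely enhancer-driven or purely promoter-driven rule evaluates as that
#' part alone.
#'
#' @slot target target TF identifier.
#' @slot promoter list of character vectors: AND-clusters of the promoter
#'   clause (empty list = clause absent).
#' @slot enhancers list of enhancer clauses; each clause is itself a list of
#'   AND-clusters.
#' @slot selfMaintain logical; `TRUE` when the target has no regulators.
#' @export
setClass("LogicRule",
  slots = c(target = "character", promoter = "list", enhancers = "list",
            selfMaintain = "logical"))

setValidity("LogicRule", function(object) {
  msg <- character()
  if (length(object@target) != 1L || !nzchar(object@target))
    msg <- c(msg, "'target' must be a single non-empty id")
  okClusters <- function(cl) all(vapply(cl, function(x)
    is.character(x) && length(x) >= 1L, logical(1)))
  if (!okClusters(object@promoter))
    msg <- c(msg, "promoter clusters must be non-empty character vectors")
  if (!all(vapply(object@enhancers, function(cl) is.list(cl) && okClusters(cl),
                  logical(1))))
    msg <- c(msg, "each enhancer clause must be a list of non-empty clusters")
  if (isTRUE(object@selfMaintain) &&
      (length(object@promoter) || length(object@enhancers)))
    msg <- c(msg, "a self-maintaining rule cannot carry clauses")
  if (!isTRUE(object@selfMaintain) &&
      !length(object@promoter) && !length(object@enhancers))
    msg <- c(msg, "a rule without clauses must be self-maintaining")
  if (length(msg)) msg else TRUE
})

#' Core gene regulatory network
#'
#' The reconstructed core GRN: identity TFs, co-factors, directed edges
#' annotated with the kinds of supporting regulatory regions, the active
#' regulatory regions per target gene, and (once compiled) one Boolean
#' [LogicRule-class] per node.
#'
#' @slot identity character vector of identity TF ids present in the network.
#' @slot cofactors character vector of co-factor TF ids.
#' @slot edges data.frame with columns `regulator`, `target`, `kinds`
#'   (comma-separated region kinds) and `n_events`.
#' @slot regions `GRanges` of active regulatory regions with metadata
#'   columns `region_id`, `gene`, `kind`.
#' @slot rules named list of [LogicRule-class] objects (may be empty before
#'   logic compilation).
#' @export
setClass("CoreGRN",
  slots = c(identity = "character", cofactors = "character",
            edges = "data.frame", regions = "GRanges", rules = "list"))

setValidity("CoreGRN", function(object) {
  msg <- character()
  nodes <- c(object@identity, object@cofactors)
  if (!length(nodes)) msg <- c(msg, "network has no nodes")
  if (anyDuplicated(nodes)) msg <- c(msg, "identity and co-factor sets overlap")
  ed <- object@edges
  need <- c("regulator", "target", "kinds", "n_events")
  if (!all(need %in% names(ed)))
    msg <- c(msg, "edges must have regulator/target/kinds/n_events columns")
  else if (nrow(ed) &&
           (!all(ed$regulator %in% nodes) || !all(ed$target %in% nodes)))
    msg <- c(msg, "edges must connect network nodes only")
  if (length(object@rules) &&
      !all(vapply(object@rules, is, logical(1), "LogicRule")))
    msg <- c(msg, "'rules' must contain LogicRule objects")
  if (length(msg)) msg else TRUE
})

#' Boolean network model for conversion simulation
#'
#' A synchronous Boolean network over the core-GRN TFs, with one
#' [LogicRule-class] per node and a set of clamped (over-expressed) TFs that
#' are held active throughout the simulation, modelling sustained cassette
#' expression.
#'
#' @slot tfs ordered character vector of node names (at most 60).
#' @slot rules named list of [LogicRule-class], one per TF.
#' @slot clamp character vector of clamped TF names (subset of `tfs`).
#' @export
setClass("BooleanNetworkModel",
  slots = c(tfs = "character", rules = "list", clamp = "character"))

setValidity("BooleanNetworkModel", function(object) {
  msg <- character()
  n <- length(object@tfs)
  if (n < 1L || n > 60L)
    msg <- c(msg, "model must have between 1 and 60 TFs")
  if (anyDuplicated(object@tfs)) msg <- c(msg, "TF names must be unique")
  if (!identical(sort(names(object@rules)), sort(object@tfs)))
    msg <- c(msg, "exactly one rule per TF is required")
  if (!all(object@clamp %in% object@tfs))
    msg <- c(msg, "clamped TFs must be network nodes")
  regs <- unique(unlist(lapply(object@rules, ruleRegulators), use.names = FALSE))
  if (length(regs) && !all(regs %in% object@tfs))
    msg <- c(msg, "rules reference TFs outside the model")
  if (length(msg)) msg else TRUE
})

#' Score breakdown for one perturbation
#'
#' Transcriptional score T, epigenetic score E, their arithmetic mean, and
#' bookkeeping on how T was computed.
#'
#' @slot transcriptional T in `[0,1]`.
#' @slot epigenetic E in `[0,1]`.
#' @slot combined `(T+E)/2`.
#' @slot perTF named numeric: per-TF epigenetic fractions.
#' @slot mode `"exact"` or `"monte_carlo"`.
#' @slot variant `"reachability"` or `"distance_weighted"`.
#' @slot nSamples number of Monte-Carlo draws (`NA` for exact).
#' @slot seed seed used for stochastic estimation (`NA` for exact).
#' @export
setClass("ScoreBreakdown",
  slots = c(transcriptional = "numeric", epigenetic = "numeric",
            combined = "numeric", perTF = "numeric", mode = "character",
            variant = "character", nSamples = "numeric", seed = "numeric"))

setValidity("ScoreBreakdown", function(object) {
  msg <- character()
  inUnit <- function(x) length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
  if (!inUnit(object@transcriptional)) msg <- c(msg, "T must lie in [0,1]")
  if (!inUnit(object@epigenetic)) msg <- c(msg, "E must lie in [0,1]")
  if (!isTRUE(all.equal(object@combined,
                        (object@transcriptional + object@epigenetic) / 2)))
    msg <- c(msg, "combined score must equal (T+E)/2")
  if (length(msg)) msg else TRUE
})
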