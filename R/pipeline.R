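#' Reconstruction parameters
#'
#' Bundles the tunable thresholds of the reconstruction pipeline with
#' their shipped defaults: background-exclusion correlation cutoff 0.75,
#' activity significance level 0.1, co-factor rank z-score cutoff -1.5,
#' cooperative reciprocal-overlap threshold 0.6243, and the promoter
#' window of 1500 bp upstream / 500 bp downstream of the TSS.
#'
#' @param nIdentity number of identity TFs to select (default 10).
#' @param correlationCutoff background-exclusion cutoff.
#' @param alpha activity significance level.
#' @param zCutoff co-factor z-score cutoff.
#' @param overlapThreshold cooperative-overlap threshold.
#' @param upstream,downstream promoter window in bp.
#' @return a named list of parameters.
#' @export
reconstructionParams <- function(nIdentity = 10, correlationCutoff = 0.75,
                                 alpha = 0.1, zCutoff = -1.5,
                                 overlapThreshold = 0.6243,
                                 upstream = 1500, downstream = 500) {
  list(nIdentity = nIdentity, correlationCutoff = correlationCutoff,
       alpha = alpha, zCutoff = zCutoff, overlapThreshold = overlapThreshold,
       upstream = upstream, downstream = downstream)
}

#' Reconstruct a cell-type-specific core GRN
#'
#' Runs the full reconstruction: correlation-filter the background
#' compendium against the query profile; select identity TFs by
#' Jensen-Shannon specificity; call gene activity; call active promoters
#' (H3K4me3) and enhancer segments (H3K27ac); identify DNase-filtered TF
#' binding events; build the scaffold; select co-factors by activity,
#' rank z-score and bidirectional identity regulation; assemble the core
#' GRN; and compile per-node Boolean logic rules from peak co-overlap and
#' PPI evidence.
#'
#' @param query named numeric expression vector of the query cell type.
#' @param compendium background [ExpressionCompendium-class].
#' @param promoterAnnotation data.frame (`gene`, `chrom`, `tss`, `strand`).
#' @param enhancerMap data.frame (`chrom`, `start`, `end`, `gene`,
#'   `enhancer_id`).
#' @param h3k4me3,h3k27ac,dnase [PeakSet-class] objects for the query cell
#'   type.
#' @param tfPeaks named list of per-TF [PeakSet-class] binding peaks.
#' @param ppi data.frame of undirected PPI pairs (`tf_a`, `tf_b`).
#' @param candidateTFs character vector of TF ids eligible as network
#'   nodes; defaults to the genes in the promoter annotation.
#' @param params list from [reconstructionParams()].
#' @return list with elements `grn` (a [CoreGRN-class] with compiled
#'   rules), `identity` (specificity table), `activity`, `zscores`,
#'   `regions`, `events` and `scaffold`.
#' @export
reconstructCoreGRN <- function(query, compendium, promoterAnnotation,
                               enhancerMap, h3k4me3, h3k27ac, dnase,
                               tfPeaks, ppi,
                               candidateTFs = NULL,
                               params = reconstructionParams()) {
  if (is.null(candidateTFs)) candidateTFs <- promoterAnnotation$gene
  candidateTFs <- sort(unique(candidateTFs))

  filtered <- filterCorrelatedSamples(query, compendium,
                                      params$correlationCutoff)
  identity <- selectIdentityTFs(query, filtered, n = params$nIdentity,
                                candidates = candidateTFs)
  activity <- activityCalls(query, compendium, genes = candidateTFs,
                            alpha = params$alpha)
  zs <- cofactorZscores(query, filtered, candidates = candidateTFs)
  zs$eligible <- zs$z <= params$zCutoff

  promWindows <- definePromoters(promoterAnnotation,
                                 upstream = params$upstream,
                                 downstream = params$downstream)
  promoters <- callActivePromoters(promWindows, h3k4me3)
  enhancers <- callActiveEnhancers(enhancerMap, h3k27ac)
  regions <- c(promoters, enhancers)

  events <- callBindingEvents(regions, tfPeaks, dnase)
  scaffold <- buildScaffold(events, activity,
                            regionIds = S4Vectors::mcols(regions)$region_id)
  cof <- selectCofactors(scaffold, identity$tf, activity, zs)
  grn <- assembleCoreGRN(scaffold, identity$tf, cof, regions)
  model <- cooperativityModel(ppi, params$overlapThreshold)
  grn <- compileLogicRules(grn, scaffold$events, model)

  list(grn = grn, identity = identity, activity = activity, zscores = zs,
       regions = regions, events = events, scaffold = scaffold)
}

#' Per-TF active region sets of a cell type
#'
#' Calls active promoters and enhancer segments from a cell type's peak
#' sets and returns them as a named list of `GRanges`, keyed by gene —
#' the inputs of [epigeneticScore()].
#'
#' @param genes genes of interest (network TFs).
#' @param promoterAnnotation,enhancerMap as in [reconstructCoreGRN()].
#' @param h3k4me3,h3k27ac [PeakSet-class] objects of the cell type.
#' @param params list from [reconstructionParams()].
#' @param includePromoter include the promoter among the regulatory
#'   elements counted by the epigenetic score (default `TRUE`).
#' @return named list of `GRanges` (metadata `region_id`).
#' @export
activeRegionSets <- function(genes, promoterAnnotation, enhancerMap,
                             h3k4me3, h3k27ac,
                             params = reconstructionParams(),
                             includePromoter = TRUE) {
  ann <- promoterAnnotation[promoterAnnotation$gene %in% genes, , drop = FALSE]
  promWindows <- definePromoters(ann, upstream = params$upstream,
                                 downstream = params$downstream)
  promoters <- callActivePromoters(promWindows, h3k4me3)
  promoters <- promoters[S4Vectors::mcols(promoters)$active]
  em <- enhancerMap[enhancerMap$gene %in% genes, , drop = FALSE]
  enhancers <- callActiveEnhancers(em, h3k27ac)
  regions <- if (includePromoter) c(promoters, enhancers) else enhancers
  md <- S4Vectors::mcols(regions)
  out <- lapply(stats::setNames(nm = sort(genes)), function(g)
    regions[md$gene == g])
  out
}

#' Per-TF active region sets of a reconstructed core GRN
#'
#' @param grn a [CoreGRN-class].
#' @param includePromoter include promoter regions (default `TRUE`).
#' @return named list of `GRanges`, keyed by network TF.
#' @export
regionSets <- function(grn, includePromoter = TRUE) {
  stopifnot(is(grn, "CoreGRN"))
  regions <- grn@regions
  if (!includePromoter)
    regions <- regions[S4Vectors::mcols(regions)$kind != "promoter"]
  md <- S4Vectors::mcols(regions)
  lapply(stats::setNames(nm = networkTFs(grn)), function(g)
    regions[md$gene == g])
}
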