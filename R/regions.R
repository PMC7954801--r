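#' Read a promoter annotation table
#'
#' TSV with header columns `gene`, `chrom`, `tss`, `strand`. TSS positions
#' are 0-based genomic coordinates.
#'
#' @param path TSV path.
#' @return data.frame with those columns.
#' @export
readPromoterAnnotation <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss", "strand")
  if (!all(need %in% names(tab)))
    stop("promoter annotation must have columns gene/chrom/tss/strand")
  tab$tss <- as.integer(tab$tss)
  tab[need]
}

#' Read an enhancer-gene association table
#'
#' TSV with header columns `chrom`, `start`, `end` (0-based half-open),
#' `gene`, `enhancer_id` (GeneHancer-like).
#'
#' @param path TSV path.
#' @return data.frame with those columns.
#' @export
readEnhancerMap <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene", "enhancer_id")
  if (!all(need %in% names(tab)))
    stop("enhancer map must have columns chrom/start/end/gene/enhancer_id")
  tab[need]
}

#' Define a promoter window around a TSS
#'
#' Strand-aware window: on `+` the interval covers `upstream` bp before and
#' `downstream` bp after the TSS; on `-` the window is mirrored. Defaults
#' are 1500 bp upstream and 500 bp downstream. The window is clipped at
#' position 0.
#'
#' @param annotation data.frame row(s) with `gene`, `chrom`, `tss`,
#'   `strand` (TSS 0-based).
#' @param upstream,downstream window extents in bp.
#' @return `GRanges` of promoter windows, named by gene, with metadata
#'   column `gene`.
#' @export
definePromoters <- function(annotation, upstream = 1500, downstream = 500) {
  tss <- as.numeric(annotation$tss)
  plus <- annotation$strand == "+"
  start0 <- ifelse(plus, tss - upstream, tss - downstream)
  end0 <- ifelse(plus, tss + downstream, tss + upstream)
  start0 <- pmax(start0, 0)
  gr <- GenomicRanges::GRanges(annotation$chrom,
          IRanges::IRanges(start = start0 + 1, end = end0),
          strand = annotation$strand)
  names(gr) <- annotation$gene
  S4Vectors::mcols(gr)$gene <- annotation$gene
  gr
}

regionGRanges <- function(chrom, start, end, region_id, gene, kind) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start, end = end))
  S4Vectors::mcols(gr)$region_id <- region_id
  S4Vectors::mcols(gr)$gene <- gene
  S4Vectors::mcols(gr)$kind <- kind
  gr
}

#' Call active promoters from H3K4me3 peaks
#'
#' A promoter is active when its window overlaps at least one H3K4me3 peak
#' by one or more base pairs. Promoter coordinates are not truncated to the
#' peak. One region per gene is returned, with `region_id`
#' `"promoter:<gene>"` and a metadata column `active`.
#'
#' @param promoters `GRanges` from [definePromoters()].
#' @param h3k4me3 a [PeakSet-class] with assay `"H3K4me3"`.
#' @return `GRanges` of promoter regions (metadata: `region_id`, `gene`,
#'   `kind`, `active`).
#' @export
callActivePromoters <- function(promoters, h3k4me3) {
  stopifnot(is(h3k4me3, "PeakSet"))
  if (assayLabel(h3k4me3) != "H3K4me3")
    stop("peak set assay must be 'H3K4me3', got '", assayLabel(h3k4me3), "'")
  hits <- GenomicRanges::countOverlaps(promoters, peakRanges(h3k4me3),
                                       minoverlap = 1L, ignore.strand = TRUE)
  gr <- GenomicRanges::granges(promoters, use.names = FALSE)
  GenomicRanges::strand(gr) <- "*"
  S4Vectors::mcols(gr)$region_id <-
    paste0("promoter:", S4Vectors::mcols(promoters)$gene)
  S4Vectors::mcols(gr)$gene <- S4Vectors::mcols(promoters)$gene
  S4Vectors::mcols(gr)$kind <- "promoter"
  S4Vectors::mcols(gr)$active <- hits > 0L
  gr
}

#' Call active enhancer segments from H3K27ac peaks
#'
#' For each (enhancer, target gene) pair, every maximal segment of the
#' enhancer intersected with the union of overlapping H3K27ac peaks becomes
#' one active region, truncated to the peak overlap. Enhancers without any
#' overlapping peak are discarded. Region ids are
#' `"<enhancer_id>|<gene>#<segment>"` with segments numbered by start
#' coordinate.
#'
#' @param enhancerMap data.frame from [readEnhancerMap()] (0-based
#'   half-open coordinates).
#' @param h3k27ac a [PeakSet-class] with assay `"H3K27ac"`.
#' @return `GRanges` of active enhancer regions (metadata: `region_id`,
#'   `gene`, `kind`, `active`).
#' @export
callActiveEnhancers <- function(enhancerMap, h3k27ac) {
  stopifnot(is(h3k27ac, "PeakSet"))
  if (assayLabel(h3k27ac) != "H3K27ac")
    stop("peak set assay must be 'H3K27ac', got '", assayLabel(h3k27ac), "'")
  peaks <- GenomicRanges::reduce(peakRanges(h3k27ac), ignore.strand = TRUE)
  enh <- GenomicRanges::GRanges(enhancerMap$chrom,
    IRanges::IRanges(start = enhancerMap$start + 1, end = enhancerMap$end))
  hits <- GenomicRanges::findOverlaps(enh, peaks, minoverlap = 1L,
                                      ignore.strand = TRUE)
  if (!length(hits)) {
    res <- regionGRanges(character(), integer(), integer(), character(),
                         character(), character())
    S4Vectors::mcols(res)$active <- logical()
    return(res)
  }
  ei <- S4Vectors::queryHits(hits)
  # reduced peaks are disjoint, so each hit is one maximal active segment
  seg <- GenomicRanges::pintersect(
    GenomicRanges::granges(enh[ei]),
    GenomicRanges::granges(peaks[S4Vectors::subjectHits(hits)]),
    ignore.strand = TRUE)
  ord <- order(ei, GenomicRanges::start(seg))
  ei <- ei[ord]; seg <- seg[ord]
  segNo <- stats::ave(ei, ei, FUN = seq_along)
  res <- regionGRanges(
    as.character(GenomicRanges::seqnames(seg)),
    GenomicRanges::start(seg), GenomicRanges::end(seg),
    paste0(enhancerMap$enhancer_id[ei], "|", enhancerMap$gene[ei],
           "#", segNo),
    enhancerMap$gene[ei], "enhancer")
  S4Vectors::mcols(res)$active <- rep(TRUE, length(res))
  res
}

#' Identify TF binding events within active, accessible regions
#'
#' A binding event is emitted for a (TF peak, region) pair when the triple
#' intersection of the TF peak, the region and at least one DNase peak
#' spans one or more base pairs — i.e. the shared bases lie inside
#' accessible chromatin within the region. One event is emitted per
#' (tf, region, peak) triple.
#'
#' @param regions `GRanges` of active regulatory regions (metadata
#'   `region_id`, `gene`, `kind`, `active`); inactive regions are ignored.
#' @param tfPeaks named list of [PeakSet-class], one per TF.
#' @param dnase a [PeakSet-class] with assay `"DNase"`.
#' @return data.frame with columns `tf`, `target_gene`, `region_id`,
#'   `kind`, `peak_chrom`, `peak_start`, `peak_end` (peak coordinates
#'   1-based closed, as in `GRanges`).
#' @export
callBindingEvents <- function(regions, tfPeaks, dnase) {
  stopifnot(is(dnase, "PeakSet"))
  if (assayLabel(dnase) != "DNase")
    stop("peak set assay must be 'DNase', got '", assayLabel(dnase), "'")
  if (!length(regions) || !length(tfPeaks))
    return(emptyEvents())
  act <- S4Vectors::mcols(regions)$active
  if (!is.null(act)) regions <- regions[act]
  dn <- peakRanges(dnase)
  rows <- list()
  for (tf in sort(names(tfPeaks))) {
    pk <- peakRanges(tfPeaks[[tf]])
    if (!length(pk)) next
    hits <- GenomicRanges::findOverlaps(pk, regions, minoverlap = 1L,
                                        ignore.strand = TRUE)
    if (!length(hits)) next
    pi <- S4Vectors::queryHits(hits); ri <- S4Vectors::subjectHits(hits)
    inter <- GenomicRanges::pintersect(
      GenomicRanges::granges(pk[pi]),
      GenomicRanges::granges(regions[ri]), ignore.strand = TRUE)
    open <- GenomicRanges::countOverlaps(inter, dn, minoverlap = 1L,
                                         ignore.strand = TRUE) > 0L
    if (!any(open)) next
    pi <- pi[open]; ri <- ri[open]
    rows[[tf]] <- data.frame(
      tf = tf,
      target_gene = S4Vectors::mcols(regions)$gene[ri],
      region_id = S4Vectors::mcols(regions)$region_id[ri],
      kind = S4Vectors::mcols(regions)$kind[ri],
      peak_chrom = as.character(GenomicRanges::seqnames(pk))[pi],
      peak_start = GenomicRanges::start(pk)[pi],
      peak_end = GenomicRanges::end(pk)[pi],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(emptyEvents())
  res <- do.call(rbind, rows)
  res <- res[order(res$tf, res$region_id, res$peak_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

emptyEvents <- function() {
  data.frame(tf = character(), target_gene = character(),
             region_id = character(), kind = character(),
             peak_chrom = character(), peak_start = integer(),
             peak_end = integer(), stringsAsFactors = FALSE)
}
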