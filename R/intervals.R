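#' Construct a PeakSet
#'
#' @param ranges a [GenomicRanges::GRanges] of peak intervals (1-based
#'   closed, the usual `GRanges` convention).
#' @param assay assay label, one of `"H3K4me3"`, `"H3K27ac"`, `"DNase"`,
#'   `"TF-binding:<tf>"` or `"other"`.
#' @param source free-text provenance.
#' @return a [PeakSet-class].
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' PeakSet(gr, assay = "DNase")
#' @export
PeakSet <- function(ranges, assay = "other", source = "") {
  new("PeakSet", ranges = ranges, assay = assay, source = source)
}

#' @describeIn PeakSet the underlying `GRanges`.
#' @param x a `PeakSet`.
#' @export
peakRanges <- function(x) {
  stopifnot(is(x, "PeakSet"))
  x@ranges
}

#' @describeIn PeakSet the assay label.
#' @export
assayLabel <- function(x) {
  stopifnot(is(x, "PeakSet"))
  x@assay
}

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet of", length(object@ranges), "intervals, assay:",
      object@assay, "\n")
  if (nzchar(object@source)) cat("  source:", object@source, "\n")
})

#' @describeIn PeakSet number of peaks.
#' @export
setMethod("length", "PeakSet", function(x) length(x@ranges))

## ---- BED / TSV I/O ---------------------------------------------------------

#' Read genomic intervals from a BED or TSV file
#'
#' Reads BED3/BED6 (0-based half-open, converted to the 1-based closed
#' `GRanges` convention) or a headered TSV with columns `chrom`, `start`,
#' `end` and optionally `strand` (also 0-based half-open). Input order is
#' preserved; records without a strand column are unstranded. Chromosome
#' names are taken verbatim; optional "chr"-prefix harmonization can be
#' requested.
#'
#' @param path input file.
#' @param dialect `"bed3"`, `"bed6"` or `"tsv"`.
#' @param assay assay label for the resulting [PeakSet-class].
#' @param chrPrefix if `TRUE`, prepend `"chr"` to chromosome names lacking it.
#' @return a [PeakSet-class].
#' @seealso [writePeaks()]
#' @export
readPeaks <- function(path, dialect = c("bed3", "bed6", "tsv"),
                      assay = "other", chrPrefix = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  header <- dialect == "tsv"
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = header, quote = "",
                      comment.char = "", colClasses = "character"),
    error = function(e) NULL)
  if (is.null(tab) || nrow(tab) == 0L) {
    return(PeakSet(GenomicRanges::GRanges(), assay = assay, source = path))
  }
  if (dialect == "tsv") {
    need <- c("chrom", "start", "end")
    if (!all(need %in% names(tab)))
      stop("TSV interval file must have columns chrom/start/end: ", path)
    chrom <- tab$chrom
    start0 <- suppressWarnings(as.numeric(tab$start))
    end0 <- suppressWarnings(as.numeric(tab$end))
    strand <- if ("strand" %in% names(tab)) tab$strand else rep("*", nrow(tab))
  } else {
    if (ncol(tab) < 3L)
      stop("BED file must have at least 3 columns: ", path)
    chrom <- tab[[1L]]
    start0 <- suppressWarnings(as.numeric(tab[[2L]]))
    end0 <- suppressWarnings(as.numeric(tab[[3L]]))
    strand <- if (dialect == "bed6" && ncol(tab) >= 6L) tab[[6L]]
              else rep("*", nrow(tab))
  }
  lineOff <- if (header) 1L else 0L
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop("malformed coordinates at line ", bad[1L] + lineOff, " of ", path)
  bad <- which(start0 >= end0 | start0 < 0)
  if (length(bad))
    stop("invalid interval (start >= end or negative) at line ",
         bad[1L] + lineOff, " of ", path)
  bad <- which(!nzchar(chrom))
  if (length(bad))
    stop("empty chromosome name at line ", bad[1L] + lineOff, " of ", path)
  if (chrPrefix) {
    noPre <- !startsWith(chrom, "chr")
    chrom[noPre] <- paste0("chr", chrom[noPre])
  }
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(start = start0 + 1, end = end0), strand = strand)
  if (dialect == "bed6" && ncol(tab) >= 4L) names(gr) <- tab[[4L]]
  PeakSet(gr, assay = assay, source = path)
}

#' Write a PeakSet as BED
#'
#' Writes BED3 (or BED6 when strands are informative), converting back to
#' 0-based half-open coordinates, so that `readPeaks(writePeaks(x))`
#' reproduces the coordinates of `x`.
#'
#' @param peaks a [PeakSet-class].
#' @param path output file.
#' @param sort if `TRUE`, sort lexicographically by chromosome then start.
#' @return `path`, invisibly.
#' @export
writePeaks <- function(peaks, path, sort = FALSE) {
  stopifnot(is(peaks, "PeakSet"))
  gr <- peaks@ranges
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  strands <- as.character(GenomicRanges::strand(gr))
  if (any(strands != "*")) {
    df$name <- if (!is.null(names(gr))) names(gr) else "."
    df$score <- 0L
    df$strand <- ifelse(strands == "*", ".", strands)
  }
  if (sort && nrow(df)) df <- df[order(df$chrom, df$start, df$end), ]
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write intervals to: ", path)
  invisible(path)
}

## ---- Overlap primitives ----------------------------------------------------

asSingleRange <- function(x, what) {
  if (is(x, "PeakSet")) x <- x@ranges
  if (!is(x, "GRanges") || length(x) != 1L)
    stop("'", what, "' must be a single-interval GRanges")
  x
}

#' Overlap length of two genomic intervals in base pairs
#'
#' Returns the number of shared bases of two single intervals; 0 when they
#' lie on different chromosomes or do not share a base. An overlap of
#' exactly 1 bp counts as overlap.
#'
#' @param a,b single-interval `GRanges`.
#' @return integer number of overlapping base pairs.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 250))
#' overlapLength(a, b)  # 50
#' @export
overlapLength <- function(a, b) {
  a <- asSingleRange(a, "a"); b <- asSingleRange(b, "b")
  if (as.character(GenomicRanges::seqnames(a)) !=
      as.character(GenomicRanges::seqnames(b))) return(0L)
  ov <- min(GenomicRanges::end(a), GenomicRanges::end(b)) -
        max(GenomicRanges::start(a), GenomicRanges::start(b)) + 1L
  max(0L, ov)
}

#' Truncate a regulatory region to a peak
#'
#' Returns the intersection of a region with a peak. The inputs must share
#' at least one base pair.
#'
#' @param region,peak single-interval `GRanges`.
#' @return the intersection interval as a `GRanges`.
#' @export
truncateToPeak <- function(region, peak) {
  region <- asSingleRange(region, "region"); peak <- asSingleRange(peak, "peak")
  if (overlapLength(region, peak) < 1L)
    stop("region and peak are disjoint; cannot truncate")
  GenomicRanges::GRanges(
    GenomicRanges::seqnames(region),
    IRanges::IRanges(
      start = max(GenomicRanges::start(region), GenomicRanges::start(peak)),
      end = min(GenomicRanges::end(region), GenomicRanges::end(peak))),
    strand = GenomicRanges::strand(region))
}

#' Reciprocal overlap fraction of two intervals
#'
#' `min(overlap/width(a), overlap/width(b))`; 0 when disjoint, 1 for
#' identical intervals. Used to decide cooperative co-binding of TF pairs.
#'
#' @param a,b single-interval `GRanges`.
#' @return fraction in `[0,1]`.
#' @export
reciprocalOverlap <- function(a, b) {
  a <- asSingleRange(a, "a"); b <- asSingleRange(b, "b")
  ov <- overlapLength(a, b)
  if (ov == 0L) return(0)
  min(ov / GenomicRanges::width(a), ov / GenomicRanges::width(b))
}
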