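annRow <- function(gene, tss, strand, chrom = "chrT") {
  data.frame(gene = gene, chrom = chrom, tss = tss, strand = strand,
             stringsAsFactors = FALSE)
}

mkPeaks <- function(assay, start0, end0, chrom = "chrT") {
  PeakSet(GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = start0 + 1, end = end0)), assay = assay)
}

test_that("promoter windows are strand-aware and clipped at zero", {
  plus <- definePromoters(annRow("g1", 10000, "+"))
  expect_equal(GenomicRanges::start(plus), 8501L)   # [8500, 10500)
  expect_equal(GenomicRanges::end(plus), 10500L)
  minus <- definePromoters(annRow("g2", 10000, "-"))
  expect_equal(GenomicRanges::start(minus), 9501L)  # [9500, 11500)
  expect_equal(GenomicRanges::end(minus), 11500L)
  clipped <- definePromoters(annRow("g3", 1000, "+"))
  expect_equal(GenomicRanges::start(clipped), 1L)   # [0, 1500)
  expect_equal(GenomicRanges::end(clipped), 1500L)
})

test_that("promoter activity needs >= 1 bp of H3K4me3 overlap, untruncated", {
  prom <- definePromoters(annRow(c("g1", "g2", "g3"),
                                 c(10000, 30000, 50000), c("+", "+", "+")))
  # one peak touching g1 by a single base, two peaks inside g3, none in g2
  k4 <- mkPeaks("H3K4me3", c(8499, 49000, 49600), c(8501, 49500, 50200))
  regions <- callActivePromoters(prom, k4)
  md <- S4Vectors::mcols(regions)
  expect_equal(unname(md$active), c(TRUE, FALSE, TRUE))
  expect_equal(sum(md$gene == "g3"), 1L)  # one region despite two peaks
  # full window retained
  expect_equal(GenomicRanges::start(regions), c(8501L, 28501L, 48501L))
  expect_error(callActivePromoters(prom, mkPeaks("DNase", 1, 10)), "H3K4me3")
})

test_that("active enhancers are truncated per peak; inactive ones dropped", {
  emap <- data.frame(chrom = "chrT", start = c(1000, 5000, 9000),
                     end = c(2000, 6000, 9500),
                     gene = c("g1", "g1", "g2"),
                     enhancer_id = c("E1", "E2", "E3"),
                     stringsAsFactors = FALSE)
  # E1: one peak half-covering; E2: two disjoint peaks; E3: none
  k27 <- mkPeaks("H3K27ac", c(1500, 5100, 5600), c(2500, 5200, 5800))
  regions <- callActiveEnhancers(emap, k27)
  md <- S4Vectors::mcols(regions)
  e1 <- regions[md$region_id == "E1|g1#1"]
  expect_equal(GenomicRanges::start(e1), 1501L)  # [1500, 2000)
  expect_equal(GenomicRanges::end(e1), 2000L)
  expect_equal(sum(startsWith(md$region_id, "E2|g1")), 2L)
  expect_false(any(md$gene == "g2"))
  # every active segment lies inside its enhancer and inside a peak
  expect_true(all(GenomicRanges::countOverlaps(regions,
    peakRanges(k27), type = "within") >= 1L))
})

test_that("binding events require the triple overlap with accessible chromatin", {
  regions <- callActiveEnhancers(
    data.frame(chrom = "chrT", start = 1000, end = 2000, gene = "g1",
               enhancer_id = "E1", stringsAsFactors = FALSE),
    mkPeaks("H3K27ac", 1000, 2000))
  tfIn <- list(A = mkPeaks("TF-binding", 1200, 1400))
  # DNase covering the intersection -> event
  ev <- callBindingEvents(regions, tfIn, mkPeaks("DNase", 1100, 1500))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$tf, "A")
  expect_equal(ev$region_id, "E1|g1#1")
  # no DNase overlap within the region -> no event
  expect_equal(nrow(callBindingEvents(regions, tfIn,
                                      mkPeaks("DNase", 3000, 4000))), 0L)
  # TF peak overlapping DNase outside the region -> no event
  tfOut <- list(A = mkPeaks("TF-binding", 2100, 2300))
  expect_equal(nrow(callBindingEvents(regions, tfOut,
                                      mkPeaks("DNase", 2100, 2300))), 0L)
})

test_that("binding events equal the brute-force triple filter on random fixtures", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      nReg <- 6
      regStarts <- sort(sample.int(50000, nReg)) + 0:(nReg - 1) * 3000
      regions <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(start = regStarts, width = 800))
      S4Vectors::mcols(regions)$region_id <- paste0("R", 1:nReg)
      S4Vectors::mcols(regions)$gene <- paste0("g", 1:nReg)
      S4Vectors::mcols(regions)$kind <- "enhancer"
      S4Vectors::mcols(regions)$active <- TRUE
      mkRand <- function(n) GenomicRanges::GRanges("chrT",
        IRanges::IRanges(start = sample.int(80000, n), width = 300))
      tfPeaks <- list(A = PeakSet(mkRand(5), "TF-binding"),
                      B = PeakSet(mkRand(5), "TF-binding"))
      dnase <- PeakSet(mkRand(8), "DNase")
      ev <- callBindingEvents(regions, tfPeaks, dnase)
      # brute force over all (tf peak, region, dnase peak) triples
      expected <- 0L
      for (tf in names(tfPeaks)) {
        pk <- peakRanges(tfPeaks[[tf]])
        for (i in seq_along(pk)) for (j in seq_along(regions)) {
          if (overlapLength(pk[i], regions[j]) < 1L) next
          inter <- truncateToPeak(pk[i], regions[j])
          open <- any(vapply(seq_along(peakRanges(dnase)), function(k)
            overlapLength(inter, peakRanges(dnase)[k]) >= 1L, logical(1)))
          if (open) expected <- expected + 1L
        }
      }
      expect_equal(nrow(ev), expected)
    }
  })
})

test_that("binding events are invariant to peak input order", {
  b <- cachedScenario()
  regions <- c(
    callActivePromoters(definePromoters(b$genome$promoterAnnotation),
                        b$targetPeaks$h3k4me3),
    callActiveEnhancers(b$genome$enhancerMap, b$targetPeaks$h3k27ac))
  ev1 <- callBindingEvents(regions, b$targetPeaks$tfPeaks,
                           b$targetPeaks$dnase)
  shuffle <- function(ps) {
    gr <- peakRanges(ps)
    PeakSet(rev(gr), assay = assayLabel(ps))
  }
  tfShuf <- lapply(b$targetPeaks$tfPeaks, shuffle)
  tfShuf <- rev(tfShuf)
  ev2 <- callBindingEvents(regions, tfShuf, shuffle(b$targetPeaks$dnase))
  expect_equal(ev1, ev2)
})
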