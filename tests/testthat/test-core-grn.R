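evRow <- function(tf, target, region, kind = "promoter", s = 100L) {
  data.frame(tf = tf, target_gene = target, region_id = region, kind = kind,
             peak_chrom = "chrT", peak_start = s, peak_end = s + 100L,
             stringsAsFactors = FALSE)
}

actTab <- function(active, inactive = character()) {
  data.frame(gene = c(active, inactive),
             p_inactive = c(rep(0.01, length(active)),
                            rep(0.5, length(inactive))),
             active = c(rep(TRUE, length(active)),
                        rep(FALSE, length(inactive))),
             p_active_marginal = 0.5, stringsAsFactors = FALSE)
}

test_that("scaffold edges require active regulator and target; self-loops kept", {
  ev <- rbind(evRow("A", "B", "promoter:B"),
              evRow("A", "A", "ENH_A|A#1", kind = "enhancer"),
              evRow("C", "B", "promoter:B"))
  sc <- buildScaffold(ev, actTab(c("A", "B"), inactive = "C"))
  expect_setequal(sc$nodes, c("A", "B"))
  expect_equal(nrow(sc$edges), 2L)
  expect_true(any(sc$edges$regulator == "A" & sc$edges$target == "A" &
                  sc$edges$kinds == "enhancer"))
  expect_true(any(sc$edges$regulator == "A" & sc$edges$target == "B" &
                  sc$edges$kinds == "promoter"))
  expect_error(buildScaffold(ev, actTab(c("A", "B", "C")),
                             regionIds = "promoter:B"), "unknown region")
})

test_that("edge kind annotation merges promoter and enhancer support", {
  ev <- rbind(evRow("A", "B", "promoter:B"),
              evRow("A", "B", "E1|B#1", kind = "enhancer"),
              evRow("A", "B", "E2|B#1", kind = "enhancer"))
  sc <- buildScaffold(ev, actTab(c("A", "B")))
  expect_equal(sc$edges$kinds, "enhancer,promoter")
  expect_equal(sc$edges$n_events, 3L)
})

test_that("co-factor selection is the conjunction of all four criteria", {
  zs <- data.frame(tf = c("C1", "C2", "C3", "C4"),
                   z = c(-2, -2, -0.5, -2),
                   eligible = c(TRUE, TRUE, FALSE, TRUE),
                   stringsAsFactors = FALSE)
  ev <- rbind(evRow("C1", "I1", "promoter:I1"),
              evRow("I1", "C1", "promoter:C1"),
              evRow("C2", "I1", "promoter:I1"),   # not regulated by identity
              evRow("C3", "I1", "promoter:I1"),   # bad z-score
              evRow("I1", "C3", "promoter:C3"),
              evRow("C4", "I1", "promoter:I1"),   # inactive
              evRow("I1", "C4", "promoter:C4"))
  act <- actTab(c("I1", "C1", "C2", "C3"), inactive = "C4")
  sc <- buildScaffold(ev, act)
  expect_equal(selectCofactors(sc, "I1", act, zs), "C1")
  expect_warning(selectCofactors(sc, c("I1", "I9"), act, zs), "absent")
})

test_that("core assembly drops promoterless nodes and induces the subgraph", {
  ev <- rbind(evRow("A", "B", "promoter:B"), evRow("B", "A", "promoter:A"),
              evRow("A", "X", "promoter:X"))
  act <- actTab(c("A", "B", "X"))
  sc <- buildScaffold(ev, act)
  regions <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(start = c(1, 1000, 2000), width = 500))
  S4Vectors::mcols(regions)$region_id <- c("promoter:A", "promoter:B",
                                           "promoter:X")
  S4Vectors::mcols(regions)$gene <- c("A", "B", "X")
  S4Vectors::mcols(regions)$kind <- "promoter"
  S4Vectors::mcols(regions)$active <- c(TRUE, TRUE, FALSE)
  expect_warning(grn <- assembleCoreGRN(sc, c("A", "B", "X"), character(),
                                        regions), "X")
  expect_equal(networkTFs(grn), c("A", "B"))
  # edge to the dropped node is excluded; remaining edges induced
  expect_equal(nrow(networkEdges(grn)), 2L)
  expect_false("X" %in% networkEdges(grn)$target)
  expect_error(assembleCoreGRN(sc, character(), character(), regions),
               "empty node set")
})

test_that("gold-standard comparison applies the shared-TF rule and set algebra", {
  gs <- data.frame(regulator = c("A", "B"), target = c("B", "C"))
  inf <- data.frame(regulator = c("A", "C"), target = c("B", "A"))
  cmp <- compareToGoldStandard(inf, gs)
  expect_equal(cmp$matching, 1L)
  expect_equal(cmp$mismatching, 1L)
  expect_equal(cmp$newly_inferred, 1L)
  expect_equal(cmp$matching + cmp$mismatching, cmp$gs_interactions)
  # identical sets -> 100% validated
  same <- compareToGoldStandard(gs, gs)
  expect_equal(same$overall_validated, 100)
  # GS edge touching a TF absent from the inferred node set is excluded
  gs2 <- rbind(gs, data.frame(regulator = "Z", target = "A"))
  cmp2 <- compareToGoldStandard(inf, gs2)
  expect_equal(cmp2$gs_interactions, 2L)
  expect_error(compareToGoldStandard(
    data.frame(regulator = "P", target = "Q"), gs), "shared")
})

test_that("gold-standard counts match a brute-force comparison on random lists", {
  withr::with_seed(31, {
    tfs <- LETTERS[1:8]
    for (rep in 1:10) {
      rnd <- function(n) data.frame(
        regulator = sample(tfs, n, replace = TRUE),
        target = sample(tfs, n, replace = TRUE), stringsAsFactors = FALSE)
      inf <- unique(rnd(12)); gs <- unique(rnd(10))
      cmp <- compareToGoldStandard(inf, gs)
      shared <- intersect(unique(c(inf$regulator, inf$target)),
                          unique(c(gs$regulator, gs$target)))
      inShared <- function(df) df[df$regulator %in% shared &
                                  df$target %in% shared, ]
      gsS <- inShared(gs); infS <- inShared(inf)
      match2 <- 0L
      for (i in seq_len(nrow(gsS))) {
        hit <- any(infS$regulator == gsS$regulator[i] &
                   infS$target == gsS$target[i])
        match2 <- match2 + as.integer(hit)
      }
      expect_equal(cmp$matching, match2)
      expect_equal(cmp$gs_interactions, nrow(gsS))
      expect_equal(cmp$inferred_interactions, nrow(infS))
    }
  })
})

test_that("export writes a parseable edge TSV and JSON bundle", {
  b <- cachedScenario()
  res <- reconstructFromBundle(b)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  exportCoreGRN(res$grn, tsv, js)
  ed <- read.table(tsv, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  expect_equal(nrow(ed), nrow(networkEdges(res$grn)))
  bundle <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_setequal(bundle$identity, res$grn@identity)
  expect_equal(length(bundle$rules), length(networkTFs(res$grn)))
})
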