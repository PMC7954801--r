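#' Configuration of the synthetic-fixture generator
#'
#' All randomness of the generator flows from `seed`; two calls with equal
#' configurations are identical. At `noiseLevel = 0` the generated data
#' are exactly recoverable: the reconstruction pipeline returns the
#' planted network, logic rules, identity TFs and co-factors.
#'
#' @param nTfs number of network TFs (identity TFs + co-factors).
#' @param nCofactors how many of them are planted as co-factors.
#' @param kPlanted size of the planted optimal instructive-factor set
#'   (a subset of the identity TFs; its first member is the planted
#'   essential TF).
#' @param nBackgroundSamples background compendium size.
#' @param nPhenotypes number of synthetic background phenotypes.
#' @param decoysPerPhenotype integer vector (length `nPhenotypes`) of
#'   phenotype-specific decoy TFs; unequal counts spread the co-factor
#'   background ranks so the rank z-score is exercised.
#' @param nHousekeeping housekeeping (non-TF) genes.
#' @param genomeLength toy chromosome length in bp (`NULL` = sized
#'   automatically).
#' @param meanEnhancersPerGene mean of the geometric enhancer count per
#'   gene (support starts at 1; most genes get 1-2 enhancers).
#' @param noiseLevel peak add/drop rate in `[0, 1]`.
#' @param seed mandatory integer seed.
#' @return a named list of settings.
#' @export
fixtureConfig <- function(nTfs = 12, nCofactors = 2, kPlanted = 3,
                          nBackgroundSamples = 30, nPhenotypes = 5,
                          decoysPerPhenotype = seq(20, by = 2,
                                                   length.out = nPhenotypes),
                          nHousekeeping = 10, genomeLength = NULL,
                          meanEnhancersPerGene = 2, noiseLevel = 0,
                          seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(nTfs >= 4, nCofactors >= 0, nTfs - nCofactors >= kPlanted,
            kPlanted >= 1, noiseLevel >= 0, noiseLevel <= 1,
            meanEnhancersPerGene >= 1,
            length(decoysPerPhenotype) == nPhenotypes)
  nIdentity <- nTfs - nCofactors
  nGenes <- nTfs + sum(decoysPerPhenotype)
  pitch <- 7000
  minLen <- nGenes * pitch + 4000
  if (is.null(genomeLength)) genomeLength <- minLen
  list(nTfs = nTfs, nIdentity = nIdentity, nCofactors = nCofactors,
       kPlanted = kPlanted, nBackgroundSamples = nBackgroundSamples,
       nPhenotypes = nPhenotypes, decoysPerPhenotype = decoysPerPhenotype,
       nHousekeeping = nHousekeeping, genomeLength = genomeLength,
       pitch = pitch, meanEnhancersPerGene = meanEnhancersPerGene,
       noiseLevel = noiseLevel, seed = seed)
}

fixtureGeneNames <- function(config) {
  pad <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
  network <- pad("TF", config$nTfs)
  list(network = network,
       identity = network[seq_len(config$nIdentity)],
       cofactors = if (config$nCofactors)
         network[config$nIdentity + seq_len(config$nCofactors)]
         else character(),
       decoys = pad("DEC", sum(config$decoysPerPhenotype)),
       housekeeping = pad("HK", config$nHousekeeping))
}

#' Generate a toy genome: promoter annotation and enhancer map
#'
#' Places the network and decoy TF genes on one toy chromosome with
#' non-overlapping promoter windows and alternating strands, and draws a
#' geometric number of enhancers per gene (support starting at 1, mean
#' `meanEnhancersPerGene`) downstream of each promoter window.
#'
#' @param config a [fixtureConfig()].
#' @return list with `promoterAnnotation` (data.frame) and `enhancerMap`
#'   (data.frame, 0-based half-open coordinates).
#' @export
generateToyGenome <- function(config) {
  withr::with_seed(config$seed, generateToyGenomeImpl(config))
}

generateToyGenomeImpl <- function(config) {
  nm <- fixtureGeneNames(config)
  genes <- c(nm$network, nm$decoys)
  nGenes <- length(genes)
  if (config$genomeLength < nGenes * config$pitch + 4000)
    stop("genome too short to place ", nGenes, " genes")
  tss <- 2000 + (seq_len(nGenes) - 1L) * config$pitch
  strand <- rep(c("+", "-"), length.out = nGenes)
  ann <- data.frame(gene = genes, chrom = "chrT", tss = as.integer(tss),
                    strand = strand, stringsAsFactors = FALSE)
  # enhancer counts: 1 + geometric, capped at 4 so placement stays in-pitch
  extraP <- 1 / config$meanEnhancersPerGene
  counts <- pmin(1L + stats::rgeom(nGenes, extraP), 4L)
  rows <- list()
  for (i in seq_len(nGenes)) {
    for (j in seq_len(counts[i])) {
      # enhancers sit beyond the largest promoter window extent (1500 bp)
      s0 <- tss[i] + 1600 + (j - 1L) * 700
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "chrT", start = s0, end = s0 + 500, gene = genes[i],
        enhancer_id = sprintf("ENH_%s_%d", genes[i], j),
        stringsAsFactors = FALSE)
    }
  }
  list(promoterAnnotation = ann, enhancerMap = do.call(rbind, rows))
}

## ---- planted network --------------------------------------------------------

# Plant a core GRN over the network TFs with per-region regulator usage.
# Node order: planted IF set first (essential TF at position 1), then the
# remaining identity TFs, then co-factors. Every node's first promoter
# cluster (and, where enhancer clauses exist, the first cluster of the
# first enhancer clause) is drawn from the planted set plus earlier nodes,
# so clamping the planted set activates the whole network from any state.
plantGRN <- function(config, genome) {
  nm <- fixtureGeneNames(config)
  nodes <- nm$network
  planted <- nodes[seq_len(config$kPlanted)]
  essential <- planted[1L]
  enhOf <- split(genome$enhancerMap$enhancer_id, genome$enhancerMap$gene)
  usage <- stats::setNames(vector("list", length(nodes)), nodes)
  ppiPairs <- list()
  addCluster <- function(pool, allowPair) {
    if (allowPair && length(pool) >= 2L && stats::runif(1) < 0.4) {
      sort(sample(pool, 2L))
    } else sample(pool, 1L)
  }
  for (i in seq_along(nodes)) {
    node <- nodes[i]
    if (node == essential) {
      usage[[node]] <- list(promoter = list(), enhancers = list())
      next
    }
    avail <- setdiff(unique(c(planted, nodes[seq_len(i - 1L)])), node)
    if (node %in% planted) {
      # other planted members are induced by the essential TF
      usage[[node]] <- list(promoter = list(essential), enhancers = list())
      next
    }
    guaranteePool <- if (node %in% nm$cofactors)
      intersect(avail, nm$identity) else avail
    clusters <- list(addCluster(guaranteePool, allowPair = TRUE))
    # optional extra singleton regulator from anywhere (OR'd, never blocks)
    extraPool <- setdiff(nodes, c(node, unlist(clusters)))
    if (length(extraPool) && stats::runif(1) < 0.5)
      clusters <- c(clusters, list(sample(extraPool, 1L)))
    enhancers <- list()
    myEnh <- enhOf[[node]]
    if (length(myEnh) && stats::runif(1) < 0.5) {
      pool2 <- setdiff(avail, NULL)
      enhancers[[myEnh[1L]]] <- list(addCluster(pool2, allowPair = TRUE))
    }
    usage[[node]] <- list(promoter = clusters, enhancers = enhancers)
  }
  # the essential TF appears in an enhancer clause of the first non-planted
  # node (clamped-off-impossible structure)
  firstFree <- nodes[config$kPlanted + 1L]
  enh1 <- enhOf[[firstFree]][1L]
  u <- usage[[firstFree]]
  if (!essential %in% unlist(u$enhancers))
    u$enhancers[[enh1]] <- c(list(essential),
                             if (!is.null(u$enhancers[[enh1]]))
                               u$enhancers[[enh1]] else NULL)
  usage[[firstFree]] <- u
  # co-factors must regulate at least one identity TF: append them as
  # singleton OR-clusters on a random identity node's promoter
  for (cf in nm$cofactors) {
    targets <- setdiff(nm$identity, essential)
    tgt <- sample(targets, 1L)
    u <- usage[[tgt]]
    if (!cf %in% unlist(c(u$promoter, u$enhancers)))
      u$promoter <- c(u$promoter, list(cf))
    usage[[tgt]] <- u
  }
  # drop duplicate TFs within a region (a TF binds a region once)
  usage <- lapply(usage, function(u) {
    seen <- character()
    u$promoter <- Filter(length, lapply(u$promoter, function(cl) {
      cl <- setdiff(cl, seen); seen <<- c(seen, cl); cl
    }))
    u$enhancers <- lapply(u$enhancers, function(clause) {
      seen2 <- character()
      Filter(length, lapply(clause, function(cl) {
        cl <- setdiff(cl, seen2); seen2 <<- c(seen2, cl); cl
      }))
    })
    u
  })
  # PPI records for every planted AND-pair
  for (node in nodes) {
    for (cl in c(usage[[node]]$promoter,
                 unlist(usage[[node]]$enhancers, recursive = FALSE))) {
      if (length(cl) == 2L) ppiPairs[[length(ppiPairs) + 1L]] <- cl
    }
  }
  ppi <- if (length(ppiPairs)) {
    unique(data.frame(tf_a = vapply(ppiPairs, `[`, character(1), 1L),
                      tf_b = vapply(ppiPairs, `[`, character(1), 2L),
                      stringsAsFactors = FALSE))
  } else data.frame(tf_a = character(), tf_b = character(),
                    stringsAsFactors = FALSE)
  list(nodes = nodes, identity = nm$identity, cofactors = nm$cofactors,
       planted = planted, essential = essential, usage = usage, ppi = ppi)
}

# planted usage -> LogicRule list and edge table (what reconstruction
# should recover)
plantedRules <- function(grn, genome) {
  canon <- function(clusters) {
    clusters <- lapply(clusters, sort)
    clusters[order(vapply(clusters, `[`, character(1), 1L))]
  }
  rules <- lapply(grn$nodes, function(node) {
    u <- grn$usage[[node]]
    enh <- u$enhancers
    # enhancer clauses in region-id order, matching the rule compiler; the
    # compiled region id is "<enhancer_id>|<gene>#<segment>"
    enhClauses <- if (length(enh))
      lapply(enh[order(names(enh))], canon) else list()
    buildLogicRule(node, canon(u$promoter), unname(enhClauses))
  })
  names(rules) <- grn$nodes
  rules
}

plantedEdges <- function(grn) {
  rows <- list()
  for (node in grn$nodes) {
    u <- grn$usage[[node]]
    for (tf in unlist(u$promoter))
      rows[[length(rows) + 1L]] <- data.frame(regulator = tf, target = node,
        kind = "promoter", stringsAsFactors = FALSE)
    for (clause in u$enhancers)
      for (tf in unlist(clause))
        rows[[length(rows) + 1L]] <- data.frame(regulator = tf, target = node,
          kind = "enhancer", stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, rows)
  key <- paste(ev$regulator, ev$target, sep = "\r")
  kinds <- vapply(split(ev$kind, key), function(k)
    paste(sort(unique(k)), collapse = ","), character(1))
  nev <- vapply(split(ev$kind, key), length, integer(1))
  parts <- strsplit(names(kinds), "\r", fixed = TRUE)
  edges <- data.frame(
    regulator = vapply(parts, `[`, character(1), 1L),
    target = vapply(parts, `[`, character(1), 2L),
    kinds = unname(kinds), n_events = unname(nev), stringsAsFactors = FALSE)
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

## ---- peak generation --------------------------------------------------------

grFrom0 <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1,
                                                 end = end0))
}

#' Generate cell-type peak sets realizing a planted network
#'
#' For the `"target"` cell type, emits H3K4me3, H3K27ac and DNase peaks
#' plus per-TF binding peaks such that the reconstruction rules recover
#' exactly the planted edges and AND-clusters at noise 0: every planted
#' regulator gets one peak inside the (accessible) active region it uses;
#' planted AND-pairs co-bind with reciprocal overlap 0.8, all other
#' co-regulators bind disjoint slots. The `"initial"` cell type carries
#' the same active regions for every non-planted TF and none for the
#' planted instructive factors (their epigenome still requires
#' remodeling), and no TF binding peaks.
#'
#' @param config a [fixtureConfig()].
#' @param plantedGRN internal planted-network description (from
#'   [generateConversionScenario()]'s `planted` element).
#' @param genome list from [generateToyGenome()].
#' @param celltype `"target"` or `"initial"`.
#' @return list of [PeakSet-class]: `h3k4me3`, `h3k27ac`, `dnase`, and
#'   `tfPeaks` (named list, possibly empty).
#' @export
generateCelltypePeaks <- function(config, plantedGRN, genome,
                                  celltype = c("target", "initial")) {
  celltype <- match.arg(celltype)
  unknown <- setdiff(plantedGRN$nodes, genome$promoterAnnotation$gene)
  if (length(unknown))
    stop("planted network references genes absent from the genome: ",
         unknown[1L])
  withr::with_seed(config$seed + 1L,
                   generatePeaksImpl(config, plantedGRN, genome, celltype))
}

generatePeaksImpl <- function(config, grn, genome, celltype) {
  ann <- genome$promoterAnnotation
  emap <- genome$enhancerMap
  wnd <- definePromoters(ann)
  k4 <- list(); k27 <- list(); dn <- list(); tfp <- list()
  nodes <- if (celltype == "target") grn$nodes
           else setdiff(grn$nodes, grn$planted)
  for (node in nodes) {
    a <- ann[ann$gene == node, ]
    w <- wnd[names(wnd) == node]
    ws0 <- GenomicRanges::start(w) - 1L
    we0 <- GenomicRanges::end(w)
    k4[[node]] <- c(a$tss - 100L, a$tss + 100L)
    dn[[paste0(node, ":prom")]] <- c(ws0, we0)
    u <- grn$usage[[node]]
    if (celltype == "target" && length(u$promoter)) {
      slot <- 0L
      for (cl in u$promoter) {
        s0 <- ws0 + 20L + slot * 200L
        tfp[[cl[1L]]] <- rbind(tfp[[cl[1L]]], c(s0, s0 + 150L))
        if (length(cl) == 2L)
          tfp[[cl[2L]]] <- rbind(tfp[[cl[2L]]], c(s0 + 30L, s0 + 180L))
        slot <- slot + 1L
      }
    }
    enhIds <- names(u$enhancers)
    for (eid in enhIds) {
      e <- emap[emap$enhancer_id == eid, ]
      k27[[eid]] <- c(e$start, e$end)
      dn[[paste0(node, ":", eid)]] <- c(e$start, e$end)
      if (celltype == "target") {
        slot <- 0L
        for (cl in u$enhancers[[eid]]) {
          s0 <- e$start + 20L + slot * 200L
          tfp[[cl[1L]]] <- rbind(tfp[[cl[1L]]], c(s0, s0 + 150L))
          if (length(cl) == 2L)
            tfp[[cl[2L]]] <- rbind(tfp[[cl[2L]]], c(s0 + 30L, s0 + 180L))
          slot <- slot + 1L
        }
      }
    }
  }
  noisify <- function(mat) {
    r <- config$noiseLevel
    if (r <= 0 || is.null(mat)) return(mat)
    keep <- stats::runif(nrow(mat)) >= r
    mat <- mat[keep, , drop = FALSE]
    nAdd <- stats::rpois(1L, r * max(1L, nrow(mat)))
    if (nAdd > 0L) {
      s0 <- floor(stats::runif(nAdd, 0, config$genomeLength - 300))
      mat <- rbind(mat, cbind(s0, s0 + 200))
    }
    mat
  }
  toPeakSet <- function(lst, assay) {
    mat <- do.call(rbind, lst)
    mat <- noisify(mat)
    gr <- if (is.null(mat) || !nrow(mat)) GenomicRanges::GRanges()
          else grFrom0("chrT", mat[, 1L], mat[, 2L])
    PeakSet(gr, assay = assay, source = "synthetic")
  }
  tfPeaks <- lapply(tfp, function(mat) {
    mat <- noisify(mat)
    gr <- if (is.null(mat) || !nrow(mat)) GenomicRanges::GRanges()
          else grFrom0("chrT", mat[, 1L], mat[, 2L])
    PeakSet(gr, assay = "TF-binding", source = "synthetic")
  })
  list(h3k4me3 = toPeakSet(k4, "H3K4me3"),
       h3k27ac = toPeakSet(k27, "H3K27ac"),
       dnase = toPeakSet(dn, "DNase"),
       tfPeaks = if (length(tfPeaks)) tfPeaks[order(names(tfPeaks))]
                 else list())
}

## ---- expression generation --------------------------------------------------

#' Generate an expression compendium with planted specificity structure
#'
#' Identity TFs are expressed exclusively in the query sample; co-factors
#' are expressed in the query and at a low uniform level across the
#' background (so their query-specificity rank is far below their mean
#' background rank, z <= -1.5); phenotype-specific decoy TFs dominate the
#' per-sample rankings of the background; housekeeping genes are near
#' constant. All values are non-negative TPM-like abundances.
#'
#' @param config a [fixtureConfig()].
#' @return list with `compendium` (an [ExpressionCompendium-class]),
#'   `query` (named target-cell profile) and `initialProfile` (named
#'   initial-cell profile in which the planted instructive factors are
#'   silent).
#' @export
generateExpressionCompendium <- function(config) {
  withr::with_seed(config$seed + 2L, generateExpressionImpl(config))
}

generateExpressionImpl <- function(config) {
  nm <- fixtureGeneNames(config)
  genes <- c(nm$network, nm$decoys, nm$housekeeping)
  nS <- config$nBackgroundSamples
  phen <- rep(sprintf("phen%02d", seq_len(config$nPhenotypes)),
              length.out = nS)
  decoyPhen <- rep(sprintf("phen%02d", seq_len(config$nPhenotypes)),
                   times = config$decoysPerPhenotype)
  vals <- matrix(0, nrow = length(genes), ncol = nS,
                 dimnames = list(genes, sprintf("bg%03d", seq_len(nS))))
  jitter <- function(n, sdlog = 0.05) exp(stats::rnorm(n, 0, sdlog))
  for (i in seq_along(nm$cofactors))
    vals[nm$cofactors[i], ] <- 0.5 * jitter(nS)
  for (i in seq_along(nm$decoys)) {
    own <- phen == decoyPhen[i]
    vals[nm$decoys[i], own] <- 80 * jitter(sum(own))
    vals[nm$decoys[i], !own] <- 0.1 * jitter(sum(!own))
  }
  for (g in nm$housekeeping)
    vals[g, ] <- 50 * jitter(nS, 0.3)
  compendium <- ExpressionCompendium(vals, phen)
  query <- stats::setNames(numeric(length(genes)), genes)
  query[nm$identity] <- 100
  query[nm$cofactors] <- 60
  query[nm$decoys] <- 0.1
  query[nm$housekeeping] <- 50
  planted <- nm$network[seq_len(config$kPlanted)]
  initial <- stats::setNames(numeric(length(genes)), genes)
  initial[setdiff(nm$identity, planted)] <- 20
  initial[setdiff(nm$cofactors, planted)] <- 0.7
  initial[planted] <- 0
  initial[nm$decoys] <- 0.1
  initial[nm$housekeeping] <- 50
  list(compendium = compendium, query = query, initialProfile = initial)
}

## ---- full scenario ----------------------------------------------------------

#' Generate a complete planted conversion scenario
#'
#' Emits a self-consistent fixture bundle: toy genome, planted core GRN
#' with Boolean rules, target- and initial-cell-type peak sets, expression
#' compendium with query and initial profiles, and PPI list. The planted
#' instructive-factor set (size `kPlanted`) has combined score 1 at noise
#' 0 — clamping it drives the Boolean network to the all-active state
#' from every initial state, and its epigenetic fractions are all 1 —
#' and its first member is an essential TF (silent in the initial cell
#' type, no incoming edges) without which the network can never be fully
#' activated.
#'
#' @param config a [fixtureConfig()].
#' @return list with elements `config`, `genome`, `planted` (nodes,
#'   identity, cofactors, planted set, essential TF, usage, `rules`,
#'   `edges`), `targetPeaks`, `initialPeaks`, `compendium`, `query`,
#'   `initialProfile`, `ppi` and `params` (matching
#'   [reconstructionParams()]).
#' @export
generateConversionScenario <- function(config) {
  genome <- generateToyGenome(config)
  planted <- withr::with_seed(config$seed + 3L, plantGRN(config, genome))
  planted$rules <- plantedRules(planted, genome)
  planted$edges <- plantedEdges(planted)
  targetPeaks <- generateCelltypePeaks(config, planted, genome, "target")
  initialPeaks <- generateCelltypePeaks(config, planted, genome, "initial")
  expr <- generateExpressionCompendium(config)
  params <- reconstructionParams(nIdentity = config$nIdentity)
  list(config = config, genome = genome, planted = planted,
       targetPeaks = targetPeaks, initialPeaks = initialPeaks,
       compendium = expr$compendium, query = expr$query,
       initialProfile = expr$initialProfile, ppi = planted$ppi,
       params = params)
}

#' Write a fixture bundle to disk as BED/TSV/JSON
#'
#' Writes every component in the plain-text formats the package readers
#' consume, plus a JSON manifest of the planted ground truth.
#'
#' @param bundle list from [generateConversionScenario()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFixtureBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  utils::write.table(bundle$genome$promoterAnnotation, p("promoters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$genome$enhancerMap, p("enhancers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$ppi, p("ppi.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (ct in c("targetPeaks", "initialPeaks")) {
    pk <- bundle[[ct]]
    tag <- sub("Peaks$", "", ct)
    writePeaks(pk$h3k4me3, p(paste0(tag, "_h3k4me3.bed")))
    writePeaks(pk$h3k27ac, p(paste0(tag, "_h3k27ac.bed")))
    writePeaks(pk$dnase, p(paste0(tag, "_dnase.bed")))
    for (tf in names(pk$tfPeaks))
      writePeaks(pk$tfPeaks[[tf]], p(paste0(tag, "_tf_", tf, ".bed")))
  }
  vals <- exprValues(bundle$compendium)
  utils::write.table(
    data.frame(gene = rownames(vals), vals, check.names = FALSE),
    p("compendium.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(vals),
               phenotype = unname(phenotypes(bundle$compendium))),
    p("compendium_metadata.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(gene = names(bundle$query), value = unname(bundle$query)),
    p("query.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = names(bundle$initialProfile),
               value = unname(bundle$initialProfile)),
    p("initial_profile.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    identity = bundle$planted$identity,
    cofactors = bundle$planted$cofactors,
    planted_set = bundle$planted$planted,
    essential = bundle$planted$essential,
    edges = bundle$planted$edges,
    rules = vapply(bundle$planted$rules, ruleToText, character(1)),
    seed = bundle$config$seed)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Run the reconstruction pipeline on a fixture bundle
#'
#' Convenience wrapper wiring a [generateConversionScenario()] bundle into
#' [reconstructCoreGRN()].
#'
#' @param bundle list from [generateConversionScenario()].
#' @return see [reconstructCoreGRN()].
#' @export
reconstructFromBundle <- function(bundle) {
  reconstructCoreGRN(
    query = bundle$query,
    compendium = bundle$compendium,
    promoterAnnotation = bundle$genome$promoterAnnotation,
    enhancerMap = bundle$genome$enhancerMap,
    h3k4me3 = bundle$targetPeaks$h3k4me3,
    h3k27ac = bundle$targetPeaks$h3k27ac,
    dnase = bundle$targetPeaks$dnase,
    tfPeaks = bundle$targetPeaks$tfPeaks,
    ppi = bundle$ppi,
    params = bundle$params)
}
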