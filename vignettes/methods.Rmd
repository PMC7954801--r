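---
title: "Reconstructing core regulatory networks and prioritizing conversion factors"
author: "convGRN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing core regulatory networks and prioritizing conversion factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convGRN)
```

# Overview

Transcription-factor over-expression can convert one human cell type into
another, but conversion efficiency is usually low. `convGRN` implements a
model-based strategy for choosing *which* TFs to over-express: it
reconstructs the core gene regulatory network (GRN) of the target cell
type from transcriptomic and epigenomic evidence, compiles the network
into a Boolean model with cooperativity logic, and ranks candidate
combinations of instructive factors (IFs) by a surrogate of conversion
efficiency that combines a transcriptional and an epigenetic score.

This vignette explains the model, its assumptions, the tunable
parameters, the numerical choices made where the design was open, and
what the synthetic-fixture generator does and does not emulate.

# Identity TFs and co-factors

The nodes of the core GRN are chosen from expression data alone.

**Identity TFs** are the TFs most specifically expressed in the target
("query") cell type relative to a large background compendium of other
cell types and tissues. Background samples that resemble the query are
first excluded: any sample whose Pearson correlation with the query —
computed on `log2(x+1)`-transformed shared genes — exceeds a cutoff
(default 0.75, calibratable with `calibrateCorrelationCutoff()` by
maximizing the F1 score of separating labelled in-class from out-of-class
samples). The log transform stabilizes the heavy right tail of TPM-like
abundances before correlating.

Specificity is then measured per TF by the Jensen–Shannon divergence
(base 2) between (i) the TF's expression distribution over the query plus
the filtered background, normalized to sum to one, and (ii) the idealized
distribution that puts all mass on the query sample. We report
`1 - sqrt(JSD)`, so a TF expressed *exclusively* in the query scores
exactly 1, and rank TFs by decreasing specificity (deterministic
lexicographic tie-break). The top `n` (default 10) become the identity
TFs. Note that under the point-mass construction an exclusively
query-specific TF has JSD 0, so "most specific" corresponds to the
*smallest* divergence; ranking by `1 - sqrt(JSD)` encodes that reading.

**Activity calls** discretize expression. For gene `g` with observed
value `x` and background values `b_1..b_N`, the empirical one-sided
p-value for the null hypothesis "g is inactive" is
`p = (1 + #{b_i >= x}) / (1 + N)`; genes with `p < 0.1` are active. The
`+1` correction keeps p strictly positive. The same background yields the
activation probability `P(active) = #{b_i < x} / N` (the empirical CDF)
used later by the prior. The p-value interface also accepts externally
computed p-values, so a dedicated bootstrap-based discretization can be
substituted. Activity and activation probabilities use the full
compendium as background, while specificity and co-factor ranks use the
correlation-filtered compendium: the filter exists specifically to keep
query-like samples from deflating specificity, whereas activity is a
question about the full range of expression states.

**Co-factors** are TFs that support the identity program without being
maximally specific themselves. A TF qualifies when all four conditions
hold: it is active; its specificity rank in the query is significantly
below its mean rank across background samples (`z <= -1.5`, with the
degenerate `sd = 0` background giving `z = -Inf` when the query rank
beats the constant mean and `z = 0` otherwise); it regulates at least one
identity TF; and it is regulated by at least one identity TF. Both
promoter- and enhancer-mediated edges satisfy the last two conditions,
and no cap is placed on the number of co-factors.

# Regulatory regions and binding events

Promoters are windows of 1500 bp upstream to 500 bp downstream of the
annotated TSS. The window is strand-aware (upstream/downstream are
biologically strand-relative, so the window is mirrored on the minus
strand) and clipped at coordinate 0. A promoter is **active** when it
overlaps at least one H3K4me3 peak by one or more base pairs; its
coordinates are not truncated.

Enhancers come from a supplied enhancer–gene association table (no
distance-based assignment is attempted). An enhancer is **active** when
it overlaps at least one H3K27ac peak, and it is truncated to the
overlap: each maximal segment of the enhancer intersected with the union
of overlapping peaks becomes one active region, so two disjoint peaks in
one enhancer yield two active regions rather than one bounding span.
Inactive enhancers are discarded. Overlapping peaks within one assay are
not merged beyond this segmentation.

A **binding event** links a TF to a target region when the triple
intersection of the TF's ChIP peak, the active region and at least one
DNase peak spans one or more base pairs — the strictest reading of
"within accessible chromatin": the accessible bases must lie inside the
region–peak intersection, not merely near it. The DNase filter applies
only at the binding-event step; region activity itself is decided by the
histone marks alone. All coordinates follow the BED 0-based half-open
convention on disk and the 1-based closed `GRanges` convention in
memory; an overlap of exactly one base pair counts as overlap, and
chromosome names are matched verbatim.

The GRN scaffold has an edge A→B whenever an active TF A has a binding
event in an active region of active gene B; self-loops are retained,
since autoregulation is pervasive in core identity circuits and the
Boolean semantics handle them naturally. The core GRN is the
node-induced subgraph over identity TFs and co-factors. Nodes without an
active promoter are dropped with a warning — under the logic semantics
below they could never be induced.

# Boolean cooperativity logic

Within one active region, TFs whose peaks overlap strongly *and* that
have a recorded protein–protein interaction are assumed to bind
cooperatively. Concretely, an undirected graph is built over the TFs
bound in the region, with an edge between A and B when their maximal
pairwise reciprocal peak overlap (`min(overlap/|A|, overlap/|B|)`)
reaches the threshold (default 0.6243) **and** the unordered pair occurs
in the PPI table; requiring both is the strict conjunctive reading of the
two conditions. The connected components of that graph are AND-clusters;
clusters combine by OR within the region. A TF with several peaks in one
region contributes its maximal pairwise overlap. The threshold can be
re-derived with `calibrateOverlapThreshold()`, which sweeps a 1e-4 grid
and maximizes balanced accuracy of separating known interacting from
non-interacting pairs; balanced accuracy is used because the two classes
are typically imbalanced, and the printed default is shipped so
calibration is optional.

The rule of a target is

```
target <- (promoter clause) & (enhancer clause 1 | enhancer clause 2 | ...)
```

— regulation requires the promoter *and* at least one enhancer. A target
with no active enhancer uses the promoter clause alone; a target whose
active promoter has no TF bound but whose enhancers do uses the enhancer
disjunction alone (the absent part is vacuously true); a target with no
regulators at all is self-maintaining (next state = current state). All
literals are positive: the model contains no repressors, so every rule is
monotone. Rules serialize to a parenthesized text grammar
(`ruleToText()` / `parseRuleText()` round-trip, with `(1)` standing for
an absent promoter clause).

# The conversion surrogate

The compiled network is a deterministic synchronous Boolean system:
every state has exactly one successor, in which each TF takes the value
of its rule. Over-expressed TFs are **clamped** active for the whole
simulation, not just flipped at the start: inducible cassettes express
continuously, and the essentiality behaviour below requires sustained
presence. Stochasticity enters only through the initial state, drawn
from a product-form **prior**: each TF is independently active with its
empirical activation probability in the initial cell type, with clamped
TFs forced to probability 1.

The **transcriptional score** T measures whether the perturbed network
eventually reaches the all-active state (the fully established identity
program, a fixed point of every compiled model). Two variants bracket
the plausible readings of "prior-weighted distance to the target state":

* `reachability` (default): `T = sum_s pi(s) * 1[d(s) < Inf]`, the prior
  probability that the trajectory from `s` ever reaches the all-active
  state;
* `distance_weighted`: finite distances are additionally rewarded for
  being short, `T = sum_s pi(s) * 1[d(s) < Inf] * (1 - d(s)/(dmax+1))`,
  with `dmax` the largest finite distance observed.

`d(s)` is the number of synchronous steps to the all-active state, `Inf`
when the trajectory enters a cycle first. Exact mode enumerates the
clamped subspace (capped at 22 free TFs, about 4M states) and computes
distances by reverse breadth-first search over the functional graph;
beyond the cap a seeded Monte-Carlo estimator draws initial states from
the prior and reports a standard error. Every stochastic path requires
an explicit seed.

The **epigenetic score** E measures remodeling still required: for each
non-perturbed network TF, the fraction of its target-active regulatory
regions (promoter and enhancer segments; promoter inclusion is
configurable) already active in the initial cell type, matching regions
by identifier with at least 1 bp of coordinate overlap. The fraction is
1 for over-expressed TFs — their remodeling is bypassed — and for TFs
with no target-active regions. E is the product of the fractions; the
target-side denominator was chosen because the score should quantify
distance *to the target* epigenome rather than symmetric dissimilarity.
E is monotone: adding a TF to a perturbation can only raise it.

The surrogate efficiency of a perturbation is `(T + E) / 2`.
`rankCombinations()` scores every size-k subset of network TFs
(exhaustive up to 1e6 combinations, explicit candidate lists beyond),
sorting by combined score with a lexicographic tie-break. Agreement
between a predicted and an experimental ranking of k combinations is
quantified by the Euclidean distance between the rank vectors and its
tail probability under the uniform permutation null
(`p = #{perm : dist <= D} / k!`), exhaustive for `k <= 8` and seeded
Monte-Carlo with at least 1e5 draws beyond.

# The synthetic-fixture generator

Real inputs to this kind of analysis are multi-gigabyte public compendia
(expression backgrounds of thousands of samples, hundreds of millions of
ChIP peaks). The package therefore ships a seeded generator of complete
miniature scenarios with planted ground truth, used by the test suite
and the acceptance script.

`generateConversionScenario()` plants, on a single toy chromosome:

* a promoter annotation and an enhancer map (geometric enhancer counts,
  mean 2, so most genes carry 1–2 enhancers, mimicking the observed
  enhancers-per-gene decay);
* a core GRN of identity TFs and co-factors whose edges, AND-clusters
  and rules are realized by construction: each planted regulator gets
  one ChIP peak inside the accessible active region it uses, planted
  cooperative pairs co-bind with reciprocal overlap 0.8 (comfortably
  above the 0.6243 threshold, so small threshold perturbations cannot
  flip labels) plus a PPI record, and competing co-regulators bind
  disjoint slots;
* an expression compendium in which identity TFs are query-exclusive,
  co-factors are uniformly low in a background dominated per sample by
  phenotype-specific decoy TFs (unequal decoy counts per phenotype
  spread the co-factor background ranks, putting their query rank far
  below the mean, `z <= -1.5`), and housekeeping genes are near
  constant;
* a planted optimal IF set whose first member is an **essential** TF:
  silent in the initial cell type (activation probability 0) with no
  incoming edges, so no perturbation omitting it can ever reach the
  all-active state — while clamping the planted set activates the whole
  network from every initial state and its epigenetic fractions are all
  1, giving combined score exactly 1 and rank 1.

At `noiseLevel = 0` the construction is exactly invertible — the
reconstruction pipeline returns the planted identity TFs, co-factors,
edges and clause-level rules — which is the basis of the end-to-end
recovery checks. Nonzero noise adds and removes peaks at the given rate.

What the fixtures do *not* emulate: read-level signal, peak-calling
artifacts, assembly/liftover issues, correlated expression noise across
genes, incomplete or erroneous PPI and enhancer annotations, and the
sheer scale of real compendia. Passing the recovery checks therefore
demonstrates the internal consistency of the pipeline's rules, not its
robustness to the noise structure of real data.

# Numerical choices and problem sizes

* Empirical p-values use the `+1/(N+1)` correction; activity needs
  `p < 0.1` strictly; the co-factor boundary `z = -1.5` is eligible.
* Grid calibrations sweep 0.01 (correlation) and 1e-4 (overlap) steps,
  breaking ties toward the larger cutoff.
* Ranking ties (identical combined scores) break lexicographically on
  the sorted, comma-joined TF names, making all outputs reproducible.
* Exact dynamics are used throughout the tests at network sizes of 8–16
  TFs (state spaces up to 2^16); Monte-Carlo agreement is checked at
  1e4 samples against exact enumeration within three standard errors.
  These sizes were chosen to keep exhaustive, oracle-verifiable
  computation the default everywhere.

# Worked example

```{r example, eval = FALSE}
cfg <- fixtureConfig(seed = 7)
bundle <- generateConversionScenario(cfg)
grn <- reconstructFromBundle(bundle)$grn
grn
#> CoreGRN: 10 identity TFs, 2 co-factors, 34 edges, 19 active regions
#>   logic rules compiled for 12 nodes

tfs <- networkTFs(grn)
marg <- sapply(tfs, function(tf)
  activationProbability(bundle$initialProfile[[tf]],
                        exprValues(bundle$compendium)[tf, ]))
ranking <- rankCombinations(
  grn, k = 3, marginals = marg,
  initialRegions = activeRegionSets(tfs, bundle$genome$promoterAnnotation,
                                    bundle$genome$enhancerMap,
                                    bundle$initialPeaks$h3k4me3,
                                    bundle$initialPeaks$h3k27ac,
                                    params = bundle$params),
  targetRegions = regionSets(grn))
head(ranking, 3)
#>         combination T E combined rank
#> 1 TF001,TF002,TF003 1 1      1.0    1
#> 2 TF001,TF002,TF004 1 0      0.5    2
#> 3 TF001,TF002,TF005 1 0      0.5    3
```

# Known limitations

* No repressor logic: all literals are positive, so the model cannot
  represent factors whose silencing is required.
* The enhancer–gene map is taken as given; mis-assigned enhancers
  propagate directly into the logic.
* Binding evidence is accepted regardless of the cell type it was
  profiled in; the DNase filter is the only cell-type-specific gate on
  binding.
* The deterministic synchronous update is one of several defensible
  semantics; asynchronous updates are not implemented.
* Exact scoring is exponential in the number of non-clamped TFs; large
  networks must use the Monte-Carlo estimator.
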