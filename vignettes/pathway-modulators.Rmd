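---
title: "Comparing subset-specific transcriptional responses with pathmod"
author: "pathmod authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing subset-specific transcriptional responses with pathmod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmod)
```

## The scientific problem

Two closely related cell subsets are exposed to the same stimulus in vivo
and profiled by RNA-Seq, one pooled library per subset and condition.  The
question is not merely *which genes respond* but *how two subsets that share
the same receptor and the same core signalling machinery produce different
transcriptional outcomes*.  The working model is that a common backbone of
core signalling molecules (receptor, adaptors, kinase cascades,
transcription factors) is "fine-tuned" in each subset by subset-specific
**pathway modulators**: differentially expressed genes that physically
interact with the core molecules.

pathmod implements the complete analysis chain needed to ask this question
on count data, and a synthetic-data module that generates inputs with
planted ground truth so every stage can be tested end to end without any
external download.

The stages are:

1. **Chimeric gene models and counting** (`buildChimericModel()`,
   `exonCoverageFilter()`, `countReads()`): per gene, the union of all
   protein-coding transcripts' exons; genes with reads in fewer than half
   of their merged exons in *every* sample are treated as not expressed;
   contiguous alignment intervals are counted with intersection-nonempty
   semantics, discarding multi-mapped reads and reads overlapping several
   genes.
2. **Single-replicate differential expression**
   (`medianRatioSizeFactors()`, `fitBlindDispersion()`, `nbExactTest()`,
   `callDE()`): median-of-ratios normalisation, a pooled ("blind")
   mean--variance trend used *fit-only*, and an exact negative binomial
   test conditioning on the pairwise count total.
3. **Length-bias-corrected enrichment** (`fitLengthWeights()`,
   `walleniusORA()`, `runORA()`, `overlapTest()`): over-representation
   analysis under the Wallenius noncentral hypergeometric distribution,
   the odds-ratio statistic, a minimum-observation term filter, BH
   adjustment, and the hypergeometric gene-list overlap test.
4. **Network analysis** (`cleanNetwork()`, `firstOrderNeighborhood()`,
   `findModulators()`, `vennPartition()`): interaction-table ingestion,
   removal of duplicate edges, self-loops and promiscuous ubiquitin,
   first-order expansion of a curated core-molecule seed list, and the
   Venn partition of each subset's DE interactors.
5. **Active subnetworks** (`scoreNodes()`, `calibrateBackground()`,
   `annealSearch()`, `mergeModules()`): z-transformed p-values, Monte-Carlo
   score calibration, simulated-annealing search for high-scoring
   connected subgraphs, and overlap-based module merging.
6. **Hubs, concordance and reporting** (`classifyHubs()`,
   `analysisConcordance()`, `writeReportBundle()`, `runPipeline()`).

## The statistical model

### Counts

Counts are modelled as negative binomial with variance
$v(\mu) = \mu + \phi\mu^2$.  With one library per condition there are no
replicates, so the variance is estimated *blind*: every sample is treated
as a replicate of every other, pooling across subsets and conditions.  Only
the fitted mean--variance trend is used downstream ("fit-only"); per-gene
empirical variances never override it.  Condition effects inflate the
pooled variances, which makes the resulting test conservative -- the price
of testing without replication.

The parametric trend is $v(\mu) = b_0\mu + b_1\mu^2$, fitted by
gamma-family iteratively reweighted least squares on the per-gene
(mean, variance) pairs of the normalised counts.  $b_0$ absorbs the
shot-noise scale (the mean of the reciprocal size factors) and $b_1$ is
the asymptotic dispersion.  Two robustness measures matter in practice:

* the fit uses *all* genes with positive mean and variance, not only genes
  with positive excess variance -- restricting to positive excess would
  bias the trend upward on Poisson-like data;
* genes whose pooled variance is dominated by condition effects (the
  planted DE genes in a simulation; strongly regulated genes on real data)
  are trend outliers.  They are trimmed at 3.5 MAD of the log residual and
  the trend refitted, up to three rounds.  Without this, a few percent of
  strongly regulated genes inflate the trend severalfold and the test
  loses most of its power.

A local (loess) trend is available via `method = "local"`.

### The exact test

For one gene with counts $k_A, k_B$ and size factors $s_A, s_B$, the test
conditions on the total $S = k_A + k_B$ and sums the probabilities of all
splits no more likely than the observed one:

$$p = \frac{\sum_{a+b=S} P(a)\,P(b)\;
       \mathbf 1\!\left[P(a)P(b) \le P(k_A)P(k_B)\right]}
      {\sum_{a+b=S} P(a)\,P(b)},$$

with $P(\cdot)$ negative binomial densities of mean $s_j\hat q$ (where
$\hat q$ is the pooled normalised mean) and the fitted dispersion at
$\hat q$.  Splits are enumerated exactly for $S \le 10{,}000$; beyond
that the window is pruned where the excluded density mass is below
$10^{-12}$.  A total of zero yields $p = 1$ by convention.

### Calling rules

Two calling rules coexist, mirroring the two ways DE lists are consumed:

* **DE lists, Venn comparison and ORA** use the raw p-value at
  $\alpha = 0.05$ (inclusive), the single-replicate convention.
* **Network input** (modulator identification, subnetwork search seeds)
  uses BH-adjusted $p \le 0.05$ *and* a two-fold change.  This is the
  FDR-controlled rule; it matters because significant null genes at low
  expression almost always show large fold changes (only large deviations
  reach significance there), so a fold-change filter alone cannot control
  the false discovery rate among network seeds.

### Enrichment with length-bias correction

Detection power in RNA-Seq grows with transcript length, so an ORA on DE
genes over-represents annotation terms populated by long genes.  The
correction weights each gene by a monotone function of length fitted from
the observed DE status: genes are binned by length (40 equal-count bins),
per-bin DE proportions are shrunk toward the global DE rate with a prior
weight of twice the bin size, and isotonic regression enforces
monotonicity.  The shrinkage is a stabiliser sized from the binomial noise
of a bin (about 500 genes of which ~10% are DE gives per-bin proportions
with ~25% relative noise; the prior reduces this threefold so that a
bias-free dataset yields weights close to 1).  The fitted weights enter
the Wallenius noncentral hypergeometric distribution as the odds
$w = \bar w_{\text{in term}} / \bar w_{\text{outside}}$; at $w = 1$ the
test reduces exactly to the central hypergeometric.

The Wallenius tail is computed by an exact forward recursion over
sequential draws for universes of at most 200 items, and otherwise by
log-space quadrature of the product-integral representation after the
substitution $t = u^D$, which turns a catastrophically underflowing
integrand into a well-scaled beta-like one; the integral is split at the
integrand mode because the peak is sharp for large draws.  The mass
function is renormalised over its support, and both routes agree to
machine precision on overlapping cases (tested).

The reported odds ratio is the odds of a DE gene occurring in the term
divided by the odds of a non-DE gene occurring in the term.  Terms in
which fewer than 10 genes are observed in **both** subsets are excluded
before testing; observation in one subset retains the term.  BH adjustment
runs within each subset's family of retained terms, separately per
annotation source.  The ORA universe is the set of genes that passed the
expression filter (configurable), not the set of all annotated genes;
with single-sample counts, unexpressed genes carry no evidence either way
and would only dilute the background.

### Active subnetworks

Node scores are $z_i = \Phi^{-1}(1 - p_i)$ with $p$ clamped to
$[10^{-10},\,1 - 10^{-10}]$; nodes without a measured p-value receive
$p = 1$ (about $z = -6.36$) rather than exclusion, so expansion nodes can
still join modules through topology.  A module $A$ of size $k$ has raw
score $z_A = \sum_{i\in A} z_i / \sqrt k$ and calibrated score
$s_A = (z_A - \mu_k)/\sigma_k$, where $\mu_k, \sigma_k$ come from Monte
Carlo over uniform random $k$-node sets (connectivity deliberately *not*
required in the background, matching the original aggregate-score
calibration).  Calibration runs on a grid of sizes (1--10 and ~15
geometrically spaced values) with linear interpolation in between;
$\sigma$ is floored at $10^{-9}$ so constant score fields degrade to a
score of zero instead of dividing by zero.

The search state is a node-inclusion vector.  Single-node toggles are
proposed -- half uniformly, half from the current best component's
neighbourhood (informed proposals; the uniform half keeps the chain
ergodic) -- and accepted always when improving, with probability
$\exp(\Delta s / T)$ otherwise, under geometric cooling
($T: 1 \to 0.01$ over 50,000 iterations by default, 3 restarts).  The
objective is the calibrated score of the best connected component of the
included set, so returned modules are always connected.  Each restart ends
with greedy single-toggle sweeps to a local optimum.  As
$T_\text{start} \to 0$ the chain accepts no worsening move and the search
degenerates to hill climbing (instrumented and tested).  Modules whose
node-set Jaccard index reaches 0.5 are merged greedily, highest-scoring
pair first, with the merged score recomputed from the union.

**A known property of the aggregate score deserves emphasis**: on networks
with hubs, large diffuse sets of mildly positive nodes can outscore small
sharp modules, because a hub connects many nodes with $z > 0$ (half of a
null background!) into one component whose summed score grows faster than
$\sqrt k$.  The optimum on a scale-free network is therefore typically a
large module *containing* the interesting structure -- which is also why
subnetworks of several hundred nodes are the realistic output scale on
interactome-like graphs.  The package's planted-module recovery benchmark
(`benchmarkPlantedModule()`) consequently uses a degree-bounded ring
background, where the planted module is provably the score's optimum and
the benchmark measures the correctness of the search rather than this
bias.

### Hubs, modulators, concordance

Within a discovered subnetwork, degree is computed on the induced subgraph
(`scope = "full"` switches to whole-network degree); hubs are nodes with
at least 5 interactions and the most highly interconnected hubs have at
least 15, both thresholds inclusive.  Pathway modulators are the DE
first-order interactors of the core molecules, seeds excluded; the two
subsets' modulator sets are partitioned into A-only / shared / B-only Venn
classes with exact percentages (display rounding to whole percent is left
to the report layer).  Concordance is the fraction of each subset's
filtered-analysis modulators that reappear among that subset's merged
unbiased subnetwork nodes.

## The synthetic-data generator

`simulationConfig()` fixes the study conditions; `genCounts()`,
`genNetwork()`, `genAnnotations()`, `genExonTable()` and
`genAlignments()` generate the data.  Defaults:

| parameter | default | meaning |
|---|---|---|
| `nGenes` | 5000 | gene universe |
| `nCore` | 48 | designated core signalling molecules |
| `nModulatorsPerSubset` | 40 | planted modulators per subset |
| `baselineMean` | 200 | median of log-normal gene means (sdlog 1.2) |
| `dispersion` | 0.02 | NB $\phi$; var $= \mu + \phi\mu^2$ |
| `foldChange` | 4 | planted multiplicative effect |
| `fracSharedDE` / `fracSubsetDE` | 0.02 / 0.01 | planted DE fractions (floor rule) |
| `lengthBiasStrength` | 0.5 | slope of DE probability vs standardised log length |
| `netAttachM` | 2 | preferential-attachment edges per node |
| `termSizes` / `termOdds` | 8--150 / 1 or 6 | annotation terms; an 8-member term exercises the size filter |

Why these values: the planted fractions, fold change and baseline mean are
the conditions the recovery analyses are defined at; the dispersion of
0.02 reflects single libraries prepared from RNA pooled over many animals,
where biological variation is largely averaged out and residual
overdispersion is modest (at $\phi$ several-fold larger, a four-fold
change at a mean of 200 carries only ~3.5$\sigma$ and no caller can be
simultaneously sensitive and FDR-controlled -- the design the generator
emulates is exactly the pooled-library one).  Sample depths are fixed at
the relative mapped-library sizes of a single-replicate two-subset
stimulation experiment (1, 0.83, 0.95, 0.39), so the two subsets are
deliberately asymmetric in power.  85% of planted effects are
up-regulations, matching the strong up-skew of stimulus-response DE sets.

The interaction network is grown by preferential attachment seeded from a
clique over the core molecules, so cores end up as hubs (degree at least
the 90th percentile, enforced); each planted modulator receives at least
one core edge, planted DE genes that are *not* modulators are kept out of
core neighbourhoods (so the filtered first-order analysis has an exact
planted answer), and a promiscuous `UBC_SYN` node with degree
$\ge 0.3\,n$ exists purely to exercise cleaning.  Annotation terms with
planted odds $w$ oversample DE genes by sequential weighted draws -- i.e.
term membership itself follows a Wallenius law, which is what the
enrichment stage assumes.

What the generator does **not** emulate: batch effects, isoform-level
expression, gapped alignments, correlated baseline programs between gene
modules, orthology mapping across species, and any directionality of
interactions.  Tests passing on this generator therefore demonstrate the
correctness of the algorithms under their own model assumptions, not
performance on real libraries, where dispersion is larger, annotation is
incomplete and the interactome is both noisy and biased toward
well-studied genes.

## Numerical choices and degenerate inputs

* Exact NB enumeration switches to tail-pruned windows above totals of
  10,000 (excluded mass $< 10^{-12}$); zero totals give $p = 1$.
* Fold changes with a zero mean on either side add half of the smallest
  positive normalised count to both sides.
* The Wallenius recursion/quadrature switch is at a universe of 200; the
  pmf is renormalised in both branches.
* Isotonic weighting floors weights at $10^{-6}$ and rescales to mean 1.
* Calibration interpolates linearly between calibrated sizes and clamps
  outside the grid; $\sigma$ floor $10^{-9}$.
* Symbol matching is case-insensitive everywhere, with the first-seen
  spelling kept for display.
* Coordinates are 0-based half-open on disk (exon tables, BED) and
  1-based closed internally; conversion happens only at reader/writer
  boundaries.
* All generators and searches take explicit seeds and are bit-reproducible
  given them.

## Design decisions on genuinely open points

* **The 50% expression filter** is stated for transcripts but counting is
  against chimeric genes; the filter here applies to merged-exon gene
  models, the only reading under which filter and counting see the same
  objects.
* **Strandedness**: counting is strand-agnostic (unstranded protocol
  assumed; verified by a strand-flip invariance test).
* **The ORA universe** is the expressed (filter-passing) gene set, not all
  annotated genes; configurable.
* **Search settings** (iterations, temperatures, restarts, number of
  modules, merge threshold 0.5) are explicit package defaults chosen for
  desk-scale runtimes; nothing in the underlying method prescribes them.
* **Degree scope for hub calling** defaults to the subnetwork-induced
  subgraph, with the full-network alternative exposed, since both
  conventions are in circulation.
* **Problem sizes used by the test-suite and acceptance script** (5,000
  genes, 10--20 simulation seeds, 500-node search benchmarks, $10^6$-draw
  Monte-Carlo oracles) are the package's chosen desk-scale study
  conditions.

## Known limitations

* The aggregate subnetwork score's large-module bias (above) means module
  *boundaries* on hub-rich networks are soft; membership of the strongest
  nodes is stable, the periphery is not.
* The blind variance estimate makes all single-replicate inferences
  conservative in the presence of real condition effects; genes regulated
  in *both* conditions of a pair contribute their effect to the variance
  and can mask themselves.
* Wallenius ORA uses a two-group odds approximation (mean weight inside
  vs outside a term), as in standard practice, rather than fully
  heterogeneous item weights.
* The modulator analysis inherits every bias of the interaction table it
  is given; it treats interactions as undirected and cannot distinguish
  regulation from binding.

## A minimal session

```{r, eval = FALSE}
cfg <- simulationConfig(nGenes = 1000, nCore = 12, nModulatorsPerSubset = 8)
res <- runPipeline(cfg, seed = 1)
res$vennDE                 # subset-specific DE percentages
res$partition              # modulator Venn classes
res$concordance            # filtered vs unbiased agreement
head(res$hubsA)            # hub table of the top module
writeReportBundle(res, "pathmod_report")
```
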