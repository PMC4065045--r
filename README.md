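# pathmod

Comparing the transcriptional responses of two closely related cell subsets
to a common stimulus, from single-replicate RNA-Seq counts to
subset-specific **pathway modulators**: differentially expressed genes that
physically interact with a shared core of signalling molecules and are
hypothesised to fine-tune a common pathway into distinct outcomes.

The package is aimed at computational biologists analysing paired
subset-versus-subset stimulation experiments (sorted immune cell subsets,
paired endothelial or myeloid populations, ...) where each
subset x condition has a single pooled library, and at methodologists who
need a fully testable, download-free reimplementation of this analysis
chain.

## What it computes

* **Chimeric gene models & counting** — per-gene union of protein-coding
  transcript exons; genes with reads in < 50% of merged exons in *all*
  samples are dropped; intersection-nonempty counting that discards
  multi-mapped reads and reads spanning several genes.
* **Single-replicate differential expression** — median-of-ratios size
  factors s_j; a pooled ("blind") mean–variance trend
  v(mu) = b0·mu + b1·mu² used fit-only; and the exact conditional test

      p = sum_{a+b=kA+kB} P(a)P(b) · 1[P(a)P(b) <= P(kA)P(kB)]
          / sum_{a+b=kA+kB} P(a)P(b)

  with negative binomial P(·) at the fitted dispersion.  Genes with
  p <= 0.05 are scored as differentially expressed; an FDR-controlled rule
  (BH-adjusted p <= 0.05 plus two-fold change) feeds the network analyses.
* **Enrichment with length-bias correction** — over-representation under
  the Wallenius noncentral hypergeometric distribution with odds
  w = mean weight in term / mean weight outside, a monotone
  length-to-weight function fitted isotonic from the DE status, odds
  ratios odds(DE in term)/odds(non-DE in term), a >= 10-observed-genes
  filter, BH adjustment, and a hypergeometric gene-list overlap test.
* **Network analysis** — cleaning (duplicate edges, self-loops,
  promiscuous ubiquitin), first-order expansion of a curated core seed
  list, per-subset modulator sets and their Venn partition.
* **Active subnetworks** — z_i = Phi^-1(1 - p_i), module score
  z_A = sum z_i / sqrt(k) calibrated against Monte-Carlo random sets,
  simulated-annealing search for the best connected subgraph, module
  merging, hub calling (degree >= 5; "most highly interconnected"
  >= 15) and concordance between the filtered and unbiased analyses.
* **Synthetic data with planted truth** — NB counts with planted shared
  and subset-specific DE (fold change >= 2), length-dependent detection
  bias, a scale-free interactome with cores wired as hubs and planted
  modulators attached to them, annotation terms with planted enrichment,
  and labelled alignment fixtures — so the whole pipeline is testable
  offline.

## Worked example

```r
library(pathmod)
cfg <- simulationConfig(nGenes = 1000, nCore = 12, nModulatorsPerSubset = 8)
res <- runPipeline(cfg, seed = 1)

res$vennDE
#> ModulatorPartition: |A| = 58 |B| = 50
#>   A-only 38 ( 66 % of A ) | shared 20 | B-only 30 ( 60 % of B )
res$partition
#> ModulatorPartition: |A| = 8 |B| = 8
#>   A-only 8 ( 100 % of A ) | shared 0 | B-only 8 ( 100 % of B )
res$concordance
#>   subset nModulators nFound percentage
#> 1      A           8      8        100
#> 2      B           8      8        100
res$subA$merged[[1]]
#> Subnetwork: k = 48 | zA = 21.75 | s = 6.705 (connected)
```

Reading: subset A called 58 DE genes of which 66% were subset-specific
(38 A-only against 20 shared) — the Venn partition of the two DE lists.
All 8 planted modulators of each subset were recovered as DE first-order
interactors of the core molecules, none shared between subsets, and every
one of them reappeared in that subset's unbiased active subnetwork
(100% concordance).  The top module of subset A is a connected
48-node subnetwork whose aggregate score sits 6.7 calibrated standard
deviations above random node sets of its size.
`writeReportBundle(res, dir)` writes the JSON/TSV/GraphML report.

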