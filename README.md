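# mirclubs

MicroRNAs regulate gene expression by each repressing hundreds to
thousands of mRNA targets, and many genes are targeted by dozens of
miRNAs. When two miRNAs share a large part of their predicted targets
they are candidates for complementary regulation of the same pathways —
a relationship invisible to sequence or expression similarity alone.
`mirclubs` is for computational biologists who want to mine genome-wide
miRNA→target prediction tables (DIANA-microT-style, TargetScan-style, or
any two-column table) for this co-targeting structure.

## What it computes

Given the target sets *A*, *B* of two miRNAs, their similarity is the
meet/min (Simpson) index

```
mm(A, B) = |A ∩ B| / min(|A|, |B|)   ∈ [0, 1]
```

The package builds the complete weighted miRNA graph of pairwise meet/min
values, sweeps graph properties (density, transitivity, Freeman
centralization, assortativity, path metrics) over candidate thresholds,
and binarizes at a chosen threshold τ (default 0.5: an edge iff two miRNAs
share at least half of the smaller target set). In the binary network it
then:

* detects **assorted clubs** — densely interconnected groups among the
  top-degree hubs (a relaxation of a rich club, internal density ≥ 0.8 by
  default rather than 1) — via a deterministic scan of the degree ranking;
* partitions all remaining miRNAs into the clubs' **spheres of
  influence**, an intermediate zone touching several clubs, and
  unassigned/isolated nodes;
* characterizes each club by **consensus target sets** (genes targeted by
  ≥ a fraction of members), broadly-targeted **gene hubs** (above the
  99th quantile of per-gene targeting counts), one-sided Fisher
  **hub-overlap tests**, and classic Fisher **GO enrichment** with
  Benjamini–Hochberg correction;
* quantifies **cross-database robustness** (per-miRNA target coverage,
  hub recovery, club density profiles) and overlays normalized
  **expression data** (log2 shift, quantile normalization, median-to-max
  node coloring, group log-fold-changes).

A seeded synthetic generator plants clubs, hub genes and expression
shifts with known truth, so the whole pipeline is testable offline.

## Worked example

```r
library(mirclubs)

sim <- generate_prediction_table(synthetic_config(seed = 42))
tm  <- sim$target_map
tm
#> target_map [synthetic(seed=42)]: 200 miRNAs, 2000 genes, 25328 interactions

bn <- threshold_network(build_weighted_network(tm), 0.5)
bn
#> binary_network: 200 nodes, 31 edges (threshold 0.5)

clubs <- detect_assorted_clubs(bn)
clubs
#> assorted_clubs: 2 club(s) among the top 11 hubs
#>   club 1: 8 members, density 1.00 (ranks 1-8)
#>   club 2: 3 members, density 1.00 (ranks 9-11)

table(partition_spheres(bn, clubs)$label)
#>    club1    club2 isolated
#>        8        3      189

hubs <- gene_hubs(tm)
hubs
#> gene_hub_set: 20 genes targeted by more than 26.87 miRNAs (q=0.99)

cons <- consensus_targets(tm, clubs$clubs[[1]]$members, 0.5)
cons
#> consensus_set: 318 genes shared by >= 4 of 8 miRNAs (fraction 0.50)

ht <- hub_overlap_test(cons$genes, hubs$genes, tm$universe)
ht$overlap; ht$p_value
#> [1] 18
#> [1] 3.890285e-13
```

Reading: the two planted clubs (8 and 3 miRNAs) are recovered exactly as
the top-11 degree hubs, each internally complete (density 1.00); the
background miRNAs share too few targets to pass τ = 0.5 and stay
isolated, so there are no sphere members in this clean simulation. All
20 planted hub genes sit above the 99th-quantile cutoff (26.87 miRNAs),
and the larger club's 318-gene consensus set contains 18 of the 20 gene
hubs where 3.2 would be expected by chance (one-sided Fisher
p ≈ 4 × 10⁻¹³) — broadly-targeted genes concentrate inside hub-club
consensus sets.

Real prediction flat files enter through
`read_prediction_table(path, dialect = "diana_v3" | "targetscan_v62" | "generic_tsv")`,
and `run_pipeline(pipeline_config(...))` executes the whole chain with
TSV/GraphML exports, a JSON run report and a log.
`inst/scripts/run_pipeline.R` is a thin command-line wrapper over the
same functions.

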