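# coexmod

Gene co-expression module mining and differential module analysis for
bulk transcriptomics, built around the questions raised by gene-fusion
subtypes of rhabdomyosarcoma: which groups of genes are co-expressed as
modules, and which of those modules shift expression between
fusion-negative tumours and tumours carrying a FOXO1–PAX3/7 fusion?

## What it does

- **Module mining (lmQCM).** A weighted network is built from absolute
  Spearman correlations between gene expression profiles. Edges that
  are locally maximal (no heavier edge at either endpoint) and of weight
  at least `γ` seed quasi-cliques; each seed grows greedily, admitting the gene
  `v` with the largest total weight to the cluster `C` while

  `density(C ∪ {v}) ≥ α_n · density(C)`, with `α_n = 1 − 1/(2λ(|C| + t))`,

  where `density(S)` is the mean pairwise edge weight of `S`. Clusters
  whose overlap ratio `|A ∩ B| / min(|A|, |B|)` exceeds `β` are merged.
  Unlike hierarchical module detection, genes may belong to several
  modules. Defaults: `γ = 0.7`, `λ = t = 1`, `β = 0.4`, minimum module
  size 10.
- **Differential module expression.** Each module is summarised by its
  first-principal-component sample scores (its eigengene); the
  inter-sample Euclidean distances of those scores are partitioned into
  between/within-group sums of squares and tested with a permutational
  ANOVA (pseudo-F, label permutations; exact enumeration on small
  designs). Direction (up/down) comes from group means of the per-sample
  module-mean expression.
- **Preprocessing.** Probe→gene collapse by element-wise maximum,
  removal of unmapped probes, and a bottom-third variance filter.
- **Set statistics.** Venn-region decomposition of module overlaps,
  multi-module gene lists, Fisher-exact over-representation against GMT
  collections with Benjamini–Hochberg control.
- **Copy number.** SEG segments → gene-level values by overlap-weighted
  averaging, calls at ±0.2 log2 ratio, and Fisher tests of module/CNV
  overlap.
- **Synthetic data.** A latent-factor generator plants correlated gene
  blocks with group shifts, probe multiplicity and CNV events, with the
  planted truth returned for validation.

## Worked example

```r
library(coexmod)

spec <- synthetic_spec()            # 25/26/7 samples, 2000 genes, 8 modules
sim  <- simulate_expression(spec, seed = 1)
ms   <- mine_modules(sim$expr)
ms
#> module_set: 8 modules (sizes 200, 150, 100, 60, 40, 25, 15, 10)

res <- diff_module_scan(sim$expr, ms, sim$annotation,
                        contrast = "neg_vs_pos", seed = 5)
res[, c("module_id", "gene_count", "pseudo_F", "p_value", "direction")]
#>   module_id gene_count   pseudo_F p_value direction
#> 1        M1        200 88.9565004   0.001        up
#> 2        M2        150 18.1025805   0.001      down
#> 3        M3        100 25.8916432   0.001        up
#> 4        M4         60 40.2345423   0.001      down
#> 5        M5         40 17.8466931   0.001        up
#> 6        M6         25 31.4571437   0.001      down
#> 7        M7         15 42.6447968   0.001        up
#> 8        M8         10  0.1066667   0.737      down
```

All eight planted modules are recovered exactly; the seven modules whose
latent factor was shifted between fusion-negative and fusion-positive
samples are flagged at p = 0.001 (the floor for 999 permutations), and
the null module M8 is not. `p_value` is the permutation p for the
module's eigengene distances against fusion status; `direction` is the
sign of the module-mean difference in the fusion-positive group.

Real data enter the same way: read a TSV or GEO series-matrix file with
`read_expression()`, collapse probes with `collapse_probes()`, filter
with `variance_filter()`, and pass a `sample_id`/`fusion_group`
annotation table. `run_pipeline()` drives the whole sequence from a
config list or YAML file and writes TSV outputs plus a manifest.

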