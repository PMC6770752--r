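---
title: "Mining and testing gene co-expression modules with coexmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and testing gene co-expression modules with coexmod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexmod)
```

## The problem

Tumour transcriptomes are shaped not only by which genes change
expression but by how genes move together. In rhabdomyosarcoma, the
FOXO1–PAX3/7 fusion protein is a potent aberrant transcription factor,
and a natural systems-level question is whether it restructures gene
co-expression: which correlated gene modules exist, and which of them
are expressed differently in fusion-positive versus fusion-negative
tumours, or between the PAX3- and PAX7-type fusions. `coexmod`
implements that analysis end to end for bulk expression matrices
(microarray intensities on the log2 scale, or any comparable
gene-by-sample matrix), together with the copy-number comparison that
often explains why co-expressed genes cluster on the same chromosome
arm.

## Preprocessing

Microarray input arrives at probe level. Probes without a gene symbol
are removed; multiple probes of one gene are collapsed by the
element-wise per-sample maximum (`collapse_probes()`), i.e. the gene's
value in each sample is the largest of its probes' values there. The
alternative of keeping the single probe with the highest mean is
available (`collapse = "max-mean-probe"`), but the element-wise rule is
the default because it uses all probes and is robust to a single probe
failing in a subset of samples.

Correlation mining needs variance to be meaningful, so the lowest-third
of genes by sample variance are removed (`variance_filter()`). The
filter is rank-based — exactly `floor(n/3)` genes are dropped, ties
broken by gene id — rather than thresholding at an interpolated
quantile, because rank removal is deterministic and convention-free
across platforms. Variance uses denominator `n - 1`; zero-variance
genes always fall in the dropped set. Filtering is done at gene level
(after collapsing), since the module analysis operates on genes.

## Module mining

`build_weight_network()` computes edge weights as absolute Spearman
correlations `|ρ|` between gene profiles. Rank correlation is robust to
the heavy tails and saturation of intensity data; the absolute value
makes anti-correlated genes strong partners, which suits modules driven
by a shared latent factor of either sign. Signed weights
(`absolute = FALSE`) and degree normalisation `w/√(d_i d_j)`
(`normalize_weights = TRUE`) are available but off by default.

The miner (`mine_modules()`) is the local maximum Quasi-Clique Merger
heuristic:

1. **Seeds** are edges with weight at least `γ` that are locally
   maximal: no edge incident to either endpoint is strictly heavier
   (`find_local_max_edges()`). Seeds are processed in weight order.
2. **Expansion** (`expand_quasi_clique()`) starts from the seed pair
   and repeatedly considers the outside gene with the largest summed
   weight to the cluster. The gene is admitted iff the density (mean
   pairwise weight) after addition is at least
   `α_n · density(C)` with `α_n = 1 − 1/(2λ(|C| + t))`. The threshold
   tightens as clusters grow, so early expansion is permissive and
   large clusters only accept genes that keep them dense. Expansion
   stops at the first rejection.
3. **Merging** (`merge_modules()`) discards clusters under 3 genes,
   then repeatedly merges any pair whose overlap ratio
   `|A ∩ B|/min(|A|,|B|)` exceeds `β`, largest clusters first, until no
   pair qualifies. Modules below `min_size` are dropped.

Defaults are `γ = 0.7` (the seed threshold that matters most in
practice; higher values yield fewer, tighter modules), `λ = 1`, `t = 1`,
`β = 0.4`, `min_size = 10` — the reference settings of the published
lmQCM method. The admission threshold formula and the overlap-ratio
merge criterion follow that reference implementation. Every tie —
seed order, candidate choice, merge scan order — is broken
lexicographically (radix/C-locale), so a given matrix and parameter set
always produce byte-identical module lists. Each mined module records
its accretion trace (gene added, density, threshold at each step),
which the test suite replays to confirm the admission rule was honoured,
and the miner is checked for exact equivalence against an independent
brute-force implementation on small random networks.

Genes may belong to several modules — the point of quasi-clique
merging over hierarchical clustering — and `module_overlap()` /
`genes_in_k_modules()` quantify that sharing.

A "consensus" analysis here means mining with all samples pooled
(negative and positive together), which finds structure common to the
cohort; mining each group separately and comparing module counts shows
how modular the two networks are. Pooling is the default reading
because it yields a single module set whose expression can then be
contrasted across groups.

## Differential module expression

`module_pc1()` summarises a module by the sample scores on the first
principal component of its (row-centred) member-gene submatrix — the
module eigengene. Only PC1 is used: it is the axis of greatest shared
variation and matches the latent-factor picture of a module; the SVD
sign is fixed so scores correlate non-negatively with the per-sample
mean module expression.

`permanova()` then tests whether the inter-sample distances of those
scores are structured by group. With squared Euclidean distances
`d²_ij`,

```
SS_total  = (1/n) Σ_{i<j} d²_ij
SS_within = Σ_g (1/n_g) Σ_{i<j ∈ g} d²_ij
pseudo-F  = (SS_between/(a−1)) / (SS_within/(n−a))
```

and the null distribution comes from permuting group labels. On 1-D
Euclidean data this pseudo-F equals the classical one-way ANOVA F
exactly, which the tests assert to 1e-10. When the number of distinct
label assignments is at most 10,000 the permutation distribution is
enumerated exhaustively (p = raw fraction of assignments at least as
extreme); otherwise 999 Monte-Carlo permutations are used with the
`(count + 1)/(n_perm + 1)` convention, so the smallest attainable p is
0.001. Vector input is canonicalised (sorted) before permuting, making
Monte-Carlo p-values invariant to sample order and group names.

`diff_module_scan()` applies this per module for a contrast —
fusion-negative vs pooled fusion-positive, or PAX3 vs PAX7 within the
positive samples — and reports direction from group means of the
per-sample module-mean expression, deliberately not from the PC1 sign,
which is arbitrary. Modules are called significant at raw p < 0.05 with
no cross-module correction by default (a Benjamini–Hochberg column is
available via `bh_adjust = TRUE`); the raw rule mirrors the
conventional reporting for this analysis, and the type-I error of the
whole scan is verified empirically in the test suite.

## Enrichment and copy number

`fisher_overlap()` tests 2×2 gene-set overlap with the exact Fisher
test, two-sided by default since both enrichment and depletion are
interpretable; `overrepresentation_scan()` runs a GMT collection
(cytoband sets, GO slims, custom sets) with BH control at FDR 0.05. The
universe defaults to the post-filter gene list that entered mining —
the set of genes that could have appeared in any module.

`gene_level_cnv()` converts segmented copy-number data (SEG, 1-based
inclusive) to per-gene values by overlap-length-weighted averaging of
segment log2 ratios over the gene interval (BED, 0-based half-open;
the reconciliation is `gene_start_1based = bed_start + 1`). A gene
fully inside one segment inherits its mean exactly. Calls use the
symmetric threshold: amplification at ≥ +0.2, deletion at ≤ −0.2,
neutral otherwise. The threshold sentence in common usage is sometimes
printed with both signs positive; only the symmetric reading is
self-consistent, and it is what the package implements.
`cnv_module_overlap()` asks, per module, whether genes carrying any
non-neutral call (in at least one sample) are over-represented among
the module's members.

## The synthetic generator

`simulate_expression()` draws from a single-factor-per-module latent
model: module m has one factor per sample,
`f_ms ~ N(μ_group, 1)` with `μ_group = δ_m` in fusion-positive groups
and 0 in negative; member genes are
`x_gs = baseline_g + a · f_ms + ε`, `ε ~ N(0, σ²)`; background genes
are baseline plus noise. This is exactly the structure the analysis
assumes — lmQCM looks for dense correlation blocks, PC1 estimates the
factor, and the group shift δ is what the permutational ANOVA should
detect — so planted-truth recovery is a sharp end-to-end test of the
pipeline, with δ in interpretable latent-sd units.

Default conditions mirror the study shape the package targets: 25
fusion-negative, 26 PAX3 and 7 PAX7 samples (58 total); 2,000 genes
(a desk-scale stand-in for the ~15,000 genes a filtered genome-wide
array yields, keeping a full mining run around two seconds); 8 disjoint
planted modules of sizes 200/150/100/60/40/25/15/10, spanning the
spread of reported module sizes with the largest capped at 200;
loading `a = 0.9` and noise `σ = 0.3`, giving within-module
correlations near 0.9 as seen in tight co-expression modules; and
latent shifts `δ = (+1.5, −1.5, +1.5, −1.5, +1.5, −1.5, +1.5, 0)` —
seven responsive modules (four up, three down, echoing that most
reported modules of this size were differential) and one null control.
A shift of 1.5 latent sd between groups of 25 and 33 puts eigengene
power near 1, so failures indicate pipeline defects rather than power
limits, while the null module guards the other side. What the
generator does *not* emulate: probe cross-hybridisation, batch
effects, outlier samples, correlated module factors, or non-Gaussian
noise — so passing recovery tests demonstrates algorithmic
correctness, not robustness to real microarray artefacts.

`simulate_probes()` expands genes to probes such that the element-wise
max recovers the gene matrix exactly (one zero-offset probe per gene),
with unmapped probes emitted as extra decoys. `simulate_cnv()` emits
per-gene segments whose gene-level values land strictly inside
(±0.3, ±0.8) for planted events and (−0.1, +0.1) for background, so
round-tripping through SEG files reproduces planted calls with zero
errors; planted events recur in every simulated sample, as clonal
events do.

## Numerical and design choices

- All lexicographic operations use radix (C-locale) sorting; results do
  not depend on `LC_COLLATE`.
- Constant genes get zero network weight (with a warning) rather than
  NA propagation; a degenerate PERMANOVA (all observations identical)
  returns p = 1 with a warning instead of dividing by zero.
- Permutation-F comparisons use a 1e-12 slack so exact ties (including
  the identity permutation) count as extreme, keeping exhaustive
  p-values exact.
- Odds ratios apply the Haldane 0.5 correction only when a cell is
  zero; p-values are never corrected this way (they come from the exact
  test).
- `diff_module_scan()` derives the permutation seed of module k as
  `seed + k`: reproducible, but modules do not share one permutation
  stream.
- Problem sizes in the test suite (2,000-gene replicates, 500 null
  replicates, 100 oracle networks) were chosen so the full suite runs
  in a few minutes on one CPU while leaving every statistical check
  adequately powered.

## Limitations

- The miner is dense-matrix: memory is O(genes²). Around 16k genes
  (a filtered genome-wide array) a run needs a few GB and minutes;
  beyond that a sparse implementation would be needed.
- The PERMANOVA has no strata or covariates; confounders (stage,
  tissue) must be handled by sample selection.
- GO/pathway enrichment is a plain Fisher scan over user-supplied GMT
  sets; no ontology propagation and no web services.
- Copy-number input must already be segmented; circular binary
  segmentation and peak calling are upstream of this package.
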