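---
title: "Methods: comparative co-expression network analysis with hemonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative co-expression network analysis with hemonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Hematopoietic cancers (acute myeloid and lymphoblastic leukemias, multiple
myeloma) show a characteristic rewiring of their gene co-expression
networks (GCNs) relative to normal bone marrow: the strongest co-expression
moves *inside* chromosomes. In a cancer GCN most top-ranked edges connect
genes on the same chromosome ("cis" edges), the network fragments into
chromosome-dominated components, and dense clusters of co-expressed
pseudogenes appear that normal marrow networks lack. `hemonet` implements
the full comparative workflow — normalization, network inference, cis/trans
topology, persistent community detection, differential expression,
enrichment and the community-level expression trend — together with a
synthetic cohort generator that plants exactly this architecture, so every
stage can be validated against known ground truth.

## Pre-processing

`preprocess_counts()` operates on the *joint* cancer + control count
matrix, mirroring a paired study design in which each cancer cohort is
normalized together with the control cohort. Steps, in order:

1. **Low-count filtering** (`filter_low_expression()`). A gene is removed
   if it hits *any* rule: mean expression at or below the 0.25 quantile of
   gene means; zeros in a strict majority (> 50%) of samples; or mean
   expression strictly below 10 counts. The mean-10 rule is a strict
   inequality (a gene with mean exactly 10 survives). The quantile
   convention is type 7 (linear interpolation), configurable. Note that
   the quantile rule is *relative to its input*: re-applying the filter
   removes a further quartile. The two absolute rules are idempotent;
   `quantile_cut = 0` disables the relative rule when a stable composite
   is needed.
2. **GC and length correction** (`gc_length_correct()`). Genes are split
   into 10 equal-frequency bins by GC content and, within each sample,
   every bin's values are mapped onto the sample-wide empirical
   distribution at the bin's internal rank grid (type-7 quantiles at
   $(r-1)/(m-1)$). The procedure repeats with gene-length bins. It is a
   full-quantile correction: bin distributions are equalized exactly while
   within-bin rank order per sample is preserved, and with a single bin
   the map is the identity.
3. **Between-lane normalization** (`between_lane_quantile()`), a
   full-quantile normalization across samples (via limma), after which all
   sample distributions are identical.
4. **TMM scaling** (`tmm_size_factors()`, via edgeR). The factor reported
   per sample is the library size times the trimmed-mean-of-M-values
   factor, rescaled to geometric mean 1 — i.e. the effective divisor.
   Trim fractions default to 0.30 on M-values and 0.05 on A-values.

The exact ordering of the correction steps inside the cited normalization
family is not fully constrained; we fixed GC → length → between-lane → TMM
and expose each step separately. In place of a multivariate noise-reduction
stage we emit a PCA separation diagnostic (`pca_phenotype_diagnostic()`):
the between-phenotype share of variance on each leading component of
log-expression, so the analyst can audit phenotype mixing after
normalization.

## Co-expression inference

Two estimators are computed for all gene pairs:

- **Mutual information** (`mutual_information_matrix()`): plug-in MI in
  bits on equal-frequency discretized profiles, with
  $B = \max(2, \lfloor\sqrt{n}\rceil)$ bins by default. Equal-frequency
  binning with the plug-in estimator is a standard, testable choice for
  rank-based dependence at cohort scale; adaptive-partitioning variants
  add estimator variance without changing the downstream rank statistics
  this pipeline consumes. The all-pairs kernel is compiled (Rcpp); at the
  supported scale (up to a few thousand genes after filtering) the full
  score matrix fits comfortably in memory, so no blocked/streamed variant
  is provided. No data-processing-inequality pruning is applied — the
  pipeline thresholds by rank and p-value only.
- **Spearman correlation** (`spearman_matrix()`): Pearson correlation of
  average ranks. Both estimators are invariant to strictly monotone
  transforms of each profile. Constant genes are flagged and score zero.

Edges are ranked by absolute score (`rank_edges()`), with ties broken
lexicographically by gene ids so rankings are reproducible. The canonical
edge-list form (`gene_a < gene_b` within rows) makes cross-network set
operations exact.

**Permutation p-values.** Reaching $p < 10^{-5}$ per edge with per-pair
permutations is infeasible at desk scale, so `permutation_null()` builds a
*pooled* null: random gene pairs scored after permuting one profile's
sample order. The add-one rule $p = (1 + \#\{null \ge s\})/(1 + N)$
guarantees $p > 0$; a warning is recorded when the pooled null is too
small for the requested significance level. Both the number of
permutations and pairs per permutation are configurable.

## Topology statistics

- `cis_fraction_curve()` evaluates, over a grid of top-$k$ cutoffs, the
  fraction of the $k$ strongest edges whose genes share a chromosome
  label. The default grid is logarithmic from $10^4$ to
  $\min(10^7, E)$ with 30 points; synthetic-scale analyses use a 1e3–1e4
  grid. Chromosome labels are compared after normalization (leading
  `chr` stripped, X/Y/MT upper-cased); genes on unplaced scaffolds keep
  their scaffold label and are therefore never cis with placed genes.
- `ks_compare()` performs the two-sample Kolmogorov–Smirnov test on the
  two sets of cis-fraction values, $D = \sup|ECDF_a - ECDF_b|$, with the
  asymptotic Kolmogorov p-value (two-sided). The cis-fraction values
  across nested cutoffs are serially dependent, so the iid assumption of
  the test does not hold strictly; the result carries that caveat
  verbatim, and the reported p-value should be read as a descriptive
  index of curve separation.
- `biotype_pair_fractions()` counts unordered biotype-family pairs among
  the top-$k$ edges; pseudogene sub-biotypes coarsen to `pseudogene`,
  `IG_*` to `IG`, `TR_*` to `TR`.
- `component_spectrum()` reports connected-component sizes of the top-$k$
  graph with per-component chromosome purity (share of members on the
  modal chromosome).
- `intersect_networks()` takes the exact set intersection of the top-$k$
  edge sets (default $k = 100{,}000$, the strongest-interaction cutoff
  used for cross-phenotype comparison) of two or more networks.

## Persistent communities

`resolution_sweep()` runs Louvain modularity optimization at 20
resolutions log-spaced in $[0.25, 4]$ (bracketing the standard resolution
1 symmetrically; the sweep is configurable and the seed is re-applied
before each resolution so partitions are independent of sweep order).
`persistence_filter()` then matches communities of adjacent resolutions
one-to-one by Jaccard similarity (greedy, decreasing similarity, threshold
0.75), collapses maximal chains to a consensus representative (genes
present in at least half of the chain's snapshots — a deterministic,
order-independent choice), scores each chain by its length
(*persistence*), and drops chains shorter than 5. The Jaccard threshold
and persistence floor follow the published defaults of the
persistent-homology-inspired community detector this stage emulates; the
resolution range used by its desktop wrapper is not documented, so our
sweep range is an explicit assumption. Containment links connect every
retained pair whose member sets nest properly. Raising the persistence
floor can only shrink the set of retained communities.

## Differential expression, enrichment, trend

`nb_wald_de()` is a deliberately compact NB2 Wald test: median-of-ratios
size factors on the joint matrix; per-gene method-of-moments dispersion
$\hat\alpha = (s^2 - \bar x)/\bar x^2$ averaged over the two groups and
floored at $10^{-8}$; log2 fold change of normalized group means with a
0.5 pseudo-mean floor; delta-method standard error
$SE = \sqrt{(1/\mu_1 + \alpha)/n_1 + (1/\mu_0 + \alpha)/n_0}/\ln 2$; and a
normal two-sided p-value with Benjamini–Hochberg adjustment. Dispersion
shrinkage toward a trend, outlier filtering and independent filtering are
intentionally omitted: the downstream use is sign/threshold
classification, for which sign and approximate magnitude suffice. Under
the default synthetic conditions the planted $\log_2$FC = 2 is recovered
within ±0.2 and the null type-I error at $\alpha = 0.05$ sits near
nominal. Genes are classified `over`/`under` by fold-change sign,
restricted to adjusted p < 0.05 (others `unclassified`); the significance
restriction is an explicit assumption, configurable via `classify_padj`.

`hypergeom_enrich()` tests community/gene-set overlaps with the upper-tail
hypergeometric distribution against a fixed universe (by default, all
genes surviving pre-processing — the natural background), adjusting across
all (community, set) pairs with BH; a pair is *enriched* at adjusted
p < $10^{-10}$. Gene sets are flat GMT entries; no ontology DAG semantics
(term ancestry, redundancy trimming) are applied.

`de_trend()` computes, per community, the proportion of overexpressed
members minus the proportion of underexpressed members, a value in
$[-1, 1]$: +1 when every member tends to overexpression, −1 when every
member tends to underexpression, 0 when the proportions balance.
Unclassified members count in the denominator. `shared_bp_matrix()`
restricts to processes enriched in *every* phenotype and reports the
trend of the union of genes across the communities enriching each
process, per phenotype.

## The synthetic cohort generator

`generate_cohort()` draws counts through a Gaussian copula: each gene's
latent profile is standard normal; inside a planted module the latent
vectors share an exchangeable correlation $\rho$ (implemented as a common
per-sample factor, $z = \sqrt{\rho}\,f + \sqrt{1-\rho}\,\varepsilon$,
positive semidefinite by construction for $\rho \in [0, 1)$); the latent
values map through the NB quantile function at each gene's mean and
dispersion. This yields exact NB2 marginals
($\mathrm{var} = \mu + \alpha\mu^2$) with controllable rank correlation —
a direct multivariate NB has no standard construction. Exchangeable
within-module correlation keeps the planted truth a clean clique.
Baseline means are log-spaced across `nb_mean_range` in a fixed gene
order (no RNG), so control and cancer cohorts generated in separate calls
share baselines and differ only by the planted fold changes
($\mu \cdot 2^{\log_2 FC}$ in cancer mode).

The default study (`generate_study()`) fixes the conditions used
throughout the tests and the acceptance script: 2,000 genes on 10
chromosomes; biotypes 75% protein-coding, 15% pseudogene, 10% lncRNA
(apportioned by deterministic largest-remainder rounding); cancer mode
plants 8 chromosome-restricted 50-gene modules at latent correlation 0.8
plus one 50-gene pseudogene module mixing chromosomes; control mode
plants 8 trans-mixed modules; 100 samples per cohort; NB means in
[20, 500] with dispersion 0.1. The pseudogene module's genes are planted
as overexpressed ($\log_2$FC = +2), with a matched number of random
non-module genes split evenly between +2 and −2 so that planted effects
are balanced and median-of-ratios size factors remain unbiased (one-sided
planting would bias them and inflate the null error rate — a property of
composition bias, not of the estimator). No quantitative effect size is
reported for the real pseudogene cluster's co-expression; its latent
correlation simply reuses the module default and is echoed in the
generator config.

What the generator deliberately does **not** emulate: real library-size
distributions, batch effects, gene-level dispersion heterogeneity,
GC/length biases (means are independent of the annotation covariates) and
read-level noise. Passing tests therefore demonstrate correctness of the
statistics and recoverability of planted structure under clean NB
sampling — not robustness to every artifact of real RNA-Seq.

## Numerical choices and degenerate inputs

- Quantile operations use type 7 throughout, matching the most common
  default; configurable where exposed.
- Equal-frequency discretization breaks ties by order of appearance
  (`ties.method = "first"`); Spearman uses average ranks. A constant gene
  is undiscretizable and scores 0 against every partner, with the gene id
  flagged.
- Edge ranking breaks absolute-score ties lexicographically; Louvain
  tie-breaking is fixed by re-seeding before each resolution.
- `rank_edges(top_k = ...)` larger than the number of pairs returns all
  pairs with a warning; empty graphs, empty communities, empty universes
  and all-zero samples/genes raise located errors.
- All randomness flows through explicit integer seeds; the full pipeline
  is byte-identical across reruns with the same seed.

## Problem sizes

The default test and acceptance configurations run the complete pipeline
at 2,000 genes × 100–200 samples (about 2 million gene pairs per network),
with 20,000-edge ranked lists, 10,000-edge community graphs and pooled
nulls of 10^5 scores. These sizes exercise every code path at full
statistical strength while keeping a laptop-class runtime; all of them
scale up through the exposed parameters.

## Known limitations

- The pooled permutation null assumes exchangeability across pairs; it
  calibrates the bulk of the p-value distribution but cannot give
  per-edge exactness.
- The KS comparison of cis-fraction curves inherits the serial dependence
  caveat above.
- The simplified NB Wald test trades DESeq2's shrinkage machinery for
  transparency; at very small group sizes (< 20 per group) its type-I
  control degrades and a full DE package should be preferred.
- Community detection is Louvain-only; the persistence filter is not a
  port of the original multi-algorithm ensemble tool.
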