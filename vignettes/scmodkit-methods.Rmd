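---
title: "Methods: droplet QC, whitened co-expression modules and hexagonal spatial binning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: droplet QC, whitened co-expression modules and hexagonal spatial binning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

scmodkit implements the bespoke computational steps of a single-nuclei plus
spatial transcriptomics workflow for solid tissue (the motivating system is
the human right atrium): quality-space droplet filtering, a deterministic
expression-processing chain, gene co-expression module discovery on whitened
correlation graphs, and hexagonal pseudo-spot binning of single-molecule
spatial data. Every stage can be exercised on seeded synthetic data with
planted ground truth; the `analysis/` scripts in the source repository run
the whole chain and write their tables under `results/`.

## Droplet quality space

Single-nuclei preparations of solid tissue contain, besides intact nuclei,
empty droplets filled with cell-free cytoplasmic RNA and nuclei carrying a
large ambient admixture. Because ambient RNA is cytoplasmic, it is mostly
spliced, carries little signal for nuclear-enriched genes, and (in cardiac
tissue especially) is rich in mitochondrial transcripts. `compute_qc_metrics()`
summarises each droplet by its splicing fraction (spliced / total counts),
mitochondrial fraction, and binned-control enrichment scores for a
nuclear-enriched gene set, a cardiomyocyte marker set and every
non-cardiomyocyte marker set. `cluster_quality_space()` standardises these
metrics and partitions droplets by k-means (default `k = 4`, 25 restarts,
seeded); k-means is our choice of unsupervised clustering for this space —
it is low-dimensional and the populations form convex blobs.

`flag_contaminated_clusters()` applies two rules to the cluster means: a
cluster is proposed *empty* when its mean splicing fraction exceeds
`splicing_max` (default 0.7) while its mean nuclear score lies below the
`nuclear_quantile` (default 0.5) quantile of cluster means, and
*contaminated* when its mean mitochondrial fraction exceeds `mito_max`
(default 0.3); the empty rule wins when both fire. These defaults are this
package's choices — the upstream tool we emulate does not publish its exact
rule — and all are configurable. `sample_outlier_filter()` then drops, within
each sample, droplets more than `n_mads = 4` scaled MADs (1.4826x) above the
sample median of the splicing or mitochondrial fraction; the filter is
one-sided because only high values indicate contamination, and a zero MAD
degenerates to "strictly above the median". "Splicing fraction" here means
the *spliced* share of counts; the convention is switchable by swapping the
layers.

## Expression chain

The processing chain is the standard one, with the stated defaults: genes
detected in fewer than 10 cells are removed; counts are normalised to
`ln(counts per 10,000 + 1)`; highly variable genes are selected by the
classic binned-dispersion recipe (back-transformed per-gene means and
variance/mean dispersions, `log1p`/`log` statistics, z-scored within 20
equal-frequency mean bins, window `0.0125 < mean < 3`, normalised dispersion
`>= 0.5`). Whether the mean statistic is taken on the `log1p` or raw scale is
switchable (`mean_scale`); `log1p` is the default. Equal-frequency bins keep
tied values together, and bins left with fewer than two genes are merged with
a neighbour so no gene is silently dropped. Per-cell covariates (total
counts, mitochondrial percentage) are regressed out gene-wise by OLS;
residuals are scaled to unit variance and clipped above at 10; PCA (default
40 components, deterministic sign: the largest-magnitude loading of each
component is positive) feeds an exact 10-nearest-neighbour graph (Euclidean,
ties to the lower cell index, union-symmetrised) and Leiden clustering at
resolution 1 with the RB-configuration objective. Batch integration and UMAP
are exposed as pass-through hooks (`batch_hook`) in the spot-processing
recipes — published external algorithms we deliberately do not re-implement —
so the stage order PCA → hook → kNN → clustering is preserved.

Marker ranking uses a two-sided Wilcoxon rank-sum test per gene (exact when
both groups have fewer than 25 cells and the data are tie-free, normal
approximation with tie correction otherwise), BH correction within cluster,
and truncation to the top 500 significant genes. The marker logFC is the
difference of mean log-normalised expression (cluster minus rest) — the
source analysis does not pin a scale, and this one is monotone in any
reasonable alternative. `score_gene_set()` follows the binned-control scheme:
25 equal-frequency expression bins, 50 control genes sampled per set gene
(seeded), score = mean over set genes minus mean over the pooled controls.
`annotate_clusters()` assigns each cluster the argmax reference score and
flags clusters scoring above the `high_quantile` (default 0.9) of per-cluster
scores for two or more types as doublet clusters.

## Co-expression modules from whitened correlations

This is the package's core algorithm. Cell-cell correlation structure
(clusters, gradients, batch) inflates gene-gene correlations and biases
module recovery. Let the column-centred expression matrix be
`X = U S V'` (cells x genes, thin SVD). `zca_gene_correlation()` forms

    M(P) = V S^P V',   C(P) = D^{-1/2} M(P) D^{-1/2},  D = diag(M(P))

for a whitening resolution `P` in `[0, 2]`. At `P = 0`, `C` equals the gene
correlation matrix of the explicitly ZCA-whitened data `(XX')^{-1/2} X`
(cell structure fully removed); at `P = 2` it is the ordinary Pearson matrix
(`X'X = V S^2 V'`); intermediate `P` interpolates. Singular values below
`1e-12` of the maximum are treated as zero (with `0^0 := 0`) so the numerical
null space is never amplified at `P = 0`. Note that when `X` has full column
rank — many more cells than genes — `C(0)` is exactly the identity: the
whitened layer then contributes no edges, and the information lives in the
intermediate resolutions. The default ensemble `P in {0, 0.5, 1}` is used by
`detect_modules()`.

`sparsity_zscore()` controls for the fact that sparse genes have unstable
correlation estimates: genes are binned into 10 equal-frequency strata of
their zero count in the *raw* matrix, and every correlation is z-scored
against the null location and scale of its (unordered) bin-pair stratum.
Stratification by bin pair rather than by single-gene margins is our choice.
The null parameters are estimated robustly — median and 1.4826xMAD of the
stratum's off-diagonal entries — because the co-expressed pairs the method
must find live in those same strata: with a plain mean/SD, a planted signal
occupying a few percent of pairs inflates the null scale enough to cap all
z-scores near the threshold, and the procedure cannot work at any sample
size. `threshold_graph()` keeps edges with `z > 4.5` (strict), retaining
isolated genes as nodes.

`multigraph_leiden()` finds modules on the ensemble of per-resolution graphs
by maximising the equally-weighted sum of per-layer RB-configuration
qualities at resolution 2 (the analysis default). The optimiser is a
multilevel local-moving scheme (move nodes greedily, aggregate communities,
repeat) followed by a refinement pass in the Leiden spirit: communities are
split into connected components of the multiplex union graph and the local
moving re-run, so every reported module is connected in at least one layer's
union. Node visiting order is the only randomness and is seeded;
`min_module_size = 2` because genuinely small modules (three genes) are
biologically meaningful in this setting. Modules are reported size-descending
with sorted gene lists; sub-threshold communities leave their genes
unassigned. On a single layer the optimiser agrees with igraph's Leiden
implementation, which the test suite uses as an independent oracle.

`score_modules()` reuses the binned-control scorer per module;
`enrich_modules()` annotates modules against user-supplied gene collections
(e.g. GWAS-prioritised lists) with a one-sided hypergeometric upper-tail
test over a stated universe and BH correction across all module x set pairs —
a local replacement for web enrichment services.

Whether module detection should see all filtered genes or only HVGs is left
to the caller (`X` is whatever matrix is passed); the analyses here use all
genes surviving the rare-gene filter, log-normalised and column-centred.

## Hexagonal pseudo-spots

`build_hex_grid()` lays out pointy-top hexagons; the "width" (default 80 px)
is the center-to-center horizontal spacing within a row, so rows are
`width * sqrt(3) / 2` apart and offset by half a width, and the hexagon size
is `width / sqrt(3)`. Width conventions differ between tools (flat-to-flat,
vertex-to-vertex, spacing); this one is documented and parameterised, and the
grid anchors at the bounding-box minimum corner and extends one hexagon
beyond it on every side. `assign_molecules()` maps each molecule to its
hexagon by fractional axial coordinates and cube rounding — equivalent to
nearest-center assignment, with exact boundary ties resolved by nearest
center then lowest hexagon index. Total counts are conserved exactly; empty
hexagons are dropped.

`process_resolve_spots()` implements the small-panel recipe: log1p *without*
library-size normalisation (with ~100-gene panels and few counts per spot,
per-spot rescaling creates artifacts), per-gene OLS regression on the
per-spot total count and detected-gene count, scaling (clip 10), PCA (15
components), kNN and seeded Leiden. Pseudo-spots with fewer than
`min_counts` (default 20) molecules are removed first — spots straddling a
tissue or domain boundary are partially covered and otherwise cluster by
coverage rather than composition. In the planted two-domain analysis we
filter at half the median spot total and cluster at resolution 0.25: two
territories are sought, so a coarse resolution matches the target
granularity (the source recipe leaves this resolution unstated; the
function default stays at 1). `process_visium_spots()` applies the
spot-platform recipe instead: normalise to 10,000 counts per spot, log1p,
HVG, regression (total counts, mitochondrial percentage), scale, PCA, kNN,
Leiden, plus per-spot marker-set scores. `quantify_gene_by_section()`
summarises one gene's per-spot log1p expression per section with the
1.5xIQR boxplot rule; sections whose panel lacks the gene are reported
missing, never as zero.

## Comparison statistics

`jaccard_index` (|A∩B|/|A∪B|; two empty sets give 0 with a warning),
`logfc_correlation` (Pearson over genes significant in both tables, or over
the union of either table's significant genes, pairwise-complete — the
union rule for "all DEGs" is our documented reading), `minmax_scale`
((v−min)/(max−min); constant input maps to zeros), and `boxplot_summary`
(type-7 linear-interpolation quantiles — the convention used everywhere in
this package — with outliers strictly beyond 1.5xIQR and whiskers at the
most extreme non-outliers). "Significant" defaults to BH FDR < 0.05.

## Synthetic data: what it emulates, and what it does not

`generate_droplet_dataset()` draws per-droplet totals from class-specific
negative binomials, gene counts from class profiles (multinomial), and
splits each gene's count into spliced/unspliced by a droplet-level Beta
draw. Nuclei default to a Beta(6,18) spliced fraction (mean 0.25, nuclear
transcripts are mostly unspliced), 30% nuclear-gene mass and 2%
mitochondrial mass; empty droplets use the ambient profile — an
abundance-weighted mixture of the cell-type profiles reweighted to 25%
mitochondrial and 4% nuclear mass — with Beta(27,3) splicing (mean 0.9);
contaminated nuclei mix their own profile 50/50 with ambient (Beta(12,8),
35% mitochondrial). The ambient composition is a stand-in: the real
ambient pool of any given tissue is unknown, and these weights are what make
the quality metrics separable. Default mixture: 60% nuclei across three cell
types, 30% empty, 10% contaminated, 2,000 droplets, 500 genes.

`generate_module_dataset()` plants a latent-factor model: module gene
`g` takes `loading * f_m + sqrt(1 - loading^2) * eps`, so two genes of one
module have population correlation `loading^2`. In counts mode the latent
value maps to a Poisson rate `exp(1 + value)` — an average retained gene at
roughly 4-5 counts per cell — and entries are thinned by Bernoulli dropout
to 50% zeros in expectation, the typical zero share of genes surviving the
rare-gene filter. Defaults: 5,000 cells, 200 genes, four 20-gene modules,
loading 0.8.

`generate_molecule_table()` places molecules uniformly within disc or
rectangle domains and draws genes from per-domain profiles;
`generate_de_comparison()` constructs paired DE tables with an exact
significant-set overlap and bivariate-normal shared logFCs.

What the generators deliberately do not model: doublets (an external mask is
accepted instead), batch effects (the integration hook is pass-through),
UMI collisions or read-level noise, within-domain spatial gradients, and
cell-type-specific library-size structure beyond the class negative
binomials. Passing tests therefore demonstrate that the implementations are
correct and calibrated under these idealised conditions — not that the
pipeline's thresholds are optimal for any particular real tissue.

## Numerical choices and problem sizes

Quantiles are type 7 everywhere. k-means uses 25 restarts; Leiden runs 10
iterations; all seeded stages restore the caller's RNG state. SVD null-space
tolerance is `1e-12` of the largest singular value; zero-variance genes scale
to zero; degenerate inputs (all-identical droplets, single-gene panels,
empty graphs) raise errors rather than guessing. The bundled analyses and
tests run at 2,000 droplets x 500 genes (QC), 5,000 cells x 200 genes
(modules; recovery at `z > 4.5` genuinely requires study-scale cell numbers,
since z grows with the square root of the cell count), and 10,000 molecules
per 1200x800 px section (spatial) — sizes chosen so the planted effects are
at the scale the methods are designed for while the whole suite runs in
about a minute.

## Known limitations

The multiplex optimiser is a greedy quality maximiser; like all
modularity-family methods it has a resolution floor and can split large
sparse modules (visible as extra small modules at marginal signal). The
empty/contaminated cluster rules assume the quality space separates the
populations — with `k` far from the number of real populations, mixed
clusters dilute the rule means. The hexbin assignment presumes planar
coordinates in a shared frame; no registration is attempted. The enrichment
test treats gene sets as unordered and ignores gene length or expression
biases.
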