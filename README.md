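# scmodkit

Tools for the bespoke computational steps of a single-nuclei + spatial
transcriptomics study of solid tissue (the motivating system is the human
right atrium), for analysts who need these stages reproducible and testable
outside a monolithic pipeline:

- **Droplet QC in a quality space.** Single-nuclei preparations contain
  empty droplets full of cytoplasmic ambient RNA and heavily contaminated
  nuclei. Per droplet we compute the splicing fraction (spliced/total
  counts), mitochondrial fraction, and binned-control enrichment scores for
  nuclear-enriched and cell-type marker sets, cluster droplets in the
  standardised metric space with k-means, flag empty clusters (high spliced
  fraction, low nuclear score) and contaminated clusters (high mitochondrial
  fraction), then apply per-sample median + 4×MAD outlier filters.
- **A deterministic expression chain.** Rare-gene filter (<10 cells),
  ln(CP10K + 1) normalisation, binned-dispersion HVG selection
  (0.0125 < mean < 3, normalised dispersion ≥ 0.5), per-gene OLS covariate
  regression, scaling (clip 10), PCA (40 PCs, sign-stable), exact 10-NN
  graph, seeded Leiden clustering (resolution 1), Wilcoxon + BH marker
  ranking (top 500 at FDR < 0.05), marker scoring and cluster annotation
  with doublet-cluster flags, per-sample proportions.
- **Co-expression modules from whitened correlations.** With the thin SVD
  `X = U S Vᵀ` of the centred expression matrix, the gene–gene association
  at whitening resolution `P` is `C(P) ∝ V S^P Vᵀ` — `P = 0` is the
  correlation of the ZCA-whitened data `(XXᵀ)^(−1/2)X` (cell–cell structure
  removed), `P = 2` the ordinary Pearson matrix. Correlations are z-scored
  within sparsity strata of the raw counts, thresholded at `z > 4.5`, and
  modules are found by multiplex Leiden-style clustering over the
  `P ∈ {0, 0.5, 1}` graph ensemble at resolution 2, with hypergeometric
  annotation against user-supplied (e.g. GWAS-prioritised) gene lists.
- **Hexagonal pseudo-spots for single-molecule spatial data.** Pointy-top
  hexagons of 80 px horizontal spacing tile the slide; molecules are
  assigned by axial cube rounding (exactly nearest-center); pseudo-spots are
  processed with the small-panel recipe (log1p without library-size
  normalisation, regression on per-spot totals and detected genes) or the
  spot-platform recipe (CP10K), and per-gene signal is summarised per
  section with 1.5×IQR boxplot statistics.
- **Seeded synthetic generators** with planted ground truth (droplet
  mixtures, factor-model gene modules, spatial expression territories,
  paired DE tables) so every stage is testable without any download.

## Worked example

The numbered drivers under `analysis/` run the whole chain on synthetic
data and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_droplet_qc.R
Rscript analysis/03_coexpression_modules.R
Rscript analysis/04_spatial_hexbin.R
Rscript analysis/05_comparisons.R
```

Output of a full run:

```
droplets: 2000 x 500 | class mix: contaminated 212 empty 587 nucleus_CM 714 nucleus_EC 196 nucleus_FB 291
module matrix: 5000 cells x 200 genes; 80 genes in modules
molecule tables: 2 sections x 10000 molecules on 1200x800 px
DE tables: expected Jaccard 0.5

retained 1194 / 2000 droplets
empty-droplet removal: precision 0.998, recall 0.947
removal reasons: contaminated_cluster 240  empty_cluster 557  kept 1194  sample_outlier 9

found 7 modules (sizes 20,20,15,14,6,5,2); ARI vs planted truth 0.958
edges per layer (P = 0, 0.5, 1): 0, 121, 205
top enrichment: module 3 overlap 9/22, p = 1.44e-06 (BH fdr 1.01e-05)

section S1: 94 occupied hexes; S2: 96
Resolve-style clustering: 70 spots, 2 clusters, ARI vs domains 1.000
ga1 per-spot log1p expression: S1 median 0.00 (q3 2.77), S2 median 0.00 (q3 2.79)
molecule map written: 10000 points

DEG Jaccard 0.500; logFC r (overlap) 0.900 over 1000 genes; (all) 0.615 over 2000
nucleus_CM proportion across samples: 55.8-63.1% (median 59.6%)
```

Reading the numbers: the QC step removes planted empty droplets with 0.998
precision and 0.947 recall against the generator's truth labels; module
detection recovers the four planted 20-gene modules (two exactly, two with a
few genes shed into small satellites) at adjusted Rand index 0.958, with the
`P = 0` layer empty as expected for a full-column-rank matrix; the
prioritised-list enrichment flags the module built from planted module 2
(9 of its genes overlap the 22-gene list, hypergeometric p = 1.4e-06); the
two planted spatial territories are recovered perfectly (ARI 1.0) after
excluding partially covered boundary hexes; and the paired DE tables
reproduce their constructed Jaccard (0.5) and shared-gene logFC correlation
(0.900 over the 1000 shared genes).

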