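# spotclone

Spatial mapping of genetic clones — and the spatial statistics around it —
for spot-based spatial transcriptomics (10x Visium-style hexagonal
lattices).

Tumours are mosaics of genetically distinct clones. When matched DNA
sequencing has identified two clones that differ in copy number over known
chromosome regions, their spatial arrangement can be read off a Visium
slide through the *dosage effect*: genes inside a gained region are, on
average, expressed proportionally to their copy number. `spotclone`
implements that inference and the downstream analyses it feeds: clone
territories, nuclear-morphology comparisons, FISH-style validation,
a spatial heterogeneity index, and tumour-microtube quantification. A
synthetic-data generator reproduces the statistical structure of all the
inputs, so every stage is testable without access to patient data.

Intended users: computational biologists analysing spatial transcriptomics
of genetically heterogeneous tumours, and anyone needing a tested,
self-contained implementation of the pieces (Potts segmentation, alpha-shape
territories, Moran's I screening, exact Mann-Whitney, hypergeometric
enrichment).

## The model

**Clone mapping.** Spots are clustered on the normalized expression of the
clone-informative gene set *G* (genes overlapping regions where the two
clones' copy numbers differ; at whole-chromosome resolution, all genes on
the differing chromosomes). The segmentation minimises a Potts-regularised
k-means objective by iterated conditional modes (ICM):

    E(l) = Σ_s ‖f_s − μ_{l(s)}‖² − β · Σ_{(s,t)∈E} 1[l(s) = l(t)]

with *E* the lattice adjacency (six hexagonal neighbours) and β > 0 the
smoothness weight, encoding that adjacent spots are more likely to belong
to the same cluster. With K = 2 clusters, the cluster with the higher mean
clone score `score(s) = mean_{g∈G} normalized(s, g)` is the gain clone A
(daughter clone); the other is the ancestral clone B. A non-spatial control
clustering (PCA → 15-NN graph → Leiden, forced to two communities) is run
on the same features and its concordance recorded.

**Clone geometry.** Per clone: largest connected component of its spots in
the adjacency graph, outlined by the alpha shape (Delaunay triangles with
circumradius ≤ 1/α). Nuclei are assigned to the clone whose territory
contains their centroid; nuclear areas are compared by a two-sided
Mann-Whitney test. FISH-style per-nucleus probe counts are compared between
clone areas the same way.

**Heterogeneity index.** A sample's transcriptional heterogeneity is the
number of segmentation clusters containing ≥ 5 spots divided by the number
of spots.

**Counts model (synthetic data).** `count(s,g) ~ NB(μ, θ)` with
`μ = L_s · β_g · ((1−c)·d_{clone(s),g} + c)`, lognormal spot factors `L_s`
and gene baselines `β_g`, dosage multiplier `d = CN/ploidy`, contamination
`c`, and `Var = μ + μ²/θ`.

## Worked example

```r
library(spotclone)

params <- sim_params(n_rows = 20, n_cols = 20, n_genes = 500, seed = 7)
truth  <- make_synthetic_truth(params, n_informative = 100)  # CN 4 vs 2

ds <- simulate_counts(truth) |>
  filter_spots(min_counts = 50, min_genes = 20) |>
  filter_genes(min_fraction = 0.1) |>
  normalize_log1p()

graph <- build_spot_graph(ds)
cm <- map_clones(ds, truth$annotation, truth$cnv_profiles, graph, seed = 1)
cm
#> <clone_map> 400 spots (A: 197, B: 203)
#>   informative genes used: 99
#>   concordance with non-spatial control: 0.9325

clone_accuracy(cm, setNames(truth$clone_field$clone, truth$clone_field$spot_id))
#> # A tibble: 1 × 2
#>   accuracy accuracy_best_pairing
#>      <dbl>                 <dbl>
#> 1    0.992                 0.992

terr    <- clone_territories(cm, graph)
nuclei  <- simulate_nuclei(truth$clone_field, density_per_mm2 = 1000, seed = 2)
compare_nuclear_area(assign_nuclei(nuclei, terr))
#> # A tibble: 1 × 7
#>   median_A median_B median_ratio       U p_two_sided   n_A   n_B
#>      <dbl>    <dbl>        <dbl>   <dbl>       <dbl> <int> <int>
#> 1     45.6     29.6         1.54 1562887   1.13e-177  1415  1361
```

The mapper recovers 99% of the spot labels from the dosage signal alone;
the simulated 1.5× nuclear-area contrast between clones is recovered from
the assigned nuclei (medians 45.6 vs 29.6 µm²). `autoplot(cm, graph)` draws
the clone map; `autoplot(cm$segmentation, graph)` the raw segmentation;
`plot_territories(terr, nuclei)` the alpha-shape outlines.

A thin command-line wrapper around the same functions ships in
`inst/cli/spotclone.R` (subcommands `simulate`, `map-clones`, `nuclei`,
`microtubes`, `full`).

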