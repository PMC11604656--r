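---
title: "Methods: clone mapping and spatial statistics in spotclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clone mapping and spatial statistics in spotclone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the design choices made where
the design was genuinely open.

## The inference problem

A tumour carrying two genetic clones that differ in copy number over known
chromosome regions leaves a transcriptional footprint on a spatial
transcriptomics slide: spots dominated by the gained clone express the
genes in the gained regions at a higher average level (the dosage effect).
`spotclone` turns that footprint into a per-spot clone map, then into
contiguous clone territories against which per-nucleus measurements
(segmentation-mask areas, FISH probe counts) can be compared.

Every spot is a mixture: of tumour cells from possibly more than one
clone, and of normal (dosage-neutral) cells. The method does not
deconvolve the mixture; it assigns each spot to the locally dominant
clone, relying on spatial smoothness to resolve ambiguous spots.

## Spatially smoothed segmentation

`segment_spatial()` minimises the Potts-regularised k-means objective

$$E(l) = \sum_s \lVert f_s - \mu_{l(s)} \rVert^2
        - \beta \sum_{(s,t) \in E} \mathbf 1[l(s) = l(t)]$$

over labelings $l$ into $K$ non-empty clusters, where $E$ is the spot
adjacency graph (edge iff centre distance ≤ 1.2 × the minimum spacing,
which captures the six hexagonal neighbours) and $\mu_k$ are cluster
means. Optimisation: seeded k-means initialisation, iterated conditional
modes (ICM) sweeps in fixed row-major spot order holding centroids fixed
within a sweep (current label retained on ties, so a sweep can never
increase the objective — asserted at run time), centroid recomputation
after each sweep, then an exact single-move polish in which the energy
change of relabelling one spot — including the induced centroid shift —
is evaluated in closed form:

$$\Delta_{a \to b}(s) = \tfrac{n_b}{n_b+1}\lVert f_s-\mu_b\rVert^2
  - \tfrac{n_a}{n_a-1}\lVert f_s-\mu_a\rVert^2
  - \beta\,(\#\text{nb}_b(s) - \#\text{nb}_a(s)).$$

Because both descents are greedy, the package runs `n_starts` k-means
starts plus `n_starts` seeded random-label starts and keeps the labelling
with the lowest final energy; everything is deterministic given `seed`.
ICM sweeps can empty a cluster; since a $K$-cluster segmentation is by
definition a partition into $K$ non-empty parts, empty clusters are
repaired deterministically by moving in the spot farthest from its
centroid.

**The smoothness weight β.** β is in squared-feature units (same units as
$\lVert f_s - \mu_k\rVert^2$). Its default is a quarter of the median
*decision margin* at initialisation — the difference between the squared
distances to the two nearest centroids. This scales the smoothing with the
between-cluster separation rather than with the noise level: it is strong
enough to flip isolated discordant spots (whose margins are small), but a
whole-sample collapse into one cluster would require the boundary bonus to
beat the separation itself, which this calibration prevents. A
noise-scaled β (a multiple of the median within-cluster squared residual)
was rejected as the default after it proved able to overwhelm weak dosage
signal and collapse K = 2 segmentations on small samples; the
heterogeneity pipeline (below) overrides it deliberately.

## Clone mapping

`map_clones()`:

1. *Informative genes*: genes whose annotated interval overlaps any region
   where the two clones' copy-number profiles differ (any-overlap rule;
   copy number outside listed intervals defaults to the ploidy). Only
   genes surviving QC are used — expression of filtered genes is
   unobservable.
2. *Segmentation*: `segment_spatial()` with K = 2 on the normalized
   expression restricted to those genes. Obtaining exactly two clusters is
   achieved by asking for exactly two, not by tuning a resolution.
3. *Polarity*: the clone score of a spot is its mean normalized expression
   over the informative genes; the cluster with the higher mean score is
   the gain clone A (the more recent daughter clone — the ancestral clone
   is mostly diploid at the informative loci). For loss regions set
   `invert_polarity = TRUE`. If the two cluster means agree within 1e-9
   the polarity is undecidable and the call errors rather than guessing.
4. *Control*: the same features are clustered without spatial information
   (PCA → 15-nearest-neighbour graph → Leiden modularity communities,
   resolution searched to give exactly two) and the label-permutation-
   invariant concordance is reported.

Scores use normalized (library-size-corrected, log1p) values, making the
polarity decision invariant to per-spot sequencing depth. Per-spot
confidence is reported as the margin between squared distances to the two
centroids, but is not thresholded.

## Clone territories and nuclear morphology

Per-spot labels are noisy, so territories are built as: largest connected
component of each clone's spots (ties broken toward the component holding
the lexicographically smallest spot id), outlined by the alpha shape —
Delaunay triangles kept iff circumradius ≤ 1/α, boundary = edges on
exactly one kept triangle, assembled into closed rings. α defaults to
1/(1.5 × spot spacing): triangles between lattice neighbours
(circumradius ≈ 0.58 × spacing) pass easily, triangles spanning holes
wider than about three spacings are removed. As α → 0 the convex hull is
recovered (tested against a convex-hull oracle). All boundary rings of the
component are kept — the even-odd containment rule then handles holes and
disconnected pieces uniformly. Degenerate inputs (collinear points, α too
large for any triangle) raise errors with diagnostics.

Nucleus centroids are assigned by point-in-polygon with boundary counted
as inside; a nucleus inside several territories (possible since opposite
hulls may overlap along their common boundary zone) is left unassigned
with a warning, as is a nucleus outside all hulls. Consequently a band of
nuclei near territory boundaries is deliberately excluded rather than
guessed; recovery tests therefore measure accuracy among *assigned*
nuclei. Areas are compared with a two-sided Mann-Whitney test plus
medians; FISH counts per probe likewise, with the empirical distribution
of 0/1/2/3/4+ signals tabulated per clone. Comparisons with fewer than two
nuclei per clone are flagged unreliable (`p = NA`) instead of being
computed.

## Heterogeneity index

The index is (number of segmentation clusters with ≥ 5 spots) / (number of
spots). The 5-spot floor removes spurious micro-clusters; the index is
invariant to cluster relabeling. The segmentation feeding it must not
split homogeneous tissue into arbitrarily many pieces, so
`sample_heterogeneity()` uses a dedicated recipe:

1. PCA of the normalized matrix (up to 30 components).
2. Keep components whose eigenvalue exceeds 1.5 × the median eigenvalue.
   For isotropic noise the eigenvalue spectrum is flat near its median, so
   the median estimates the noise floor and the retained components are
   those carrying regional signal; with $r$ true regions this retains
   about $r - 1$ components.
3. Estimate the within-region noise scale as the median squared residual
   of a k-means fit with $d + 1$ clusters ($d$ = retained components —
   the smallest region count consistent with $d$ signal dimensions), and
   set β to twice that scale. Here a *noise*-scaled β is correct: any
   split of a homogeneous region only fits noise, and the boundary
   penalty must beat that gain.
4. Segment with K = `het_k_max` (default 12) and count clusters of ≥ 5
   spots.

Comparisons between sample groups use a one-sided Mann-Whitney test on the
per-sample indices.

## Supporting statistics

- **Moran's I** (`morans_i()`), with row-normalized adjacency weights, is
  used to rank spatially variable genes. This replaces Gaussian-process
  spatially-variable-gene detection: both serve as a screening step that
  ranks genes whose expression varies smoothly across the tissue, and
  Moran's I is fully specified and desk-checkable (pair closed forms, and
  the permutation-null mean −1/(n−1), are tested).
- **Spatial variance fraction** (`spatial_variance_fraction()`): the share
  of a gene's variance attributable to the tissue's spatial makeup is
  computed as a region R² — one minus the ratio of pooled within-region to
  total sum of squares — rather than as a Gaussian-process variance
  decomposition, whose internals are not reproducible from a description.
  It lies in [0, 1], is affine-invariant, and is monotone in the same
  sense.
- **Mann-Whitney U** (`mann_whitney_u()`): exact by enumeration when
  n₁ + n₂ ≤ 16 without ties, otherwise normal approximation with midrank
  tie correction and continuity correction; the all-tied degenerate case
  returns p = 1.
- **Hypergeometric enrichment** (`hypergeometric_enrichment()`): upper
  tail P(X ≥ k) evaluated in log space, so tails far below double
  precision survive (used for signature enrichment such as
  tumour-microtube gene sets; the universe is an explicit parameter since
  "all genes" vs "expressed genes" is an analysis choice).
- **Benjamini-Hochberg** (`bh_adjust()`): textbook step-up, validated
  against an independent implementation.

These are exercised against brute-force oracles (full enumeration, pmf
summation, BFS, convex hull, exhaustive Potts search) in the test suite;
where an established R routine provides the computation it is used behind
the interface, and the oracle checks remain independent of it.

## The synthetic generator

What it emulates: a hexagonal offset lattice (100 µm spacing — the
standard Visium geometry); a two-clone spatial field (half-split, or
thresholded Gaussian-smoothed noise for curved boundaries); negative
binomial counts with mean $L_s\,\beta_g\,((1-c)\,d_{clone(s),g} + c)$ and
variance $\mu + \mu^2/\theta$; nuclei as a per-spot Poisson process with
clone-dependent lognormal areas; FISH counts as Binomial(CN, efficiency) +
Poisson(false positives); fixed-size 400 × 400 µm structure crops for
microtube quantification. Dosage is linear in copy number over ploidy —
the simplest defensible calibration, since no quantitative
dosage-to-expression curve is established; contamination mixes means
rather than whole counts, keeping the clone contrast analytic:
the expected informative-gene ratio is $((1-c)d + c)$ against a diploid
ancestor. Each generator consumes one explicitly seeded RNG stream
(`withr::with_seed`), so outputs are bit-reproducible and global RNG state
is untouched.

Default study conditions: 40 × 40 lattice, 2000 genes of which 200 are
informative at copy number 4 vs 2, contamination 0.2, θ = 2, library-size
log-sd 0.3, gene log-sd 1, baseline mean 0.5. For the multi-region
heterogeneity experiments: Voronoi partitions of a 14 × 14 lattice into
2/4/8 regions, 200 genes at baseline mean 2 (a realistic per-spot depth of
a few hundred UMIs over a 200-gene panel), per-region lognormal gene
multipliers with log-sd 0.5. Test and acceptance problem sizes (10 seeds
for recovery, 10 replicate 5-vs-5 experiments, 200 null simulations, ~2000
nuclei per clone for the power check) were chosen as the smallest sizes at
which the Monte-Carlo error is clearly below the margins being tested.

What it does **not** emulate — and what passing tests therefore do not
show: sequencing-depth spatial artefacts, cell-type composition gradients
within a clone, segmentation errors upstream of the nucleus table,
spot-swapping/bleed, more than two clones, or real histology. Results on
synthetic data bound the method's behaviour under its own assumptions,
not its accuracy on tissue.

## Numerical and interface choices

- "Less than" thresholds from the QC rules are implemented strictly:
  a gene detected in exactly 10% of spots (or exactly 10 spots) is kept.
- Cell areas are kept at ≥ 10 µm², microtube areas strictly > 2 µm²,
  exactly as the filters are stated; filtering is idempotent.
- Microtube area per cell aggregates crops by their mean by default;
  pooling structures across crops is exposed as `aggregate = "pool"`
  since either reading of "per sample" is defensible.
- Group comparisons of per-sample microtube values use pairwise Welch
  t-tests with BH correction rather than a Dunnett-corrected ANOVA; the
  multivariate-t machinery Dunnett requires is out of proportion for this
  package, and pairwise Welch + FDR answers the same question.
- Genomic intervals are 0-based half-open throughout; MatrixMarket files
  are written with the `coordinate integer general` header and read with
  1-based indices converted internally.
- Spot/gene order never changes silently; permutation invariance of the
  clone map is tested.
- The non-spatial control's Leiden default resolution is 0.1, at which
  clearly separated point clouds form single communities on sparse kNN
  graphs; when a fixed community count is required the resolution is
  searched and, failing an exact hit, communities are merged by
  hierarchical clustering of their centroids.

## Known limitations

Two clones only (the label field and polarity rule are binary); expression
dosage is assumed linear and shared across informative genes; the
heterogeneity index counts clusters, not biological programs, and depends
on the segmentation scale parameters; the alpha-shape outline inherits the
lattice resolution (~one spot spacing); exact Mann-Whitney switches to the
approximation in the presence of any tie; nucleus assignment discards
boundary nuclei rather than modelling assignment uncertainty.
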