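---
title: "Methods: spatial analysis of airway-wall niches and inflammatory hubs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial analysis of airway-wall niches and inflammatory hubs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`airwayhubs` analyzes imaging-based single-cell spatial transcriptomics of
the human airway wall together with bulk-spatial (GeoMx-style) region
profiles. The pipeline covers: transcript/cell quality control and count
matrices; niche annotation from hand-drawn region polygons; dot-plot
expression statistics with rank-based and ANOVA comparisons; nearest-neighbor
distance statistics between cell clusters; detection of proinflammatory
transcript-density hubs; ROI processing (limit of quantification, target
filtering, upper-quartile normalization, signature enrichment); and spatial
drug-to-cell target scoring. A synthetic tissue generator with a recorded
ground truth closes the loop: every estimator in the package is exercised
against data whose true parameters are known.

Cluster labels are inputs throughout: the package neither clusters nor embeds
cells, and it does not parse vendor binary bundles — the interface is the
plain per-cell and per-transcript CSV dialect.

# Quality control and count matrices

Each detected transcript carries a decoding quality value `qv`. Transcripts
with `qv < 20` are removed (the threshold value itself is kept; the removal is
strictly less-than), and cells left with no assigned transcript are then
dropped. QC is idempotent, and the QC report gives the median transcripts per
retained cell both before and after the transcript filter, since conventions
differ on which of the two a headline "median transcripts per cell" refers to.

The raw count matrix tallies retained transcripts per cell and gene.
Transcripts outside any segmented cell (the `UNASSIGNED` sentinel) never
enter the matrix but are kept for density maps, which reflect total detected
transcripts irrespective of assignment.

Expression *levels* are displayed on a normalized layer,
`log(1 + raw * m / total_cell)` with `m` the median per-cell total. This
median-library-size log transform was chosen deliberately over a
regression-based variance-stabilizing normalization: the normalized layer is
used only for displayed means, ranks and rank-based tests — every
expressing-cell *frequency* is computed on the raw layer by contract — so a
monotone per-cell rescaling is sufficient, keeps the package dependency-light,
and makes the invariants easy to state (normalization preserves within-cell
rank order; frequencies are normalization-invariant). The provenance flag on
the matrix records which normalization produced the layer.

# Niche regions

Niches (epithelial band, mucous gland, smooth-muscle band) arrive as named
simple polygons in GeoJSON, mirroring manual region selection on the vendor
browser. Membership is centroid-in-polygon, **boundary inclusive**, so cells
sitting exactly on a hand-drawn outline are never silently dropped. When
regions overlap, the first region in file order wins — a deterministic rule
standing in for selections that are drawn to avoid overlap but are not
guaranteed disjoint by the format. Regions with disrupted tissue are excluded
upstream by the user simply by not drawing them; no computable exclusion
criterion exists.

# Expression statistics

The dot-plot table reports, per cluster x condition x gene: the fraction of
cells with at least one raw transcript, the mean normalized expression, the
two-sided Mann-Whitney P of the cluster against all other clusters in the
same condition, and the Mann-Whitney P between the two conditions within the
cluster. Cells are pooled across donors within a condition, matching how the
dot plots alternate condition columns; per-donor aggregation can be performed
upstream by subsetting. No multiple-testing correction is applied by default
(significance calls are raw P < 0.05); Benjamini-Hochberg is available via
`p_adjust = "BH"`.

`compare_two_sided()` uses the exact Mann-Whitney distribution when both
groups have at most 8 observations and no ties occur, and the normal
approximation with tie correction otherwise. No continuity correction is
applied: identical multisets then give P = 1 exactly, which is the natural
reading of "no evidence of a shift". ANOVA designs use `aov` with Tukey's
HSD, or Dunnett comparisons against the reference level (via `multcomp`) for
the two-way region-by-pathology layout; the two-way post hoc model is
additive, which is the standard frame for Dunnett contrasts when interactions
are not themselves under test. Inputs with zero variance are flagged
degenerate and reported as P = 1 rather than NaN.

`top_k()` ranks genes by mean normalized expression with lexicographic tie
breaks; the `k = 5` output is the cluster's primary gene signature reused for
ROI enrichment. Percent changes follow
`(target - reference) / reference * 100`.

# Nearest-neighbor statistics

For a source cluster A and target cluster B, the per-cell shortest distance
is the Euclidean distance from each A cell to its nearest B cell (self
excluded when A = B). The implementation buckets target cells on a uniform
grid and searches expanding rings; the search is exact — a candidate found at
ring k bounds how many further rings must be scanned — and the test suite
verifies exact agreement with an O(n^2) distance-matrix oracle on randomized
instances. Nearest-neighbor ties need no resolution for distances (the
minimum is the minimum).

Distance repartitions are right-open histograms of the shortest distances up
to `d_max` (default 100 um, with 150 um as the wider display option — both
windows are in use in the field and both are supported), normalized by *all*
source cells, so the bin fractions sum to the fraction of cells within the
window. Neighbor counts within `R` (default 50 um) and the
positive-interaction rule (at least one A-B pair within `R`) complete the
profile. Condition comparisons are two-sided Mann-Whitney tests on the
per-cell shortest distances, reported with the sign of the median difference
so that contraction (disease cells closer together) appears as a negative
direction.

When niche labels are present the analyses accept a `niche` argument and run
within the niche; otherwise they run on the whole section. Donor sections
produced by the generator are spaced farther apart than any neighbor window,
so pooled statistics cannot cross sections.

# Inflammatory hub detection

Density maps are Gaussian-smoothed 2D histograms of the transcript positions
of a gene set (default gene sets: the chemokine panel and the alarmins TSLP
and IL-33). Defaults: 10 um bins and a 25 um kernel bandwidth — hubs penetrate
on the order of 50 um into the tissue, and half that penetration depth is a
natural smoothing scale. The kernel is normalized and truncated at 4
bandwidths, so total intensity equals the transcript count away from the map
edge (conservation within 1% for interior transcripts; edge bins lose mass to
truncation, which is accepted rather than renormalized).

Hubs are contiguous high-density areas. The threshold comes from a
permutation null: each of `n_perm` (default 200) permutations redraws the
gene-set transcript positions from the positions of *all* panel transcripts,
preserving the tissue's overall spatial density. The default threshold is the
`null_quantile` (default 0.99) of the **per-permutation maximum** bin
density. This family-wise choice is deliberate: a pointwise per-bin quantile
threshold leaves ~1% of bins above threshold in every dataset, and because
smoothing correlates neighboring bins those exceedances arrive as contiguous
blobs larger than any reasonable area floor — a uniformly scattered gene set
would then yield spurious hubs in most datasets. With the maximum-based
threshold a uniform gene set yields no hub in about `null_quantile` of
datasets, while a planted hub with a 5-fold density multiplier is recovered
with its footprint matching the planted disc (Jaccard >= 0.5, median ~0.64 in
the recovery simulations). The pointwise variant remains available as
`tau_type = "per_bin"` for exploratory, deliberately permissive maps.

Hubs are 8-connected components of suprathreshold bins with area of at least
`min_area` (default 500 um^2). Footprints are unions of grid bins; hub
membership of a cell is bin membership of its centroid, composition is the
per-cluster fraction of member cells, and detected hub count is
non-increasing in the threshold by construction.

# ROI (GeoMx-style) processing

Negative probes estimate background. The per-ROI limit of quantification is
`exp(mean(log(neg)) + k_sd * sd(log(neg)))` — `k_sd` (default 2) geometric
standard deviations above the geometric mean, computed in log space with the
sample (n-1) standard deviation, the standard DSP convention; an
arithmetic-space variant is available behind a flag. Probe counts of zero are
an error by default rather than silently pseudo-counted.

Target filtering removes negative probes from the target space and drops a
target only when it is below its ROI's LOQ in **every** ROI *and* its summed
raw reads fall under the raw floor (default 5,000). The conjunction is the
chosen reading of "consistently below the limit of quantification (<5,000 raw
reads)": the parenthetical glosses the LOQ criterion with a read floor, and
requiring both keeps targets that either criterion alone would defend. The
disjunctive reading is available via `rule = "or"`.

Q3 normalization scales each ROI by (geometric mean of all ROI upper
quartiles) / (its own upper quartile), with quartiles computed by linear
interpolation on the filtered target counts. The geometric-mean anchor is the
common DSP convention; any common anchor gives the same relative profiles.
After normalization all ROI upper quartiles are equal, so the operation is
idempotent.

Cell-type presence in an ROI is inferred by a rank-based single-sample
enrichment score of the cluster's top-5 gene signature: genes are ranked by
decreasing expression, signature genes advance a running sum proportionally
to their rank statistic raised to an exponent (default 0.25), other genes
retreat it uniformly, and the score integrates the running-sum deviation.
Both the exponent and the signature size are configurable; the score is
invariant under strictly monotone transforms of the profile, positive when
the signature occupies top ranks and negative at the bottom.

# Drug-to-cell scoring

A drug-target table (ChEMBL-derived; drug and target columns) is filtered to
the measured panel; drugs left without a measured target are dropped and
counted. Each cell's score for a drug is the mean expression of the drug's
target genes — exactly the gene's own value for single-target drugs, and
linear in the expression layer. The normalized layer is the default scoring
substrate, with `layer = "raw"` available where literal raw-expression
scoring is wanted; the choice is pinned in the call, not hidden in state.
Cluster summaries report the fraction of impacted cells (score above 0 by
default — "impacted" has no canonical definition, so the threshold is
exposed), the mean interaction strength, a two-sided rank-sum P of the
cluster against all other cells, and the per-cluster top-5 drugs by strength
with lexicographic tie breaks. Spatial projection joins scores with cell
centroids and rasterizes bin-mean scores on the same grid convention as the
density maps.

# The synthetic tissue generator

The generator emulates the statistical structure the analysis assumes, not
the tissue's biology:

* **Geometry.** Three stacked bands — epithelial (0-150 um), smooth muscle
  (150-250 um), mucous gland (250-450 um) — per donor section; donor sections
  are laid out side by side with a 200 um gap, like biopsies on a shared
  slide. Niche polygons must not overlap (shared edges are allowed).
* **Clusters.** 16 clusters with niche placement rules and multinomial
  abundance weights; realized proportions match the weights to within
  binomial error.
* **Expression.** Negative-binomial counts over a 339-gene panel
  (canonical airway markers plus filler probes), with per-cluster marker
  boosts, modest chemokine/alarmin rates in the stromal producer clusters,
  and a per-donor log-normal factor (sigma = 0.1) on gene means so per-donor
  summaries are non-degenerate. Baseline rates are free parameters — no
  per-cluster abundances or dispersions are published for the real tissue —
  and are set so the median per-cell total is of the order of 30 transcripts,
  matching the throughput of the imaging platform.
* **Hubs.** Hub centers are drawn inside a configured niche; inside a hub
  radius (default 40 um) the configured gene set's means are multiplied
  (default 5-fold).
* **Molecules.** Transcript positions are the cell centroid plus isotropic
  Gaussian jitter (sigma = 3 um); no molecule-level placement model is
  published, and jitter at sub-cell-diameter scale is the simplest mechanism
  that separates bin-level density from cell-level counts. Quality values are
  a two-component Gaussian mixture (high mode 35, low mode 12) with a
  configurable low fraction (default 0.05), giving a known fraction below the
  QC threshold. A configurable fraction of molecules (default 0.02) is left
  unassigned to any cell.
* **Condition effects.** Per-gene log2 fold changes by condition (disease
  defaults: chemokines and alarmins reduced, CXCL12 unchanged, CXCL17
  increased, MUC5B and APOD increased, CPA3 reduced) and a spatial
  contraction factor c in (0, 1]: disease-condition cell displacements are
  shrunk toward the nearest hub anchor by c (default 0.7). Contraction about
  an anchor scales all pairwise distances among cells sharing that anchor by
  exactly c, so it is the simplest mechanism that reproduces reduced
  shortest distances with a known target ratio.

Everything is drawn under a caller-supplied seed and equal (config, seed)
gives bit-identical outputs. The `synthetic_truth` record stores planted hub
anchors and radii, the fold-change matrix, the contraction factors and the
expected disease/reference median-distance ratio.

What the generator does **not** emulate: segmentation errors and doublets,
cell morphology (cells are points), image channels, spatial autocorrelation
of expression beyond hubs, and realistic panel-wide co-expression structure.
Passing the recovery tests therefore demonstrates that the estimators recover
planted parameters under the stated noise model — not that the defaults are
estimates of real airway tissue.

# Numerical conventions and problem sizes

* Coordinates are physical micrometres everywhere; y increases downward.
* Histogram bins and repartition bins are right-open; quantiles use linear
  interpolation (R type 7); geometric means require strictly positive input.
* Ties: gene rankings break lexicographically; identical pooled samples give
  P = 1.
* The recovery simulations used by the test suite and by
  `scripts/acceptance.R` run at the sizes stated in the respective checks:
  50 random neighbor toys up to 500 cells; 500 null replicates at n = 20/20
  for test calibration; 100 seeds for hub recovery (1,200 cells, one planted
  hub, 5-fold multiplier, 40 um radius), uniform-null calibration, distance
  contraction (2,000 cells per condition, c = 0.7), ROI target recovery, and
  drug knock-down detection (500 cells per condition, 80% target
  knock-down). These sizes give binomial standard errors of a few percent on
  the reported rates while keeping a full run in the minutes range on one
  core.

# Known limitations

* Distances are 2D; serial sections or 3D stacks are out of scope.
* The neighbor statistics assume cluster labels are correct; label noise
  propagates directly.
* Hub delineation depends on bandwidth and bin size; footprints are unions
  of grid bins, so sub-bin boundary precision is not meaningful.
* The enrichment score is a presence statistic, not a constrained-regression
  deconvolution; it does not estimate cell-type proportions.
* Drug scores measure target-gene expression, not pharmacology: binding,
  penetration and dosing are outside the model.
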