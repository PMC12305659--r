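---
title: "Bioactivity networking of Cell Painting profiles and LC-MS features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bioactivity networking of Cell Painting profiles and LC-MS features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpbionet)
```

## The problem

Complex natural-product extracts contain hundreds of metabolites, only a
few of which drive a biological effect. cpbionet links two untargeted
readouts of the same extract library — image-based morphological profiles
from the Cell Painting assay and aligned LC-MS feature tables — so that
individual mass-spectrometric features can be scored for how strongly and
how consistently they co-occur with a cellular phenotype. Features passing
both scores form a bipartite extract–feature network whose communities
point at candidate bioactive metabolites, which are then annotated by
molecular formula, adduct and mass accuracy.

The pipeline stages are:

1. **HistDiff normalization** — single-cell feature distributions per well
   are reduced to one signed score per feature against pooled vehicle
   controls.
2. **CP score and activity filter** — each sample's profile collapses to a
   phenotype-strength scalar; samples at or below the vehicle reference are
   removed.
3. **FCBF feature selection** — symmetrical-uncertainty based removal of
   invariant and redundant features.
4. **Hierarchical clustering with positive-control gating** — Spearman
   distance, Ward linkage, and a flat cut at the lowest height that keeps
   the positive-control replicates in one cluster.
5. **Bioactivity networking** — per-MS-feature activity and cluster
   scores, thresholded at (0.03, 0.5), bipartite graph, Louvain
   communities.
6. **Annotation** — monoisotopic mass, adduct m/z and ppm error against a
   compound database.

## The HistDiff score

For one treated well and one feature, lay a common grid of `n_bins`
equal-width bins over the pooled range of treated plus control values,
histogram both, smooth each histogram with a column-stochastic Gaussian
kernel over bins (`smooth` is the kernel SD in bins), and rescale to unit
mass, giving $h_{trt}$ and $h_{ctl}$. The score is

$$d \;=\; \operatorname{sign}\!\Big(\sum_b (h_{trt}(b)-h_{ctl}(b))\,s(b)\Big)
  \cdot \sum_b \big|h_{trt}(b)-h_{ctl}(b)\big|,$$

where $s(b) = +1$ for bins strictly above the control-median bin and $-1$
at or below it. The magnitude is the total histogram discrepancy
$2(1-\text{overlap})$, so identical distributions score exactly 0, a
distribution shifted entirely clear of the control scores exactly $\pm 2$,
and $|d| \le 2$ always. The sign encodes the direction of displacement
relative to the control median — the increasing/decreasing semantics used
when the profiles are drawn as a diverging heatmap. A purely symmetric
spread change has no net displacement and scores near 0; this is a
deliberate property of a *signed* summary, not an oversight.

Degenerate inputs: a feature constant in both pools scores 0 with a
notice; an empty treated table is an error naming the well. Scores are
invariant to a common affine rescaling of both pools because the grid is
recomputed from the data.

Defaults: `n_bins = 32` (fine enough to resolve a 3-SD shift at a few
hundred cells per well without starving bins), `smooth = 1` bin
(suppresses sampling jitter; set 0 to reproduce closed-form cases
exactly).

## CP score and the activity filter

The per-sample phenotype strength is the Euclidean norm
$\sqrt{\sum_j d_j^2}$ over all features. One source section of the
protocol this package models describes the plain sum of squares; the more
detailed description uses the square root, which we take as the default
(`cp_score(..., sqrt = FALSE)` gives the other reading). The activity
filter removes every sample whose CP score is at or below the vehicle
reference — *at or below*, so a sample exactly at the reference is
removed. The reference statistic is the maximum of the vehicle CP scores
by default (conservative; `median` and an upper `quantile` are available),
because the underlying protocol does not name the statistic. Vehicle
wells are scored leave-one-out against the pool of the remaining vehicle
wells and are never retained.

## Feature selection

Symmetrical uncertainty $SU(X,Y) = 2\,I(X;Y)/(H(X)+H(Y))$ is computed on
equal-frequency discretized values (5 bins by default; robust to the
heavy-tailed feature families the generator produces). FCBF ranks
features by SU with a binary active/inactive class label (the output of
the activity filter — the only label available in-pipeline), drops those
at or below the relevance threshold, and removes every feature whose SU
with an already-kept, higher-ranked feature is at least its SU with the
class. Ties break lexicographically by feature id so selection is
reproducible.

Two practical choices deserve attention:

* **Relevance threshold.** The default is a permutation null: the class
  labels are permuted, the maximum SU across features recorded, and the
  threshold set to the median of those maxima over 10 permutations
  (`fcbf_auto_threshold()`). This adapts to the finite-sample SU bias,
  which grows with the number of discretization cells and shrinks with
  sample count.
* **Padding.** Under a *binary* class label, all class-responsive features
  are mutually redundant in FCBF's sense, and the predominance rule can
  legitimately collapse hundreds of informative features onto one or two.
  Downstream fingerprint geometry (Spearman clustering, Pearson cluster
  scores) needs dimensionality, so the pipeline pads the FCBF output back
  to `min_fingerprint_features` (default 20) with the next most relevant
  features by SU. The pure FCBF result is preserved in the
  `selected_fcbf` column of `feature_selection.csv`; `fcbf()` itself is
  unmodified and matches the definition-based enumeration oracle in the
  tests.

## Clustering and gating

Fingerprints are clustered with the distance $1-\rho_s$ (Spearman) and
Ward linkage. Ward is formally defined for Euclidean distances; we apply
the generalized Lance–Williams update (`hclust`, `ward.D2`) directly to
the correlation distance matrix, which is common practice for profile
data and is documented here explicitly. Constant fingerprints have
undefined rank correlations; their distances are set to 1 with a notice.

"Gating by contiguous clustering of the positive control" is
operationalized as the *lowest* cut height at which all positive-control
replicates fall into one flat cluster — the unique parameter-free reading
that guarantees contiguity. The tests verify minimality by scanning every
merge height. Gating is idempotent, and the flat cluster count is
monotone non-increasing in the cut height.

## Bioactivity scores and the network

Extract fingerprints for networking are the absolute HistDiff values of
the selected features, min–max scaled to $[0,1]$ per feature across the
profiled extracts. For a feature $f$ detected in extracts $E_f$
(intensity strictly above `min_intensity`, default 0):

* **activity score** $= \operatorname{mean}_{e \in E_f}
  \operatorname{mean}_j a_{ej}^2 \in [0,1]$. The protocol phrase "sum of
  the mean of the squares" is grammatically ambiguous; the mean-over-
  extracts reading keeps the score in $[0,1]$, dimensionally consistent
  with the 0.03 inclusion threshold, and the literal sum is available via
  `aggregate = "sum"`.
* **cluster score** $=$ mean Pearson correlation over all unordered pairs
  of $E_f$, in $[-1,1]$. A single-extract feature scores 1 by convention
  (no pair contradicts consistency; configurable via `singleton_score`);
  a pair involving a constant fingerprint contributes 0 with a notice.

Features with activity $\ge 0.03$ and cluster score $\ge 0.5$ — the
published operating point: a low strength bar that only has to clear
background noise, and a high consistency bar — enter the bipartite
network; isolated extracts are dropped. Communities are found by Louvain
modularity optimization under a fixed seed.

## Annotation

Monoisotopic masses use C = 12 exactly, H = 1.00782503, N = 14.0030740,
O = 15.9949146, Na = 22.9897693 (plus S, P, K, Cl, F, Br, I, Si). Adduct
names of the form `[M+H]+`, `[M+Na]+`, `[M+H-H2O-CH2O]+` are parsed into
signed formula gains/losses. The electron mass is *not* subtracted by
default: the printed reference values this package reproduces follow that
vendor convention (the 4.3 ppm check value only reproduces without
electron correction); `electron_correction = TRUE` restores the strict
physical m/z, shifting singly charged ions by ~0.5 mDa. Annotation
enumerates all (feature, compound, adduct) triples within `tol_ppm`,
ranked by |ppm|, and exports ppm at one decimal place to mirror the
reference table. One compound in the bundled reference CSV
(`3-Acetyl-8-ole-benzoylaconine`, C52H79NO12) is internally inconsistent —
its printed adduct m/z is ~12 Da above what the printed formula allows
(one CH2 short of a C53 reading that would reconcile it) — and is kept as printed rather than silently
corrected; it is excluded from acceptance checks.

## The synthetic world

The generator emulates the screening campaign at desk scale and carries
its ground truth so recovery is testable without any download.

* **Plate**: the full 384-well layout — rows A, B, O, P and columns 1 and
  24 vehicle (edge buffering), columns 2 and 23 twelve-point 2-fold
  positive-control dilutions, remaining wells 4-point 2-fold sample
  series. By default ~94 wells are populated (16 vehicle, top 3 doses of
  each positive control, 18 treatments × 4 doses) with 200 raw features
  and Poisson(300) cells per well — scaled down from the campaign's
  2,090 features × 6,088 samples for desk-scale testing.
* **Cell-level features**: independent location-scale families, 60%
  Gaussian, 20% shifted-lognormal, 20% scaled-t (df 5), so HistDiff is
  exercised on non-Gaussian shapes.
* **Phenotypes**: 8 of 18 treatments are active, grouped into 2 MOA
  classes of 4 extracts sharing an effect vector (±3 SD at saturation on
  20 random features) scaled by a per-extract potency in [0.8, 1.25].
  Four related extracts per class mirrors the community sizes observed in
  the study this models. The concentration response is
  $s(c) = c/(c+ec_{50})$ with $ec_{50} = 300$ µg/mL: with a 200 µg/mL top
  dose this reproduces the observed ~1.6× drop in CP score per 2-fold
  dilution of the most active extract, and makes the lowest doses
  near-inactive — matching the observed fragmentation of clusters across
  test concentrations.
* **MS features**: 120 aligned features with rt in [0, 11] min and m/z in
  [50, 1500]. Eight planted markers per MOA class are present in exactly
  the extracts of that class; background features occupy 4 extracts drawn
  uniformly; every absent cell flips to a false presence with probability
  0.01 (a realistic residual misalignment rate for peak-filtered,
  aligned tables). Intensities are log-normal where present.
* **Reference library**: fingerprints drawn around per-class centroids
  with within-class noise 0.3, plus tight positive-control replicates for
  gating tests.

What the generator does **not** emulate: microscope images and
segmentation (cell×feature tables are the input contract), retention-time
alignment drift, ion mobility, batch effects, plate-edge gradients, or
correlated feature blocks. A green end-to-end test therefore establishes
that the statistical machinery recovers planted co-occurrence structure
at realistic noise levels — not that it would survive uncorrected batch
structure in raw screening data.

## Determinism and numerical notes

Every generator derives per-well or per-stream seeds from the master
seed, so a well's content does not depend on which other wells are
requested, and identical configs give byte-identical CSV outputs
(checked by md5 in the tests). Oracle comparisons use 1e-12 tolerances
for closed-form quantities; statistical assertions (KS
indistinguishability, recovery rates, clustering purity) run under fixed
seeds at the sizes stated above. The run manifest records the package
version, seed, full config, a config hash and per-file checksums.

## Known limitations

* The binary activity label makes FCBF collapse aggressively; the
  padding default trades selector purity for fingerprint dimensionality
  (see above) and its size is a tunable, not an inference.
* Cluster scores of features carried by extracts with weak phenotypes are
  dominated by fingerprint noise; the 0.5 threshold is doing real work
  and should not be lowered casually.
* Annotation is MS1-only (exact mass + adduct); fragmentation evidence,
  isotope patterns and collision cross-sections are out of scope.
* Ward on a correlation distance is a pragmatic convention, not a
  variance decomposition.
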