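---
title: "Measuring phyllotaxy from voxel-carved reconstructions: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring phyllotaxy from voxel-carved reconstructions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyllo3d)
```

## The trait and the measurement model

Phyllotaxy is the azimuthal arrangement of leaves around the stem. Grasses
such as sorghum and maize are conventionally modeled as perfectly
alternating: each leaf emerges 180 degrees from its predecessor. This
package measures how real (or simulated) plants deviate from that ideal.

Each leaf `i` carries an azimuth `phi_i` in the stem's coordinate frame;
the phyllotaxic angle between successive leaves is

    phi_i = (azimuth[i+1] - azimuth[i]) mod 360,

normalized into `[0, 360)`, and its deviation from alternation is
`Phi_i = |phi_i - 180|`. Because the value reported for a leaf pair depends
on which side of the plant measurement starts from, each angle has a
*conjugate* `360 - phi` describing the same pair seen from the other side;
`align_pair()` resolves this ambiguity between two measurement series by
the sign of their Pearson correlation (non-negative: same side, leave as
is; negative: conjugate one series elementwise).

The measurement chain is:

1. **Silhouettes.** Binary masks from five turntable side views at 0, 72,
   144, 216 and 288 degrees plus a top view, with known calibration.
2. **Visual hull.** `carve()` keeps a voxel iff its center projects into
   the foreground of every view. The hull is a superset of the true plant;
   it can add material (webbing between limbs) but never remove it.
3. **Skeleton.** `thin()` applies sequential topology-preserving curve
   thinning (simple-point deletion under 26/6 connectivity, six fixed
   border-direction sub-iterations, endpoints retained), `join_gaps()`
   bridges disconnected fragments, `break_small_cycles()` removes
   small reconstruction handles, and `prune_spurious()` deletes branches a
   classifier labels as noise. A valid single-shoot skeleton must be a
   tree; `is_tree()` gates downstream analysis.
4. **Organs.** `segment_plant()` labels a node as stem when it lies on more
   than two of the root-to-tip tree paths, orders the remaining leaf
   segments by attachment height, and `measure_phyllotaxy()` expresses
   each leaf's direction in the stem's PCA frame.
5. **Reliability and genetics.** Range filters, conjugate alignment and
   pooled squared correlations quantify repeatability; deviations feed
   per-plant summary metrics, a one-way random-effects model for
   broad-sense heritability, and a resampling (RMIP) association scan.

Reconstructions are scored by reprojecting the hull into every view and
comparing with the input masks via the Dice coefficient
`2|A∩B|/(|A|+|B|)`; the aggregate score is the unweighted mean over views
(a pixel-pooled variant is available, since either reading of a single
"accuracy score" is defensible). Reconstructions below 0.70 aggregate
Dice, or without tree topology, are rejected; the 0.70 boundary itself is
kept, because the removal rule acts strictly below the threshold.

## The synthetic plant generator

Real images are replaced by a procedural generator whose ground truth
makes every stage verifiable. A plant is a vertical stem capsule with
leaves attached at cumulative internode heights; each leaf rises at its
inclination and droops along a planar arc (total direction change
`leaf_droop * 180` degrees, capped at 165 degrees from vertical).

Defaults, chosen once for a sorghum-like habit at the vegetative stage:

| parameter | default | rationale |
|---|---|---|
| leaves per plant | 5–8 | lower-canopy counts at imaging age |
| internode length | 40–80 mm | pre-elongation internodes |
| inclination | 20–60 deg from the stem axis | typical emergence angles |
| deviation `Phi` | 0–60 deg | spans near-perfect to clearly non-alternating |
| leaf length | 300 mm | decimeter-scale blades |
| stem radius | 8 mm; leaf capsule radius 6 mm | centimeter-scale organs |
| leaf droop | 0.35 (63 deg of bend) | rising-then-drooping blades |

The generator emulates the imaging geometry (calibrated turntable views, a
cube of side 768 mm imaged at 512^3 = 1.5 mm/voxel scale in the reference
configuration, 3 mm/voxel at the 256^3 default used here), not appearance:
leaves are capsule tubes without blade width, twist or texture, there is
no occlusion by pots or hardware, no segmentation error, and no plant
movement between views. Passing tests therefore demonstrate correctness of
the geometry pipeline on clean input; they do not certify performance on
real images, where segmentation quality and canopy motion dominate.

`make_population()` supplies the quantitative-genetics tail: biallelic
markers in Hardy–Weinberg proportions at uniform minor-allele frequencies
in [0.05, 0.5], genotype dosages 0/1/2, and phenotypes built as genotypic
value (configured causal-marker contributions plus a polygenic effect)
plus residual. Components are standardized empirically — each piece is
rescaled to its target variance and residuals are orthogonalized against
the genotypic values — so the recorded ground-truth variance components
are exact by construction rather than sampled. `h2_target` is the
per-observation ratio `s2G / (s2G + s2R)`; `h2_for_H()` converts a desired
broad-sense heritability at `n` replicates into that ratio.

## Camera and grid geometry

World coordinates put the plant base at the bottom center of a cube of
side `world_extent` (default 768 mm). Orthographic side views are the
default (a turntable at camera distance is well approximated by parallel
projection, and the visual-hull argument is exact there); pinhole
projection is available. Pixel size is `sqrt(2) * world_extent /
(image_size - 2)` so that even the cube's corners project inside every
image. `rig_for_grid()` picks `image_size = 2 + floor(1.3 * resolution)`,
making pixels about 9 percent larger than voxels: every interior mask
pixel then receives at least one voxel-center reprojection, so the
center-point reprojection stays an exact subset of the input silhouette
while round-trip Dice scores remain informative.

## Numerical choices and degenerate inputs

* **Thinning.** Sequential simple-point deletion with a frozen border set
  per sub-iteration (one erosion layer per direction per pass) and a fixed
  direction order (up, down, +y, -y, +x, -x), so results are
  deterministic. Curve tips are protected both when a voxel has at most
  one object neighbor and when it has exactly two mutually adjacent
  neighbors (the wedge tip of a thick diagonal line, which would otherwise
  let 2-voxel-wide structures nibble themselves away).
* **Skeleton graph.** 26-adjacency edges, with triangle chords removed
  (longest first) so that acyclic voxel curves satisfy `|E| = |V| - 1`;
  genuine cycles have no chords and survive for `is_tree()` to reject.
* **Gap joining.** Components whose closest nodes are within 15 mm (five
  reference voxels) are bridged at that closest pair, repeatedly.
* **Cycle breaking.** Visual hulls of crossing leaves can carry thin
  handles; chords of cycles shorter than 150 mm (half a default leaf) are
  removed as reconstruction noise, and the dangling strand is left for the
  spur pruner. Longer cycles are treated as real topology errors.
* **Spur pruning.** The default rule classifier removes terminal branches
  shorter than 60 mm (twice the 20-voxel leaf-axis window at 3 mm/voxel)
  or with mean local radius below 4 mm (webbing sheets thin to about one
  reference voxel, real organs are at least 6 mm across). A linear
  support-vector classifier trained on synthetically labeled branches is
  available as `train_branch_classifier()`; the deterministic rule is the
  default for reproducibility. The branch containing the root is never
  pruned, and labeling every branch spurious raises a degenerate-input
  error.
* **Stem rule fallback and recursion.** For plants with at most two
  non-root tips the literal "more than two paths" rule classifies nothing
  as stem, so "at least two paths" is used and the record flagged. The
  same relaxed rule is re-applied recursively inside any multi-tip leaf
  component: the path-count rule cannot tell the last stem internode from
  the base of the topmost leaf, and the recursion resolves every leaf to a
  single tip. Afterwards, leading leaf-path nodes within 1.5 voxels of the
  stem axis are absorbed back into the stem; this restores the top leaf's
  attachment and azimuth window, at the cost of a systematic upward bias
  of attachment heights (the first stretch of an inclined leaf base lies
  inside the stem's hull and cannot be attributed to the leaf).
* **Frames and signs.** The stem frame orients `e1` upward, `e2` toward
  +x (ties toward +y), `e3 = e1 × e2`; leaf axes point away from the
  junction. These conventions are arbitrary — which is precisely why the
  conjugate-alignment step exists — but fixing them makes runs
  deterministic. Collinear stems fall back to a deterministic `e2` in the
  orthogonal plane.
* **Ties in leaf ordering.** Equal attachment heights are broken by world
  azimuth about the junction, then by path length.
* **Angle bookkeeping.** Azimuths live in the half-open `[0, 360)` for
  both leaf azimuths and phyllotaxic angles, removing the 0/360 double
  representation; `conjugate(0)` is 0. The range filter keeps
  `90 <= phi <= 270`, equivalently `Phi <= 90`, with inclusive boundaries;
  the equivalence is asserted in the tests. Plants with a single measured
  leaf carry no phyllotaxy information and are rejected.
* **Alignment caveat.** Per-plant conjugate alignment chooses the flip
  that makes the within-plant correlation non-negative. With only a
  handful of angles per plant this selection inflates the pooled null
  R-squared above zero; the null-behavior test therefore uses long
  per-plant series, where the effect is negligible.
* **Heritability.** Variance components by REML (lme4) with an unbalanced
  method-of-moments fallback, negative estimates truncated at zero;
  `H = s2G / (s2G + s2R / n)` with `n = 2` as a configured constant (the
  minimum replication), not a harmonic mean. Genotypes may be capped to a
  seeded random subsample of replicates. All-unreplicated designs are
  unidentifiable and raise an error.
* **Association scan.** The engine is deliberately a single-marker linear
  model (optionally with genotype principal components); iterative
  model-selection engines can be plugged into `rmip()` through the same
  contract. Masking acts on plant-level phenotype records — the natural
  reading of masking "phenotypic records" — and unmasked records are
  averaged per genotype before scanning; each iteration draws its mask
  from a seeded per-iteration stream. `marker_qc()` attributes each
  excluded marker to the first filter it fails, in the order biallelic,
  indel, missingness, heterozygosity, minor-allele frequency; the
  surviving set is order-independent.

## Problem sizes in the test suite

Unit tests reconstruct at 64–128 voxels per axis; the ground-truth
recovery suite runs twenty plants at 256^3 (about 2–3 s per plant);
heritability recovery uses 200 genotypes by 2 replicates over 100 seeds
per heritability level; the RMIP suite uses 300 genotypes, 1000 markers
and 50 resampling iterations over 10 seeds. These sizes were chosen so the
whole suite completes on a single desktop core in a few minutes while
keeping Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* Accuracy claims hold for the lower canopy of single-shoot plants.
  Tillers are not segmented (a tiller can be added to the generator to
  study failure modes); multi-tip ambiguity at the apex is resolved by
  recursion rather than by modeling the whorl.
* Attachment heights are biased upward by the stem-line absorption step;
  ranks and azimuths are unaffected in the tested regime.
* The visual hull cannot recover concavities; thin crossing organs can
  leave webbing that survives as extra material. The radius-floor pruner
  and cycle breaker remove most of it at 3 mm voxels; at coarser grids the
  radius contrast vanishes (and matters less, since webbing merges anyway).
* The branch classifier is a functional stand-in trained on synthetic
  labels, not a replication of any particular trained model.
* FarmCPU-style iterative engines, kinship adjustment and effective-marker
  estimation are out of scope; the effective marker count is an input.
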