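---
title: "Detection of phytoplankton specimens in bright-field microscopy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection of phytoplankton specimens in bright-field microscopy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how the pipeline works, why each tunable has the
default it has, and which design questions were genuinely open — the kind
of information a maintainer needs and the function reference does not
carry.

## Problem setting

Water samples examined under a conventional light microscope at 10×
magnification produce multi-specimen colour images at roughly 1.5 pixels
per micrometre. They contain phytoplankton of widely varying size and
shape, together with debris, minerals and zooplankton, over a bright but
unevenly illuminated background. The pipeline must (i) find every object,
(ii) reunite sparse colonies whose cells have no visible connection, and
(iii) reject non-phytoplankton objects, keeping recall high: the intended
operating regime fixes recall at 90 % and optimises precision there,
because losing true specimens is costlier than keeping some debris.

All physical parameters are stated in micrometres and converted with the
image's resolution (`um_to_px()`), so nothing silently assumes one
magnification.

## Foreground–background separation

Each RGB channel is thresholded against its Gaussian-weighted local mean
minus an offset, and the three masks are OR-fused.

* `threshold_sigma_um = 75` µm. The window must be larger than the target
  cells so a specimen cannot dominate its own local average; 75 µm (112.5
  px at default resolution) comfortably exceeds typical cell diameters in
  these samples.
* `threshold_offset_frac = 0.08`. The offset C resolves against the dtype
  maximum (0.08 × 255 = 20.4, kept fractional), not against the observed
  intensity range — the observed range would make the threshold depend on
  what happens to be in the image.
* Polarity: foreground is *darker* than the local mean. Bright-field
  specimens absorb light. The polarity is nonetheless a configuration
  switch (`dark_foreground`), since the convention is inferred from the
  physics rather than prescribed.
* Numerics: the Gaussian window is truncated at ±3σ and realised as two
  1-D FFT convolutions on a reflect-padded grid (symmetric, edge-inclusive
  reflection), padded up to a (2,3,5)-smooth length. A direct windowed-sum
  oracle in the test suite pins the border convention down. Windows whose
  σ falls below 0.5 px are rejected as degenerate.

## Candidate detection

Connected foreground components (8-connectivity, so diagonal chains of
cells stay together) become candidates; their external contour defines the
segmentation, i.e. internal holes are filled before anything else is
measured. Filters:

* `min_area_um2 = 5` µm², applied to the *filled* area. Area is used
  rather than an axis length because it is shape-agnostic; whether the
  filter runs before or after hole filling was an open choice, resolved
  as: after (the candidate is its filled region).
* Border rule: a candidate whose mask touches the 1-pixel outer frame is
  discarded regardless of area — partially imaged specimens cannot be
  identified or counted reliably. Mere bounding-box adjacency does not
  trigger the rule; an actual mask pixel on the frame does.

Contours are traced with Moore-neighbour tracing (clockwise, terminating
when the start pixel is re-entered towards the same second pixel). The
exact tracing algorithm is deliberately not part of the contract: the test
suite enforces the output property — components of the hole-filled mask —
against an independent flood-fill oracle.

## Colony merging

A Delaunay triangulation of candidate centroids links each detection to
its natural neighbours; an edge survives iff

* centroid distance ≤ `merge_distance_um = 105` µm, **and**
* mean-colour difference ≤ `merge_colour_frac = 0.15` of the dynamic range
  (38.25 levels) on *every* RGB channel.

Surviving connected subgraphs are fused (union mask, union bbox; centroid,
area and colour recomputed). Candidate colour is averaged over the filled
mask, not the bounding box, so background cannot skew it.

Design notes:

* The per-channel colour rule is used because the threshold is stated per
  channel; a Euclidean-RGB alternative is available as
  `colour_rule = "euclidean"`.
* One pass only: triangulate, prune, fuse. No re-triangulation after
  fusion.
* Degenerate inputs: 0/1 candidates have no edges; 2 candidates get the
  single pair; fully collinear centroid sets fall back to the complete
  graph so the thresholds still decide; duplicate centroids are jittered
  by 10⁻⁶ px under the configured seed.
* The triangulation is a hand-written Bowyer–Watson. Its bounding
  "super-triangle" vertices are treated symbolically as points at
  infinity: incircle tests against triangles containing a super vertex
  reduce to orientation tests. With a finite bounding triangle,
  near-collinear hull triangles have circumcircles large enough to reach
  the bounding vertices and hull edges are silently lost — this was
  observed against the brute-force empty-circumcircle oracle during
  development and is the reason for the symbolic treatment.

## Descriptors

Candidates are described on their bounding box grown by 10 % of its own
width/height per side (clamped to the image): the surrounding background
is included intentionally, because the foreground/background proportion in
the histogram acts as an implicit shape feature.

* **Colour**: raw RGB triples of all pixels in the grown box.
* **Texture**: responses of a complex Gabor bank at one scale and `No`
  orientations, computed on the grayscale image (luma weights
  0.299/0.587/0.114). Responses are computed over the *whole image* before
  cropping, to avoid boundary artefacts in small boxes. The envelope
  spread follows from the bandwidth: σ = (1/πf_c)·√(ln2/2)·(2^B+1)/(2^B−1),
  which is exactly the spread making the half-magnitude frequency
  bandwidth equal B octaves. Kernels are sampled on odd grids covering
  ±3σ; responses are raw (unnormalised), with the scaling recorded in the
  dictionary for reproducibility.

Both feature families feed a bag-of-visual-words model: k-means centroids
(MacQueen, 5 seeded restarts, 100 iterations — a deliberate buy-over-build
on `stats::kmeans`; Hartigan–Wong's transfer stage struggles with the
heavy duplication in pixel data) form the dictionary, and a region is the
L1-normalised histogram of nearest-centroid assignments (Euclidean, ties
to the lowest index so histograms are deterministic). L1 normalisation
removes the region-size dependence, which spans orders of magnitude
between small cells and large colonies. In `mode = "both"`, the two
normalised histograms are concatenated.

## Classification and model selection

Five classifier families are wrapped behind one surface
(`train_classifier` / `predict_scores`, higher score = more
phytoplankton-like): random forest, RBF SVM (decision values, oriented to
the positive class), kNN (score = neighbour vote fraction), gradient
boosted trees, and a generative GMM — one mixture per class, scored by the
class-conditional log-likelihood difference plus the log prior ratio, with
a diagonal-Gaussian fallback when a class is too small or degenerate for
an EM fit.

Model selection follows a two-stage cross-validated grid search:

1. descriptor parameters (word counts; and f_c, B, No for texture) with
   the classifier at default hyperparameters;
2. classifier hyperparameters at the stage-1 descriptor.

Fitness is mean held-out **precision at 90 % recall** across stratified
folds (5 by default; folds are a function of the seed and the labels
only). Precision at fixed recall is preferred over PR-curve area because
area rewards performance at recall levels the application will never use.
Dictionaries are rebuilt inside each training fold, so held-out candidates
never influence the words they are scored against; the final dictionary is
rebuilt on the whole training set. Folds without positive candidates are
excluded from the fitness with a warning; configurations whose word count
exceeds the available rows are skipped. Ties break to the earliest
configuration in declared grid order. Cross-validation splits at the
candidate level (stratified); the reference protocol does not say whether
splitting was per image or per candidate, and candidate-level keeps folds
balanced at small image counts.

The operating threshold is the highest score threshold reaching the target
recall with maximal precision, chosen on the training scores.

## Synthetic study conditions

The generator renders what the pipeline is designed to survive, with exact
ground truth:

* 512 × 384 px fields at 1.5 px/µm; background level 220 with a planar
  illumination gradient (amplitude 25 levels) in a random direction and
  additive Gaussian sensor noise (sd 3), clipped to [0, 255];
* 2–4 solid elliptical specimens (radius 5–12 µm) with a sinusoidal
  texture at 0.25 cycles/px (Gabor-detectable by construction);
* 1–2 sparse colonies of 4–7 cells (radius 3.5–6 µm) spaced 25–55 µm —
  inside the 105 µm merge distance — sharing a base colour with ±8-level
  jitter, well inside the 38.25-level colour threshold;
* 1–2 debris objects with grey/blue palettes and uncorrelated speckle
  texture;
* occasionally (p = 0.25) a specimen crossing the image border, which the
  edge rule must discard.

Placement enforces the merge thresholds in reverse: objects whose palettes
differ by less than the colour threshold (plus a margin covering
illumination drift and jitter) must sit further apart than the merge
distance, and specimen/debris palettes differ by at least 60 levels on
some channel, so cross-object Delaunay edges always fail at least one
pruning test. Colonies are placed first (largest footprint) and draw
palettes without replacement. Placement is bounded rejection sampling; an
overfull specification errors rather than degrades.

What the generator does **not** emulate: out-of-focus blur and
depth-of-field, partial occlusion and physical overlap of specimens,
taxon-specific morphology, chromatic aberration. Tests passing on these
scenes therefore demonstrate the algorithms' correctness and the
pipeline's end-to-end behaviour under the stated conditions — not
performance on real samples, where overlapping specimens in particular
will produce undersegmentation that these scenes exclude by construction.

## Problem sizes used in the checked examples

The end-to-end checks run on a 30-image dataset (15 train / 15 test, ~6
objects per image, ~130 eligible specimens, ~40 colonies), with one
descriptor configuration per mode (k = 10 words; texture at f_c = 0.25,
B = 1.5, No = 4) and a random-forest classifier — sizes chosen so the
whole suite runs comfortably on a laptop while every rate is estimated
from three-digit counts. The full reference grids (word counts 2–100, 12
frequencies, 4 bandwidths, 4 or 8 orientations, five classifier families)
remain available through `descriptor_grid()` and `grid_search()` for
larger studies.

## Known limitations

* Undersegmentation from physically touching specimens is accepted; no
  watershed-style splitting is attempted.
* Merging thresholds are global, not per-taxon; very large sparse colonies
  can exceed the centroid-distance threshold between distant cells even
  when intermediate cells chain them together (chaining is in fact what
  usually saves them).
* The GMM wrapper selects its covariance model by BIC within the requested
  component count; on near-degenerate descriptor sets it falls back to a
  diagonal Gaussian, which is deliberately crude.
* Species-level classification is out of scope; the output is a binary
  phytoplankton / other decision per detection.
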