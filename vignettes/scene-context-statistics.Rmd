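---
title: "Quantifying object-scene context: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying object-scene context: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scenestats)
```

## The problem

Objects are not scattered randomly through the world: faucets come with
sinks, skies sit above mountains, and a kitchen contains many more labeled
things than a mountainside. `scenestats` quantifies these regularities from
polygon-annotated scene photographs (LabelMe-style XML, one file per image)
and asks, for three successively richer descriptions of a scene, how much
category information each one carries:

1. **Ensemble statistics** treat annotations as unnamed "things" and
   summarize each scene by six numbers: object density, number of distinct
   labels, mean and variance of object size (as fractions of image area),
   the area-weighted center of mass, and spacing regularity (the
   coefficient of variation of pairwise center distances).
2. **Bag of words** uses the object labels but not their positions: object
   frequency within and across categories, Zipf rank-frequency structure,
   diagnosticity `p(category | object present)`, scene-object specificity,
   co-occurrence and frequent object groups, unique object combinations,
   the Shannon entropy of the label distribution, and the mutual
   information between object presence and category membership.
3. **Structural statistics** add coarse location: per-object position
   variance, occupancy maps on a normalized grid, indoor/outdoor location
   contrasts, and quadrant-count features.

Each representation's sufficiency for categorization is measured with
leave-one-out linear classification (LIBSVM via `e1071`: linear kernel,
`C = 1`, one-vs-one voting, features z-scored on each training fold) at
the basic level (16 categories, chance 6.25%) and the superordinate level
(indoor / urban / natural, chance 33%), reporting a confusion matrix,
accuracy, macro one-vs-rest AUC from decision values, the nonparametric
sensitivity index A′, and an exact binomial test against chance.

## The category taxonomy and cleaning model

The taxonomy is a two-level map: 16 basic-level categories (8 indoor:
bathroom, bedroom, conference room, corridor, dining room, kitchen, living
room, office; 4 urban: skyscraper, city center, street, highway; 4
natural: coast, open country, mountain, forest) grouped into 3
superordinates. Free-typed annotation labels are noisy, so cleaning is a
first-class, *table-driven* step: a normalization table maps each raw
label either to a canonical label or to deletion, tagged with a change
class (misspelling, plural, subordinate, superordinate, synonym,
container, part, other). Rename targets must themselves be canonical —
chains are rejected at construction — which makes cleaning idempotent and
non-vocabulary-increasing by construction. The table is user data, not
code: different labs can supply different cleaning policies.

## The synthetic-data generator

Real annotated databases of this kind are not redistributable, so the
package ships a seeded generator whose defaults encode the statistical
structure the analyses assume. Each of the 16 categories has a
`category_profile`:

* **Presence probabilities.** Every object has an independent per-scene
  Bernoulli presence probability. Each category carries 3 exclusive
  objects at probability 0.9 (distinctive objects such as a bath mat or a
  podium) plus a superordinate-specific shared vocabulary with
  1/rank-decaying weights, scaled so the expected number of distinct
  objects per scene matches the category's target (19.5 for kitchens down
  to 3.2 for mountains). "wall" appears in every category at low
  probability outdoors, making it the only fully universal object.
* **Density.** The expected total region count per scene matches the
  category mean (33.1 for kitchens, 5.1 for mountains, and so on).
  Mechanically, a scene's instances are its present objects plus a
  negative-binomial surplus (dispersion `size = 5`, giving the strong
  overdispersion real region counts show) of duplicate instances sampled
  from the present objects. Duplicates are weighted toward countable
  background objects (windows, chairs, trees) and away from the exclusive
  objects, which occur at most once per scene; this both is realistic and
  yields an approximately Zipfian marginal rank-frequency distribution
  (log-log slope ≈ −1 over the top 50 ranks).
* **Geometry.** Every instance is an axis-aligned rectangle: the
  downstream statistics consume only labels, areas and bounding-box
  centers, so rectangles exercise every code path while keeping exact
  closed-form oracles available in the tests. Areas are log-normal
  (σ = 0.6 on the log scale) with category-specific means from 5% of
  image area (living rooms) to 43% (mountains). Horizontal placement is
  uniform; vertical placement follows per-object bands: boundary objects
  are pinned (sky high, floor low), other objects inherit a category band
  that sits lower in the image for indoor scenes than outdoor ones, which
  reproduces the higher outdoor center of mass. Three objects shared
  across superordinates — door, window and plant — are deliberately
  placed higher indoors than outdoors, planting a real indoor/outdoor
  location contrast for the structural stage to find.
* **Reproducibility.** Every scene derives its own RNG substream from
  `(seed, profile index, scene index)`, so databases are byte-identical
  across runs and individual scenes are reproducible independently of how
  many others are generated.

What the generator does *not* emulate: co-occurrence dependence beyond
shared vocabularies (presence draws are independent given the category),
non-rectangular and overlapping-in-depth polygon shapes, occlusion
interpolation, and annotator label noise (cleaning is exercised through
explicit fixtures instead). Passing tests on synthetic data therefore
demonstrate that the *machinery* is correct and well calibrated, not that
any particular real-world database will show the same effect sizes.

## Statistical and numerical choices

* **Object "center".** The bounding-box midpoint
  `((xmin + xmax)/2, (ymin + ymax)/2)` of the polygon vertices, used for
  the center of mass, spacing, position variance and quadrant features.
  The vertical coordinate of the scene center of mass is reported as the
  fraction from the image *bottom*, so "higher in the image" reads as a
  larger number.
* **Spacing regularity.** Pairwise Euclidean distances between bbox
  centers on coordinates first normalized by image width and height (so
  differently sized images are comparable), then SD divided by mean. With
  exactly two objects the single distance has SD 0 by convention; with
  one object the statistic is undefined and flagged.
* **Superordinate contrasts.** The unit of analysis is the basic-level
  category mean; groups are compared with an equal-variance two-sample
  t-test, giving df = 14 for indoor-vs-outdoor (8 vs 8 categories) and
  df = 6 for urban-vs-natural (4 vs 4).
* **Entropy and mutual information.** Standard Shannon definitions in
  bits with `0 log 0 = 0`. Entropy uses instance counts (the marginal
  object distribution); diagnosticity and MI use scene-level presence.
  The per-pair binary MI is computed by expanding
  `I(S, O) = H(S) − H(S|O)` over the four presence-by-membership cells;
  the test suite verifies it against the independent
  `H(S) + H(O) − H(S, O)` joint-table route to 1e-12. Object rankings
  use MI against the full 16-way category variable (the summed binary
  version is also available).
* **Co-occurrence probability** for a pair is joint-presence scenes
  divided by scenes containing either object, so 1 means "always found
  together". This normalization is a declared package choice.
* **Frequent groups.** Exact top-k mining by levelwise apriori candidate
  generation with support pruning; the support threshold auto-lowers
  until the top-k is complete, so results equal exhaustive enumeration.
  All ranking ties in the package break lexicographically for
  determinism.
* **Exact combinatorics.** `combination_count()` computes binomial
  coefficients under exact big-integer arithmetic (base-1e4 digit
  vectors, multiplicative recurrence with exact division), since
  vocabulary-scale counts like C(617, 6) ≈ 7.5 × 10^13 sit near the edge
  of double precision and larger k exceed it.
* **Occupancy maps and contrasts.** Polygons are rasterized by
  pixel-center / cell-center membership under the even-odd rule, on the
  native grid for coverage and on a common 64×64 normalized grid for
  cross-image maps (coarse enough that a Bonferroni correction over
  cells is meaningful, fine enough to localize vertical shifts). Masks
  within a scene are unioned for per-scene occupancy, and summed across
  instances for occupancy maps, which makes mass conservation an exact
  invariant.
* **Location-contrast significance.** The per-cell data are binary
  per-scene occupancies in two usually unbalanced groups. A t-test —
  pooled or Welch — is badly anti-conservative at Bonferroni-corrected
  thresholds on such data (the true null is discrete), which the
  package's own permutation calibration exposes: family-wise error rates
  of 0.1–0.8 instead of 0.05. The default per-cell test is therefore
  Fisher's exact test on the occupied-by-group 2×2 table (vectorized
  hypergeometric tails, two-sided as twice the smaller tail), which
  restores family-wise control while still detecting the planted
  vertical shifts; `test = "t"` (with near-empty cells excluded from
  testing) remains available, and the Welch t map is always returned as
  a descriptive statistic. `location_contrast_null()` re-runs the
  machinery under permuted group labels as a calibration check.
* **Quadrant features.** An instance belongs to the quadrant containing
  its bbox center; centers exactly on a midline go to the lower-index
  quadrant (left before right, top before bottom), preserving row-sum
  conservation.
* **A′.** The standard nonparametric approximation
  `0.5 + (H − F)(1 + H − F) / (4H(1 − F))` for `H ≥ F`, with the
  symmetric complement below the diagonal and 0.5 at degenerate corners;
  per-category hit and false-alarm rates are read one-vs-rest from the
  confusion matrix.
* **Classifier details.** Features are z-scored with each training
  fold's mean and SD (the ensemble features have wildly different
  scales); constant columns are left unscaled. Multi-class AUC is the
  macro average of one-vs-rest rank AUCs over per-class scores formed by
  summing signed one-vs-one decision values. Prediction ties in the
  one-vs-one vote resolve by category order.

## Problem sizes

The bundled evaluation uses a 16-category × 50-scene recovery database
(800 scenes) for classification and structural recovery, 100
scenes/category (1600 scenes) for frequency-recovery checks, 1000 scenes
of a single profile for presence-probability convergence, and 200
permutations for the contrast null calibration; unit fixtures are 1–40
scenes with closed-form expectations. These sizes were chosen so the full
evaluation runs on a laptop in minutes while keeping Monte-Carlo error
well inside the asserted tolerances.

## Known limitations

* Statistics describe *photographs*: center bias and vertical placement
  partly reflect photographer framing, not world structure.
* Polygon areas are treated per object; overlapping polygons mean sizes
  can sum past the image area, and the union is only used where coverage
  is the question.
* Self-intersecting polygons get absolute shoelace areas, which only
  approximate their even-odd rasterized area.
* The LOO classifier refits once per scene; for databases far beyond 10^3
  scenes a held-out-fold design would be preferable to the literal
  leave-one-out protocol implemented here.
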