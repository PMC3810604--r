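# scenestats

Object–scene context statistics for polygon-annotated scene databases.

Human scene recognition leans on context: objects have typical
environments, sizes, positions and companions. `scenestats` is an R
toolkit for *measuring* those regularities from LabelMe-style annotations
(one XML file per image: per-object labels plus polygon outlines) and for
asking how much scene-category information each level of description
carries. It is aimed at visual-cognition researchers who need normative
object statistics to design experiments, and at vision researchers who
want quantified context priors.

The package works at three levels:

* **Ensemble statistics** — each scene as six summary numbers over its
  unnamed "things": density *n*, distinct-label count, mean and variance
  of object area (fraction of image area), area-weighted center of mass
  (x, y), and spacing regularity CV = sd(d)/mean(d) over pairwise
  center distances.
* **Bag of words** — the multiset of object labels: per-category object
  frequency, Zipf rank–frequency slope, diagnosticity *p*(category |
  object), scene–object specificity, co-occurrence, frequent *n*-object
  groups (exact apriori mining), unique object combinations, label
  entropy *H* = −Σ *p*(o) log₂ *p*(o), and object–category mutual
  information *I*(S; O) = *H*(S) − *H*(S | O) in bits.
* **Structural statistics** — coarse spatial layout: per-object position
  variance, occupancy maps on a normalized 64×64 grid, indoor/outdoor
  location contrasts with exact per-cell tests, and quadrant-count
  features.

Each representation is scored with leave-one-out linear SVM
classification (LIBSVM via `e1071`, linear kernel, C = 1) at the
basic level (16 categories, chance 6.25%) and superordinate level
(indoor/urban/natural, chance 33%), with confusion matrices, macro AUC,
A′ sensitivity and exact binomial tests.

Because hand-annotated scene databases are rarely redistributable, the
package includes a seeded synthetic-annotation generator
(`default_profiles()`, `generate_database()`) whose 16-category defaults
encode realistic structure — category-specific densities (kitchens ≈ 33
regions/scene, mountains ≈ 5), Zipfian object frequencies, category-
exclusive objects, and vertical placement bands — so the entire pipeline
is testable end to end with no downloads. See the vignette
(`vignettes/scene-context-statistics.Rmd`) for the full model and design
rationale.

## Worked example

```r
library(scenestats)

db <- default_database(scenes_per_category = 20, seed = 1)
db
#> <scene_database> 320 scenes, 16 categories, 105-label vocabulary

superordinate_contrast(db, "density", "indoor-vs-outdoor")[c("t", "df", "p")]
#> $t
#> [1] 4.332536
#> $df
#> [1] 14
#> $p
#> [1] 0.0006888296

rank_frequency(db, top_ranks = 50)$slope
#> [1] -1.088587

top_diagnostic(diagnosticity(db), "bathroom", 3)
#>           object diagnosticity support
#> 1       bath mat             1      18
#> 2 shower curtain             1      18
#> 3     toothbrush             1      20

ent <- database_entropy(db)
c(ent$entropy_bits, ent$uniform_limit_bits)
#> [1] 5.514705 6.714246

feats <- ensemble_feature_matrix(db)
loo_evaluate(feats[, 3:9], feats$category)
#> <evaluation_report> n=320 accuracy=0.475 (chance 0.062, p=1.27e-93) AUC=0.819 A'=0.838

loo_evaluate(count_matrix(db), scene_categories(db))
#> <evaluation_report> n=320 accuracy=0.997 (chance 0.062, p=0) AUC=0.999 A'=0.999
```

Reading the output: indoor scenes carry significantly more labeled
regions than outdoor ones (t(14) = 4.3); the object marginal is
Zipf-like (log–log slope ≈ −1); bathroom-exclusive objects are perfectly
diagnostic of bathrooms; the label distribution needs ~5.5 bits/object
against a 6.7-bit uniform limit; and while six ensemble numbers already
categorize scenes far above 6.25% chance, the full bag of words is
near-ceiling.

A full pipeline run (ingestion or simulation → cleaning → all three
statistical levels → classification, with CSV/JSON outputs and a
manifest) is available as `run_pipeline(pipeline_config(...))` or from
the shell via `inst/cli/scenestats.R`.

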