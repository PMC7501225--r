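---
title: "Raycast descriptors and neural classification of infant head shapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Raycast descriptors and neural classification of infant head shapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(craniorays)
```

## The problem

Craniosynostosis — premature fusion of one or more cranial sutures — deforms
the growing infant skull in subtype-specific ways: sagittal fusion produces a
long, narrow head (scaphocephaly), metopic fusion a triangular, keel-shaped
forehead (trigonocephaly), and unilateral coronal fusion an asymmetric,
unilaterally flattened forehead (anterior plagiocephaly). Surface imaging by
3D stereophotogrammetry captures the outer head shape without ionizing
radiation, and the question this package addresses is whether a compact,
standardized shape descriptor extracted from such surface meshes supports
reliable automatic classification into healthy, scaphocephaly,
trigonocephaly and anterior plagiocephaly.

`craniorays` implements the full pipeline: a hemi-icosphere raycast
descriptor, mirroring augmentation across the mid-sagittal plane, per-ray
standardization, a small feed-forward neural network, and linked stratified
10-fold cross-validation — together with a parametric synthetic head-shape
generator so every stage can be exercised and validated without clinical
data.

## The descriptor

Input meshes are assumed pre-oriented in a fixed head frame: the sella
turcica at the origin, +z superior, +y anterior, and x = 0 the mid-sagittal
plane. From the origin, one ray is cast along each direction of a sampling
hemisphere, and the distance to the *farthest* intersection with the mesh
(the outer skin surface) is recorded. The vector of ray lengths, in
millimetres, is the shape descriptor.

The sampling hemisphere is the closed upper half (z ≥ 0, equator included)
of a Class-I geodesic subdivision of a vertex-up icosahedron at frequency
*f*, projected to the unit sphere. The full sphere has 10 f² + 2 vertices
and, for even *f*, a ring of 5 f vertices lies exactly on the equator, so
the hemisphere carries 5 f² + 5 f ⁄ 2 + 1 directions. The default *f* = 12
gives 751 directions, the descriptor size the method was designed around.
Directions are sorted canonically (z descending, then azimuth), which makes
the descriptor layout — and any trained model — stable across runs. The
construction is configurable but the frequency must be even; odd
frequencies have no equatorial vertex ring and are rejected.

Two numerical details worth noting:

* **Mirror permutation.** Reflecting the head across the mid-sagittal plane
  maps each ray direction onto another direction of the set, so mirroring in
  descriptor space is an index permutation, computed once by exact pairing of
  reflected directions (tolerance 10⁻⁶; in practice mirror pairs are
  bit-exact because ring longitudes are evaluated with `cospi`/`sinpi`). The
  permutation is an involution; at *f* = 12 exactly 25 directions lie on the
  plane and map to themselves — the two poles-and-rings great-circle paths
  that the symmetry plane cuts through the geodesic lattice carry 4 f lattice
  points in total, of which 25 fall on the closed upper hemisphere.
* **Raycasting.** Möller–Trumbore intersection against every triangle, in
  compiled code; intersections closer than 10⁻⁹ mm are ignored
  (self-intersection offset), zero-area triangles are skipped, and the
  farthest hit is returned so that, on noisy open scans, the outermost
  surface wins. Rays that miss can `error` (the default for closed synthetic
  meshes), be filled from the sphere-neighbourhood average (`fill`, intended
  for hole-ridden photogrammetry), or pass through as `NA`.

On analytic test surfaces (spheres, ellipsoids) meshed at geodesic frequency
16 (2562 vertices), raycast lengths agree with the closed-form ray–surface
distances to better than 0.5% relative error; this oracle equivalence is
asserted in the test suite.

## Standardization and augmentation

Each subject contributes its original descriptor and its mirrored
counterpart (the permuted vector), which doubles the training data and
suppresses incidental left–right asymmetries. Features are standardized per
ray: subtract the per-ray mean, divide by the per-ray population
(divide-by-N) standard deviation. Standardizing across a population whose
head sizes vary removes global size almost entirely — two deformed heads
identical up to uniform scale map to standardized vectors correlating above
0.99 — which is the intended effect: the classifier should see shape, not
age.

Two scaler populations are supported. The default fits the scaler on the
training fold only (original + mirrored rows) and applies it unchanged to
the test fold, which is the leakage-free convention. The historical
formulation computed per-ray statistics over *all* subjects before
splitting; `scaling = "all"` reproduces that for comparison. On the
synthetic cohorts the difference is negligible, but the default avoids
building test-set statistics into the preprocessing.

Standard deviations below 10⁻¹² mm (rays constant across the population)
are clamped with a warning rather than dividing by zero.

## The classifier

A conventional feed-forward network maps the 751 standardized features to
four softmax outputs in the fixed order healthy, scaphocephaly,
trigonocephaly, plagiocephaly. Each hidden block is affine → batch
normalization → leaky ReLU → dropout; this ordering is a common convention
(the method description leaves it open) and is fixed here as configuration.
Defaults, all exposed in `classifier_config()`:

| parameter | default | meaning |
|---|---|---|
| hidden sizes | 192, 128, 64, 32 | widths of the four hidden blocks |
| leaky ReLU α | 0.2 | negative-side slope |
| dropout rate | 0.5 | per-unit drop probability (training only) |
| batch-norm momentum | 0.8 | fraction of the moving statistic retained per batch |
| input noise std | 0.5 | Gaussian noise on standardized inputs (training only) |
| learning rate | 10⁻³ | Adam step size |
| decay | 10⁻⁶ | time-based decay: lr ⁄ (1 + decay · step) |
| clip norm | 0.001 | global gradient-norm ceiling, applied before Adam |
| batch size | 256 | larger than most training folds, so 2 batches/epoch |
| max epochs | 1000 | upper bound; early stopping almost always fires first |
| patience | 50 | epochs without validation improvement before halting |

The trainable parameter count at the default architecture is 180,388
(affine weights and biases plus batch-norm scale and shift). "Decay" is
interpreted as legacy time-based learning-rate decay per optimizer step and
"clip normalization" as global-norm clipping of the full gradient; both are
configurable. The aggressive clip (0.001) makes progress slow and steady —
Adam's per-parameter normalization restores usable step sizes — which is why
trained folds typically run 400–1000 epochs before the patience window
closes.

Training minimizes categorical cross-entropy; after every epoch the
validation loss is evaluated in inference mode (no noise, no dropout,
moving batch-norm statistics), and the weights of the best validation epoch
are restored at the end. The forward/backward pass is implemented twice: a
reference implementation in plain R (`mlp_forward`/`mlp_backward`, verified
against finite differences in the tests) and a compiled training loop that
reproduces it, used by `cranionet()` because cross-validation retrains the
network ten times. Both draw all randomness from R's RNG, so a fit is
bit-reproducible given its seed. Prediction ties are broken toward the
lowest class index.

Which data should serve as the early-stopping validation set inside a
cross-validation is a genuinely open choice. The default carves a
stratified 10% of the training-fold *subjects* (both orientations linked)
so the held-out fold stays untouched; `validation = "test-fold"` instead validates
on the held-out fold itself, replicating the historical setup at the cost
of an optimistic stopping signal. Both modes are flagged in printed output.

## Cross-validation and metrics

Folds are assigned at the subject level, stratified by class (per-class
fold counts differ by at most one, with a rotating remainder so small
classes spread evenly); a subject's mirrored descriptor therefore lands in
the same fold by construction, and the test suite verifies over 100 seeds
that no pair is ever separated. With the study composition of 53 / 76 / 40 /
27 subjects and k = 10, fold sizes are 19 or 20.

Every subject contributes exactly one entry to the aggregated confusion
matrix — by default the prediction of its original-orientation descriptor;
`eval_mode = "mirror-average"` averages the original and mirrored softmax
first. Per-fold matrices are always retained and written by the pipeline.
From the 4×4 matrix the one-vs-rest metrics follow: recall/sensitivity
TP ⁄ (TP+FN), precision TP ⁄ (TP+FP), specificity TN ⁄ (TN+FP), and overall
accuracy trace ⁄ total. Metrics with zero denominators are reported as
undefined (`NaN`), never as zero. Displayed percentages are rounded to one
decimal.

A note on the reference confusion matrix used as a worked example (class
totals 53 / 76 / 40 / 27 with a single error, one plagiocephaly subject
predicted healthy): its accuracy is 195 ⁄ 196 = 99.5% and its plagiocephaly
sensitivity 26 ⁄ 27 = 96.3%, but the formula-exact healthy specificity is
142 ⁄ 143 ≈ 99.3%, not the 99.2% sometimes quoted alongside it; this package
always reports the formula-exact value.

## The synthetic generator

The generator exists so the pipeline's claims are testable without clinical
meshes; it emulates the geometry of infant head surfaces, not their
anatomy. The base shape is a superellipsoid with exponent 2.5 and relative
semi-axes (1, 1.25, 1.15) — flatter-sided than an ellipsoid, a reasonable
cartoon of a calvarium — sampled on a geodesic lattice at frequency 16
(2562 vertices), so meshes are closed and watertight by construction.
Deformations are smooth coordinate maps of severity *s*:

* **scaphocephaly** — elongate y by (1 + 0.25 s), narrow x by (1 − 0.15 s);
  at s = 1 the cephalic index drops from ≈ 0.80 to ≈ 0.55, a pronounced
  version of the clinical contrast between healthy and sagittal-fusion head
  shapes;
* **trigonocephaly** — compress |x| in the anterior–superior region by up to
  0.35 s, growing linearly with y; the gate is cosine-tapered in both y and
  z rather than a hard octant test, so the displacement field is continuous
  and the wedge emerges without a crease artefact at the boundary;
* **plagiocephaly** — radially flatten the anterior-right octant by up to
  0.35 s with cosine-tapered boundaries. The depth was fixed at 0.35 so
  that at the mildest simulated severity (0.5) the descriptor's mirror
  asymmetry exceeds three times the bump-noise floor — i.e. simulated
  disease is always distinguishable from simulated measurement noise, by
  design.

After deformation, 20 Gaussian bumps (amplitude 1 mm, angular width
0.25–0.45 rad, positions and signs seeded) model smooth surface noise, the
head is scaled to a half-width drawn uniformly from 55–75 mm (the head-size
spread of 3–6-month-old infants), and shifted so the sella origin sits
inside, below centre. Severity 0 reproduces the healthy shape exactly, for
every class.

The default cohort reproduces the study composition — 53 healthy, 76
scaphocephaly, 40 trigonocephaly, 27 plagiocephaly — with patient severities
uniform on [0.5, 1]. Per-subject seeds are derived as
`master_seed · 10⁴ + index`, so any subject can be regenerated in isolation
and whole cohorts are bit-reproducible.

What the generator does *not* emulate: faces, ears and necks; real
photogrammetry artefacts (holes, hair, texture noise); age-dependent growth;
the unknown severity distribution of a clinical population; and any overlap
or ambiguity between subtypes. Synthetic severities of 0.5–1.0 produce
well-separated classes, so a high cross-validated accuracy on this cohort
demonstrates that the pipeline is implemented correctly and that the
descriptor carries the class signal — it does not certify clinical
performance, which can only be established on real stereophotographs.

## Problem sizes and runtime

The package's own validation runs at the study scale: 196 subjects (392
descriptors with mirroring), 751 rays against 5120-triangle meshes, ten
folds of up to 1000 epochs. On one CPU core the full synthetic
cross-validation takes on the order of eight minutes, dominated by network
training; single fits on toy problems run in seconds. Mesh resolution
(generator frequency 16, sampler frequency 12) was chosen so that raycast
discretization error (< 0.5%) is far below the class separation.

## Known limitations

* Input meshes must already be in the head frame; automatic landmarking of
  raw scans (locating the sella turcica) is out of scope.
* The hemisphere ordering is canonical for this package but there is no
  universal convention; descriptors are not interchangeable with other
  implementations unless directions are matched.
* The classifier is deliberately the reference architecture; no
  hyperparameter search or alternative models are provided.
* Synthetic accuracy is a property target, not a clinical claim (see above).

## A minimal run

```{r example}
cohort <- generate_cohort(cohort_spec(counts = c(8, 8, 8, 8), seed = 1))
sphere <- build_hemisphere(12)
feats  <- cohort_features(cohort, sphere)
cfg    <- classifier_config(hidden_sizes = c(32, 16), max_epochs = 150,
                            seed = 1)
cv     <- crossvalidate(feats, cfg, k = 4, seed = 1)
print(cv)
```
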