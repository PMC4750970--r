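---
title: "The two-pass hash-and-profile pipeline: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-pass hash-and-profile pipeline: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(grainhash)
```

# The problem

Discriminating the pollen of closely related species — the motivating case
is black versus white spruce (*Picea mariana* / *P. glauca*) — is hard even
for expert palynologists, yet their changing ratio in sediment cores is a
valuable paleoclimate signal. grainhash implements a two-pass visual
recognition pipeline for brightfield slide scans of pollen:

1. **Pollen spotting** (pass 1): a per-pixel binary classifier separates
   pollen pixels from the slide background.
2. **Species classification** (pass 2), in two variants:
   a profile-rule classifier that reconstructs the per-slide mixture ratio
   of the two species, and a scalable confidence-gated window classifier
   that calls species at grain/window level and aggregates to slide calls.

Both passes share one learning core, and both are exercised end to end on a
bundled synthetic-slide simulator with known ground truth.

# The hash histogram pixel classifier

Every pixel of interest is represented by a *grid example*: a square
lattice of `grid_size^2` neighboring intensities with pitch `grid_spacing`
(clamped at plane borders, so edge pixels replicate), quantized to
`Q = floor(max_intensity / q) + 1` levels by integer division with factor
`q`. A fixed random table holds one 64-bit value per (grid slot, channel,
level) combination; the values of an example's slots are summed modulo
2^64 and reduced modulo `B` (`bins`) to a bin index. Training increments a
positive or negative count for the bin of every labeled example;
prediction looks the bin up and calls the pixel positive iff the positive
count strictly exceeds the negative count. This is a histogram estimator
over a hashed, quantized feature space — an approximate nearest-neighbor
scheme in the locality-sensitive-hashing family, with O(1) training and
prediction cost per pixel.

Numerical and tie-break conventions (all deliberate, all documented in the
function reference):

* Unseen bins and exact count ties classify as **negative** (background):
  background is the majority phenomenon in slide imagery, so abstaining to
  it is the conservative default.
* The quantization factor is a **real** number >= 1; `floor(value / q)`
  generalizes integer division naturally and lets random search explore
  fractional factors (the species-model default, q = 14.24, is such a
  random-search optimum).
* For even grid sizes the lattice center is top-left biased: offsets run
  from `-floor((g-1)/2) * s` to `ceil((g-1)/2) * s`.
* The random table is derived on the fly from a stored integer seed with
  the splitmix64 mixer in keyed counter mode, so a model file only needs
  the seed and the two count arrays; 64-bit summation wraps modulo 2^64 by
  construction. Model files are written uncompressed, which keeps their
  size linear in `B` (about 32 MB at the default `B` = 2,048,000).
* Intensities default to 8-bit `[0, 255]`; `max_intensity` is exposed for
  other bit depths.

All spatial indices in the package are 0-based `(z, row, col, channel)`
with half-open rectangles — the arithmetic of grid sampling and window
tiling stays free of off-by-one ambiguity.

# Pass 1: pollen spotting

`train_spotter()` turns every pixel of every labeled window into one
training example. Windows labeled by several annotators enter as separate
windows: replicates are deliberately not merged by vote, so annotator
disagreement acts as label smoothing. Accuracy is plain pixel agreement
over all pixels (`pixel_agreement()`, equal to 1 minus the normalized
Hamming distance), because the headline agreement numbers in this problem
pool background and foreground pixels; `dice_coefficient()` is provided
for overlap-focused evaluation. `loo_cross_validate()` implements
leave-one-window-out cross-validation in a single pass by exploiting the
additivity of the count arrays (the fold model is the full model minus the
held-out window's counts).

# Pass 2a: profile rules and mixture ratios

A *profile* is a vertical line of `L` contiguous pixels lying entirely
inside the pollen mask whose *information content* — the mean absolute
difference of adjacent intensities, in intensity units per pixel — reaches
`ic_min` (default 5.0). IC is a focus/contrast score: it filters the
out-of-focus z-planes and flat interiors out of the training pool.

A candidate rule is a training profile; its Manhattan distance to every
training profile splits the set into *near* and *far* bins at a threshold
chosen by exhaustive search over the distinct observed distances,
minimizing training error. Each bin predicts the class with the larger
joint count (ties fall to the larger-prior class, then to class A). The
`k` lowest-error rules vote with equal weight; a slide's predicted mixture
ratio is the raw fraction of its profiles voted class A, deliberately
uncalibrated — evaluation regresses predicted on true ratios and reports
r². The objective of the per-rule threshold search is the one genuinely
open design point in this scheme; training-error minimization — low-error
rules are by construction the discriminative ones — is what
`evaluate_rule()` implements, verified exactly against a brute-force scan
in the test suite.

# Pass 2b: confidence-gated window classification

Square windows are sampled uniformly at random over a slide's z-planes and
kept only when their spotted-pollen fraction exceeds
`min_pollen_fraction` (default 0.5). A species hash model — trained only
on mask-positive pixels of pure reference slides, where the class label is
certain — classifies each pollen pixel of a window; the window's
*confidence* is the absolute difference of its two class fractions in
percent (100 for a unanimous window, 0 for an even split). Windows below
`confidence_min` abstain; if fewer than `min_classifications_per_slide`
windows pass, abstained windows are force-classified in descending
confidence order (maximizing the expected correctness of forced calls).
The slide call is the majority over classified windows, ties broken by the
larger summed confidence — the simplest aggregation consistent with
slide-level accuracy reporting, since no explicit rule is prescribed.
Function defaults carry random-search optima for the spruce
discrimination problem: window 256 px, confidence 43.61%, minimum 1
classification.

# Parameter optimization

`coordinate_descent()` sweeps one dimension at a time in declared order,
advancing along each dimension's ordering (powers of two, in the classic
spotting space) and stopping at the first non-improvement; one full cycle
by default, more via `cycles`. `random_search()` samples parameter points
uniformly (discrete dimensions over their value lists, continuous over
their intervals) with a stored seed; the default budget is 397 points. Both cache objective evaluations per point — CV objectives
are expensive and deterministic given seeds — and both record a full
`search_trace`. `learning_curve()` resamples training pools at a ladder of
sizes. Gradient-based optimizers are out of scope: the interesting
dimensions are discrete.

# The synthetic-slide simulator

Real slide archives at this problem's scale are tens of terabytes and not
redistributable, so validation runs on `generate_slide()` imagery: about
100 non-overlapping circular grains on a bright noisy background, imaged
as a z-stack in which planes away from the focal plane are Gaussian-blurred
in proportion to their focal offset, with per-plane sensor noise. Each
grain's interior is low-pass filtered Gaussian speckle with class-specific
spatial scale, anisotropy, contrast and mean interior intensity,
approximating exine-ornamentation texture differences. Two standard
experimental designs are built in: `generate_reference_set()` builds 12
pure slides (2 simulated individuals per class, 3 replicate slides each,
individual-level texture jitter shared across replicates — so held-out
individuals differ systematically from training individuals), and
`generate_ratio_series()` builds the 22 constructed slides at 0–100%
class A in 10% steps, two per ratio, 100 grains each.

Two simulator choices deserve explanation:

* **Classes differ in mean interior intensity (`base`) as well as texture
  scale and contrast.** With perfectly matched means, the class-conditional
  Manhattan-distance distributions of short profiles differ only in shape,
  which is too weak a signal for near/far rules to recover mixture ratios
  with slope near 1. A modest mean-brightness difference is a legitimate
  correlate of species and staining, and gives both second-pass
  classifiers an honest but solvable problem.
* **Geometry is scaled down.** Real grains span ~350 px at 0.23 µm/px;
  simulated grains span ~40–52 px on 1024-px slides so that a full
  12 + 22-slide experiment runs in minutes. Parameters that are lengths
  scale with them: the synthetic suite uses 24-px windows in place of the
  256-px default (both roughly one grain across), profiles of length 40
  rather than the default 128 (a profile must fit inside a grain), and
  spotting/species grids found by the package's own cross-validation on
  pilot synthetic data (grid 3×3, spacing 1–2, quantization 64). The
  full-scale values remain the documented function defaults.

What passing the synthetic suite does **not** show: robustness to scanner
artifacts (stitching seams, illumination falloff), to touching or
overlapping grains, to debris and non-pollen particulates, or to texture
families unlike band-limited Gaussian speckle. Results on synthetic slides
are a validation of the algorithms and their implementation, not a claim
about field imagery.

# Validation design in the test suite

The test suite validates each operation against independent oracles
(explicit-table histogram classifier, brute-force threshold scans,
exhaustive profile enumeration, closed-form least squares) and then runs
the full pipeline at the study design's conditions with fixed seeds:
pollen spotting must reach 95% held-out pixel agreement, leave-2-slides-out
species classification 90% accuracy with held-out individuals, and the
22-slide ratio reconstruction r² of at least 0.9 with regression slope
within 15% of unity.

Two behavioral checks mirror known qualitative results. Ensemble accuracy
as a function of `k` rises to an interior optimum and then degrades when
low-quality rules are admitted — the synthetic analogue admits out-of-focus
candidate profiles (IC filter disabled for the candidate pool) to populate
the low-quality tail. Learning curves are non-decreasing, within noise, in
both training slides and windows per slide.

One subtlety: the permutation null. Destroying the label–texture
association should leave slide-classification accuracy at chance. With a
*single fixed* label permutation and leave-2-out CV over 12 slides,
however, a strong classifier lands systematically *below* chance — the
held-out slide's permuted label is anticorrelated with the permuted-label
majority of its texture group (the "anti-learning" artifact of
cross-validation under permuted labels at small n). The package therefore
implements the permutation null by redrawing a seeded permutation in every
CV repeat (`cross_validate_slides(..., permute_labels = TRUE)`), which
samples the proper permutation distribution; the suite checks the result
against a ±3σ binomial band around 0.5.

# Limitations

* Two classes only; multi-class extension would change the confidence
  definition and the rule bins.
* The pixel classifier memorizes hashed patterns; it generalizes through
  quantization coarseness, not through any notion of feature similarity,
  and so needs dense coverage of the pattern space it will see.
* Only vertical profiles are implemented (the scan-order-efficient
  choice); orientation is a natural extension point.
* The simulator's defocus model is isotropic Gaussian blur; real optical
  sectioning has asymmetric point-spread behavior.
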