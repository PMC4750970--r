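# grainhash

Hash-based pixel classification and species-ratio reconstruction for
pollen slide imagery.

Counting and identifying pollen grains on microscope slides is a
bottleneck of palynology, and some species pairs — the canonical case is
black versus white spruce (*Picea mariana* / *P. glauca*), whose changing
ratio tracks North American paleoclimate — are hard even for experts.
`grainhash` implements a two-pass visual-recognition pipeline for z-stack
brightfield slide scans, for researchers who want automated pollen counts
with a fully inspectable, feature-free learning core:

1. **Pollen spotting** — per-pixel foreground/background segmentation.
2. **Species classification** — either per-slide mixture-ratio
   reconstruction from pixel-line profiles, or scalable grain-level calls
   from confidence-gated windows.

A synthetic-slide simulator with known ground truth, two hyperparameter
search strategies, and a command-line interface round out the package.

## The core algorithm

Each pixel *p* is represented by a *grid example* g(p): a `g x g` lattice
of neighboring intensities with pitch *s*, quantized to
`Q = floor(max_intensity / q) + 1` levels by integer division. A fixed
seeded table R of random 64-bit values — one per (slot, level) pair —
hashes the example to a bin

    h(p) = ( Σ_j R[j, g_j(p)] mod 2^64 ) mod B,

and per-bin label counts `n+[h]`, `n-[h]` accumulated over training pixels
form the model: predict positive iff `n+[h(p)] > n-[h(p)]`. This is a
histogram classifier over a hashed feature space (a locality-sensitive
hashing scheme) with O(1) cost per pixel, which is what makes slide-scale
pixel classification tractable.

For ratio reconstruction, a *profile* is a vertical line of L pollen
pixels with information content `IC = (1/n) Σ |x_i − x_{i+1}| ≥ 5.0`
(an in-focus/contrast filter). A rule is a training profile plus a
near/far Manhattan-distance threshold chosen to minimize training error;
the k lowest-error rules vote with equal weight, and a slide's predicted
ratio is the fraction of its profiles voted to class A. For grain-level
calls, windows with >50 % spotted pollen are classified by pixel vote and
abstain below a confidence floor (`|frac_A − frac_B| × 100`).

## Worked example

```r
library(grainhash)

# 1. Simulate a small study: 4 pure reference slides and 5 mixed slides
spec <- synthetic_slide_spec(image_size = 512L, n_grains = 40L, seed = 42)
refs <- generate_reference_set(spec, individuals_per_class = 1L,
                               replicates = 2L)
series <- generate_ratio_series(spec, ratios = c(0, 0.25, 0.5, 0.75, 1),
                                duplicates = 1L)

# 2. Pass 1: train a pollen spotter on a labeled window
spot_spec <- grid_spec(grid_size = 3, grid_spacing = 1, quantization = 64)
w <- extract_window(refs[[1]]$stack, z = 2, 0, 0, 512, 512)
spotter <- train_spotter(list(set_window_mask(w, refs[[1]]$mask)),
                         spot_spec, seed = 1)
held <- gh_window(refs[[2]]$stack$planes[[3]])
pixel_agreement(predict_window_mask(spotter, held), refs[[2]]$mask)
#> [1] 0.9782

# 3. Pass 2: profile-rule ensemble -> mixture ratios
res <- run_ratio_experiment(refs, series, n_rules = 256L, k = 32L, seed = 1)
round(data.frame(actual = res$actual, predicted = res$predicted), 3)
#>   actual predicted
#> 1   0.00     0.058
#> 2   0.25     0.312
#> 3   0.50     0.400
#> 4   0.75     0.670
#> 5   1.00     0.932
c(r_squared = res$r_squared, res$fit["slope"])
#> r_squared     slope
#>     0.979     0.843
```

The spotter agrees with ground truth on 97.8 % of the held-out slide's
pixels, and the predicted class-A fractions track the true mixture ratios
(r² = 0.98) on this deliberately small demonstration; the full study-scale
experiment (12 reference slides, 22 ratio slides of 100 grains each) is
exercised in the test suite with tighter recovery.

A shell interface wraps the same functions:

```sh
grainhash simulate --out slide1 --ratio 0.3 --seed 7
grainhash spot-train --slides slide1,slide2 --out spot.bin --quantization 64
grainhash spot-predict --model spot.bin --slide slide1 --z 2 --out mask.png
```

(`exec/grainhash` after installation; run it with no arguments for the
full command list: `simulate`, `spot-*`, `ratio-*`, `species-*`,
`optimize`.)

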