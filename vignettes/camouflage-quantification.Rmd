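---
title: "Quantifying background-matching camouflage in patchy scenes"
author: "patchcamo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying background-matching camouflage in patchy scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchcamo)
```

## The problem

An animal (or an artificial target) with a fixed, uniform colour sits in a
heterogeneous natural scene composed of visually distinct microhabitat
patches — grass, dried bracken, dark shrub, leaf litter. It can *specialise*,
matching the colour of one patch type, or *generalise*, matching the average
colour of the whole scene. Which strategy better reduces detection by a
searching observer depends on the colour difference between the target and
the background it is actually seen against, and on the spatial scale of the
patches relative to the target: a target much larger than the typical patch
is almost always viewed against a patchwork, whose local average colour is
close to the scene average.

`patchcamo` implements the full quantitative pipeline for this question:

1. **Colour** — conversion of display-encoded RGB imagery to CIE 1976
   L\*a\*b\* and the CIEDE2000 colour difference (ΔE₀₀), the perceptual
   currency of every later step.
2. **Design** — specialist/generalist target colour summaries and a
   paint-matching rule for realising them with a finite palette.
3. **Scene analysis** — edge-preserving smoothing, naive Bayes microhabitat
   segmentation, connected-component patch statistics, near-zone
   construction, and the two contrast predictors ΔE\_near and ΔE\_whole.
4. **Stimuli** — generation of a balanced visual-search stimulus database
   (crops, target recolouring) and constrained 20-slide presentation sets.
5. **Survival** — detection risk modelled by Cox proportional hazards on a
   transformed distance scale, with Gaussian frailties, likelihood-ratio
   tests, AIC ladders and proportional-hazards diagnostics.
6. **Synthetic data** — generators for patchy scenes with ground truth and
   detection trials with known hazard structure, so every stage is testable
   end to end without field data.

## Colour model

Images are treated as display-encoded RGB with a plain power nonlinearity:
decoding raises normalised channels to `1/power` with `power = 0.42` (the
piecewise sRGB transfer function is available via `piecewise = TRUE`).
Linear RGB maps to XYZ through the standard sRGB/D65 primary matrix, and to
Lab against the D65 white point (Y normalised to 1). This replaces
camera-specific calibration: absolute Lab values from this path will differ
from a cone-catch calibrated workflow, so all downstream claims are made on
ΔE *differences* and on simulated data, never on absolute colour
reproduction.

`delta_e_ciede2000()` implements the full CIE 2000 formula (chroma
correction `G`, hue rotation term `R_T`, weighting functions `S_L, S_C,
S_H`, `atan2`-based hue angles mapped to `[0°, 360°)`, the branch rules for
hue differences and means). It is verified against the 34 published
verification pairs to 10⁻⁴ in the test suite, and is continuous across the
hue branches.

```{r}
delta_e_ciede2000(c(50, 2.6772, -79.7751), c(50, 0, -82.7485))
```

## Synthetic scenes

`generate_scene()` builds a labelled scene from a `scene_spec()`:
independent Gaussian noise fields (one per microhabitat) are smoothed with a
Gaussian kernel of standard deviation `patch_scale_px / 2`, standardised,
and combined by argmax after adding per-field offsets calibrated so the
realised areal fractions match the requested weights within sampling error.
Pixel colours are then drawn per channel as Gaussians around the label
means. The smoothed-field construction (rather than, say, Voronoi cells)
gives continuous control of patch scale and naturally intermingled,
heavy-tailed patch-size distributions like those of real vegetation mosaics.

Default microhabitat colours are realistic temperate-vegetation Lab values,
chosen once for the simulators (per-channel SDs 5, 3, 5):

| microhabitat | L  | a   | b  |
|--------------|----|-----|----|
| grass        | 52 | −16 | 30 |
| bracken      | 56 | 10  | 36 |
| bramble      | 30 | −8  | 14 |
| leaf litter  | 44 | 8   | 24 |

Two features matter for what the simulations can and cannot show. First,
the four specialists span a *graded* range of mismatch to the scene average
(ΔE₀₀ ≈ 9–17): the generalist is closest, leaf litter next, bramble
furthest. Real scenes have this property too (scene elements differ in how
far they sit from the average), and it is what makes a continuous contrast
predictor genuinely richer than the binary specialist/generalist covariate.
Second, the scenes are stationary Gaussian mosaics: they have no skyline,
shadows, occlusion, perspective or texture, so passing tests demonstrate
correctness of the pipeline's *measurement and inference machinery*, not
robustness to real photographic structure.

The target is a stylised synthetic hare silhouette (`hare_silhouette()`:
ellipse body, head, ears; 0.65 width-to-height aspect), scaled by the scene
resolution: 400 mm at 0.8 px/mm (the 10 m photograph scale) gives a 320 px
tall mask; at 0.3 px/mm (30 m), 120 px.

## Scene analysis

`ranked_smooth()` is an iterated, threshold-gated, distance-weighted
channelwise median filter. A neighbour at distance `r` inside
`kernel_radius` (default 3) contributes only if its luminance difference
and chromatic (a, b) distance from the centre fall below gates derived from
Weber fractions (`weber_lum = 0.1`, `weber_chrom = 0.05`) scaled to channel
range and attenuated by `(1 − r/radius)^falloff` (`falloff = 2`); the
filter runs for 3 iterations by default. The gate multiplier
(`threshold_mult = 2`, i.e. 20 L units and 10 chroma units at the kernel
centre) was chosen so that the default parameters visibly denoise the
synthetic fixtures while preserving boundaries of ΔE₀₀ ≈ 40. Receptor-noise
ranked filters in imaging toolkits are not specified to the pixel by their
five parameters alone; this contract is a documented interpretation living
behind a small interface, so an alternative filter can be swapped in.

Segmentation is a diagonal-covariance Gaussian naive Bayes classifier
(`fit_classifier()` / `classify_pixels()`): per-pixel argmax of log prior
plus per-channel log likelihoods, SDs floored at 10⁻⁶, uniform priors by
default, exact posterior ties to the lowest class index, excluded pixels
(target, exclusion ring, skyline masks) labelled `NA`. Patch structure
comes from `particle_analysis()` — connected components per habitat
(8-connected by default; 4-connected available and used for the
checkerboard contract) with one row per patch.

The *near zone* is the band of width equal to the target height around the
target, beyond a thin exclusion ring (4 px at 0.8 px/mm, 2 px at
0.3 px/mm) that guards against target-pixel contamination. Dilations use a
square (Chebyshev) structuring element — deterministic and closed-form
testable (`near_zone_mask()` reproduces exact dilation arithmetic for
rectangles and a brute-force distance oracle for irregular shapes); bands
are clipped at image borders and the realised area is whatever survives the
clip. `contrast_predictors()` returns ΔE₀₀ between the target colour and
the mean Lab of (i) the near zone and (ii) the whole scene minus target,
ring and scene exclusions.

## Detection-risk model

Field detection distances are transformed to a survival response:
`response = 1 − d_detect/d_max`, so 0 means "spotted at the maximum
possible viewing distance" and larger values mean the observer approached
closer before detecting. A missed target is censored at the closest
possible approach, `1 − d_min/d_max`. Online search times are used
directly, censored at the 10 s timeout, with strata formed from crop size
crossed with quartiles of the target's distance from screen centre
(quartiles of the analysed dataset, inclusive empirical quantiles, boundary
ties to the lower quartile — computed per dataset, configurable).

`fit_cox()` maximises the Efron-tie partial likelihood (ties are expected:
rangefinder-quantised distances). Random effects — observer ability,
position difficulty — are normal log-frailties fitted by penalised Newton
iteration, with variances chosen to maximise the Laplace approximation to
the integrated partial likelihood. Fixed-effects fits delegate to
`survival::coxph()`, which also serves as an independent cross-check: with
a single frailty term of fixed variance the two routes maximise the same
objective and agree to 10⁻⁶ in the tests; the fully independent oracle is a
naive `optim`-based Efron likelihood in the test helpers. Reported CIs are
Wald on the log-hazard scale. For mixed fits, AIC uses the
integrated-likelihood convention (−2·integrated log-likelihood + 2·(fixed
coefficients + variance parameters)); AICs are only compared between models
sharing the same random-effect structure, and `aic_ladder()` flags
differences above 6 as substantial. `ph_check()` applies the scaled
Schoenfeld residual score test; for mixed fits it diagnoses the equivalent
fixed-effects model, mirroring standard practice.

Pairwise treatment contrasts, when extracted from colour-level fits, are
reported uncorrected (an optional Holm adjustment can be applied with
`p.adjust`); the multiplicity convention of the original analyses is not
stated, so the default here is the conservative disclosure of raw
contrasts.

## Simulated detection trials

`generate_detection_trials()` imposes proportional hazards *directly on the
transformed scale* `u ∈ [0, 1 − d_min/d_max]` — the scale the models are
fitted on; no claim is made about hazards on raw metres, and the
exponential baseline is a simulator convention, not an empirical claim.
Event draws beyond a position's maximum `u` are censored, and detection
distance is back-computed as `d = d_max(1 − u)`.

Defaults are the emulated study's conditions: 39 observer trials × 20
positions (780 presentations); maximum viewing distance
`30 + Exp(mean 27)` m truncated at 200 m (range 30–200, mean ≈ 57 m);
minimum approach U(1, 15) m; baseline hazard 2.5 on the u-scale, giving
≈ 10% missed targets under the null; frailty SDs 0.2. Strategy is assigned
balanced within observer (the field ratio of 2 generalist to 8 specialist
colours is a paint-availability constraint, not a statistical requirement;
balance maximises power for parameter-recovery checks). One global seed
expands into per-component substreams by a counter scheme
(`substream_seed()`), so adding a pipeline stage never perturbs earlier
streams and every record set is bitwise reproducible.

`simulate_contrast_study()` chains the generators: one synthetic scene per
position, target placed, ΔE\_near and ΔE\_whole computed for all five
treatment colours (four microhabitat means and their areal average), and
trials simulated with the hazard driven by ΔE\_near (slope log 1.064 per ΔE
unit). The scene geometry — 512 px scenes at 0.15 px/mm with 48 px patches,
so the near zone holds roughly 15 patches and covers ~13% of the scene —
was chosen so that near-zone composition genuinely varies between
positions. That regime is the mechanism of interest: the whole-image mean
is nearly constant across positions while the local surround is not, which
is exactly why near-zone contrast should out-predict whole-scene contrast.
With patches much finer than the target, both predictors collapse onto the
scene average and carry identical information; with patches much larger
than the near zone, specialists sometimes sit on a matching patch and the
specialist/generalist comparison flips — neither regime is the one the
pipeline is built to quantify.

## Problem sizes and numerical choices

The test and acceptance workloads use: 512² scenes (5 seeds) for
segmentation accuracy; 512² field-scale scenes (0.8 px/mm, 320 px target,
8 px patches, 3 seeds) for patch statistics; 200 replicates of the 780-
presentation design for CI coverage of a true hazard ratio of 0.5; 100
replicates at n = 2000 for null calibration; and 200–1000 seeds for the
slide-set constraint battery. These sizes give Monte-Carlo error small
enough for the stated thresholds (e.g. binomial SE ≈ 2% at 200 replicates
for 90% coverage) while keeping a full run within minutes on one CPU.

Numerical conventions, in one place: SD floor 10⁻⁶ in the classifier;
posterior and argmax ties to the lowest index; paint-ranking ties broken by
name; the paint guard excludes a paint whose ΔE to another group's median
is less than *or equal to* its own (ties conservative, toward exclusion);
"range of values" for paint eligibility is the per-channel axis-aligned
min–max box of the group's samples (simplest reading of per-channel
reporting; a convex-hull rule would be stricter and is deliberately not the
default); boxes use closed inequalities; Newton steps are halved until the
penalised likelihood is non-decreasing; frailty variances are profiled on
the log scale (Brent for one term, Nelder-Mead for several); the linear
predictor is shifted by its maximum before exponentiation (exactly
neutral in the partial likelihood).

## Known limitations

* Absolute Lab values depend on the sRGB-style decoding path and are not
  comparable to camera-calibrated cone-catch workflows.
* The ranked filter is a contract-level design keyed to its five parameters,
  not a pixel-exact port of any existing imaging-toolkit filter.
* The Laplace-profile frailty estimator is accurate for moderate group
  counts (here 39 and 20); with very few groups the variance estimate is
  biased low, as for all such approximations. Its contract is recovery and
  coverage behaviour, which the acceptance checks measure directly.
* Synthetic scenes are stationary Gaussian mosaics; conclusions about real
  photographs require the real imagery.
* The slide-set sampler enforces the stated marginal constraints (habitat,
  orientation, treatment, crop size, no location repeats); joint balance
  beyond those marginals is not enforced, matching the stated design.
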