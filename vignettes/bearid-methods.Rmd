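---
title: "Evaluating polar-bear photo-identification: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating polar-bear photo-identification: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bearid)
```

## The problem

Polar bears carry a pattern of pigmented whisker spots on the muzzle that
is individual-specific, and identification studies compare *sets* of
photographs (all pictures of one bear from one photography occasion)
pairwise: are the two sets the same bear or different bears? Two routes to
that judgement exist. An automated matcher registers each photograph to a
standard pixel grid, binarizes the whisker region, and scores pairs by a
Chamfer dissimilarity; a threshold on the dissimilarity then classifies
pairs. Alternatively, human observers rate pairs visually. Either way the
evaluation vocabulary is the same: a same-bear pair rated "different" is a
false negative, a different-bear pair rated "same" is a false positive, and

$$\mathrm{FNR} = \frac{\sum FN}{\sum TP + \sum FN}, \qquad
  \mathrm{FPR} = \frac{\sum FP}{\sum TN + \sum FP}, \qquad
  \mathrm{ER} = \sqrt{\mathrm{FPR}^2 + \mathrm{FNR}^2}.$$

`bearid` implements both routes, the modified ROC analysis that picks the
operating threshold, a permutation null for "how well would a random rater
do", and the binomial mixed models that quantify observer repeatability
and the effect of photogrammetric experience. Because the original zoo
photographs are not distributable, a synthetic-data module generates every
input the pipeline needs, with the statistical structure the analyses
assume; all tests and the worked examples run on those synthetic inputs.

## The synthetic study

`sim_individuals()` draws each bear's left and right whisker-spot pattern
by uniform rejection sampling inside a rectangular whisker region with a
minimum-separation constraint (defaults: 15-40 spots per side, radius 3 px,
separation at least 8 px on a 256 x 256 grid). No generative model of real
spot patterns is claimed; this is the simplest mechanism with controllable
distinctiveness. `sim_photo_sets()` gives three occasions per bear and one
for the last (43 sets for 15 bears; a 42-set pool is one argument away),
with occasion dates generated as metadata at a mean spacing of 25 days and
never used in computation. `sim_trials()` draws 15 sets per trial without
replacement, rejecting draws whose number of distinct individuals falls
outside 10-11, mirroring the experimental design's composition.

`render_photo()` draws the spots as dark disks after a random affine pose
perturbation (rotation up to 8 degrees, log-scale 0.08, shear 0.05,
translation 8 px), adds a linear illumination gradient, Gaussian blur and
pixel noise according to the quality label, and reports the landmarks under
the same pose plus annotation jitter. Quality is a generator-assigned label
(high / low / unsuitable, default proportions 0.253 / 0.414 / 0.333),
mirroring subjective photo grading: it is an input to downstream grouping,
never re-derived from pixels. Two rendering defaults deserve a note
because earlier drafts got them wrong:

* **Spot contrast is moderate** (grey level 120 on a 210 background).
  With near-black spots, blurring never removes a spot and the
  within-individual dissimilarity was *not* monotone in blur; at moderate
  contrast blur genuinely erodes detectability, and the generator satisfies
  the intended degradation ordering (dissimilarity non-decreasing in blur
  and jitter, verified in the test suite over 50 replicates).
* **The adaptive-threshold offset is 25 grey levels.** At offset 10,
  Gaussian noise at SD 10 seeds adjacent dark pixel pairs that survive the
  "< 2 pixels" component filter and swamp the binaries; at offset 25 such
  false components are essentially impossible for noise SD up to about 12
  while spots (contrast 90) remain detected.

What the generator does **not** emulate: fur texture, scars and other
physiognomic features, perspective foreshortening beyond an affine map,
landmark annotation bias (jitter is zero-mean), or observer learning over
trials. Passing tests on synthetic imagery therefore demonstrate the
*correctness of the computations* and the qualitative orderings (within <
between, degradation hurts), not field-level error rates.

All generators are pure functions of `(inputs, seed)`: a single study seed
fans out to per-entity child seeds by stable string hashing
(`child_seed()`), so adding an entity never perturbs any other entity's
draws, on any platform.

## The whisker-spot matcher

`warp_to_grid()` solves the unique affine map sending the photograph's
three facial landmarks (eye corner, nose notch, trailing mouth edge) to
fixed targets on the standard grid and resamples by inverse mapping with
bilinear interpolation (grey levels are warped first; thresholding comes
after). Coordinates are 0-based pixel centres, origin top-left. Collinear
landmarks are an error; landmarks outside the image warn and proceed. The
grid itself (256 x 256, fixed targets, crop window x 48-207, y 112-211) is
a configurable convention: no particular size is canonical, and the tests
run on a 128 x 128 grid for speed.

`binarize_whisker_region()` crops the whisker window and thresholds dark
pixels by a local adaptive mean (15 px window, offset 25), with a global
percentile fallback for flat lighting. The original enhancement chain that
this stage stands in for is not reprinted in the source literature; the
adaptive default is a declared substitute chosen for robustness to
illumination gradients, not a reconstruction. A zero-variance crop yields
an empty, flagged image rather than an error.

`denoise_spots()` removes connected components smaller than 2 pixels,
using 8-connectivity so a diagonal pixel pair counts as one size-2
component and survives. The labelling is computed in-package (vectorized
neighbour matching plus graph components) because the available image
library labels 4-connected components only.

`chamfer_dissimilarity()` averages, over the black pixels of each image,
the Euclidean distance to the nearest black pixel of the other image, and
averages the two directions. Distances come from an exact Euclidean
distance transform (verified against brute-force nearest-neighbour search
to 1e-9 in the test suite). An image with no black pixels makes the pair
*incomparable*: the `NA` sentinel propagates and the pair is excluded
downstream, never silently scored 0 or infinity.

`pairwise_dissimilarity()` selects at most one left and one right image
per set (highest quality available), never compares across sides, records
the lower of the two side dissimilarities when both are available, and
groups a pair as high quality only when both sets are high quality.

## Threshold choice and uncertainty

`roc_curve()` sweeps the threshold over the observed dissimilarity values
(plus infinite sentinels); a pair below the threshold is rated same, at or
above it different. Equality goes to "different": the classification rule
is stated only for "below" and "above", and sending ties to "different" is
the FPR-conservative completion. The optimal threshold minimises the
distance $\sqrt{FPR^2 + FNR^2}$ to the origin, with ties broken by lower
FPR (field use favours few false matches) and then lower threshold.

`roc_band()` bootstraps the curve with resampling stratified by truth
class -- unstratified resampling at these sample sizes (a handful of
same-bear pairs) would regularly produce single-class replicates -- and
reports the 2.5/97.5 percentile band of FNR on a fixed FPR grid,
pointwise in FPR. The observed curve is included as one of the
`n_replicates` curves, so the band always contains the point estimate and
collapses onto it when `n_replicates = 1`; at the default 10,000
replicates the effect is negligible.

## The permutation null

For each trial, `simulate_null()` scores the truth matrix against a copy
of itself with the set order randomized (a label permutation applied to
rows and columns jointly; a cell-shuffling mode is available behind a
flag, and both have identical marginal expectations). For a uniformly
random permutation the image of any fixed pair is a uniformly random pair,
so with $s$ same-pairs among $N$,
$E[\mathrm{FPR}] = s/N$ and $E[\mathrm{FNR}] = 1 - s/N$: the two expected
rates sum to one exactly. The test suite checks the simulation against
exhaustive permutation enumeration on small trials. Note that under the
stated trial composition (15 sets, at most 3 per individual, 10-11
distinct individuals) the same-pair fraction is at most 7/105, about
0.067, so a reported null FPR near 0.099 cannot arise from this procedure
on such trials; the package reproduces the stated procedure and reports
whatever the design implies rather than any particular printed value.

## Observer models

Both observer analyses are binomial mixed models with a logit link fitted
by Laplace maximum likelihood (`lme4::glmer`).

**Repeatability.** `fit_rating_repeatability()` models the rating itself
with a random intercept per comparison and computes the latent-scale
repeatability $R = \sigma^2_{comparison} / (\sigma^2_{comparison} +
\pi^2/3)$, the established definition for binary data, with the standard
error from a parametric bootstrap (simulate from the fit, refit, SD of the
replicate $R$). Whether the published denominator also included an
observer variance component is not documented, so a variant with both
random effects is computed and reported side by side
(`R_with_observer`).

**Experience.** `fit_experience_model()` models the binary outcome
(0 = correct) with fixed effects for photogrammetric experience
(0 = trained), similarity class, and their interaction, and random
intercepts for observer and comparison ID (comparison ids are globally
unique, realising nesting within trial; an explicit trial intercept is
included by default and may legitimately fit as singular). The same-bear
class is coded 1. A published table legend states the opposite coding, but
that coding is inconsistent with the same source's group-rate table and
its own text ("errors were smaller when different bears were compared"):
with the positive similarity coefficient, the class coded 1 must be the
high-error (same-bear) class. The two-step fitting strategy is mirrored:
the main-effects model is fitted first and kept as a diagnostic; the
interaction model is the final model.

Group rates (`group_rate_table()`) are population-averaged: the inverse
logit is integrated over the fitted random-effect distribution, which is
what an observer group realises over many comparisons; conditional
(random effects at zero) predictions are available as an option. The
published group rates are consistent with this marginalization: a total
latent SD near 2.1 makes the published logit coefficients imply
false-positive rates of about 0.003 (experienced) and 0.009
(inexperienced), which is how the simulation defaults
(`sd_observer = 0.5`, `sd_comparison = 2.0`) were chosen. No single
symmetric latent variance reproduces all four published rates at once
(the implied experienced-group FNR is nearer 0.18 than 0.13), a
discrepancy the package documents rather than hides. At these
dimensions -- about six expected false-positive events in the experienced
group -- the intercept is weakly identified, which is consistent with the
convergence trouble the original analysis reported; parameter-recovery
checks must expect wide intervals for it.

**Arithmetic notes.** The Euclidean error rate of the printed high-quality
whisker rates (FNR 0.061, FPR 0.200) is 0.209 by the stated formula; a
Results paragraph prints 0.256 for this quantity while the same source's
Discussion uses 0.209. The package computes 0.209 and does not reproduce
0.256.

## Numerical choices and degenerate inputs

* Rates with an empty similarity class are `NA`, never 0, and `NA`
  propagates to ER; silent zeros would fake perfect performance.
* Counts are pooled across trials and observers before division, matching
  the summation form of the rate definitions.
* Internal values are kept at full precision; reports round half-even to
  3 decimals (R's `round()`).
* The threshold grid is the set of observed values (no discretization
  error), with $\pm\infty$ sentinels for the degenerate ends.
* Chamfer symmetry is exact by construction (the two directed terms are
  averaged); zero occurs iff the black-pixel sets coincide.
* Bootstrap and simulation functions take explicit seeds and are
  deterministic given them.

## Problem sizes used in the checks

The shipped test-suite and examples run the full analysis logic at reduced
problem sizes chosen to keep the whole suite comfortably within a routine
CI run: a 128 x 128 grid with 10-18 spots per side for image tests, 50
replicates for render-degradation medians, 200-4000 replicates for
Monte-Carlo nulls, and 20-30 parametric-bootstrap replicates for
mixed-model standard errors (the user-facing defaults remain 10,000 for
the ROC band and 1000 for model bootstraps, the values used by the
original analyses). Coefficient recovery for the experience model is
checked at the study's own dimensions: 10 observers by 525 comparisons.
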