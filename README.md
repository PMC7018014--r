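# bearid

Polar bears lack the coat patterns that make other carnivores easy to tell
apart, but the spatial pattern of pigmented whisker spots on the muzzle is
individual-specific. Field studies therefore compare *photo sets* — all
pictures of one bear from one photography occasion — pairwise and ask: same
bear or different bears? `bearid` is an R package for evaluating how well
that question gets answered, whether by an automated whisker-spot matcher
or by human observers rating the photographs. It is written for wildlife
biologists and quantitative ecologists assessing photo-identification
protocols.

## What it computes

**Whisker-spot matcher.** Each photograph is registered to a standard
pixel grid by the affine map defined by three facial landmarks (eye
corner, nose notch, trailing mouth edge), the whisker region is cropped
and binarized (adaptive mean threshold), components smaller than 2 pixels
are removed, and photo pairs are scored by the symmetric Chamfer
dissimilarity

```
d(A,B) = ( mean_{a in A} min_{b in B} ||a-b||  +  mean_{b in B} min_{a in A} ||b-a|| ) / 2
```

in pixels on the standard grid (exact Euclidean distance transform).

**Threshold choice.** Pairs below a dissimilarity threshold are declared
"same". `roc_curve()` sweeps the threshold and plots the false negative
rate (FNR) against the false positive rate (FPR); the optimal threshold
minimises the distance `sqrt(FPR^2 + FNR^2)` to the origin, and
`roc_band()` gives a stratified-bootstrap confidence band of FNR at each
FPR.

**Error statistics.** For any rated comparison table,
`FNR = ΣFN/(ΣTP+ΣFN)`, `FPR = ΣFP/(ΣTN+ΣFP)`, and the combined error rate
`ER = sqrt(FPR^2 + FNR^2)`.

**Baselines and observer models.** `simulate_null()` scores each trial's
truth matrix against a random reordering of itself (the random-rater
baseline, with exact marginals `E[FPR] = s/N`, `E[FNR] = 1 − s/N`);
`fit_rating_repeatability()` estimates the latent-scale repeatability
`R = σ²_comparison/(σ²_comparison + π²/3)` of binary ratings;
`fit_experience_model()` fits the binomial GLMM
`outcome ~ experience × similarity_class + (1|observer) + (1|comparison)`
and `group_rate_table()` turns it into per-group FPR/FNR/ER.

**Synthetic data.** Real muzzle photographs are not redistributable, so
`sim_individuals()`, `render_photo()`, `sim_trials()`, `sim_observers()`
and `sim_ratings()` generate whisker-spot patterns, rendered photographs
at controlled quality, trial designs (15 sets per trial, 10–11 distinct
bears) and observer ratings with known error probabilities — every
analysis in the package runs end-to-end on them, and `run_study()` chains
the whole pipeline from one seeded configuration.

## Worked example

```r
library(bearid)

grid  <- standard_grid()
bears <- sim_individuals(15, seed = 1)
sets  <- sim_photo_sets(bears, seed = 1)          # 43 sets
trials <- sim_trials(sets, n_trials = 5, seed = 1)

photos <- render_study_photos(sets, bears, seed = 1, grid = grid)
bins   <- process_photos(photos, grid)
diss   <- pairwise_dissimilarity(bins)
#> 18 set(s) excluded: no usable photograph

low <- dplyr::filter(diss, quality_group == "low", status == "ok")
roc_curve(low, quality_group = "low")
#> <whisker_roc> [low] 13 same + 272 different pairs, 287 thresholds
#>   optimal threshold 5.67: FPR 0.000, FNR 0.000, ER 0.000

observers <- sim_observers()                      # 4 experienced, 6 not
cmp <- build_comparison_table(trials)             # 525 comparisons
outcomes <- classify_outcomes(cmp, sim_ratings(cmp, observers, seed = 1))
confusion_rates(outcomes)
#> # A tibble: 1 x 8
#>      tp    tn    fp    fn     n    fpr   fnr    er
#>   <int> <int> <int> <int> <int>  <dbl> <dbl> <dbl>
#> 1   123  4966    34   127  5250 0.0068 0.508 0.508

simulate_null(trials, n = 1000, seed = 1)
#> <null_summary> 1000 replicates/trial x 5 trials (permute_labels)
#>   expected FPR 0.048 (95% CI 0.040-0.050)
#>   expected FNR 0.951 (95% CI 0.800-1.000)
```

Reading the output: 18 of the 43 sets drew the `unsuitable` quality label
and are excluded, as in a real study where some occasions yield no usable
whisker photograph. Even the low-quality pairs separate perfectly here
(optimal ER 0) because synthetic spot patterns are more distinctive than
real muzzles -- the generator demonstrates the machinery, not field error
rates. The confusion row pools all 5250 rating cells of the ten simulated
observers: few false matches (FPR 0.007) but many missed matches
(FNR 0.51, dominated by the six untrained observers), while the
permutation null shows a random rater would miss nearly all matches
(expected FNR 0.95). Exact numbers depend only on the seeds shown.

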