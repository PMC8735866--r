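# nmphtools

Tools for studying how learning reshapes neural representations, using
stimuli whose similarity is *built in by construction*. The package has two
halves that meet in the middle:

1. **Correlation-targeted image synthesis.** Given any differentiable,
   layer-tapped feature extractor, the synthesis engine produces pairs of
   images A and B whose feature-pattern Pearson correlation *r*<sub>l</sub>
   at chosen layers is driven to prescribed targets: held fixed at
   *r* = 0.25 at constrained (lower/middle) layers and swept linearly from
   0 to 1 at the target (deep) layers across eight *model similarity
   levels*. The result is a 8 endpoint-pairs x 8 levels grid of 128 images.
   A deterministic random-weight convolutional extractor ships with the
   package, so the entire algorithm runs and is tested without any
   pretrained network.

2. **Nonmonotonic-plasticity (NMPH) analysis pipeline.** For a temporal
   statistical-learning experiment built on those images: templating and
   paired-sequence run designs with exact timing constraints; double-gamma
   GLM estimation of per-image voxel patterns; pairmate pattern similarity
   and model-brain correspondence (Fisher-transformed second-order
   correlation); representational change Δ*r* = *r*<sub>post</sub> −
   *r*<sub>pre</sub> per level (positive = integration, negative =
   differentiation); and the theory-constrained cubic model of the
   nonmonotonic plasticity hypothesis,

   Δ*r*(x) = a x³ + b x² + c x + d,  a > 0,

   fit on standardized levels x, evaluated by leave-one-participant-out
   cross-validation, with participant bootstrap CIs and a conservative
   pairmate re-shuffling permutation null. A synthetic-data generator
   plants known pairmate correlations, change curves, BOLD signals and
   behavioral arrangement distances, giving every stage a ground truth.

## Worked example

Simulate a 36-participant study with the default planted U-shaped change
curve, estimate per-level representational change, and fit the constrained
cubic:

```r
library(nmphtools)

spec     <- sim_spec(n_participants = 36, n_voxels = 2000, seed = 1)
patterns <- synthetic_patterns(spec)

# one participant's change curve (post - pre pairmate correlation)
pre  <- pairmate_similarity(patterns[[1]]$pre,  run_label = "pre")
post <- pairmate_similarity(patterns[[1]]$post, run_label = "post")
round(representational_change(pre, post), 3)
#> [1]  0.047  0.056 -0.008 -0.014 -0.116 -0.077 -0.008  0.086

curves <- t(sapply(patterns, function(s)
  representational_change(pairmate_similarity(s$pre),
                          pairmate_similarity(s$post))))

fit <- fit_constrained_cubic(1:8, colMeans(curves))
fit
#> Theory-constrained cubic (leading coefficient >= 1e-06)
#> Coefficients (standardized levels):
#>       a       b       c       d
#>  0.0498  0.0490 -0.0793 -0.0620
#> SSE 0.0017413 (unconstrained 0.0017413)

loo_cv(curves)
#> Leave-one-out CV over 36 participants: mean r = 0.9078

round(dip_contrasts(colMeans(curves)), 3)
#>              level5              level6 level4_minus_trough level8_minus_trough
#>              -0.094              -0.096               0.064               0.154
```

The positive leading coefficient `a` and the negative change at levels 5-6
flanked by higher values at levels 4 and 8 are the U-shaped signature: no
change for dissimilar pairmates, differentiation at moderate similarity,
integration near identity. The cross-validated mean r of 0.91 says the
curve generalizes across held-out participants (here the generator planted
exactly this shape).

Synthesis runs the same way at any scale:

```r
ext  <- make_toy_extractor(1, n_layers = 4, channels = c(6, 6, 6, 24))
spec <- synthesis_spec(image_size = 64, init_iters = 100, tune_iters = 100,
                       volleys = 1, window_fraction = 1, crop_quantile = 0,
                       seed = 1)
imgs <- lapply(1:24, function(ch) channel_image(ext, "conv4", ch, 50, spec))
eps  <- select_endpoints(imgs, ext, k = 16)   # 8 maximally decorrelated pairs
set  <- synthesize_set(ext, eps, spec)        # 128 images
validate_set(set, ext)$second_order
```

A command-line entry point wrapping the same functions lives at
`inst/cli/nmph.R` (`design`, `simulate`, `analyze`, `nmphfit`,
`synthesize`, `validate`, `pipeline` subcommands).

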