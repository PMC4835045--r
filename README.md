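# rcmstrata

Automated segmentation of skin strata in reflectance confocal microscopy
(RCM) depth stacks.

RCM images human skin *in vivo* as a stack of horizontal (*en-face*) optical
sections acquired at increasing depth, typically 2 μm apart. Interpreting a
stack starts with a deceptively simple question: *which anatomical stratum is
each section showing?* `rcmstrata` answers it automatically, classifying
every section into one of four strata —

| label | stratum | appearance in RCM |
|-------|---------|-------------------|
| `SC`  | stratum corneum | bright keratin speckle |
| `VE`  | viable epidermis | keratinocyte honeycomb |
| `DEJ` | dermal-epidermal junction | bright basal-cell rings around dark papilla centres |
| `PD`  | papillary dermis | fibrillar collagen meshwork |

— and converting the per-section labels into the depths of the three
inter-strata interfaces. It is aimed at quantitative dermatology work
(e.g. measuring stratum corneum or epidermal thickness across a cohort)
where labelling thousands of sections by hand is impractical.

## Method

Each section is represented by a *bag of visual features*:

1. **Working scale.** The acquisition (1000×1000 px, 500×500 μm) is
   down-sampled 4× with a truncated-sinc (Lanczos-3) pre-filter to 250×250 px.
2. **Patches.** 7×7 pixel patches `x` are contrast-normalised,
   `x ← (x − mean(x)) / sqrt(var(x) + 1)`, and decorrelated with a
   regularised zero-component-analysis (ZCA) whitening transform
   `W = V_r (Λ_r + εI)^{−1/2} V_rᵀ` (ε = 0.1, retaining the leading
   eigenvectors holding 95% of the spectral energy).
3. **Dictionary.** A hierarchical spherical k-means tree (branching factor
   `n_splits`, depth `n_levels`; 18³ = 5832 words at the standard operating
   point) clusters whitened patches by cosine similarity; its leaves are the
   visual words.
4. **Encoding.** All dense patches of a section are quantized by greedy
   descent of the tree, and the word-count histogram is scaled to unit L2
   norm. Each section is encoded together with its 90°/180°/270° rotations:
   at training time the four encodings are separate examples, at prediction
   time they are pooled by averaging.
5. **Classifier.** One-vs-rest L1-regularised logistic regression
   (inverse regularisation `C`, default 100) yields per-section class
   probabilities; the argmax is the predicted stratum.
6. **Interfaces.** The SC/VE, VE/DEJ and DEJ/PD interface depths are the
   cumulative label counts times the section spacing, e.g.
   `ve_dej_um = (#SC + #VE) × 2 μm`.

Model selection uses 10-fold cross-validation **partitioned on
participants** (never on sections), with the whitening model and dictionary
re-learned inside every fold so no held-out participant leaks into any
fitting stage; `leakage_audit()` verifies this from the recorded id sets.

## Worked example

The package ships a seeded generator of synthetic RCM-like cohorts (four
parametric textures, known labels and interfaces), so the whole pipeline can
be exercised without clinical data:

```r
library(rcmstrata)

bench <- synthetic_holdout_benchmark(rng_seed = 1)
round(bench$accuracy, 3)
#> [1] 1
bench$confusion
#>          compared
#> reference SC VE DEJ PD
#>       SC  32  0   0  0
#>       VE   0 29   0  0
#>       DEJ  0  0  25  0
#>       PD   0  0   0 30
round(bench$overall_interface_mae_um, 2)
#> [1] 0
```

This generates 25 synthetic participants, holds 5 out (stratified by age
group), fits the full pipeline on the other 20 and scores the held-out
sections: here every one of the 116 test sections is classified correctly,
so all interface depths are recovered exactly (mean absolute error 0 μm).
On real skin the published operating point of this method classifies 85.6%
of test sections correctly with interface errors of a few micrometres; the
synthetic textures are deliberately cleaner than skin.

Lower-level pieces are exported individually (`read_stack()`,
`downsample_section()`, `fit_whitening()`, `learn_dictionary()`,
`encode_section()`, `strata_fit()`, `predict()`, `estimate_interfaces()`,
`strata_grid_search()`, ...); see the methods vignette
(`vignettes/strata-segmentation.Rmd`) for the full model description. A thin
command-line interface covering `synth`, `learn-dict`, `encode`, `train`,
`gridsearch`, `predict` and `evaluate` is installed at
`system.file("cli", "rcm-strata.R", package = "rcmstrata")`.

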