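---
title: "Segmenting RCM depth stacks into skin strata: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting RCM depth stacks into skin strata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Reflectance confocal microscopy acquires *en-face* (horizontal) optical
sections of living skin at increasing depth, typically 2 μm apart to ~100 μm.
Four anatomical strata succeed each other with depth: stratum corneum (SC),
viable epidermis (VE), dermal-epidermal junction (DEJ) and papillary dermis
(PD). `rcmstrata` assigns one stratum to every section of a stack and
derives the three interface depths from the labels. The package assumes one
stratum per section — the convention under which such stacks are usually
ground-truthed — while tolerating (with a warning, not an error) label
tables that violate it, because deep skin furrows genuinely mix strata
within a section.

Conventions fixed throughout: section indices are 0-based, section 0 is the
most superficial, the depth of section *i* is *i* × `spacing_um` (depths are
relative to the first imaged section — the imaging origin is not
recoverable from the stack itself); pixel values live in [0, 1].

## The representation

Each section becomes an L2-normalised histogram over a learned vocabulary of
local texture elements ("visual words"):

* **Down-sampling.** A truncated-sinc pre-filter limits aliasing before 4×
  decimation (1000 → 250 px, i.e. 2 μm/px). We realise the truncated sinc as
  a Lanczos-3 kernel — the standard, well-tested member of that family — with
  per-output renormalised weights so constants are preserved exactly,
  including at borders. Dimensions not divisible by the factor are cropped
  to the largest multiple.
* **Patch normalisation.** Every 7×7 patch is centred and scaled by
  `sqrt(var + 1)`; the variance uses the population (1/N) convention and the
  regulariser sits under the square root with the variance, so flat patches
  map to zero instead of exploding. The regulariser of 1 is deliberately
  small: well-contrasted patches are barely changed.
* **Whitening.** The ZCA transform is learned from the pooled random patches
  of the training sections. Numerical choices: eigenvalues are clipped at 0
  before anything else; the energy rule retains the smallest leading set of
  eigenpairs reaching 95% of the spectral sum; truncation happens *first*
  and the regulariser ε = 0.1 is then added to the retained eigenvalues.
  (Regularising before truncating would barely change which axes survive,
  but the truncate-then-regularise order is the one that motivates the
  truncation — discarding near-null axes that ε alone leaves numerically
  fragile.) The transform is symmetric (ZCA rather than PCA form), so
  whitened patches stay in pixel space.
* **Dictionary.** Spherical k-means clusters unit directions by cosine
  similarity with a fixed 10 iterations per node — convergence is fast in
  practice and a fixed count keeps runs reproducible. Initialisation samples
  k distinct vectors without replacement; an empty cluster is re-seeded with
  the vector worst-represented by the current centroids (deterministic given
  the assignment). The hierarchy re-clusters each group into `n_splits`
  subgroups per level; a node with fewer patches (or fewer distinct
  directions) than `n_splits` fills its subtree with copies of its own
  centroid, so the leaf count is always `n_splits^n_levels`. Zero-norm
  patches are assigned the first basis vector as their direction.
* **Quantization.** Greedy descent — at each level take the child with the
  best cosine, ties to the lowest index — matching the hierarchy's purpose
  (speed). Exhaustive leaf search is available (`method = "exhaustive"`)
  and coincides with greedy descent for one-level dictionaries; a config
  flag rather than the default because the tree exists precisely to avoid
  the exhaustive scan. The encoder actually evaluates these dot products in
  the rank-r eigenbasis of the whitening model, which is algebraically
  identical (the transform has rank r ≤ 49) and saves a third of the
  arithmetic; a unit test pins the equality against the explicit route.
* **Rotation handling.** Training uses each section and its three
  right-angle rotations as four independent examples; prediction averages
  the four histograms and rescales to unit norm. Renormalising after the
  average is our choice (the plain average of unit vectors is shorter than
  1): it keeps test vectors on the same sphere the classifier was trained
  on, and `renormalize = FALSE` restores the plain average. Pooling is also
  applied to validation folds during model selection — every accuracy we
  report is a pooled-prediction accuracy.

## The classifier

Four one-vs-rest L1-penalised logistic regressions (glmnet) on the
histograms. The inverse-regularisation convention is
`objective = C · Σ log-loss + |w|₁`, i.e. glmnet's `lambda = 1/(n·C)`; the
default `C = 100` is the operating point selected by cross-validation in the
method's original clinical evaluation, along with the 3-level, 18-split
dictionary (5832 words). Multiclass probabilities rescale the per-class
sigmoids to sum to 1 (the standard one-vs-rest contract). Argmax ties break
towards the anatomically shallowest stratum — an arbitrary but documented
and deterministic rule.

Model selection (`strata_grid_search()`) runs 10-fold cross-validation
partitioned on participants. The whitening model and dictionary are
re-learned inside every fold from the fold's training participants only.
That is the conservative, leakage-free reading of "cross-validated grid
search" (re-using one dictionary across folds would let validation
participants shape the vocabulary); it is also the expensive reading, which
is why the default splits grid is coarse ({4, 6, …, 18}). Every fitting
stage records the participant ids it saw, and `leakage_audit()` replays
those records against the fold assignments. Exact accuracy ties go to the
simplest model (fewest levels, then splits, then smallest C).

## Interface depths

Interfaces are estimated by *counting* labels, not by locating the first
transition: `sc_ve_um = #SC × spacing`, `ve_dej_um = (#SC + #VE) × spacing`,
`dej_pd_um = (#SC + #VE + #DEJ) × spacing`. Counting makes the estimate
well-defined even when the predicted sequence is not anatomically monotone,
and it is permutation-invariant by construction. Agreement between two sets
of interface depths is summarised by per-interface mean absolute error and
per-interface Pearson correlation across stacks (per stack, not per
participant, so every acquisition contributes); a reference interface with
zero variance across stacks has no defined correlation and is reported as
`NA` rather than 1.

## The synthetic generator

`generate_stack()`/`generate_cohort()` emulate the structure of a clinical
RCM dataset: ordered strata with distinct textures, configurable per-stratum
thicknesses, additive Gaussian pixel noise, optional furrows (a localized
region showing the texture of a stratum several sections deeper, the main
real-world violation of the one-stratum assumption), and a participant ×
body-site × age-group metadata table. Texture parameters and thicknesses are
drawn **per participant** and shared across that participant's stacks, so
participant-partitioned cross-validation genuinely tests generalisation to
unseen individuals rather than to unseen noise.

The textures are parametric sketches of the diagnostic features, not
photorealistic speckle physics:

* SC — bright isotropic granules (thresholded fine-grain smoothed noise)
  over broad blotches;
* VE — honeycomb: bright boundaries of a jittered-lattice cell partition
  around dark interiors;
* DEJ — dark papilla discs ringed by bright annuli over a dimmed honeycomb;
* PD — an interwoven fibrillar meshwork: oriented band-pass noise, thresholded
  into bright strands, whose local orientation drifts across the section in
  domains (0/45/90/135° around a per-participant base orientation).

Two scale choices matter and were made once, on anatomical grounds: the
speckle grain (1.5–2.5 px) sits well below the fibril wavelength (9–14 px),
as corneocyte speckle is much finer than collagen bundles at this
resolution; and PD fibrils form a multi-oriented meshwork within every
section, as papillary collagen does. Both properties are also what make the
strata distinguishable to a 7-px patch vocabulary: a texture pair separated
only by a global orientation drawn uniformly per participant would not be
linearly separable from bag-of-words histograms of held-out participants —
a real limitation of orientation-pooled bag-of-features representations,
worth remembering when applying the method to strongly anisotropic tissue.

What passing the synthetic benchmark does **not** show: robustness to the
optical degradations of real RCM (depth-dependent signal loss, speckle
statistics, motion artefacts), to furrowed mixed-strata sections, or to
pathology. The clean textures make the synthetic task easier than skin —
the benchmark verifies the pipeline's mechanics (representation, leakage-free
training, pooling, interface arithmetic), not clinical performance, which is
what the bundled clinical confusion tables (`reference_confusion()`)
document: 85.6% section accuracy against a dermatologist whose own
intra-observer repeatability was 97.4%.

## Problem sizes used by the tests

The test suite and acceptance script keep the published constants (7×7
patches, normalisation regulariser 1, ε = 0.1, 95% energy, 10 k-means
iterations) and scale the *data* down: unit tests run on 48–80 px sections
and 10-participant cohorts; the end-to-end benchmark
(`synthetic_holdout_benchmark()`) uses 20+5 participants, one ~16–32-section
stack each at the native 250 px working scale, encoding stride 2, and a
2-level × 6-split dictionary — a compact vocabulary that the four synthetic
textures saturate (held-out accuracy is at or near 1.0 across seeds, against
the ≥0.90 / ≤6 μm recovery criteria). Stride 1 and deeper dictionaries are
the defaults for real data.

## Known limitations

* One label per section; mosaics and partial-section labelling are out of
  scope, as are DICOM/proprietary acquisition formats (multi-page TIFF and
  PNG/TIFF directories only; JPEG directories are not read).
* The interface estimate inherits any classification bias: systematic
  misclassification of one stratum shifts its interfaces by the
  corresponding section count.
* Pearson correlations are computed across stacks and are reported `NA`
  under zero variance rather than being imputed.
* The classifier is linear in the word histogram; texture classes that
  differ only through word co-occurrence or global arrangement (rather than
  word frequency) are outside its capacity.
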