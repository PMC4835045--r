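# Shared fixtures, built once per test run and cached. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small synthetic cohort: 10 participants x 1 stack, 64 px sections,
# ~12-16 sections per stack
mini_cohort <- function() fixture("mini_cohort", {
  generate_cohort(10, stacks_per_participant = 1, rng_seed = 42,
                  width_px = 64, height_px = 64, noise_sigma = 0.03,
                  spec_ranges = list(sc_thickness = c(3, 4),
                                     ve_thickness = c(3, 5),
                                     dej_thickness = c(3, 4),
                                     pd_thickness = c(3, 4)))
})

mini_split <- function() fixture("mini_split", {
  coh <- mini_cohort()
  holdout_split(coh$metadata$participant_id, coh$metadata$age_group,
                c("20-30" = 1, "50-70" = 2), rng_seed = 11)
})

# pipeline fitted on the mini cohort's training participants
mini_fit <- function() fixture("mini_fit", {
  coh <- mini_cohort()
  train_sids <- coh$metadata$stack_id[
    coh$metadata$participant_id %in% mini_split()$train]
  strata_fit(coh$stacks[train_sids],
             coh$labels[coh$labels$stack_id %in% train_sids, ],
             n_levels = 2, n_splits = 3, C = 100, downsample_factor = 1,
             stride = 2, n_random_patches = 80, rng_seed = 7)
})

mini_predictions <- function() fixture("mini_predictions", {
  coh <- mini_cohort()
  test_sids <- coh$metadata$stack_id[
    coh$metadata$participant_id %in% mini_split()$test]
  predict(mini_fit(), coh$stacks[test_sids])
})

# small participant-partitioned grid search (used for the leakage audit)
mini_cv <- function() fixture("mini_cv", {
  coh <- mini_cohort()
  strata_grid_search(coh$stacks, coh$labels,
                     levels_grid = 1, splits_grid = c(2, 3), C_grid = 100,
                     n_folds = 5, rng_seed = 13, downsample_factor = 1,
                     stride = 2, n_random_patches = 60)
})

# whitening + flat dictionary learned from iid patches, for quantizer tests
random_patch_setup <- function(n = 2000, d = 49, k = 8, seed = 101) {
  fixture(sprintf("rps_%d_%d_%d_%d", n, d, k, seed), {
    patches <- with_seed(seed, matrix(stats::rnorm(n * d), n, d))
    patches <- normalize_patches(patches, 1)
    wm <- fit_whitening(patches)
    white <- apply_whitening(wm, patches)
    dict <- learn_dictionary(white, n_levels = 1, n_splits = k, rng_seed = seed)
    list(patches = patches, whitening = wm, white = white, dict = dict)
  })
}

# expand printed 4x4 confusion counts into aligned per-section label tables
expand_confusion <- function(counts) {
  ref <- character(0); cmp <- character(0)
  for (i in 1:4) for (j in 1:4) {
    ref <- c(ref, rep(strata_levels()[i], counts[i, j]))
    cmp <- c(cmp, rep(strata_levels()[j], counts[i, j]))
  }
  n <- length(ref)
  list(reference = data.frame(stack_id = "t", section_index = seq_len(n) - 1L,
                              stratum = ref, stringsAsFactors = FALSE),
       compared = data.frame(stack_id = "t", section_index = seq_len(n) - 1L,
                             stratum = cmp, stringsAsFactors = FALSE))
}

# internal seeded-RNG helper mirrored for tests
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
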