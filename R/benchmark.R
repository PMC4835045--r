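# End-to-end synthetic benchmark: generate a cohort, hold out participants,
# fit the pipeline, and score held-out classification and interface recovery.

#' Synthetic holdout benchmark of the full pipeline
#'
#' Generates a synthetic cohort, holds out participants (stratified by age
#' group), fits the complete pipeline on the remaining participants and
#' evaluates pooled-rotation per-section accuracy, the confusion matrix and
#' interface-depth recovery on the held-out participants. This is the
#' package's parameter-recovery experiment: with the default 20+5-participant
#' cohort the pipeline should recover held-out accuracy well above 0.9 and a
#' mean interface error within a few micrometres, the scale of performance
#' reported for clinical data.
#'
#' @param rng_seed seed controlling the cohort, the holdout split and the
#'   pipeline fit.
#' @param n_train,n_test training and held-out participant counts (test
#'   participants split 2/3 between the two age groups).
#' @param n_levels,n_splits,C,stride,n_random_patches pipeline parameters
#'   (defaults: a 2-level, 6-split dictionary, C = 100, stride 2 — a compact
#'   operating point suited to the four synthetic textures).
#' @param width_px section size of the generated stacks (default 250, the
#'   working scale; sections are generated at working scale so no further
#'   down-sampling is applied).
#' @param thickness_range `c(min, max)` sections per stratum drawn per
#'   participant.
#' @return List with `accuracy`, `confusion`, `interface_mae_um` (per
#'   interface), `overall_interface_mae_um`, `n_test_sections`,
#'   `n_test_stacks` and the fitted `model`.
#' @export
synthetic_holdout_benchmark <- function(rng_seed = 1, n_train = 20,
                                        n_test = 5, n_levels = 2,
                                        n_splits = 6, C = 100, stride = 2,
                                        n_random_patches = 100,
                                        width_px = 250,
                                        thickness_range = c(4, 8)) {
  n_part <- n_train + n_test
  tr <- thickness_range
  coh <- generate_cohort(n_part, stacks_per_participant = 1,
                         rng_seed = rng_seed,
                         width_px = width_px, height_px = width_px,
                         spec_ranges = list(sc_thickness = tr,
                                            ve_thickness = tr,
                                            dej_thickness = tr,
                                            pd_thickness = tr))
  n_young <- round(n_test * 2 / 5)
  split <- holdout_split(coh$metadata$participant_id, coh$metadata$age_group,
                         c("20-30" = n_young, "50-70" = n_test - n_young),
                         rng_seed = rng_seed)
  train_sids <- coh$metadata$stack_id[
    coh$metadata$participant_id %in% split$train]
  test_sids <- coh$metadata$stack_id[
    coh$metadata$participant_id %in% split$test]
  fit <- strata_fit(coh$stacks[train_sids],
                    coh$labels[coh$labels$stack_id %in% train_sids, ],
                    n_levels = n_levels, n_splits = n_splits, C = C,
                    downsample_factor = 1, stride = stride,
                    n_random_patches = n_random_patches,
                    rng_seed = rng_seed + 1)
  stopifnot(isTRUE(leakage_audit(fit, split$test)))
  pred <- predict(fit, coh$stacks[test_sids])
  test_labels <- coh$labels[coh$labels$stack_id %in% test_sids, ]
  ca <- confusion_and_accuracy(test_labels, pred)
  agr <- interface_agreement(
    interface_table(pred, 2),
    coh$interfaces[coh$interfaces$stack_id %in% test_sids, ])
  list(accuracy = ca$accuracy, confusion = ca$confusion,
       interface_mae_um = agr$mae_um,
       overall_interface_mae_um = agr$overall_mae_um,
       n_test_sections = sum(ca$confusion), n_test_stacks = length(test_sids),
       model = fit)
}
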