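# Agreement metrics and interface-depth estimation.

test_that("confusion matrix and accuracy follow the trace/total definition", {
  lab <- data.frame(stack_id = "s", section_index = 0:5,
                    stratum = c("SC", "SC", "VE", "DEJ", "PD", "PD"))
  same <- confusion_and_accuracy(lab, lab)
  expect_equal(same$accuracy, 1)
  expect_equal(unname(diag(same$confusion)), c(2, 1, 1, 2))
  expect_equal(sum(same$confusion) - sum(diag(same$confusion)), 0)

  pred <- lab
  pred$stratum <- c("SC", "VE", "VE", "DEJ", "DEJ", "PD")
  both <- confusion_and_accuracy(lab, pred)
  expect_equal(both$accuracy, 4 / 6)
  expect_equal(both$confusion["SC", "VE"], 1L)
  expect_equal(both$confusion["PD", "DEJ"], 1L)

  expect_error(confusion_and_accuracy(lab, pred[-1, ]), "cover")
})

test_that("grouped accuracy partitions the overall count additively", {
  lab <- data.frame(stack_id = rep(c("a", "b"), each = 4),
                    section_index = rep(0:3, 2),
                    stratum = rep(c("SC", "VE", "DEJ", "PD"), 2))
  pred <- lab
  pred$stratum[c(2, 5)] <- c("DEJ", "VE")  # two mistakes
  meta <- data.frame(stack_id = c("a", "b"),
                     participant_id = c("p1", "p2"),
                     body_site = c("dorsal", "volar"))

  overall <- confusion_and_accuracy(lab, pred)$accuracy
  one_group <- grouped_accuracy(lab, pred, meta, "participant_id")
  expect_equal(sum(one_group$n * one_group$accuracy) / sum(one_group$n),
               overall)

  by_stratum <- grouped_accuracy(lab, pred, group_keys = "stratum")
  expect_equal(sum(by_stratum$n * by_stratum$accuracy), 8 * overall)
  expect_equal(by_stratum$accuracy[by_stratum$stratum == "VE"], 0.5)

  by_site <- grouped_accuracy(lab, pred, meta, c("body_site", "stratum"))
  expect_equal(nrow(by_site), 8)
  expect_error(grouped_accuracy(lab, pred, meta, "no_such_key"), "unknown")

  ps <- per_stack_accuracy(lab, pred)
  expect_equal(ps$accuracy, c(0.75, 0.75))
  # a half-correct stack reports 0.5
  pred2 <- lab; pred2$stratum[1:2] <- c("PD", "PD")
  expect_equal(per_stack_accuracy(lab, pred2)$accuracy[1], 0.5)
})

test_that("interface depths follow the label-count formula", {
  labs <- rep(c("SC", "VE", "DEJ", "PD"), times = c(10, 15, 12, 13))
  d <- estimate_interfaces(labs, spacing_um = 2)
  expect_equal(unclass(d),
               c(sc_ve_um = 20, ve_dej_um = 50, dej_pd_um = 74))
  # permutation invariance: counting ignores order
  expect_equal(unclass(estimate_interfaces(with_seed(60, sample(labs)), 2)),
               unclass(d))
  # degenerate all-SC stack
  expect_equal(unname(unclass(estimate_interfaces(rep("SC", 50), 2))),
               c(100, 100, 100))
  # monotone: one extra SC section lifts all three interfaces by the spacing
  d2 <- estimate_interfaces(c(labs, "SC"), 2)
  expect_equal(unclass(d2), unclass(d) + 2)
  # interfaces are ordered and bounded by the stack depth
  expect_true(all(diff(unclass(d)) >= 0) && d[["dej_pd_um"]] <= 50 * 2)
  expect_error(estimate_interfaces(character(0)), "empty")
})

test_that("interface agreement computes MAE and Pearson r with the zero-variance rule", {
  ref <- data.frame(stack_id = c("a", "b", "c"),
                    sc_ve_um = c(10, 20, 30), ve_dej_um = c(30, 40, 50),
                    dej_pd_um = c(50, 60, 70))
  same <- interface_agreement(ref, ref)
  expect_equal(unname(same$mae_um), c(0, 0, 0))
  expect_equal(unname(same$pearson_r), c(1, 1, 1))

  shifted <- ref
  shifted[, -1] <- shifted[, -1] + 4
  sh <- interface_agreement(shifted, ref)
  expect_equal(unname(sh$mae_um), c(4, 4, 4))
  expect_equal(sh$overall_mae_um, 4)
  expect_equal(unname(sh$pearson_r), c(1, 1, 1))

  # worked example: direct formula evaluation as the oracle
  auto <- ref
  auto$sc_ve_um <- c(12, 18, 33)
  ia <- interface_agreement(auto, ref)
  expect_equal(unname(ia$mae_um[1]), (2 + 2 + 3) / 3)
  x <- c(10, 20, 30); y <- c(12, 18, 33)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(unname(ia$pearson_r[1]), r_oracle)

  # zero-variance reference -> undefined correlation, reported missing
  flat <- ref; flat$sc_ve_um <- c(20, 20, 20)
  expect_true(is.na(interface_agreement(ref, flat)$pearson_r[1]))
  expect_error(interface_agreement(ref, ref[-1, ]), "different stacks")
})

test_that("probability profiles are tidy, complete and depth-indexed", {
  pred <- mini_predictions()
  sid <- pred$stack_id[1]
  prof <- probability_depth_profile(pred, spacing_um = 2, stack_id = sid)
  expect_equal(nrow(prof), sum(pred$stack_id == sid))
  expect_true(all(abs(rowSums(prof[, -1]) - 1) < 1e-8))
  expect_equal(prof$depth_um, (seq_len(nrow(prof)) - 1) * 2)
  expect_error(probability_depth_profile(pred), "exactly one")
})
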