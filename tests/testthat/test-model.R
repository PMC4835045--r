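# One-vs-rest L1 logistic classifier, holdout split, grid search and the
# leakage audit.

# linearly separable encodings: one tight cluster per stratum near a distinct
# unit corner of a d-dim simplex, mimicking L2-normalised histograms
separable_encodings <- function(n_per = 30, d = 12, sd = 0.02, seed = 50) {
  with_seed(seed, {
    corners <- diag(d)[1:4, ]
    x <- corners[rep(1:4, each = n_per), ] +
      matrix(abs(rnorm(4 * n_per * d, sd = sd)), 4 * n_per, d)
    x <- x / sqrt(rowSums(x^2))
    list(x = x, y = rep(strata_levels(), each = n_per))
  })
}

test_that("separable classes train to perfect accuracy with confident probabilities", {
  s <- separable_encodings()
  clf <- train_classifier(s$x, s$y, C = 100)
  pr <- predict(clf, s$x)
  expect_equal(mean(as.character(pr$class) == s$y), 1)
  expect_true(all(abs(rowSums(pr$probability) - 1) < 1e-8))
  expect_true(all(pr$probability[cbind(seq_along(s$y),
                                       match(s$y, strata_levels()))] > 0.9))
})

test_that("regularisation limits behave as expected", {
  s <- separable_encodings()
  # C -> 0: weights vanish, predictions collapse towards priors
  tiny <- train_classifier(s$x, s$y, C = 1e-5)
  expect_true(all(tiny$weights == 0))
  pr <- predict(tiny, s$x)$probability
  expect_lt(max(apply(pr, 2, stats::sd)), 1e-8)

  # sparsity is monotone in the penalty: more exact zeros at C = 100 than at
  # C = 1e5 on data with many irrelevant features. Classes must overlap so
  # residuals stay non-trivial (perfectly separable data zeroes the noise
  # coordinates at any penalty).
  noisy <- with_seed(52, {
    corners <- diag(4)
    xsig <- corners[rep(1:4, each = 25), ] +
      matrix(rnorm(100 * 4, sd = 0.35), 100, 4)
    cbind(xsig, matrix(rnorm(100 * 76, sd = 0.05), 100, 76))
  })
  y <- rep(strata_levels(), each = 25)
  frac_zero <- function(C) {
    mean(train_classifier(noisy, y, C = C)$weights == 0)
  }
  expect_gt(frac_zero(100), frac_zero(1e5))

  expect_error(train_classifier(s$x[1:60, ], s$y[1:60]), "missing class")
})

test_that("prediction is deterministic with anatomical tie-breaking", {
  null_clf <- structure(
    list(weights = matrix(0, 5, 4,
                          dimnames = list(NULL, strata_levels())),
         intercepts = stats::setNames(numeric(4), strata_levels()),
         C = 1, n_words = 5),
    class = "strata_classifier")
  pr <- predict(null_clf, matrix(1, 3, 5))
  # perfect four-way tie -> shallowest stratum (SC) wins
  expect_true(all(pr$class == "SC"))
  expect_equal(unname(pr$probability[1, ]), rep(0.25, 4))
  expect_error(predict(null_clf, matrix(1, 2, 7)), "does not match")
})

test_that("holdout split stratifies by age group, reproducibly", {
  ids <- sprintf("p%02d", 1:54)
  ages <- rep(c("20-30", "50-70"), c(25, 29))
  sp <- holdout_split(ids, ages, c("20-30" = 8, "50-70" = 10), rng_seed = 4)
  expect_length(sp$test, 18)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_equal(sum(sp$test %in% ids[1:25]), 8)
  expect_identical(sp, holdout_split(ids, ages, c("20-30" = 8, "50-70" = 10),
                                     rng_seed = 4))
  expect_false(identical(sp$test, holdout_split(
    ids, ages, c("20-30" = 8, "50-70" = 10), rng_seed = 5)$test))
  expect_error(holdout_split(ids[1:5], ages[1:5], c("20-30" = 9)), "only")
})

test_that("full pipeline fit predicts complete, normalised per-section output", {
  coh <- mini_cohort()
  fit <- mini_fit()
  expect_s3_class(fit, "strata_model")
  expect_setequal(fit$participants, mini_split()$train)
  pred <- mini_predictions()
  test_sids <- coh$metadata$stack_id[
    coh$metadata$participant_id %in% mini_split()$test]
  n_expected <- sum(vapply(coh$stacks[test_sids], n_sections, integer(1)))
  expect_equal(nrow(pred), n_expected)
  expect_true(all(abs(rowSums(pred[, c("p_SC", "p_VE", "p_DEJ", "p_PD")]) - 1)
                  < 1e-8))
  # the audit confirms no held-out participant touched any fitting stage
  expect_true(leakage_audit(fit, mini_split()$test))
  expect_s3_class(leakage_audit(fit, fit$participants[1]), "data.frame")
})

test_that("grid search partitions by participant and reports a full CV table", {
  cv <- mini_cv()
  expect_s3_class(cv, "strata_cv")
  # every participant sits in exactly one fold
  expect_length(cv$folds, 10)
  expect_true(all(table(cv$folds) >= 1))
  # full table: 2 grid points x 5 folds
  expect_equal(nrow(cv$table), 10)
  expect_true(all(cv$table$accuracy >= 0 & cv$table$accuracy <= 1))
  expect_true(cv$best$n_splits %in% c(2, 3))
  # fold assignment is seed-deterministic
  coh <- mini_cohort()
  again <- strata_grid_search(coh$stacks, coh$labels, levels_grid = 1,
                              splits_grid = 2, C_grid = 100, n_folds = 5,
                              rng_seed = 13, downsample_factor = 1,
                              stride = 2, n_random_patches = 60)
  expect_identical(cv$folds, again$folds)
  expect_error(strata_grid_search(coh$stacks, coh$labels, n_folds = 11,
                                  rng_seed = 1),
               "at least 11")
})
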