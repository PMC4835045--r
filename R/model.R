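# One-vs-rest L1 logistic regression over section encodings, the top-level
# fitting interface, and participant-partitioned model selection.

#' Train the one-vs-rest L1 logistic classifier
#'
#' Fits four binary L1-penalised logistic regressions (one per stratum, via
#' glmnet) on section encodings. The inverse regularisation strength `C`
#' follows the convention `objective = sum of log-losses * C + |w|_1`, i.e.
#' glmnet's penalty is `lambda = 1 / (n * C)`: larger `C` means weaker
#' regularisation. Multiclass probabilities are the per-class sigmoid scores
#' rescaled to sum to 1.
#'
#' @param x encoding matrix (rows = training examples, columns = visual
#'   words). Rotation-augmented training rows inherit their section's label.
#' @param y strata labels (coerced with [as_stratum()]); all four strata must
#'   be present.
#' @param C inverse regularisation constant (default 100).
#' @return An object of class `strata_classifier` with a `d x 4` weight
#'   matrix `weights`, `intercepts`, `C` and the dictionary size `n_words`.
#' @export
train_classifier <- function(x, y, C = 100) {
  x <- as.matrix(x)
  y <- as_stratum(y)
  present <- table(y)
  if (any(present == 0)) {
    stop("missing class(es) in training data: ",
         paste(names(present)[present == 0], collapse = ", "))
  }
  n <- nrow(x)
  lam <- 1 / (n * C)
  weights <- matrix(0, ncol(x), 4,
                    dimnames = list(NULL, strata_levels()))
  intercepts <- stats::setNames(numeric(4), strata_levels())
  for (cls in strata_levels()) {
    yb <- as.numeric(y == cls)
    fit <- glmnet::glmnet(x, yb, family = "binomial", alpha = 1,
                          lambda = lam * c(100, 10, 1),
                          standardize = FALSE)
    co <- as.matrix(stats::coef(fit, s = lam))
    intercepts[cls] <- co[1, 1]
    weights[, cls] <- co[-1, 1]
  }
  structure(list(weights = weights, intercepts = intercepts, C = C,
                 n_words = ncol(x)),
            class = "strata_classifier")
}

#' @export
print.strata_classifier <- function(x, ...) {
  nz <- colSums(x$weights != 0)
  cat(sprintf("<strata_classifier> one-vs-rest L1 logistic, %d words, C = %g\n",
              x$n_words, x$C))
  cat("  non-zero weights:",
      paste(sprintf("%s %d", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.strata_classifier <- function(object, ...) {
  rbind("(Intercept)" = object$intercepts, object$weights)
}

#' Predict strata for encoded sections
#'
#' @param object a [train_classifier()] model.
#' @param newx matrix of pooled section encodings (or a single encoding).
#' @param ... unused.
#' @return List with `class` (factor over the strata; argmax ties broken
#'   towards the anatomically shallowest stratum) and `probability`
#'   (matrix with columns `SC, VE, DEJ, PD`, rows summing to 1).
#' @export
predict.strata_classifier <- function(object, newx, ...) {
  if (is.null(dim(newx))) newx <- matrix(as.numeric(newx), 1)
  newx <- as.matrix(newx)
  if (ncol(newx) != object$n_words) {
    stop("encoding length ", ncol(newx), " does not match the classifier (",
         object$n_words, " words)")
  }
  scores <- sweep(newx %*% object$weights, 2, object$intercepts, `+`)
  p <- stats::plogis(scores)
  p <- p / rowSums(p)
  colnames(p) <- strata_levels()
  cls <- factor(strata_levels()[max.col(p, ties.method = "first")],
                levels = strata_levels(), ordered = TRUE)
  list(class = cls, probability = p)
}

# ---------------------------------------------------------------------------
# Top-level pipeline fit

labelled_sections <- function(stacks, labels) {
  by_id <- stats::setNames(stacks, vapply(stacks, `[[`, "", "stack_id"))
  missing <- setdiff(unique(labels$stack_id), names(by_id))
  if (length(missing)) {
    stop("labels reference unknown stack(s): ", paste(missing, collapse = ", "))
  }
  by_id
}

#' Fit the full strata segmentation pipeline
#'
#' Runs the complete training pipeline on labelled depth stacks:
#' down-sampling, random patch extraction, contrast normalisation, regularised
#' ZCA whitening, hierarchical spherical k-means dictionary learning,
#' rotation-augmented section encoding and one-vs-rest L1 logistic regression.
#' Defaults reproduce the standard operating point of the method: 7x7 patches
#' at a 4x down-sampled working scale, patch-normalisation regulariser 1,
#' whitening `eps` 0.1 with 95% retained energy, 10 k-means iterations per
#' node, a 3-level/18-split dictionary (5832 words) and `C = 100`.
#'
#' @param stacks list of [depth_stack()]s (raw acquisition scale).
#' @param labels a `label_table` covering the training sections.
#' @param n_levels,n_splits dictionary depth and branching factor.
#' @param C inverse regularisation constant of the classifier.
#' @param downsample_factor decimation factor to the working scale
#'   (4 for 1000 px acquisitions; use 1 if stacks are already down-sampled).
#' @param patch_size patch edge length in pixels.
#' @param patch_norm_reg,zca_eps,energy_fraction whitening parameters, see
#'   [fit_whitening()].
#' @param n_iter spherical k-means iterations per node.
#' @param stride dense-encoding stride.
#' @param n_random_patches random patches drawn per section for dictionary
#'   learning.
#' @param rng_seed seed controlling patch sampling and k-means initialisation.
#' @return An object of class `strata_model` bundling the whitening model,
#'   dictionary, classifier, parameters and the set of participants whose
#'   sections were used to fit each stage.
#' @seealso [predict.strata_model()], [strata_grid_search()]
#' @export
strata_fit <- function(stacks, labels,
                       n_levels = 3, n_splits = 18, C = 100,
                       downsample_factor = 4, patch_size = 7,
                       patch_norm_reg = 1, zca_eps = 0.1,
                       energy_fraction = 0.95, n_iter = 10,
                       stride = 1, n_random_patches = 100,
                       rng_seed = 1) {
  by_id <- labelled_sections(stacks, labels)
  participants <- sort(unique(vapply(
    by_id[unique(labels$stack_id)], `[[`, "", "participant_id")))
  with_seed(rng_seed, {
    # patch pool for whitening + dictionary, from labelled sections only
    pool <- list()
    for (sid in unique(labels$stack_id)) {
      stk <- by_id[[sid]]
      for (i in labels$section_index[labels$stack_id == sid]) {
        sec <- downsample_section(stk$sections[[i + 1L]], downsample_factor)
        pool[[length(pool) + 1L]] <-
          extract_random_patches(sec, n_random_patches, patch_size)
      }
    }
    pool <- do.call(rbind, pool)
    pool <- normalize_patches(pool, patch_norm_reg)
    whitening <- fit_whitening(pool, zca_eps = zca_eps,
                               energy_fraction = energy_fraction,
                               patch_norm_reg = patch_norm_reg)
    dictionary <- learn_dictionary(apply_whitening(whitening, pool),
                                   n_levels = n_levels, n_splits = n_splits,
                                   n_iter = n_iter)
    # rotation-augmented training encodings (4 examples per section)
    xs <- list(); ys <- list()
    for (sid in unique(labels$stack_id)) {
      sub <- labels[labels$stack_id == sid, ]
      enc <- encode_stack(by_id[[sid]], whitening, dictionary, stride = stride,
                          pool = FALSE, downsample_factor = downsample_factor)
      keep <- enc$meta$section_index %in% sub$section_index
      xs[[sid]] <- enc$x[keep, , drop = FALSE]
      ys[[sid]] <- sub$stratum[match(enc$meta$section_index[keep],
                                     sub$section_index)]
    }
    x <- do.call(rbind, xs)
    y <- do.call(c, lapply(ys, as.character))
    classifier <- train_classifier(x, y, C = C)
    structure(
      list(whitening = whitening, dictionary = dictionary,
           classifier = classifier, participants = participants,
           params = list(n_levels = n_levels, n_splits = n_splits, C = C,
                         downsample_factor = downsample_factor,
                         patch_size = patch_size,
                         patch_norm_reg = patch_norm_reg, zca_eps = zca_eps,
                         energy_fraction = energy_fraction, n_iter = n_iter,
                         stride = stride,
                         n_random_patches = n_random_patches,
                         rng_seed = rng_seed),
           n_train_sections = nrow(labels)),
      class = "strata_model")
  })
}

#' @export
print.strata_model <- function(x, ...) {
  cat(sprintf(
    "<strata_model> %d-level x %d-split dictionary (%d words), C = %g\n",
    x$params$n_levels, x$params$n_splits, n_words(x$dictionary),
    x$params$C))
  cat(sprintf("  trained on %d labelled sections from %d participant(s)\n",
              x$n_train_sections, length(x$participants)))
  invisible(x)
}

#' @export
summary.strata_model <- function(object, ...) {
  print(object)
  print(object$whitening)
  print(object$classifier)
  invisible(object)
}

#' @export
coef.strata_model <- function(object, ...) coef(object$classifier)

#' Predict strata through the depth of stacks
#'
#' Applies the fitted pipeline to new depth stacks. Each section is encoded
#' together with its three right-angle rotations and the four histograms are
#' pooled by averaging before classification, so prediction is deterministic
#' and rotation-stable.
#'
#' @param object a [strata_fit()] model.
#' @param stacks a [depth_stack()] or list of them (raw acquisition scale, as
#'   at fit time).
#' @param ... unused.
#' @return A `strata_prediction` data frame with columns `stack_id`,
#'   `section_index`, `predicted_stratum`, `p_SC`, `p_VE`, `p_DEJ`, `p_PD`.
#'   The spacing of each predicted stack is kept in the
#'   `"spacing_um"` attribute for downstream interface estimation.
#' @export
predict.strata_model <- function(object, stacks, ...) {
  if (inherits(stacks, "depth_stack")) stacks <- list(stacks)
  p <- object$params
  out <- list()
  spacing <- stats::setNames(
    vapply(stacks, `[[`, numeric(1), "spacing_um"),
    vapply(stacks, `[[`, character(1), "stack_id"))
  for (stk in stacks) {
    enc <- encode_stack(stk, object$whitening, object$dictionary,
                        stride = p$stride, pool = TRUE,
                        downsample_factor = p$downsample_factor)
    pr <- predict(object$classifier, enc$x)
    out[[stk$stack_id]] <- data.frame(
      stack_id = enc$meta$stack_id,
      section_index = enc$meta$section_index,
      predicted_stratum = pr$class,
      p_SC = pr$probability[, "SC"], p_VE = pr$probability[, "VE"],
      p_DEJ = pr$probability[, "DEJ"], p_PD = pr$probability[, "PD"],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "spacing_um") <- spacing
  class(res) <- c("strata_prediction", "data.frame")
  res
}

# ---------------------------------------------------------------------------
# Participant-level splitting and model selection

#' Stratified participant holdout split
#'
#' Randomly holds out test participants stratified by age group, so the test
#' set preserves the cohort's age composition. Splitting is always by
#' participant, never by stack or section.
#'
#' @param participant_id character vector of participant ids (one entry per
#'   participant, or per stack — duplicates are collapsed).
#' @param age_group age-group label aligned with `participant_id`.
#' @param test_counts named vector giving the number of test participants per
#'   age group (e.g. `c("20-30" = 8, "50-70" = 10)`), or a single unnamed
#'   fraction in (0, 1) applied to every group (rounded to nearest).
#' @param rng_seed seed; the same seed reproduces the same split.
#' @return List with character vectors `train` and `test` (disjoint, jointly
#'   covering all participants).
#' @export
holdout_split <- function(participant_id, age_group, test_counts,
                          rng_seed = NULL) {
  df <- unique(data.frame(participant_id = as.character(participant_id),
                          age_group = as.character(age_group),
                          stringsAsFactors = FALSE))
  if (anyDuplicated(df$participant_id)) {
    stop("participants mapped to more than one age group")
  }
  groups <- split(df$participant_id, df$age_group)
  if (is.null(names(test_counts))) {
    if (length(test_counts) != 1 || test_counts <= 0 || test_counts >= 1) {
      stop("unnamed test_counts must be a single fraction in (0, 1)")
    }
    test_counts <- stats::setNames(
      vapply(groups, function(g) max(1L, round(length(g) * test_counts)),
             integer(1)), names(groups))
  }
  unknown <- setdiff(names(test_counts), names(groups))
  if (length(unknown)) stop("unknown age group(s): ",
                            paste(unknown, collapse = ", "))
  test <- with_seed(rng_seed, unlist(lapply(names(test_counts), function(g) {
    k <- test_counts[[g]]
    if (k > length(groups[[g]])) {
      stop("requested ", k, " test participants from age group '", g,
           "' but only ", length(groups[[g]]), " available")
    }
    sort(sample(groups[[g]], k))
  }), use.names = FALSE))
  list(train = sort(setdiff(df$participant_id, test)), test = sort(test))
}

# Assign participants to n_folds cross-validation folds, deterministically
# for a given seed. Returns a named integer vector participant -> fold.
make_participant_folds <- function(participants, n_folds, rng_seed = NULL) {
  participants <- sort(unique(as.character(participants)))
  if (length(participants) < n_folds) {
    stop("need at least ", n_folds, " participants for ", n_folds,
         "-fold participant-partitioned CV (got ", length(participants), ")")
  }
  shuffled <- with_seed(rng_seed, sample(participants))
  folds <- stats::setNames(rep(seq_len(n_folds), length.out = length(shuffled)),
                           shuffled)
  folds[order(names(folds))]
}

#' Participant-partitioned cross-validated grid search
#'
#' Selects the dictionary shape and regularisation constant by `n_folds`-fold
#' cross-validation partitioned on participants: for every fold and every
#' `(n_levels, n_splits)` the whitening model and dictionary are re-learned
#' from the fold-training participants only (no leakage), encodings are built
#' once, and each `C` re-trains only the classifier. Validation accuracy is
#' the pooled-rotation per-section accuracy on the fold's held-out
#' participants. The grid point maximising mean accuracy across folds wins;
#' exact ties go to the simplest model (fewest levels, then fewest splits,
#' then smallest `C`).
#'
#' @param stacks list of [depth_stack()]s.
#' @param labels `label_table` covering the training sections.
#' @param levels_grid,splits_grid,C_grid grids to search. Defaults: levels
#'   1-3; splits `{4, 6, ..., 18}` (coarse grid over the 4-18 range); `C`
#'   `10^(0:5)`.
#' @param n_folds number of folds (default 10).
#' @param rng_seed seed for fold assignment and pipeline fits.
#' @param ... further fixed parameters passed to [strata_fit()]
#'   (`downsample_factor`, `stride`, `n_random_patches`, ...).
#' @return Object of class `strata_cv`: `best` (list `n_levels`, `n_splits`,
#'   `C`, `mean_accuracy`), `table` (one row per grid point x fold), `folds`
#'   (participant -> fold map) and `audit` (per-fold record of the
#'   participant id sets used at each fitting stage, see [leakage_audit()]).
#' @export
strata_grid_search <- function(stacks, labels,
                               levels_grid = 1:3,
                               splits_grid = seq(4, 18, by = 2),
                               C_grid = 10^(0:5),
                               n_folds = 10, rng_seed = 1, ...) {
  by_id <- labelled_sections(stacks, labels)
  stack_participant <- vapply(by_id, `[[`, "", "participant_id")
  folds <- make_participant_folds(
    stack_participant[unique(labels$stack_id)], n_folds, rng_seed)
  rows <- list()
  audit <- list()
  fixed <- list(...)
  for (f in seq_len(n_folds)) {
    val_ids <- names(folds)[folds == f]
    train_ids <- names(folds)[folds != f]
    train_stacks <- by_id[stack_participant[names(by_id)] %in% train_ids]
    val_stacks <- by_id[stack_participant[names(by_id)] %in% val_ids]
    train_lab <- labels[labels$stack_id %in% names(train_stacks), ]
    val_lab <- labels[labels$stack_id %in% names(val_stacks), ]
    for (L in levels_grid) for (S in splits_grid) {
      fit <- do.call(strata_fit, c(
        list(stacks = train_stacks, labels = train_lab,
             n_levels = L, n_splits = S, C = C_grid[1],
             rng_seed = rng_seed + f),
        fixed))
      audit[[length(audit) + 1L]] <- data.frame(
        fold = f, n_levels = L, n_splits = S,
        stage = c("whitening", "dictionary", "classifier"),
        train_participants = paste(sort(train_ids), collapse = "|"),
        validation_participants = paste(sort(val_ids), collapse = "|"),
        fitted_on = paste(fit$participants, collapse = "|"),
        stringsAsFactors = FALSE)
      # rebuild training encodings once, then sweep C re-training only the
      # classifier (whitening/dictionary fixed within this grid cell)
      enc_train <- fold_encodings(train_stacks, train_lab, fit, pool = FALSE)
      enc_val <- fold_encodings(val_stacks, val_lab, fit, pool = TRUE)
      for (C in C_grid) {
        clf <- train_classifier(enc_train$x, enc_train$y, C = C)
        pred <- predict(clf, enc_val$x)$class
        acc <- mean(as.character(pred) == as.character(enc_val$y))
        rows[[length(rows) + 1L]] <- data.frame(
          fold = f, n_levels = L, n_splits = S, C = C,
          n_validation_sections = length(enc_val$y),
          accuracy = acc, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(accuracy ~ n_levels + n_splits + C, tab, mean)
  agg <- agg[order(-agg$accuracy, agg$n_levels, agg$n_splits, agg$C), ]
  best <- as.list(agg[1, ])
  names(best)[names(best) == "accuracy"] <- "mean_accuracy"
  structure(list(best = best, table = tab, folds = folds,
                 audit = do.call(rbind, audit)),
            class = "strata_cv")
}

# Encode the labelled sections of a set of stacks with a fitted pipeline.
fold_encodings <- function(stacks, labels, fit, pool) {
  xs <- list(); ys <- list()
  for (sid in unique(labels$stack_id)) {
    sub <- labels[labels$stack_id == sid, ]
    enc <- encode_stack(stacks[[sid]], fit$whitening, fit$dictionary,
                        stride = fit$params$stride, pool = pool,
                        downsample_factor = fit$params$downsample_factor)
    keep <- enc$meta$section_index %in% sub$section_index
    xs[[sid]] <- enc$x[keep, , drop = FALSE]
    ys[[sid]] <- as.character(
      sub$stratum[match(enc$meta$section_index[keep], sub$section_index)])
  }
  list(x = do.call(rbind, xs), y = do.call(c, ys))
}

#' @export
print.strata_cv <- function(x, ...) {
  cat(sprintf(
    "<strata_cv> best: %d level(s) x %d splits, C = %g (mean accuracy %.3f)\n",
    x$best$n_levels, x$best$n_splits, x$best$C, x$best$mean_accuracy))
  cat(sprintf("  %d grid points x %d folds, %d participants\n",
              nrow(unique(x$table[, c("n_levels", "n_splits", "C")])),
              max(x$table$fold), length(x$folds)))
  invisible(x)
}

#' Audit a cross-validation or holdout run for participant leakage
#'
#' Verifies, from the construction records, that no participant contributed
#' to both the fitting side and the evaluation side: for every fold and
#' fitting stage of a [strata_grid_search()] run (or for a fitted
#' [strata_fit()] model against an explicit test-participant set), the
#' participants the stage was fitted on must be disjoint from the evaluation
#' participants.
#'
#' @param object a `strata_cv` or `strata_model`.
#' @param test_participants (for a `strata_model`) the held-out participant
#'   ids.
#' @return `TRUE` if the audit passes; otherwise a data frame of violations,
#'   with one row per (fold, stage) overlap.
#' @export
leakage_audit <- function(object, test_participants = NULL) {
  if (inherits(object, "strata_model")) {
    overlap <- intersect(object$participants, test_participants)
    if (length(overlap) == 0) return(TRUE)
    return(data.frame(stage = "pipeline",
                      overlapping_participants = paste(overlap, collapse = "|"),
                      stringsAsFactors = FALSE))
  }
  stopifnot(inherits(object, "strata_cv"))
  a <- object$audit
  bad <- list()
  for (i in seq_len(nrow(a))) {
    fitted_on <- strsplit(a$fitted_on[i], "|", fixed = TRUE)[[1]]
    val <- strsplit(a$validation_participants[i], "|", fixed = TRUE)[[1]]
    train <- strsplit(a$train_participants[i], "|", fixed = TRUE)[[1]]
    overlap <- intersect(fitted_on, val)
    outside <- setdiff(fitted_on, train)
    if (length(overlap) || length(outside)) {
      bad[[length(bad) + 1L]] <- data.frame(
        fold = a$fold[i], stage = a$stage[i],
        overlapping_participants = paste(union(overlap, outside),
                                         collapse = "|"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(bad) == 0) TRUE else do.call(rbind, bad)
}
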