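# Agreement metrics: confusion matrices, (grouped / per-stack) accuracy,
# interface-depth estimation and interface agreement statistics.

# Align two label sets on (stack_id, section_index); error if coverage differs.
align_labels <- function(reference, compared) {
  as_tab <- function(df, col) {
    if (!is.data.frame(df)) stop("expected a label/prediction data frame")
    lab_col <- intersect(c(col, "stratum", "predicted_stratum"), names(df))[1]
    if (is.na(lab_col)) stop("no label column found")
    data.frame(stack_id = as.character(df$stack_id),
               section_index = as.integer(df$section_index),
               label = as_stratum(df[[lab_col]]), stringsAsFactors = FALSE)
  }
  r <- as_tab(reference, "stratum")
  c_ <- as_tab(compared, "predicted_stratum")
  kr <- paste(r$stack_id, r$section_index)
  kc <- paste(c_$stack_id, c_$section_index)
  if (length(kr) != length(kc) || !setequal(kr, kc) ||
      anyDuplicated(kr) || anyDuplicated(kc)) {
    stop("reference and compared label sets do not cover the same ",
         "(stack_id, section_index) pairs")
  }
  data.frame(stack_id = r$stack_id, section_index = r$section_index,
             reference = r$label, compared = c_$label[match(kr, kc)],
             stringsAsFactors = FALSE)
}

#' Confusion matrix and overall accuracy
#'
#' Cross-tabulates reference against compared labels over the same section
#' coverage. Rows are the reference stratum, columns the compared stratum,
#' both in anatomical order; accuracy is the trace divided by the total.
#' Either argument may be a label table, a prediction table, or (for the
#' two-matrix case) the counts may be supplied directly as a 4x4 matrix via
#' [accuracy_from_confusion()].
#'
#' @param reference,compared data frames with `stack_id`, `section_index` and
#'   a `stratum`/`predicted_stratum` column.
#' @return List with `confusion` (4x4 integer matrix) and `accuracy`.
#' @export
confusion_and_accuracy <- function(reference, compared) {
  al <- align_labels(reference, compared)
  cm <- table(factor(al$reference, levels = strata_levels()),
              factor(al$compared, levels = strata_levels()))
  cm <- matrix(as.integer(cm), 4, 4,
               dimnames = list(reference = strata_levels(),
                               compared = strata_levels()))
  list(confusion = cm, accuracy = sum(diag(cm)) / sum(cm))
}

#' Metrics from a printed confusion matrix
#'
#' Computes the overall agreement and per-reference-stratum (row) accuracies
#' directly from 4x4 confusion counts, e.g. a published table.
#'
#' @param confusion 4x4 numeric matrix, rows = reference stratum, columns =
#'   compared stratum, in order SC, VE, DEJ, PD.
#' @return List with `accuracy` (trace/total), `class_accuracy` (named,
#'   per reference row) and `total` (section count).
#' @export
accuracy_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(all(dim(confusion) == c(4, 4)), all(confusion >= 0))
  list(accuracy = sum(diag(confusion)) / sum(confusion),
       class_accuracy = stats::setNames(diag(confusion) / rowSums(confusion),
                                        strata_levels()),
       total = sum(confusion))
}

#' Accuracy by metadata group
#'
#' Tabulates classification accuracy for combinations of grouping keys, e.g.
#' age group x body site x stratum. Grouping keys may name columns of the
#' per-stack metadata (joined on `stack_id`), the special key `"stratum"`
#' (the reference stratum) or `"stack_id"`.
#'
#' @param reference,predictions as in [confusion_and_accuracy()].
#' @param metadata optional per-stack metadata data frame keyed by
#'   `stack_id`.
#' @param group_keys character vector of grouping keys.
#' @return Data frame with the group columns, `n` (sections) and `accuracy`.
#' @export
grouped_accuracy <- function(reference, predictions, metadata = NULL,
                             group_keys = "stratum") {
  al <- align_labels(reference, predictions)
  al$stratum <- al$reference
  al$correct <- as.character(al$reference) == as.character(al$compared)
  if (!is.null(metadata)) {
    if (!all(al$stack_id %in% metadata$stack_id)) {
      stop("metadata does not cover all stacks")
    }
    al <- merge(al, metadata, by = "stack_id", sort = FALSE,
                suffixes = c("", ".meta"))
  }
  bad <- setdiff(group_keys, names(al))
  if (length(bad)) stop("unknown group key(s): ", paste(bad, collapse = ", "))
  groups <- al[, group_keys, drop = FALSE]
  agg <- stats::aggregate(al$correct, groups,
                          function(z) c(n = length(z), accuracy = mean(z)))
  out <- cbind(agg[, group_keys, drop = FALSE],
               n = as.integer(agg$x[, "n"]), accuracy = agg$x[, "accuracy"])
  out[do.call(order, out[group_keys]), , drop = FALSE]
}

#' Per-stack classification accuracy
#'
#' @inheritParams grouped_accuracy
#' @return Data frame with `stack_id`, `n` and `accuracy`, one row per stack.
#' @export
per_stack_accuracy <- function(reference, predictions) {
  grouped_accuracy(reference, predictions, group_keys = "stack_id")
}

#' Estimate inter-strata interface depths from section labels
#'
#' Interface depths are defined by counting labels, not by locating the first
#' transition: the SC/VE interface lies at `(#SC) * spacing` micrometres below
#' section 0, the VE/DEJ interface at `(#SC + #VE) * spacing`, and the DEJ/PD
#' interface at `(#SC + #VE + #DEJ) * spacing`. Counting makes the estimate
#' well-defined (and order-free) even when a predicted label sequence is not
#' anatomically monotone.
#'
#' @param section_labels strata labels of one stack's sections (any order).
#' @param spacing_um vertical section spacing in micrometres.
#' @return Object of class `interface_depths`: named numeric vector
#'   `c(sc_ve_um, ve_dej_um, dej_pd_um)`.
#' @export
estimate_interfaces <- function(section_labels, spacing_um = 2) {
  if (length(section_labels) == 0) stop("empty stack: no section labels")
  counts <- table(factor(as_stratum(section_labels),
                         levels = strata_levels()))
  d <- cumsum(counts)[c("SC", "VE", "DEJ")] * spacing_um
  structure(stats::setNames(as.numeric(d),
                            c("sc_ve_um", "ve_dej_um", "dej_pd_um")),
            class = "interface_depths")
}

#' @export
print.interface_depths <- function(x, ...) {
  cat(sprintf("SC/VE %.4g um | VE/DEJ %.4g um | DEJ/PD %.4g um\n",
              x["sc_ve_um"], x["ve_dej_um"], x["dej_pd_um"]))
  invisible(x)
}

#' Interface depths for every stack in a prediction or label table
#'
#' @param labels a `label_table` or `strata_prediction`.
#' @param spacing_um section spacing, a single value or a named vector per
#'   stack id.
#' @return Data frame with `stack_id`, `sc_ve_um`, `ve_dej_um`, `dej_pd_um`.
#' @export
interface_table <- function(labels, spacing_um = 2) {
  col <- intersect(c("stratum", "predicted_stratum"), names(labels))[1]
  ids <- unique(labels$stack_id)
  sp <- if (length(spacing_um) == 1 && is.null(names(spacing_um))) {
    stats::setNames(rep(spacing_um, length(ids)), ids)
  } else spacing_um
  rows <- lapply(ids, function(sid) {
    d <- estimate_interfaces(labels[[col]][labels$stack_id == sid], sp[[sid]])
    data.frame(stack_id = sid, sc_ve_um = d[["sc_ve_um"]],
               ve_dej_um = d[["ve_dej_um"]], dej_pd_um = d[["dej_pd_um"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Agreement between automatic and reference interface depths
#'
#' Computes, across stacks, the mean absolute error (micrometres) per
#' interface and pooled over all three interfaces, and the Pearson
#' correlation per interface. A reference interface with zero variance across
#' stacks has no defined correlation and is reported as `NA`.
#'
#' @param auto,reference data frames as returned by [interface_table()]
#'   (matched on `stack_id`).
#' @return List with `mae_um` (named, per interface), `overall_mae_um`,
#'   `pearson_r` (named, per interface) and `n_stacks`.
#' @export
interface_agreement <- function(auto, reference) {
  if (!setequal(auto$stack_id, reference$stack_id)) {
    stop("auto and reference cover different stacks")
  }
  reference <- reference[match(auto$stack_id, reference$stack_id), ]
  cols <- c("sc_ve_um", "ve_dej_um", "dej_pd_um")
  a <- as.matrix(auto[, cols])
  r <- as.matrix(reference[, cols])
  err <- abs(a - r)
  pear <- vapply(cols, function(cl) {
    if (stats::sd(r[, cl]) == 0 || stats::sd(a[, cl]) == 0) return(NA_real_)
    stats::cor(a[, cl], r[, cl])
  }, numeric(1))
  list(mae_um = stats::setNames(colMeans(err), cols),
       overall_mae_um = mean(err),
       pearson_r = pear,
       n_stacks = nrow(auto))
}

#' Strata probability profile through a stack's depth
#'
#' Arranges per-section class probabilities against depth, the form used to
#' visualise how the classifier tracks anatomy through a stack.
#'
#' @param prediction a `strata_prediction` restricted to one stack (or with a
#'   `stack_id` argument selecting one).
#' @param spacing_um section spacing in micrometres.
#' @param stack_id optional stack to select when `prediction` holds several.
#' @return Data frame `depth_um, p_SC, p_VE, p_DEJ, p_PD`, one row per
#'   section in depth order.
#' @export
probability_depth_profile <- function(prediction, spacing_um = 2,
                                      stack_id = NULL) {
  if (!is.null(stack_id)) {
    prediction <- prediction[prediction$stack_id == stack_id, ]
  }
  if (length(unique(prediction$stack_id)) != 1) {
    stop("prediction must cover exactly one stack (use the stack_id argument)")
  }
  prediction <- prediction[order(prediction$section_index), ]
  data.frame(depth_um = prediction$section_index * spacing_um,
             p_SC = prediction$p_SC, p_VE = prediction$p_VE,
             p_DEJ = prediction$p_DEJ, p_PD = prediction$p_PD)
}

#' Reference confusion matrices from the clinical evaluation
#'
#' Bundled 4x4 confusion counts over the 5319-section clinical test set on
#' which the method was originally evaluated: the automated classifier versus
#' the dermatologist's ground-truth labelling, and the dermatologist's first
#' versus second labelling session (intra-observer repeatability). Rows are
#' the ground-truth (second-session) stratum, columns the compared labelling.
#' Useful as worked examples for [accuracy_from_confusion()].
#'
#' @param which `"automatic"` or `"intraobserver"`.
#' @return 4x4 integer matrix with strata dimnames.
#' @export
reference_confusion <- function(which = c("automatic", "intraobserver")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("confusion_", which, ".csv"),
                      package = "rcmstrata", mustWork = TRUE)
  df <- utils::read.csv(path, row.names = 1)
  m <- as.matrix(df)
  dimnames(m) <- list(reference = strata_levels(), compared = strata_levels())
  storage.mode(m) <- "integer"
  m
}
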