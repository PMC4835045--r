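# Reading and writing depth stacks, label tables and prediction tables.
#
# Conventions fixed here and used throughout the package:
#   * section index is 0-based; section 0 is the most superficial section;
#   * the depth of section i is i * spacing_um micrometres below section 0;
#   * pixel values are stored in [0, 1] (integer images are divided by the
#     maximum of their sample type when read).

#' Construct a depth stack
#'
#' A depth stack is an ordered series of en-face grayscale sections acquired
#' at increasing depth, the unit of clinical analysis. Section 0 is the most
#' superficial; consecutive sections are `spacing_um` micrometres apart.
#'
#' @param sections list of numeric matrices (all the same dimensions) with
#'   values in `[0, 1]`, ordered superficial to deep.
#' @param spacing_um vertical distance between consecutive sections in
#'   micrometres (default 2, the usual acquisition spacing).
#' @param stack_id identifier of the stack.
#' @param participant_id,body_site,age_group,phototype optional per-stack
#'   metadata; `body_site` is typically `"dorsal"` or `"volar"`.
#' @return An object of class `depth_stack`.
#' @export
depth_stack <- function(sections, spacing_um = 2, stack_id = "stack",
                        participant_id = NA_character_,
                        body_site = NA_character_,
                        age_group = NA_character_,
                        phototype = NA_character_) {
  if (!is.list(sections) || length(sections) == 0) {
    stop("empty stack: 'sections' must be a non-empty list of matrices")
  }
  if (!all(vapply(sections, is.matrix, logical(1)))) {
    stop("all sections must be numeric matrices")
  }
  dims <- vapply(sections, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("mixed section dimensions within one stack")
  }
  if (!is.numeric(spacing_um) || length(spacing_um) != 1 || spacing_um <= 0) {
    stop("spacing_um must be a single positive number")
  }
  structure(
    list(sections = sections, spacing_um = spacing_um,
         stack_id = as.character(stack_id),
         participant_id = as.character(participant_id),
         body_site = as.character(body_site),
         age_group = as.character(age_group),
         phototype = as.character(phototype)),
    class = "depth_stack")
}

#' @export
print.depth_stack <- function(x, ...) {
  d <- dim(x$sections[[1]])
  cat(sprintf(
    "<depth_stack '%s'> %d sections of %dx%d px, %.3g um spacing (0-%.3g um)\n",
    x$stack_id, length(x$sections), d[1], d[2], x$spacing_um,
    (length(x$sections) - 1) * x$spacing_um))
  if (!is.na(x$participant_id)) {
    cat(sprintf("  participant %s, site %s, age group %s\n",
                x$participant_id, x$body_site, x$age_group))
  }
  invisible(x)
}

#' Number of sections in a stack
#' @param stack a [depth_stack()].
#' @return Integer section count.
#' @export
n_sections <- function(stack) length(stack$sections)

# Coerce one decoded image to a grayscale [0,1] matrix; colour input errors.
as_gray_section <- function(img, where) {
  if (is.array(img) && length(dim(img)) == 3) {
    if (dim(img)[3] == 1) {
      img <- img[, , 1]
    } else {
      stop("colour image in ", where, ": stacks must be grayscale")
    }
  }
  if (!is.matrix(img)) stop("unsupported image content in ", where)
  storage.mode(img) <- "double"
  img
}

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image extension '", ext, "' for ", path,
         " (supported: png, tif/tiff)"))
  as_gray_section(img, path)
}

#' Read a depth stack from disk
#'
#' Reads either a multi-page grayscale TIFF or a directory of single-image
#' PNG/TIFF files (ordered by file name, so zero-padded numbering such as
#' `s00.png ... s49.png` reads in acquisition order). Pixel values are mapped
#' to `[0, 1]` by dividing by the maximum of the integer sample type, so 8-
#' and 16-bit stacks share one scale.
#'
#' @param path multi-page TIFF file or directory of single-image files.
#' @param spacing_um vertical section spacing in micrometres.
#' @param stack_id identifier; defaults to the file/directory base name.
#' @param ... further metadata passed to [depth_stack()].
#' @return A [depth_stack()], sections in superficial-to-deep order.
#' @export
read_stack <- function(path, spacing_um = 2, stack_id = NULL, ...) {
  if (is.null(stack_id)) {
    stack_id <- tools::file_path_sans_ext(basename(path))
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop("empty stack: no images found in ", path)
    sections <- lapply(files, read_one_image)
  } else {
    if (!file.exists(path)) stop("no such file or directory: ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) == 0) stop("empty stack: no pages in ", path)
    sections <- lapply(pages, as_gray_section, where = path)
  }
  depth_stack(sections, spacing_um = spacing_um, stack_id = stack_id, ...)
}

#' Write a depth stack as a multi-page TIFF
#'
#' @param stack a [depth_stack()].
#' @param path output file path.
#' @param bits_per_sample 8 or 16.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits_per_sample = 8) {
  stopifnot(inherits(stack, "depth_stack"))
  tiff::writeTIFF(lapply(stack$sections, clip01), path,
                  bits.per.sample = bits_per_sample)
  invisible(path)
}

#' Read a per-section label table
#'
#' Reads a CSV with header `stack_id,section_index,stratum`. Strata tokens are
#' parsed case-insensitively from `SC, VE, DEJ, PD`. A duplicated
#' `(stack_id, section_index)` pair is an error. Within each stack, labels are
#' expected to be monotone non-decreasing in anatomical order with depth (the
#' single-stratum-per-section ground-truth convention); a violation raises a
#' warning rather than an error, since externally labelled stacks with deep
#' furrows can legitimately mix strata.
#'
#' @param path CSV file path.
#' @return A `label_table` data frame with columns `stack_id` (character),
#'   `section_index` (integer, 0-based) and `stratum` (ordered factor).
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  label_table(df)
}

#' Validate a label table
#'
#' @param df data frame with columns `stack_id`, `section_index`, `stratum`.
#' @return The validated `label_table` (see [read_labels()]).
#' @export
label_table <- function(df) {
  need <- c("stack_id", "section_index", "stratum")
  if (!all(need %in% names(df))) {
    stop("label table must have columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(stack_id = as.character(df$stack_id),
                    section_index = as.integer(df$section_index),
                    stratum = as_stratum(df$stratum),
                    stringsAsFactors = FALSE)
  if (anyNA(out$section_index) || any(out$section_index < 0)) {
    stop("section_index must be a non-negative integer (0-based)")
  }
  key <- paste(out$stack_id, out$section_index)
  if (anyDuplicated(key)) {
    stop("duplicate (stack_id, section_index) label(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  for (sid in unique(out$stack_id)) {
    sub <- out[out$stack_id == sid, ]
    sub <- sub[order(sub$section_index), ]
    if (is.unsorted(as.integer(sub$stratum))) {
      warning("labels for stack '", sid,
              "' are not monotone in anatomical order with depth")
    }
  }
  class(out) <- c("label_table", "data.frame")
  out
}

#' Write a label table as CSV
#' @param labels a `label_table` (see [read_labels()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(
    data.frame(stack_id = labels$stack_id,
               section_index = labels$section_index,
               stratum = as.character(labels$stratum)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-section predictions as CSV
#'
#' Output columns are `stack_id, section_index, predicted_stratum, p_SC, p_VE,
#' p_DEJ, p_PD`, one row per section. Requires a complete prediction set:
#' every stack must cover a contiguous 0-based run of section indices, and the
#' four class probabilities in each row must sum to 1 (tolerance `1e-6`).
#'
#' @param predictions a `strata_prediction` data frame as returned by
#'   [predict.strata_model()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  need <- c("stack_id", "section_index", "predicted_stratum",
            "p_SC", "p_VE", "p_DEJ", "p_PD")
  if (nrow(predictions) == 0) stop("incomplete predictions: empty set")
  if (!all(need %in% names(predictions))) {
    stop("predictions must have columns: ", paste(need, collapse = ", "))
  }
  for (sid in unique(predictions$stack_id)) {
    idx <- sort(predictions$section_index[predictions$stack_id == sid])
    if (!identical(as.integer(idx), seq(0L, length(idx) - 1L))) {
      stop("incomplete predictions: stack '", sid,
           "' is missing sections (indices must cover 0..n-1)")
    }
  }
  psum <- rowSums(predictions[, c("p_SC", "p_VE", "p_DEJ", "p_PD")])
  if (any(abs(psum - 1) > 1e-6)) {
    stop("class probabilities must sum to 1 in every row")
  }
  out <- predictions[, need]
  out$predicted_stratum <- as.character(out$predicted_stratum)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a predictions CSV written by [write_predictions()]
#' @param path CSV file path.
#' @return A `strata_prediction` data frame.
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$predicted_stratum <- as_stratum(df$predicted_stratum)
  class(df) <- c("strata_prediction", "data.frame")
  df
}

#' Read a per-stack metadata table
#'
#' @param path CSV with header
#'   `stack_id,participant_id,body_site,age_group,phototype` (extra columns
#'   are preserved).
#' @return Data frame keyed by `stack_id`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stack_id", "participant_id")
  if (!all(need %in% names(df))) {
    stop("metadata must have at least columns: ", paste(need, collapse = ", "))
  }
  df
}
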