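# Section encoding: dense patches -> normalise -> whiten -> quantize ->
# L2-normalised visual-word histogram, with right-angle rotation augmentation
# for training and rotation pooling for prediction.

#' Rotate an image by a right angle
#' @param image numeric matrix.
#' @param degrees one of 0, 90, 180, 270 (counter-clockwise).
#' @return Rotated matrix.
#' @export
rotate_image <- function(image, degrees) {
  switch(as.character(degrees),
    "0" = image,
    "90" = t(image)[ncol(image):1, , drop = FALSE],
    "180" = image[nrow(image):1, ncol(image):1, drop = FALSE],
    "270" = t(image)[, nrow(image):1, drop = FALSE],
    stop("degrees must be one of 0, 90, 180, 270"))
}

new_encoding <- function(h, stack_id, section_index, rotation) {
  structure(h, stack_id = stack_id, section_index = section_index,
            rotation = rotation, class = "section_encoding")
}

#' @export
print.section_encoding <- function(x, ...) {
  cat(sprintf("<section_encoding> %d words, rotation %s (stack %s, section %s)\n",
              length(x), attr(x, "rotation"),
              attr(x, "stack_id") %||% "?",
              attr(x, "section_index") %||% "?"))
  invisible(x)
}

#' Encode one en-face section as a visual-word histogram
#'
#' Extracts every dense patch, contrast-normalises with the whitening model's
#' `patch_norm_reg`, whitens, quantizes each patch to its visual word and
#' returns the word-count histogram scaled to unit L2 norm (term-frequency
#' normalisation). The section must already be at the working (down-sampled)
#' scale.
#'
#' @param section numeric matrix at the working scale.
#' @param whitening a [fit_whitening()] model.
#' @param dictionary a [learn_dictionary()] object.
#' @param stride dense-extraction stride (default 1 = all patches).
#' @param stack_id,section_index,rotation optional provenance attached to the
#'   encoding.
#' @param quantize_method passed to [quantize()].
#' @return A `section_encoding`: length-`K` unit-L2 numeric vector.
#' @export
encode_section <- function(section, whitening, dictionary, stride = 1,
                           stack_id = NA_character_, section_index = NA_integer_,
                           rotation = "0", quantize_method = "greedy") {
  p <- as.integer(sqrt(whitening$dim))
  patches <- extract_dense_patches(section, patch_size = p, stride = stride)
  patches <- normalize_patches(patches, whitening$patch_norm_reg)
  # fast path: whiten and quantize in the rank-r whitening basis, where the
  # dot products (hence word assignments) equal those of the full ZCA frame
  if (!is.null(whitening$basis)) {
    proj <- whitening_projector(whitening)
    px <- patches %*% proj$P
    px <- px - rep(proj$offset, each = nrow(px))
    plevels <- lapply(dictionary$levels, project_to_basis, model = whitening)
    words <- quantize_core(plevels, dictionary$n_splits, px, quantize_method)
  } else {
    patches <- apply_whitening(whitening, patches)
    words <- quantize(dictionary, patches, method = quantize_method)
  }
  h <- tabulate(words, nbins = n_words(dictionary))
  new_encoding(h / sqrt(sum(h^2)), stack_id, section_index, rotation)
}

#' Encode a section together with its three right-angle rotations
#'
#' Rotation augmentation reduces the rotation variance of the representation:
#' at training time the four encodings are used as independent examples
#' (inheriting the section's label); at prediction time they are pooled with
#' [pool_rotations()].
#'
#' @inheritParams encode_section
#' @return List of 4 `section_encoding`s tagged `"0"`, `"90"`, `"180"`,
#'   `"270"`.
#' @export
encode_with_rotations <- function(section, whitening, dictionary, stride = 1,
                                  stack_id = NA_character_,
                                  section_index = NA_integer_,
                                  quantize_method = "greedy") {
  if (nrow(section) != ncol(section)) {
    stop("rotation augmentation requires a square section")
  }
  lapply(c("0", "90", "180", "270"), function(rot) {
    encode_section(rotate_image(section, as.numeric(rot)),
                   whitening, dictionary, stride = stride,
                   stack_id = stack_id, section_index = section_index,
                   rotation = rot, quantize_method = quantize_method)
  })
}

#' Pool rotation encodings into one prediction-time encoding
#'
#' Averages the four rotation histograms element-wise and rescales the result
#' to unit L2 norm, so pooled test vectors live on the same sphere as the
#' training vectors (set `renormalize = FALSE` for the plain average).
#'
#' @param encodings list of 4 `section_encoding`s of the same section.
#' @param renormalize rescale the mean to unit L2 norm (default `TRUE`).
#' @return A `section_encoding` with `rotation = "POOLED"`.
#' @export
pool_rotations <- function(encodings, renormalize = TRUE) {
  if (length(encodings) != 4) stop("expected 4 rotation encodings")
  ids <- unique(vapply(encodings, function(e)
    paste(attr(e, "stack_id"), attr(e, "section_index")), character(1)))
  if (length(ids) != 1) {
    stop("cannot pool encodings from different sections: ",
         paste(ids, collapse = " vs "))
  }
  if (length(unique(lengths(encodings))) != 1) {
    stop("cannot pool encodings of different dictionary sizes")
  }
  h <- Reduce(`+`, lapply(encodings, as.numeric)) / 4
  if (renormalize) h <- h / sqrt(sum(h^2))
  new_encoding(h, attr(encodings[[1]], "stack_id"),
               attr(encodings[[1]], "section_index"), "POOLED")
}

#' Encode every section of a stack
#'
#' Batch encoder used by the fitting and prediction paths. With
#' `pool = TRUE` (prediction) each section yields one pooled row; with
#' `pool = FALSE` (training) each section yields four rows, one per rotation.
#'
#' @param stack a [depth_stack()] whose sections are at the working scale.
#' @inheritParams encode_section
#' @param pool pool rotations (`TRUE`) or keep them as separate rows.
#' @param downsample_factor decimation applied to each section before
#'   encoding (1 = sections already at the working scale).
#' @return List with `x` (matrix, rows = encodings, columns = words) and
#'   `meta` (data frame `stack_id`, `section_index`, `rotation`).
#' @export
encode_stack <- function(stack, whitening, dictionary, stride = 1,
                         pool = TRUE, downsample_factor = 1,
                         quantize_method = "greedy") {
  stopifnot(inherits(stack, "depth_stack"))
  rows <- list()
  meta <- list()
  for (i in seq_along(stack$sections)) {
    sec <- downsample_section(stack$sections[[i]], downsample_factor)
    encs <- encode_with_rotations(sec, whitening, dictionary, stride = stride,
                                  stack_id = stack$stack_id,
                                  section_index = i - 1L,
                                  quantize_method = quantize_method)
    if (pool) encs <- list(pool_rotations(encs))
    for (e in encs) {
      rows[[length(rows) + 1L]] <- as.numeric(e)
      meta[[length(meta) + 1L]] <- data.frame(
        stack_id = attr(e, "stack_id"),
        section_index = attr(e, "section_index"),
        rotation = attr(e, "rotation"), stringsAsFactors = FALSE)
    }
  }
  list(x = do.call(rbind, rows), meta = do.call(rbind, meta))
}
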