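# Patch-level feature extraction: anti-aliased down-sampling, random and
# dense patch extraction, per-patch contrast normalisation.

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Decimation matrix for one axis: each output sample is a truncated-sinc
# (Lanczos) weighted average of input samples centred on its block. Rows are
# renormalised to sum to 1, which preserves constants exactly (also at the
# borders, where the kernel is clipped).
lanczos_decimation_matrix <- function(n_in, factor, lobes = 3) {
  n_out <- n_in %/% factor
  D <- matrix(0, n_out, n_in)
  half <- lobes * factor
  for (m in seq_len(n_out)) {
    center <- (m - 1) * factor + (factor + 1) / 2
    lo <- max(1L, ceiling(center - half))
    hi <- min(n_in, floor(center + half))
    d <- (lo:hi) - center
    w <- sinc(d / factor) * sinc(d / half)
    D[m, lo:hi] <- w / sum(w)
  }
  D
}

#' Down-sample an en-face section with a truncated-sinc pre-filter
#'
#' Reduces an image by an integer factor per axis after low-pass filtering
#' with a truncated-sinc (Lanczos, 3 lobes) kernel to limit aliasing. A
#' 1000x1000 px acquisition at factor 4 becomes the 250x250 px working scale
#' (2 um per pixel) at which patches are extracted. Dimensions not divisible
#' by the factor are cropped (top-left) to the largest multiple first.
#'
#' @param image numeric matrix.
#' @param factor integer decimation factor per axis (>= 1); 1 returns the
#'   input unchanged.
#' @param lobes number of sinc lobes retained by the truncation (default 3).
#' @return The filtered, decimated matrix.
#' @export
downsample_section <- function(image, factor = 4, lobes = 3) {
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1 ||
      factor != round(factor)) {
    stop("factor must be a single integer >= 1")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  h <- nrow(image) %/% factor * factor
  w <- ncol(image) %/% factor * factor
  if (h < factor || w < factor) stop("image smaller than decimation factor")
  image <- image[seq_len(h), seq_len(w), drop = FALSE]
  Dr <- lanczos_decimation_matrix(h, factor, lobes)
  Dc <- if (w == h) Dr else lanczos_decimation_matrix(w, factor, lobes)
  Dr %*% image %*% t(Dc)
}

# Assemble an n x p^2 patch matrix from top-left corners (r, c), 1-based.
# Each patch is vectorised column-major, consistently everywhere.
gather_patches <- function(section, rows, cols, patch_size) {
  p <- patch_size
  out <- matrix(0, length(rows), p * p)
  j <- 0L
  for (dc in 0:(p - 1L)) {
    for (dr in 0:(p - 1L)) {
      j <- j + 1L
      out[, j] <- section[cbind(rows + dr, cols + dc)]
    }
  }
  attr(out, "patch_size") <- p
  out
}

#' Extract patches at random locations
#'
#' Samples `n_patches` top-left positions uniformly (with replacement) among
#' all positions where the full patch lies in bounds. Used to collect the
#' patch pool for whitening and dictionary learning.
#'
#' @param section numeric matrix (already down-sampled).
#' @param n_patches number of patches to draw.
#' @param patch_size patch edge length in pixels (default 7).
#' @param rng_seed optional integer seed; the same seed reproduces the same
#'   patch set. `NULL` draws from the current RNG stream.
#' @return Numeric matrix of `n_patches` rows, each a flattened
#'   `patch_size^2` pixel vector.
#' @export
extract_random_patches <- function(section, n_patches, patch_size = 7,
                                   rng_seed = NULL) {
  p <- patch_size
  if (nrow(section) < p || ncol(section) < p) {
    stop("section (", nrow(section), "x", ncol(section),
         ") is smaller than the patch size ", p)
  }
  with_seed(rng_seed, {
    r <- sample.int(nrow(section) - p + 1L, n_patches, replace = TRUE)
    cc <- sample.int(ncol(section) - p + 1L, n_patches, replace = TRUE)
    gather_patches(section, r, cc, p)
  })
}

#' Extract all patches in a dense sliding window
#'
#' Extracts the patch at every position whose row and column offsets are
#' multiples of `stride` and whose full extent lies in bounds, in row-major
#' order. For a `W x W` section with patch edge `p` and stride 1 this yields
#' `(W - p + 1)^2` patches (59,536 for 250x250 px, p = 7).
#'
#' @inheritParams extract_random_patches
#' @param stride step between consecutive window positions (>= 1).
#' @return Numeric patch matrix as in [extract_random_patches()].
#' @export
extract_dense_patches <- function(section, patch_size = 7, stride = 1) {
  p <- patch_size
  if (stride < 1) stop("stride must be >= 1")
  if (nrow(section) < p || ncol(section) < p) {
    stop("section (", nrow(section), "x", ncol(section),
         ") is smaller than the patch size ", p)
  }
  rows <- seq.int(1L, nrow(section) - p + 1L, by = stride)
  cols <- seq.int(1L, ncol(section) - p + 1L, by = stride)
  gather_patches(section,
                 rep(rows, each = length(cols)),
                 rep(cols, times = length(rows)), p)
}

#' Contrast-normalise patches
#'
#' Maps each patch `x` to `(x - mean(x)) / sqrt(var(x) + patch_norm_reg)`,
#' with the mean and (population, 1/N) variance taken over the patch's own
#' pixels. The regulariser keeps low-variance patches finite: a constant
#' patch maps to the zero vector. The default of 1 is deliberately small so
#' that already well-contrasted patches are barely altered.
#'
#' @param patches numeric patch matrix (rows = patches).
#' @param patch_norm_reg variance regulariser added under the square root.
#' @return Patch matrix of the same shape, each row with zero mean.
#' @export
normalize_patches <- function(patches, patch_norm_reg = 1) {
  m <- .rowMeans(patches, nrow(patches), ncol(patches))
  v <- .rowMeans(patches * patches, nrow(patches), ncol(patches)) - m * m
  v[v < 0] <- 0
  # length-n vectors recycle down columns, i.e. per patch (row)
  out <- (patches - m) / sqrt(v + patch_norm_reg)
  attr(out, "patch_size") <- attr(patches, "patch_size")
  out
}
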