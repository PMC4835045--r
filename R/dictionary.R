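# Visual dictionary: spherical k-means and the hierarchical vocabulary tree.
#
# Internally word ids are 1-based (R convention); a dictionary with n_levels
# levels and n_splits children per node has K = n_splits^n_levels leaves,
# identified with the rows of the deepest centroid matrix.

#' Spherical k-means
#'
#' Clusters unit vectors by cosine similarity: a fixed number of alternating
#' steps of (a) assigning each vector to the centroid with the largest dot
#' product and (b) replacing each centroid by the L2-normalised sum of its
#' assigned vectors. Initial centroids are `k` distinct input vectors sampled
#' without replacement. Input rows are L2-normalised first; zero rows map to
#' the first basis vector by convention. An empty cluster is re-seeded with
#' the input vector least well represented by the current centroids (lowest
#' maximum cosine).
#'
#' @param x numeric matrix, rows are vectors to cluster.
#' @param k number of centroids (>= 1; at most the number of distinct rows).
#' @param n_iter fixed iteration count (default 10; few iterations suffice in
#'   practice, and a fixed count keeps runs reproducible).
#' @param rng_seed optional seed for initial centroid sampling; `NULL` uses
#'   the current RNG stream.
#' @return `k x d` matrix of unit-norm centroids, with attributes
#'   `objective` (sum of maximal cosines after each assignment step) and
#'   `assignment` (final cluster index per row).
#' @export
spherical_kmeans <- function(x, k, n_iter = 10, rng_seed = NULL) {
  x <- l2_normalize_rows(x)
  ux <- unique(x)
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(ux)) {
    stop("degenerate initialisation: k = ", k, " exceeds the number of ",
         "distinct vectors (", nrow(ux), ")")
  }
  centroids <- with_seed(rng_seed,
    ux[sample.int(nrow(ux), k, replace = FALSE), , drop = FALSE])
  objective <- numeric(n_iter)
  assign_idx <- rep(1L, nrow(x))
  for (it in seq_len(n_iter)) {
    sim <- x %*% t(centroids)
    assign_idx <- max.col(sim, ties.method = "first")
    best <- sim[cbind(seq_len(nrow(x)), assign_idx)]
    objective[it] <- sum(best)
    sums <- rowsum(x, factor(assign_idx, levels = seq_len(k)))
    nrm <- sqrt(rowSums(sums^2))
    counts <- tabulate(assign_idx, nbins = k)
    for (j in seq_len(k)) {
      if (counts[j] > 0 && nrm[j] > 1e-12) {
        centroids[j, ] <- sums[j, ] / nrm[j]
      } else if (counts[j] == 0) {
        far <- which.min(best)
        centroids[j, ] <- x[far, ]
        best[far] <- Inf  # don't reuse the same vector for another empty cluster
      }
      # a non-empty cluster whose vectors cancel exactly keeps its centroid
    }
  }
  attr(centroids, "objective") <- objective
  attr(centroids, "assignment") <- assign_idx
  centroids
}

#' Learn a hierarchical spherical k-means dictionary
#'
#' Clusters the whitened patch pool into `n_splits` groups, then recursively
#' re-clusters each group into `n_splits` subgroups until `n_levels` levels
#' exist; patches are L2-normalised before clustering at every level. The
#' leaves of the resulting complete `n_splits`-ary tree are the
#' `K = n_splits^n_levels` visual words. A node holding fewer patches than
#' `n_splits` (or fewer distinct directions) fills its whole subtree with
#' copies of its own centroid, so `K` is fixed regardless of the data.
#'
#' @param patches whitened patch matrix (rows = patches).
#' @param n_levels tree depth (typically 1-3).
#' @param n_splits branching factor per level (>= 2; typically 4-18).
#' @param n_iter spherical k-means iterations per node.
#' @param rng_seed optional seed making the whole hierarchy reproducible.
#' @return An object of class `visual_dictionary`: `n_levels`, `n_splits`,
#'   `dim`, and `levels` — a list of centroid matrices, one per level in
#'   level order (`n_splits^l` rows at level `l`); the last is the leaf/word
#'   matrix.
#' @export
learn_dictionary <- function(patches, n_levels, n_splits, n_iter = 10,
                             rng_seed = NULL) {
  if (n_levels < 1) stop("n_levels must be >= 1")
  if (n_splits < 2) stop("n_splits must be >= 2")
  x <- l2_normalize_rows(patches)
  with_seed(rng_seed, {
    levels <- vector("list", n_levels)
    # membership of each patch at the current level's nodes
    node_of <- rep(1L, nrow(x))
    parent_centroid <- matrix(l2_normalize_rows(t(colMeans(x))), 1)
    for (l in seq_len(n_levels)) {
      n_parents <- n_splits^(l - 1)
      cent <- matrix(0, n_parents * n_splits, ncol(x))
      child_of <- integer(nrow(x))
      for (j in seq_len(n_parents)) {
        rows <- which(node_of == j)
        slot <- (j - 1L) * n_splits + seq_len(n_splits)
        sub <- x[rows, , drop = FALSE]
        n_distinct <- if (length(rows)) nrow(unique(sub)) else 0L
        if (n_distinct >= n_splits) {
          cc <- spherical_kmeans(sub, n_splits, n_iter, rng_seed = NULL)
          cent[slot, ] <- cc
          child_of[rows] <- (j - 1L) * n_splits +
            attr(cc, "assignment")
        } else {
          # under-populated node: replicate the parent centroid downwards
          cent[slot, ] <- matrix(parent_centroid[j, ], n_splits,
                                 ncol(x), byrow = TRUE)
          if (length(rows)) child_of[rows] <- (j - 1L) * n_splits + 1L
        }
      }
      levels[[l]] <- cent
      node_of <- child_of
      parent_centroid <- cent
    }
    structure(list(n_levels = as.integer(n_levels),
                   n_splits = as.integer(n_splits),
                   dim = ncol(x), levels = levels),
              class = "visual_dictionary")
  })
}

#' Number of visual words in a dictionary
#' @param dictionary a [learn_dictionary()] object.
#' @return Integer `n_splits^n_levels`.
#' @export
n_words <- function(dictionary) {
  as.integer(dictionary$n_splits^dictionary$n_levels)
}

#' @export
print.visual_dictionary <- function(x, ...) {
  cat(sprintf("<visual_dictionary> %d level(s) x %d splits = %d words (dim %d)\n",
              x$n_levels, x$n_splits, n_words(x), x$dim))
  invisible(x)
}

#' Quantize whitened patches to visual words
#'
#' Maps each patch to a word id in `1..K`. The default greedy descent picks,
#' at every tree level, the child centroid with the largest cosine similarity
#' (ties broken towards the lowest child index; a zero patch therefore follows
#' the all-lowest-index path). `method = "exhaustive"` instead searches all
#' leaf centroids directly; for a one-level dictionary the two are identical.
#'
#' @param dictionary a [learn_dictionary()] object.
#' @param patches whitened patch matrix (rows = patches) or a single vector.
#' @param method `"greedy"` (tree descent, the fast default) or
#'   `"exhaustive"` (argmax cosine over all leaves).
#' @return Integer vector of word ids in `1..n_words(dictionary)`.
#' @export
quantize <- function(dictionary, patches,
                     method = c("greedy", "exhaustive")) {
  method <- match.arg(method)
  if (is.null(dim(patches))) patches <- matrix(patches, 1)
  if (ncol(patches) != dictionary$dim) {
    stop("patch dimension ", ncol(patches),
         " does not match dictionary dimension ", dictionary$dim)
  }
  quantize_core(dictionary$levels, dictionary$n_splits, patches, method)
}

# Shared quantization kernel. `levels` may hold the dictionary's native
# centroids or their coordinates in the whitening basis (the encoder's fast
# path): dot products, argmaxes and tie-breaks are identical in either frame.
quantize_core <- function(levels, ns, patches, method) {
  # cosine argmax == dot-product argmax: centroids are unit norm and the
  # patch norm is a per-row constant
  n_levels <- length(levels)
  if (method == "exhaustive") {
    sim <- patches %*% t(levels[[n_levels]])
    return(max.col(sim, ties.method = "first"))
  }
  node <- max.col(patches %*% t(levels[[1]]), ties.method = "first")
  if (n_levels > 1) {
    for (l in 2:n_levels) {
      cent <- levels[[l]]
      new_node <- integer(length(node))
      for (j in unique(node)) {
        rows <- which(node == j)
        slot <- (j - 1L) * ns + seq_len(ns)
        sim <- patches[rows, , drop = FALSE] %*% t(cent[slot, , drop = FALSE])
        new_node[rows] <- (j - 1L) * ns + max.col(sim, ties.method = "first")
      }
      node <- new_node
    }
  }
  node
}
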