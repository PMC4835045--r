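# Regularised ZCA whitening learned from the pooled normalised patches and
# applied identically at dictionary-learning and encoding time.

#' Fit a regularised ZCA whitening transform
#'
#' Eigendecomposes the sample covariance (population, 1/N convention) of the
#' contrast-normalised patches, retains the smallest number of leading
#' eigenpairs whose eigenvalue sum reaches `energy_fraction` of the total
#' (negative eigenvalues from numerical noise are clipped to 0 first), and
#' builds the symmetric zero-component-analysis transform
#' `W = V_r diag(1/sqrt(lambda_r + eps)) V_r'`. Truncating the low-energy
#' axes before regularising avoids numerical instability from near-null
#' directions; `eps` then damps the retained low-variance axes.
#'
#' @param patches contrast-normalised patch matrix (rows = patches).
#' @param zca_eps eigenvalue regulariser `eps` (default 0.1, the usual choice
#'   for small image patches).
#' @param energy_fraction fraction of total spectral energy to retain
#'   (default 0.95).
#' @param patch_norm_reg the contrast-normalisation regulariser the patches
#'   were prepared with; stored so the model can be re-applied consistently.
#' @return An object of class `whitening_model` with elements `mean`
#'   (length-d centring vector), `W` (symmetric d x d transform of rank `rank`),
#'   `eigenvalues`, `rank`, `zca_eps`, `energy_fraction`, `patch_norm_reg`.
#' @export
fit_whitening <- function(patches, zca_eps = 0.1, energy_fraction = 0.95,
                          patch_norm_reg = 1) {
  x <- as.matrix(patches)
  n <- nrow(x)
  d <- ncol(x)
  if (n < d) {
    warning("fewer patches (", n, ") than patch dimension (", d,
            "): covariance is rank deficient")
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  covm <- crossprod(xc) / n
  eg <- eigen(covm, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  total <- sum(vals)
  r <- if (total <= 0) 1L else {
    which(cumsum(vals) >= energy_fraction * total - 1e-12)[1]
  }
  Vr <- eg$vectors[, seq_len(r), drop = FALSE]
  lr <- vals[seq_len(r)]
  W <- Vr %*% (t(Vr) / sqrt(lr + zca_eps))
  structure(
    list(mean = mu, W = W, eigenvalues = vals, rank = as.integer(r),
         basis = Vr, scale = 1 / sqrt(lr + zca_eps),
         zca_eps = zca_eps, energy_fraction = energy_fraction,
         patch_norm_reg = patch_norm_reg, dim = d),
    class = "whitening_model")
}

#' @export
print.whitening_model <- function(x, ...) {
  cat(sprintf(
    "<whitening_model> dim %d, rank %d (%.0f%% energy), eps %.3g, patch reg %.3g\n",
    x$dim, x$rank, 100 * x$energy_fraction, x$zca_eps, x$patch_norm_reg))
  invisible(x)
}

#' Apply a fitted whitening transform
#'
#' Maps each patch `x` to `W (x - mean)`. Patches must have been
#' contrast-normalised with the same `patch_norm_reg` used at fit time.
#'
#' @param model a [fit_whitening()] model.
#' @param patches contrast-normalised patch matrix.
#' @return Whitened patch matrix of the same shape.
#' @export
apply_whitening <- function(model, patches) {
  stopifnot(inherits(model, "whitening_model"))
  x <- as.matrix(patches)
  if (ncol(x) != model$dim) {
    stop("patch dimension ", ncol(x), " does not match the whitening model (",
         model$dim, ")")
  }
  # (x - 1 mu') W == x W - 1 (mu' W): avoids materialising the centred copy
  out <- x %*% model$W
  mw <- drop(model$mean %*% model$W)
  out <- out - rep(mw, each = nrow(out))
  attr(out, "patch_size") <- attr(patches, "patch_size")
  out
}

# Rank-r factorisation of the whitening step, used by the encoder's fast
# path: with W = V diag(s) V', the cosine geometry of whitened patches is
# preserved in the r-dimensional coordinates  x %*% V diag(s)  (V has
# orthonormal columns), so quantization can run in r <= d dimensions with
# identical argmax results.
whitening_projector <- function(model) {
  P <- model$basis * rep(model$scale, each = nrow(model$basis))
  list(P = P, offset = drop(model$mean %*% P))
}

# project whitened d-dim vectors (e.g. dictionary centroids) into the same
# r-dim coordinates: for v in the retained subspace, coordinates are V'v
project_to_basis <- function(model, x) x %*% model$basis

#' Save / load pipeline artifacts
#'
#' Whitening models, dictionaries, classifiers and fitted pipelines are plain
#' R lists; they are serialised with [saveRDS()] into a single archive file so
#' the identical transform is reused between training and test time.
#'
#' @param object object to save.
#' @param path file path (conventionally `.rds`).
#' @return `path` invisibly, or the restored object for `load_artifact()`.
#' @export
save_artifact <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_artifact
#' @export
load_artifact <- function(path) {
  if (!file.exists(path)) {
    stop("missing artifact: ", path,
         " (run the producing stage first)")
  }
  readRDS(path)
}
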