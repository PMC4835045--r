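# Internal helpers shared across the pipeline.

#' Anatomical strata labels
#'
#' The four en-face strata recognised by the pipeline, in canonical
#' superficial-to-deep order: stratum corneum (`SC`), viable epidermis (`VE`),
#' dermal-epidermal junction (`DEJ`) and papillary dermis (`PD`). All label
#' columns and probability columns in the package follow this order.
#'
#' @return Character vector `c("SC", "VE", "DEJ", "PD")`.
#' @export
strata_levels <- function() c("SC", "VE", "DEJ", "PD")

#' Parse strata labels
#'
#' Converts a character (or factor) vector of strata tokens to an ordered
#' factor over [strata_levels()]. Matching is case-insensitive; any other
#' token is an error.
#'
#' @param x character or factor vector of labels.
#' @return Factor with levels `SC < VE < DEJ < PD` (ordered).
#' @export
as_stratum <- function(x) {
  tok <- toupper(trimws(as.character(x)))
  bad <- !tok %in% strata_levels()
  if (any(bad)) {
    stop("unknown stratum token(s): ",
         paste(unique(tok[bad]), collapse = ", "),
         " (expected one of SC, VE, DEJ, PD)")
  }
  factor(tok, levels = strata_levels(), ordered = TRUE)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Row-wise L2 normalisation. Rows with norm below `tol` are mapped to the
# first basis vector, the designated direction for degenerate (flat) patches.
l2_normalize_rows <- function(x, tol = 1e-12) {
  x <- as.matrix(x)
  nrm <- sqrt(rowSums(x^2))
  zero <- nrm < tol
  nrm[zero] <- 1
  y <- x / nrm
  if (any(zero)) {
    y[zero, ] <- 0
    y[zero, 1] <- 1
  }
  y
}

scale01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] < .Machine$double.eps) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Periodic Gaussian blur via FFT; adequate for stationary noise fields.
blur_fft <- function(img, sigma) {
  if (sigma <= 0) return(img)
  h <- nrow(img); w <- ncol(img)
  fy <- c(0:floor(h / 2), -(ceiling(h / 2) - 1):-1)[1:h] / h
  fx <- c(0:floor(w / 2), -(ceiling(w / 2) - 1):-1)[1:w] / w
  gy <- exp(-2 * pi^2 * sigma^2 * fy^2)
  gx <- exp(-2 * pi^2 * sigma^2 * fx^2)
  Re(stats::fft(stats::fft(img) * outer(gy, gx), inverse = TRUE)) / (h * w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
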