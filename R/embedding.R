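#' Diffusion-map embedding of samples
#'
#' Nonlinear spectral embedding for developmental staging. A Gaussian kernel
#' \eqn{K_{ij} = \exp(-d_{ij}^2 / 2\sigma^2)} is computed on Euclidean
#' distances between samples, density-normalized with anisotropy exponent 1
#' (\eqn{\tilde K = K / (p_i p_j)} with \eqn{p} the kernel row sums), and
#' row-normalized to a stochastic transition matrix. Diffusion components
#' (DCs) are the eigenvectors of this matrix belonging to the largest
#' non-unit eigenvalues; samples that are transcriptionally similar receive
#' nearby coordinates and the leading component typically orders samples
#' along developmental progression.
#'
#' @param x Numeric matrix, samples x features (e.g. variance-stabilized
#'   expression of dynamic genes, transposed to samples-in-rows), no NAs, at
#'   least 3 samples.
#' @param n_components Number of diffusion components (< number of samples).
#' @param bandwidth Kernel width \eqn{\sigma}: a positive number or `"auto"`
#'   (median of nonzero pairwise distances).
#' @param stage Optional per-sample stage labels (ordered factor or character
#'   in stage order); used only to orient each component's sign so that its
#'   correlation with stage order is nonnegative. Without it, each component
#'   is oriented so its first nonzero loading is positive.
#' @return Object of class `diffusion_map`: list with `coordinates` (samples
#'   x DCs), `eigenvalues` (descending, unit eigenvalue excluded),
#'   `bandwidth`, `transition` (the stochastic matrix), `sample_ids`.
#' @examples
#' x <- matrix(rnorm(60), nrow = 12)
#' dm <- diffusion_map(x, n_components = 2)
#' head(dm$coordinates)
#' @export
diffusion_map <- function(x, n_components = 3, bandwidth = "auto",
                          stage = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) abort("`x` must not contain missing values.")
  n <- nrow(x)
  if (n < 3) abort("At least 3 samples are required.")
  if (n_components >= n) {
    abort("`n_components` must be smaller than the number of samples.")
  }
  d <- as.matrix(dist(x))
  if (identical(bandwidth, "auto")) {
    nz <- d[upper.tri(d)]
    nz <- nz[nz > 0]
    if (length(nz) == 0) abort("All samples are identical; bandwidth undefined.")
    sigma <- median(nz)
  } else {
    sigma <- bandwidth
    if (!is.numeric(sigma) || sigma <= 0) abort("`bandwidth` must be positive.")
  }
  k <- exp(-d^2 / (2 * sigma^2))
  p <- rowSums(k)
  k1 <- k / tcrossprod(p)                  # anisotropy exponent 1
  dd <- rowSums(k1)
  trans <- k1 / dd
  # symmetric conjugate for a stable eigendecomposition
  a <- k1 / tcrossprod(sqrt(dd))
  eig <- eigen(a, symmetric = TRUE)
  phi <- eig$vectors / sqrt(dd)            # right eigenvectors of `trans`
  idx <- 2:(n_components + 1)
  coords <- phi[, idx, drop = FALSE]
  evals <- eig$values[idx]
  # unit-normalize and orient
  for (j in seq_len(ncol(coords))) {
    coords[, j] <- coords[, j] / sqrt(sum(coords[, j]^2))
    s <- component_sign(coords[, j], stage)
    coords[, j] <- coords[, j] * s
  }
  ids <- rownames(x) %||% paste0("sample", seq_len(n))
  dimnames(coords) <- list(ids, paste0("DC", seq_len(ncol(coords))))
  dimnames(trans) <- list(ids, ids)
  structure(list(coordinates = coords, eigenvalues = evals,
                 bandwidth = sigma, transition = trans, sample_ids = ids),
            class = "diffusion_map")
}

component_sign <- function(v, stage) {
  if (!is.null(stage)) {
    ord <- if (is.factor(stage)) as.numeric(stage) else
      match(stage, unique(stage))
    r <- suppressWarnings(cor(v, ord, method = "spearman"))
    if (is.finite(r) && r != 0) return(sign(r))
  }
  nz <- v[abs(v) > .Machine$double.eps^0.5]
  if (length(nz) == 0) 1 else sign(nz[1])
}

#' @export
print.diffusion_map <- function(x, ...) {
  cat("<diffusion_map> ", length(x$sample_ids), " samples, ",
      ncol(x$coordinates), " components; bandwidth ",
      signif(x$bandwidth, 4), "\n", sep = "")
  cat("  eigenvalues:", signif(x$eigenvalues, 4), "\n")
  invisible(x)
}
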