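#' Median-of-ratios size factors
#'
#' Estimates one positive scale factor per sample as the median, over genes
#' expressed in every sample, of the ratio of the sample's count to the
#' gene's geometric mean across samples. Genes with a zero count in any sample
#' are excluded from the reference set. The estimator is defined only up to a
#' constant, so factors are rescaled to geometric mean 1.
#'
#' @param counts Integer matrix, genes x samples (or a `sim_experiment`).
#' @return Named numeric vector of positive size factors, geometric mean 1.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' size_factors(m)
#' @export
size_factors <- function(counts) {
  counts <- as_count_matrix(counts)
  logc <- log(counts)
  loggeo <- rowMeans(logc)
  use <- is.finite(loggeo)                 # genes nonzero in all samples
  if (!any(use)) {
    abort("No gene has nonzero counts in every sample; size factors are undefined.")
  }
  sf <- apply(logc[use, , drop = FALSE], 2,
              function(col) exp(median(col - loggeo[use])))
  sf / exp(mean(log(sf)))
}

#' Fragments per kilobase of exon per million mapped fragments
#'
#' \eqn{\mathrm{FPKM}_{ij} = c_{ij} / \big((L_i/10^3)(N_j/10^6)\big)} with
#' \eqn{L_i} the exonic length in bp and \eqn{N_j} the per-sample total
#' fragment count (defaulting to the column sum of the analyzed matrix).
#'
#' @param counts Integer matrix, genes x samples (or a `sim_experiment`).
#' @param lengths Named numeric vector or tibble (`gene_id`, `length_bp`) of
#'   exonic lengths (> 0) covering every gene.
#' @param totals Optional per-sample total mapped fragments (> 0).
#' @return Numeric matrix of FPKM values, same dimensions as `counts`.
#' @export
fpkm <- function(counts, lengths = NULL, totals = NULL) {
  if (inherits(counts, "sim_experiment") && is.null(lengths)) {
    lengths <- setNames(counts$genes$length_bp, counts$genes$gene_id)
  }
  counts <- as_count_matrix(counts)
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length_bp, lengths$gene_id)
  }
  if (is.null(lengths) || !all(rownames(counts) %in% names(lengths))) {
    abort("`lengths` must cover every gene in the matrix.")
  }
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) abort("Gene lengths must be strictly positive.")
  if (is.null(totals)) totals <- colSums(counts)
  if (any(totals <= 0)) abort("Per-sample totals must be positive.")
  sweep(sweep(counts, 1, len / 1e3, `/`), 2, totals / 1e6, `/`)
}

#' Variance-stabilizing transformation for NB counts
#'
#' On size-factor-normalized counts \eqn{x}, applies the closed form of the
#' variance-stabilizing integral \eqn{\int_0^x d\mu/\sqrt{\mu + \alpha\mu^2}}
#' for a common dispersion \eqn{\alpha}:
#' \eqn{\mathrm{VST}(x) = (2/\sqrt{\alpha})\,\mathrm{asinh}(\sqrt{\alpha x})},
#' with the limit \eqn{2\sqrt{x}} at \eqn{\alpha = 0}. The transform is
#' strictly increasing and maps 0 to 0; on NB data with dispersion
#' \eqn{\alpha} the variance of transformed replicates is approximately
#' constant across the mean range.
#'
#' @param counts Integer matrix, genes x samples (or a `sim_experiment`).
#' @param factors Size factors; default [size_factors()] of the matrix.
#' @param alpha Common NB dispersion (>= 0); default estimated by
#'   [estimate_common_dispersion()].
#' @param condition Optional per-sample grouping used when estimating `alpha`.
#' @return Matrix of variance-stabilized values.
#' @export
vst <- function(counts, factors = NULL, alpha = NULL, condition = NULL) {
  counts <- as_count_matrix(counts)
  if (is.null(factors)) factors <- size_factors(counts)
  if (any(factors <= 0)) abort("Size factors must be positive.")
  if (is.null(alpha)) {
    alpha <- estimate_common_dispersion(counts, factors, condition)
  }
  if (alpha < 0) abort("`alpha` must be >= 0.")
  x <- sweep(counts, 2, factors, `/`)
  vst_values(x, alpha)
}

#' @rdname vst
#' @param x Nonnegative normalized counts.
#' @export
vst_values <- function(x, alpha) {
  if (alpha < 0) abort("`alpha` must be >= 0.")
  if (alpha == 0) return(2 * sqrt(x))
  (2 / sqrt(alpha)) * asinh(sqrt(alpha * x))
}

#' Pooled method-of-moments common dispersion
#'
#' For each gene with replication, computes the within-group mean and variance
#' of normalized counts and the moment estimate
#' \eqn{\alpha_i = (v_i - \mu_i \overline{1/s}) / \mu_i^2}; the common value is
#' the median over genes, floored at 1e-8.
#'
#' @inheritParams vst
#' @return A single dispersion value.
#' @export
estimate_common_dispersion <- function(counts, factors = NULL,
                                       condition = NULL) {
  counts <- as_count_matrix(counts)
  if (is.null(factors)) factors <- size_factors(counts)
  if (is.null(condition)) condition <- rep("all", ncol(counts))
  mom <- dispersion_moments(counts, factors, condition)
  est <- (mom$v - mom$mu * mom$zbar) / mom$mu^2
  est <- est[is.finite(est)]
  if (length(est) == 0) return(1e-8)
  max(median(est), 1e-8)
}

#' Per-sample detection rate
#'
#' Fraction of annotated genes whose expression exceeds a floor, per sample.
#' The default floor of 0 counts a gene as detected if any fragment was
#' observed; `threshold = 10` on an FPKM layer gives the robust-detection
#' variant.
#'
#' @param expr Numeric matrix, genes x samples (counts, FPKM, ...).
#' @param threshold Expression floor; a gene is detected if value > threshold.
#' @return Tibble with `sample_id` and `detection_rate` between 0 and 1.
#' @export
detection_rate <- function(expr, threshold = 0) {
  expr <- as_expr_matrix(expr)
  tibble(sample_id = colnames(expr),
         detection_rate = unname(colMeans(expr > threshold)))
}

#' Mean-relative (stage-scaled) expression
#'
#' Averages replicates within stage, log-transforms with a pseudocount, and
#' centers each gene on its cross-stage mean:
#' \eqn{r_{is} = \log_b(\bar e_{is} + c) - \mathrm{mean}_s \log_b(\bar e_{is} + c)}.
#' Positive values mark stages where the gene is preferentially expressed;
#' each gene's row sums to zero across stages.
#'
#' @param expr Numeric matrix, genes x samples (typically FPKM).
#' @param stages Per-sample stage labels (character or factor, length =
#'   ncol(expr)). Stage order follows factor levels or first appearance.
#' @param log_base Logarithm base (default 2).
#' @param pseudocount Added before the log (default 1).
#' @return Numeric matrix, genes x stages, rows summing to zero.
#' @export
scale_to_stage_mean <- function(expr, stages, log_base = 2, pseudocount = 1) {
  expr <- as_expr_matrix(expr)
  if (length(stages) != ncol(expr)) {
    abort("`stages` must label every sample (column).")
  }
  if (!is.factor(stages)) stages <- factor(stages, levels = unique(stages))
  stages <- droplevels(stages)
  if (nlevels(stages) < 2) {
    abort("At least two stages are required to compute relative expression.")
  }
  sm <- stage_mean(expr, stages)
  lg <- log(sm + pseudocount) / log(log_base)
  lg - rowMeans(lg)
}

#' Stage-mean expression (replicates averaged within stage)
#'
#' @inheritParams scale_to_stage_mean
#' @return Numeric matrix, genes x stages.
#' @export
stage_mean <- function(expr, stages) {
  expr <- as_expr_matrix(expr)
  if (!is.factor(stages)) stages <- factor(stages, levels = unique(stages))
  stages <- droplevels(stages)
  out <- vapply(levels(stages), function(s) {
    rowMeans(expr[, stages == s, drop = FALSE])
  }, numeric(nrow(expr)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(expr))
  dimnames(out) <- list(rownames(expr), levels(stages))
  out
}

# internal -------------------------------------------------------------------

as_count_matrix <- function(x) {
  if (inherits(x, "sim_experiment")) x <- x$counts
  if (!is.matrix(x)) x <- as.matrix(x)
  if (any(x < 0)) abort("Counts must be nonnegative.")
  x
}

as_expr_matrix <- function(x) {
  if (inherits(x, "sim_experiment")) x <- x$counts
  if (!is.matrix(x)) x <- as.matrix(x)
  x
}

dispersion_moments <- function(counts, factors, condition) {
  condition <- as.character(condition)
  x <- sweep(counts, 2, factors, `/`)
  groups <- split(seq_len(ncol(x)), condition)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  if (length(groups) == 0) {
    abort(paste0("No condition has >= 2 replicates; dispersion cannot be ",
                 "estimated. Supply `alpha` explicitly."))
  }
  idx <- unlist(groups, use.names = FALSE)
  ss <- 0; mu_num <- 0
  df <- sum(vapply(groups, length, integer(1)) - 1)
  for (g in groups) {
    xg <- x[, g, drop = FALSE]
    mg <- rowMeans(xg)
    ss <- ss + rowSums((xg - mg)^2)
  }
  v <- ss / df
  mu <- rowMeans(x[, idx, drop = FALSE])
  zbar <- mean(1 / factors[idx])
  list(mu = mu, v = v, zbar = zbar)
}
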