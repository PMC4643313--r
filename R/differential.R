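#' Per-gene NB dispersion with trend regularization
#'
#' Gene-wise dispersions are estimated by the method of moments on
#' size-factor-normalized counts, pooling within-condition variances:
#' \eqn{\hat\alpha_i = (v_i - \mu_i \overline{1/s})/\mu_i^2}. A mean-dispersion
#' trend \eqn{\alpha(\mu) = a_0 + a_1/\mu} is then fitted across genes by a
#' gamma-family regression, and each gene's working dispersion is the maximum
#' of its own estimate and the trend value (a conservative sharing rule),
#' floored at 1e-8.
#'
#' @param counts Integer matrix, genes x samples (or `sim_experiment`).
#' @param factors Size factors (default [size_factors()]).
#' @param condition Per-sample condition labels; at least one condition needs
#'   two or more replicates.
#' @return Tibble with `gene_id`, `base_mean`, `dispersion_gene`,
#'   `dispersion_trend`, `dispersion`.
#' @export
estimate_dispersion <- function(counts, factors = NULL, condition = NULL) {
  if (inherits(counts, "sim_experiment") && is.null(condition)) {
    condition <- counts$samples$stage
  }
  counts <- as_count_matrix(counts)
  if (is.null(factors)) factors <- size_factors(counts)
  if (is.null(condition)) abort("`condition` is required.")
  mom <- dispersion_moments(counts, factors, condition)
  raw <- (mom$v - mom$mu * mom$zbar) / mom$mu^2
  raw[!is.finite(raw)] <- 1e-8             # constant / all-zero genes
  raw <- pmax(raw, 1e-8)
  trend <- fit_dispersion_trend(mom$mu, raw)
  tibble(gene_id = rownames(counts) %||% sprintf("gene%05d", seq_along(raw)),
         base_mean = unname(mom$mu),
         dispersion_gene = unname(raw),
         dispersion_trend = unname(trend),
         dispersion = pmax(unname(raw), unname(trend), 1e-8))
}

fit_dispersion_trend <- function(mu, raw) {
  use <- is.finite(mu) & mu > 1e-3 & raw > 1e-7
  if (sum(use) < 10) {
    fallback <- if (any(use)) median(raw[use]) else 1e-8
    return(rep(max(fallback, 1e-8), length(mu)))
  }
  dat <- data.frame(a = raw[use], im = 1 / mu[use])
  fit <- tryCatch(
    glm(a ~ im, data = dat, family = Gamma(link = "identity"),
        start = c(median(dat$a), 1)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    fit <- tryCatch(
      suppressWarnings(glm(a ~ im, data = dat,
                           family = Gamma(link = "identity"),
                           start = c(median(dat$a), 1))),
      error = function(e) NULL)
  }
  if (is.null(fit)) return(rep(max(median(dat$a), 1e-8), length(mu)))
  co <- pmax(coef(fit), 0)
  tr <- co[1] + co[2] / mu
  tr[!is.finite(tr)] <- max(co[1], 1e-8)
  pmax(tr, 1e-8)
}

#' Exact conditioned NB test for a two-group contrast
#'
#' For each gene the counts in the two groups are summed; under the null
#' hypothesis of a shared normalized mean, each group sum is negative binomial
#' with mean proportional to the group's summed size factors and an effective
#' size derived from the per-sample dispersion. Conditioning on the observed
#' overall total \eqn{T}, the two-sided p-value is the probability of all
#' splits \eqn{(a, T-a)} whose conditional probability does not exceed that of
#' the observed split. Fold changes are computed from size-factor-normalized
#' group means with a pseudocount.
#'
#' @param counts Integer matrix, genes x samples (or `sim_experiment`).
#' @param factors Size factors.
#' @param dispersion Per-gene dispersion vector (recycled if scalar), e.g.
#'   the `dispersion` column of [estimate_dispersion()].
#' @param condition Per-sample condition labels.
#' @param contrast Length-2 character vector `c(A, B)`; fold change is
#'   reported as log2 of B relative to A.
#' @param pseudocount Added to normalized means before the log ratio.
#' @return Tibble (`nb_de` rows): `gene_id`, `contrast_a`, `contrast_b`,
#'   `base_mean_a`, `base_mean_b`, `log2fc`, `pval`, `padj` (BH across genes).
#' @examples
#' m <- matrix(rpois(80, 20), nrow = 10)
#' rownames(m) <- paste0("g", 1:10)
#' colnames(m) <- paste0("s", 1:8)
#' grp <- rep(c("A", "B"), each = 4)
#' nb_exact_test(m, rep(1, 8), 0.1, grp, c("A", "B"))
#' @export
nb_exact_test <- function(counts, factors = NULL, dispersion = 0.1,
                          condition = NULL, contrast = NULL,
                          pseudocount = 1) {
  if (inherits(counts, "sim_experiment") && is.null(condition)) {
    condition <- counts$samples$stage
  }
  counts <- as_count_matrix(counts)
  if (is.null(factors)) factors <- size_factors(counts)
  condition <- as.character(condition)
  if (is.null(contrast) || length(contrast) != 2) {
    abort("`contrast` must name two conditions, c(A, B).")
  }
  missing <- setdiff(contrast, condition)
  if (length(missing) > 0) {
    abort(paste0("Unknown condition label(s) in contrast: ",
                 paste(missing, collapse = ", ")))
  }
  ia <- which(condition == contrast[1])
  ib <- which(condition == contrast[2])
  if (is.data.frame(dispersion)) dispersion <- dispersion$dispersion
  disp <- rep_len(dispersion, nrow(counts))
  sa <- factors[ia]; sb <- factors[ib]
  SA <- sum(sa); SB <- sum(sb)
  ka <- as.numeric(rowSums(counts[, ia, drop = FALSE]))
  kb <- as.numeric(rowSums(counts[, ib, drop = FALSE]))
  pv <- vapply(seq_len(nrow(counts)), function(i) {
    nb_exact_pval(ka[i], kb[i], SA, SB, sum(sa^2), sum(sb^2), disp[i])
  }, numeric(1))
  mean_a <- rowMeans(sweep(counts[, ia, drop = FALSE], 2, sa, `/`))
  mean_b <- rowMeans(sweep(counts[, ib, drop = FALSE], 2, sb, `/`))
  res <- tibble(
    gene_id = rownames(counts) %||% sprintf("gene%05d", seq_along(pv)),
    contrast_a = contrast[1], contrast_b = contrast[2],
    base_mean_a = unname(mean_a), base_mean_b = unname(mean_b),
    log2fc = unname(log2(mean_b + pseudocount) - log2(mean_a + pseudocount)),
    pval = pv)
  res$log2fc[mean_a == 0 & mean_b == 0] <- 0
  res$padj <- bh_adjust(res$pval)
  res
}

# Conditional two-sided p for one gene. ka, kb: group sums; SA, SB: summed
# size factors; SA2, SB2: summed squared factors; alpha: dispersion.
nb_exact_pval <- function(ka, kb, SA, SB, SA2, SB2, alpha) {
  total <- ka + kb
  if (total == 0) return(1)
  q <- total / (SA + SB)
  mu_a <- q * SA; mu_b <- q * SB
  a <- 0:total
  if (alpha <= 1e-12) {
    lp <- dpois(a, mu_a, log = TRUE) + dpois(total - a, mu_b, log = TRUE)
  } else {
    size_a <- SA^2 / (alpha * SA2)
    size_b <- SB^2 / (alpha * SB2)
    lp <- dnbinom(a, mu = mu_a, size = size_a, log = TRUE) +
      dnbinom(total - a, mu = mu_b, size = size_b, log = TRUE)
  }
  lobs <- lp[ka + 1]
  if (!is.finite(lobs)) return(1)
  keep <- lp <= lobs + 1e-7
  # normalize within the conditional distribution
  m <- max(lp)
  exp_lp <- exp(lp - m)
  min(sum(exp_lp[keep]) / sum(exp_lp), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Validated step-up false-discovery-rate correction (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param pvals Numeric vector of p-values between 0 and 1 (NA allowed).
#' @return Adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvals, method = "BH")
}

#' All pairwise stage contrasts
#'
#' Runs [nb_exact_test()] for every unordered pair of condition labels (in
#' level order) and row-binds the results; BH adjustment is applied within
#' each contrast.
#'
#' @inheritParams nb_exact_test
#' @return Tibble of DE rows for all contrasts.
#' @export
de_all_pairs <- function(counts, factors = NULL, dispersion = 0.1,
                         condition = NULL, pseudocount = 1) {
  if (inherits(counts, "sim_experiment") && is.null(condition)) {
    condition <- counts$samples$stage
  }
  levels <- if (is.factor(condition)) levels(droplevels(condition)) else unique(as.character(condition))
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  bind_rows(lapply(pairs, function(pr) {
    nb_exact_test(counts, factors, dispersion, condition, pr, pseudocount)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
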