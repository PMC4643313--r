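#' DAPI-normalize per-cell channel intensities
#'
#' Divides each marker channel (NANOG, GATA6, CDX2) by the same cell's DAPI
#' intensity, making calls invariant to cell-wise staining and illumination
#' scale. Cells with missing or non-positive DAPI are dropped and counted.
#'
#' @param cells Tibble with columns `cell_id`, `embryo_id`, `treatment`,
#'   `nanog`, `gata6`, `cdx2`, `dapi` (see [simulate_if_cells()] /
#'   [read_cells()]).
#' @return The table with added `nanog_norm`, `gata6_norm`, `cdx2_norm`
#'   columns; attribute `n_dropped` counts removed cells.
#' @export
normalize_cells <- function(cells) {
  req <- c("cell_id", "embryo_id", "treatment", "nanog", "gata6", "cdx2",
           "dapi")
  if (!all(req %in% names(cells))) {
    abort(paste0("`cells` must contain columns: ",
                 paste(req, collapse = ", ")))
  }
  bad <- is.na(cells$dapi) | cells$dapi <= 0
  if (any(bad)) {
    inform(sprintf("Dropped %d cell(s) with missing or non-positive DAPI.",
                   sum(bad)))
  }
  out <- cells[!bad, , drop = FALSE]
  out$nanog_norm <- out$nanog / out$dapi
  out$gata6_norm <- out$gata6 / out$dapi
  out$cdx2_norm <- out$cdx2 / out$dapi
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' Otsu threshold of a numeric vector
#'
#' The threshold maximizing the between-class variance
#' \eqn{w_1 w_2 (m_1 - m_2)^2} over candidate cuts at midpoints between
#' consecutive sorted unique values. With fewer than two distinct values the
#' maximum value itself is returned (so that a strict `>` comparison calls
#' every observation negative).
#'
#' @param x Numeric vector.
#' @return A single threshold.
#' @export
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  u <- sort(unique(x))
  if (length(u) < 2) return(if (length(u)) u else NA_real_)
  cand <- (u[-1] + u[-length(u)]) / 2
  n <- length(x)
  best <- -Inf; thr <- cand[1]
  xs <- sort(x)
  csum <- cumsum(xs)
  for (tc in cand) {
    n1 <- sum(xs <= tc)
    m1 <- csum[n1] / n1
    m2 <- (csum[n] - csum[n1]) / (n - n1)
    bcv <- (n1 / n) * ((n - n1) / n) * (m1 - m2)^2
    if (bcv > best + 1e-15) { best <- bcv; thr <- tc }
  }
  thr
}

#' Call marker positivity per cell
#'
#' Thresholds a normalized channel to a boolean call. The default rule fits
#' an Otsu threshold to each embryo's (log-scale) intensity distribution,
#' since absolute staining levels vary between embryos; fixed-threshold and
#' quantile rules are available. Embryos with fewer than 3 cells fall back to
#' a global threshold with a warning. Comparison is strict (`value >
#' threshold`).
#'
#' @param cells Normalized cell table (see [normalize_cells()]).
#' @param channel One of `"nanog"`, `"gata6"`, `"cdx2"`; the
#'   `<channel>_norm` column is thresholded.
#' @param method `"otsu"` (default, per embryo), `"fixed"`, or `"quantile"`.
#' @param threshold Threshold for `method = "fixed"`.
#' @param prob Probability for `method = "quantile"` (per embryo).
#' @param log Apply the Otsu rule on log10 intensities (default TRUE;
#'   immunofluorescence intensities are closer to log-normal).
#' @return The table with an added `<channel>_pos` logical column; attribute
#'   `thresholds` records the threshold used per embryo.
#' @export
call_positive <- function(cells, channel = c("nanog", "gata6", "cdx2"),
                          method = c("otsu", "fixed", "quantile"),
                          threshold = NULL, prob = 0.75, log = TRUE) {
  channel <- match.arg(channel)
  method <- match.arg(method)
  col <- paste0(channel, "_norm")
  if (!col %in% names(cells)) {
    abort(paste0("Column `", col, "` not found; run normalize_cells() first."))
  }
  v <- cells[[col]]
  tf <- if (log) function(z) log10(z + 1e-12) else identity
  if (method == "fixed") {
    if (is.null(threshold)) abort("`threshold` is required for the fixed rule.")
    cells[[paste0(channel, "_pos")]] <- v > threshold
    attr(cells, "thresholds") <- tibble(embryo_id = "(all)",
                                        threshold = threshold)
    return(cells)
  }
  thr_fun <- if (method == "otsu") {
    function(z) otsu_threshold(tf(z))
  } else {
    function(z) quantile(tf(z), prob, names = FALSE)
  }
  global_thr <- thr_fun(v)
  embryos <- split(seq_along(v), cells$embryo_id)
  thr <- vapply(embryos, function(ix) {
    if (length(ix) < 3) {
      warn(sprintf("Embryo with %d cell(s): using global %s threshold.",
                   length(ix), channel))
      global_thr
    } else {
      thr_fun(v[ix])
    }
  }, numeric(1))
  pos <- logical(length(v))
  for (e in names(embryos)) {
    ix <- embryos[[e]]
    pos[ix] <- tf(v[ix]) > thr[e]
  }
  cells[[paste0(channel, "_pos")]] <- pos
  attr(cells, "thresholds") <- tibble(embryo_id = names(thr),
                                      threshold = unname(thr))
  cells
}

#' Classify cells into lineage classes and flag NANOG-high cells
#'
#' From NANOG and GATA6 positivity: `NANOG-only` (N+/G-), `GATA6-only`
#' (G+/N-), `coexpressing` (N+/G+), `double-negative` otherwise -- mutually
#' exclusive and exhaustive. A cell is `nanog_high` when it is NANOG-positive
#' and its normalized NANOG intensity is at least `high_factor` times the
#' average normalized NANOG over all cells of the reference scope (inclusive
#' comparison).
#'
#' @param cells Cell table with `nanog_pos`, `gata6_pos` and `nanog_norm`
#'   columns (see [call_positive()]).
#' @param high_factor NANOG-high multiplier (default 1.5).
#' @param high_scope Reference for the average: `"embryo"` (default) or
#'   `"treatment"`.
#' @return The table with `class` (factor) and `nanog_high` columns.
#' @export
classify_lineage <- function(cells, high_factor = 1.5,
                             high_scope = c("embryo", "treatment")) {
  high_scope <- match.arg(high_scope)
  req <- c("nanog_pos", "gata6_pos", "nanog_norm")
  if (!all(req %in% names(cells))) {
    abort("Run call_positive() for NANOG and GATA6 first.")
  }
  cls <- with(cells, ifelse(nanog_pos & !gata6_pos, "NANOG-only",
                     ifelse(gata6_pos & !nanog_pos, "GATA6-only",
                     ifelse(nanog_pos & gata6_pos, "coexpressing",
                            "double-negative"))))
  cells$class <- factor(cls, levels = c("NANOG-only", "GATA6-only",
                                        "coexpressing", "double-negative"))
  scope <- if (high_scope == "embryo") cells$embryo_id else cells$treatment
  ref <- stats::ave(cells$nanog_norm, scope, FUN = mean)
  cells$nanog_high <- cells$nanog_pos &
    cells$nanog_norm >= high_factor * ref
  cells
}

#' Per-embryo lineage-class proportions
#'
#' Counts and fractions of each lineage class and of NANOG-high cells per
#' embryo (the experimental unit), with the treatment label carried along.
#'
#' @param calls Classified cell table from [classify_lineage()].
#' @return Tibble with one row per embryo: `embryo_id`, `treatment`,
#'   `n_cells`, per-class counts (`n_*`) and fractions (`frac_*`), and
#'   `frac_nanog_high`. Fractions over the four classes sum to 1.
#' @export
embryo_proportions <- function(calls) {
  if (!"class" %in% names(calls)) abort("Run classify_lineage() first.")
  calls %>%
    group_by(.data$embryo_id, .data$treatment) %>%
    summarise(
      n_cells = n(),
      n_nanog_only = sum(.data$class == "NANOG-only"),
      n_gata6_only = sum(.data$class == "GATA6-only"),
      n_coexpressing = sum(.data$class == "coexpressing"),
      n_double_negative = sum(.data$class == "double-negative"),
      n_nanog_high = sum(.data$nanog_high),
      .groups = "drop") %>%
    mutate(
      frac_nanog_only = .data$n_nanog_only / .data$n_cells,
      frac_gata6_only = .data$n_gata6_only / .data$n_cells,
      frac_coexpressing = .data$n_coexpressing / .data$n_cells,
      frac_double_negative = .data$n_double_negative / .data$n_cells,
      frac_nanog_high = .data$n_nanog_high / .data$n_cells)
}

#' Treatment-level summary of per-embryo statistics
#'
#' @param props Per-embryo table from [embryo_proportions()].
#' @param stat Column to summarise (default `frac_nanog_only`).
#' @return Tibble with `treatment`, `n_embryos`, `mean`, `sd`.
#' @export
treatment_summary <- function(props, stat = "frac_nanog_only") {
  props %>%
    group_by(.data$treatment) %>%
    summarise(n_embryos = n(),
              mean = mean(.data[[stat]]),
              sd = sd(.data[[stat]]),
              .groups = "drop")
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Fixed-effects one-way ANOVA of a per-embryo statistic across treatment
#' groups, with all pairwise comparisons adjusted by Tukey's honest
#' significant difference (studentized-range distribution on the within-group
#' degrees of freedom). Intended for per-embryo fractions so the embryo, not
#' the cell, is the experimental unit.
#'
#' Degenerate inputs are handled explicitly: if all groups have identical
#' values the F statistic is 0 and all p-values 1; if within-group variance
#' is zero but means differ, the overall and pairwise p-values are floored at
#' 1e-15.
#'
#' @param data Data frame of per-group observations.
#' @param value Column (unquoted or string) holding the statistic.
#' @param group Column (unquoted or string) holding the group label.
#' @return Object of class `anova_tukey`: list with `f_statistic`,
#'   `p_overall`, `df_between`, `df_within`, `comparisons` (tibble `pair`,
#'   `group_a`, `group_b`, `diff`, `lwr`, `upr`, `p_adj`), `group_means`.
#' @examples
#' d <- data.frame(g = rep(c("a", "b", "c"), each = 4),
#'                 y = c(rnorm(4), rnorm(4, 1), rnorm(4, 2)))
#' fit <- anova_tukey(d, y, g)
#' glance(fit)
#' @export
anova_tukey <- function(data, value, group) {
  vq <- enquo(value); gq <- enquo(group)
  vname <- as_name(vq); gname <- as_name(gq)
  y <- data[[vname]]
  g <- factor(data[[gname]])
  if (nlevels(g) < 2) abort("At least two groups are required.")
  sizes <- table(g)
  if (any(sizes < 2)) {
    abort(paste0("Every group needs >= 2 observations; offending group(s): ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  d <- data.frame(y = y, g = g)
  fit <- aov(y ~ g, data = d)
  an <- summary(fit)[[1]]
  ssb <- an[["Sum Sq"]][1]; ssw <- an[["Sum Sq"]][2]
  dfb <- an[["Df"]][1]; dfw <- an[["Df"]][2]
  means <- tapply(y, g, mean)
  if (ssw <= .Machine$double.eps * sum(y^2 + 1)) {
    if (ssb <= .Machine$double.eps * sum(y^2 + 1)) {
      # all values identical
      f <- 0; p <- 1
      cmp <- pairwise_frame(means, p_adj = 1, lwr = 0, upr = 0)
    } else {
      f <- Inf; p <- 1e-15
      cmp <- pairwise_frame(means, p_adj = 1e-15)
      cmp$p_adj[cmp$diff == 0] <- 1
    }
  } else {
    f <- an[["F value"]][1]
    p <- an[["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$g
    nm <- rownames(tk)
    parts <- strsplit(nm, "-", fixed = TRUE)
    cmp <- tibble(
      pair = nm,
      group_a = vapply(parts, `[`, "", 2),
      group_b = vapply(parts, `[`, "", 1),
      diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
      p_adj = pmin(pmax(tk[, "p adj"], 0), 1))
  }
  structure(list(f_statistic = f, p_overall = p, df_between = dfb,
                 df_within = dfw, comparisons = cmp,
                 group_means = tibble(group = names(means),
                                      mean = as.numeric(means),
                                      n = as.integer(sizes)),
                 value = vname, group = gname),
            class = "anova_tukey")
}

pairwise_frame <- function(means, p_adj, lwr = NA_real_, upr = NA_real_) {
  nm <- names(means)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  bind_rows(lapply(pairs, function(pr) {
    tibble(pair = paste(pr[2], pr[1], sep = "-"),
           group_a = pr[1], group_b = pr[2],
           diff = unname(means[pr[2]] - means[pr[1]]),
           lwr = lwr, upr = upr, p_adj = p_adj)
  }))
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat("<anova_tukey> F(", x$df_between, ", ", x$df_within, ") = ",
      signif(x$f_statistic, 4), ", p = ", format.pval(x$p_overall, digits = 3),
      "\n", sep = "")
  print(x$comparisons)
  invisible(x)
}
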