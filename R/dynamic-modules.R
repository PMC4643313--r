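#' Select dynamically expressed genes
#'
#' A gene is dynamic if it is (a) differentially expressed between at least
#' two stages -- significant in at least `min_contrasts` pairwise contrasts at
#' level `alpha` -- and (b) robustly detected, with stage-mean FPKM exceeding
#' `fpkm_min` in at least one stage.
#'
#' @param de Tibble of pairwise DE results as produced by [de_all_pairs()]
#'   (columns `gene_id`, `contrast_a`, `contrast_b`, `pval`, `padj`). All
#'   stage pairs of the design must be present.
#' @param stage_fpkm Numeric matrix of stage-mean FPKM (genes x stages), e.g.
#'   `stage_mean(fpkm(...), stages)`.
#' @param alpha Significance level on `p_col` (default 0.05).
#' @param fpkm_min Robust-detection floor (default 10; a gene qualifies with
#'   stage-mean FPKM strictly greater than this in >= 1 stage).
#' @param p_col Which p-value column gates significance, `"padj"` (default)
#'   or `"pval"`.
#' @param min_contrasts Minimum number of significant pairwise contrasts
#'   (default 1, i.e. differential between at least two stages).
#' @return Tibble with `gene_id`, `n_sig_contrasts`, `max_stage_fpkm`,
#'   `dynamic`.
#' @export
select_dynamic_genes <- function(de, stage_fpkm, alpha = 0.05, fpkm_min = 10,
                                 p_col = c("padj", "pval"),
                                 min_contrasts = 1) {
  p_col <- match.arg(p_col)
  stages <- colnames(stage_fpkm)
  expected <- utils::combn(stages, 2, simplify = FALSE)
  have <- unique(paste(de$contrast_a, de$contrast_b, sep = "\r"))
  have <- c(have, unique(paste(de$contrast_b, de$contrast_a, sep = "\r")))
  missing <- expected[!vapply(expected, function(pr) {
    paste(pr[1], pr[2], sep = "\r") %in% have
  }, logical(1))]
  if (length(missing) > 0) {
    abort(paste0("DE results are missing contrast(s): ",
                 paste(vapply(missing, paste, "", collapse = " vs "),
                       collapse = "; ")))
  }
  sig <- de %>%
    group_by(.data$gene_id) %>%
    summarise(n_sig_contrasts = sum(.data[[p_col]] < alpha, na.rm = TRUE),
              .groups = "drop")
  fp <- tibble(gene_id = rownames(stage_fpkm),
               max_stage_fpkm = apply(stage_fpkm, 1, max))
  out <- left_join(fp, sig, by = "gene_id")
  out$n_sig_contrasts[is.na(out$n_sig_contrasts)] <- 0L
  out$dynamic <- out$n_sig_contrasts >= min_contrasts &
    out$max_stage_fpkm > fpkm_min
  out[, c("gene_id", "n_sig_contrasts", "max_stage_fpkm", "dynamic")]
}

#' Expression modules by hierarchical clustering of scaled profiles
#'
#' Clusters dynamic genes on their mean-relative stage profiles. The default
#' distance is 1 minus the Pearson correlation between profiles (grouping by
#' shape, so modules read as "maximally expressed in morulae" etc.) with
#' average linkage; the tree is cut into exactly `k` clusters (or at height
#' `h`). Module labels are renumbered contiguously in dendrogram leaf order so
#' the labeling is deterministic.
#'
#' @param rel_expr Numeric matrix, genes x stages, of mean-relative expression
#'   (rows centered; see [scale_to_stage_mean()]), restricted to the dynamic
#'   genes.
#' @param k Number of modules (default 10). Ignored when `h` is given.
#' @param distance `"pearson"` (1 - correlation) or `"euclidean"`.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param h Optional height cut instead of a count cut.
#' @return Object of class `module_assignment`: list with `assignment`
#'   (tibble `gene_id`, `module`, `leaf_order`), `hclust`, `k`, `distance`,
#'   `linkage`, `rel_expr`.
#' @export
cluster_modules <- function(rel_expr, k = 10,
                            distance = c("pearson", "euclidean"),
                            linkage = "average", h = NULL) {
  distance <- match.arg(distance)
  if (is.null(rownames(rel_expr))) {
    abort("`rel_expr` needs gene identifiers as row names.")
  }
  n <- nrow(rel_expr)
  if (is.null(h) && k > n) {
    abort(sprintf("Cannot cut %d genes into %d modules.", n, k))
  }
  if (distance == "pearson") {
    cc <- suppressWarnings(cor(t(rel_expr)))
    cc[!is.finite(cc)] <- -1               # zero-variance rows: maximal distance
    diag(cc) <- 1
    d <- as.dist(1 - cc)
  } else {
    d <- dist(rel_expr)
  }
  hc <- hclust(d, method = linkage)
  labels_raw <- if (is.null(h)) cutree(hc, k = k) else cutree(hc, h = h)
  k_eff <- length(unique(labels_raw))
  # relabel 1..k in dendrogram leaf order
  leaf_genes <- rownames(rel_expr)[hc$order]
  first_seen <- labels_raw[leaf_genes]
  map <- setNames(seq_len(k_eff), unique(first_seen))
  module <- unname(map[as.character(labels_raw)])
  assignment <- tibble(
    gene_id = rownames(rel_expr),
    module = as.integer(module),
    leaf_order = match(rownames(rel_expr), leaf_genes))
  structure(list(assignment = assignment, hclust = hc, k = k_eff,
                 distance = distance, linkage = linkage,
                 rel_expr = rel_expr),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat("<module_assignment> ", nrow(x$assignment), " genes in ", x$k,
      " modules (", x$distance, " distance, ", x$linkage, " linkage)\n",
      sep = "")
  print(dplyr::count(x$assignment, .data$module))
  invisible(x)
}

#' Adjusted Rand index between a module assignment and ground truth
#'
#' Scores recovery of planted modules: 1 for identical partitions (up to
#' relabeling), about 0 for unrelated ones.
#'
#' @param assignment A `module_assignment`, or a tibble with `gene_id` and
#'   `module`.
#' @param truth Named vector of true labels (names = gene ids), or a tibble
#'   with `gene_id` and `module` (e.g. `sim$genes` filtered to dynamic genes).
#' @return Adjusted Rand index between -1 and 1, computed on the common gene set.
#' @export
module_recovery_score <- function(assignment, truth) {
  if (inherits(assignment, "module_assignment")) {
    assignment <- assignment$assignment
  }
  if (is.data.frame(truth)) {
    truth <- setNames(truth$module, truth$gene_id)
  }
  common <- intersect(assignment$gene_id, names(truth))
  if (length(common) == 0) {
    abort("Assignment and truth share no genes.")
  }
  a <- assignment$module[match(common, assignment$gene_id)]
  b <- truth[common]
  mclust::adjustedRandIndex(a, b)
}
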