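#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_tile geom_boxplot
#'   geom_col labs scale_fill_gradient2 theme_minimal facet_wrap autoplot
#'   element_text theme position_dodge
#' @export
ggplot2::autoplot

#' Plot a diffusion-map embedding
#'
#' @param object A `diffusion_map`.
#' @param dims Two component names to plot (default DC1 vs DC2).
#' @param colour Optional vector (e.g. stage labels) used to colour samples.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diffusion_map <- function(object, dims = c("DC1", "DC2"),
                                   colour = NULL, ...) {
  df <- tidy(object)
  if (!all(dims %in% names(df))) abort("Requested components not present.")
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot(df, aes(x = .data[[dims[1]]], y = .data[[dims[2]]]))
  p <- if (is.null(colour)) p + geom_point(size = 2) else
    p + geom_point(aes(colour = .data$colour), size = 2) +
      labs(colour = "stage")
  p + theme_minimal() + labs(title = "Diffusion map")
}

#' Heatmap of module profiles in dendrogram order
#'
#' @param object A `module_assignment`.
#' @param ... Unused.
#' @return A ggplot of mean-relative expression, genes ordered by dendrogram
#'   leaf order and annotated by module.
#' @export
autoplot.module_assignment <- function(object, ...) {
  rel <- object$rel_expr
  ord <- object$assignment$gene_id[order(object$assignment$leaf_order)]
  df <- as_tibble(rel, rownames = "gene_id") %>%
    tidyr::pivot_longer(-"gene_id", names_to = "stage",
                        values_to = "rel_expr") %>%
    mutate(gene_id = factor(.data$gene_id, levels = ord),
           stage = factor(.data$stage, levels = colnames(rel)))
  ggplot(df, aes(x = .data$stage, y = .data$gene_id,
                 fill = .data$rel_expr)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    theme_minimal() +
    theme(axis.text.y = ggplot2::element_blank()) +
    labs(y = "genes (dendrogram order)", fill = "relative\nexpression")
}

#' Plot a per-stage network connectivity profile
#'
#' @param object A `connectivity_profile`.
#' @param ... Unused.
#' @return A ggplot of active node and edge counts per stage.
#' @export
autoplot.connectivity_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("n_active_nodes",
                                                 "n_active_edges"),
                            names_to = "what", values_to = "n")
  ggplot(df, aes(x = .data$stage, y = .data$n, colour = .data$what,
                 group = .data$what)) +
    geom_line() + geom_point() + theme_minimal() +
    labs(y = "count", colour = NULL,
         title = "Network activity by stage")
}

#' Plot scaled pathway scores
#'
#' @param object A `pathway_scores` object (after [scale_scores()]).
#' @param ... Unused.
#' @return A ggplot tile map of pathway-by-condition scaled scores.
#' @export
autoplot.pathway_scores <- function(object, ...) {
  df <- tidy(object)
  fill <- if ("scaled" %in% names(df)) "scaled" else "score"
  ggplot(df, aes(x = .data$condition, y = .data$pathway,
                 fill = .data[[fill]])) +
    geom_tile() +
    scale_fill_gradient2(midpoint = if (fill == "scaled") 1 else NA,
                         low = "blue", mid = "white", high = "red") +
    theme_minimal() + labs(fill = fill)
}

#' Boxplot of a per-embryo statistic by treatment
#'
#' @param props Per-embryo table from [embryo_proportions()].
#' @param stat Column to plot (default `frac_nanog_only`).
#' @return A ggplot.
#' @export
plot_lineage_proportions <- function(props, stat = "frac_nanog_only") {
  ggplot(props, aes(x = .data$treatment, y = .data[[stat]])) +
    geom_boxplot(outlier.shape = 4) +
    theme_minimal() + labs(y = stat)
}
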