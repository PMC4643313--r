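#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a diffusion-map embedding
#'
#' @param x A `diffusion_map`.
#' @param ... Unused.
#' @return Tibble with `sample_id` and one column per diffusion component.
#' @export
tidy.diffusion_map <- function(x, ...) {
  out <- as_tibble(x$coordinates)
  out <- dplyr::bind_cols(tibble(sample_id = x$sample_ids), out)
  out
}

#' @rdname tidy.diffusion_map
#' @export
glance.diffusion_map <- function(x, ...) {
  tibble(n_samples = length(x$sample_ids),
         n_components = ncol(x$coordinates),
         bandwidth = x$bandwidth,
         lambda_1 = x$eigenvalues[1])
}

#' Tidy a module assignment
#'
#' @param x A `module_assignment`.
#' @param ... Unused.
#' @return The per-gene assignment tibble (`gene_id`, `module`,
#'   `leaf_order`).
#' @export
tidy.module_assignment <- function(x, ...) x$assignment

#' @rdname tidy.module_assignment
#' @export
glance.module_assignment <- function(x, ...) {
  tibble(n_genes = nrow(x$assignment), k = x$k,
         distance = x$distance, linkage = x$linkage)
}

#' Tidy ANOVA/Tukey results
#'
#' `tidy()` returns the pairwise Tukey comparisons; `glance()` the one-way
#' ANOVA summary.
#'
#' @param x An `anova_tukey` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.anova_tukey <- function(x, ...) x$comparisons

#' @rdname tidy.anova_tukey
#' @export
glance.anova_tukey <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, p_value = x$p_overall,
         df_between = x$df_between, df_within = x$df_within)
}

#' Tidy pathway scores
#'
#' @param x A `pathway_scores` object.
#' @param ... Unused.
#' @return Long tibble with `pathway`, `condition`, `score` and (after
#'   [scale_scores()]) `scaled`.
#' @export
tidy.pathway_scores <- function(x, ...) {
  long <- as_tibble(x$scores, rownames = "pathway") %>%
    tidyr::pivot_longer(-"pathway", names_to = "condition",
                        values_to = "score")
  if (!is.null(x$scaled)) {
    sc <- as_tibble(x$scaled, rownames = "pathway") %>%
      tidyr::pivot_longer(-"pathway", names_to = "condition",
                          values_to = "scaled")
    long <- left_join(long, sc, by = c("pathway", "condition"))
  }
  long
}

#' Tidy an interaction network
#'
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @return The edge tibble.
#' @export
tidy.interaction_network <- function(x, ...) x$edges

#' @rdname tidy.interaction_network
#' @export
glance.interaction_network <- function(x, ...) {
  tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
         n_activation = sum(x$edges$sign == "activation"),
         n_inhibition = sum(x$edges$sign == "inhibition"))
}
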