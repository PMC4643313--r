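#' Directed signed interaction network
#'
#' A lightweight container for curated regulatory interactions: a node set of
#' gene symbols and directed edges with sign (`"activation"` or
#' `"inhibition"`). Duplicate (source, target, sign) triples are dropped.
#'
#' @param edges Tibble or data frame with columns `source`, `target`, `sign`.
#' @param nodes Optional character vector of nodes (defaults to all edge
#'   endpoints; extra isolated nodes may be supplied).
#' @return Object of class `interaction_network`: list with `nodes` and
#'   `edges` (tibble).
#' @export
interaction_network <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  req <- c("source", "target", "sign")
  if (!all(req %in% names(edges))) {
    abort("`edges` needs columns source, target, sign.")
  }
  if (!all(edges$sign %in% c("activation", "inhibition"))) {
    abort("Edge sign must be 'activation' or 'inhibition'.")
  }
  edges <- distinct(edges[, req])
  endpoint <- unique(c(edges$source, edges$target))
  nodes <- sort(unique(c(nodes, endpoint)))
  structure(list(nodes = nodes, edges = edges),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("<interaction_network> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Reduce a network to dynamic genes plus anchor regulators
#'
#' Takes the induced subgraph on the union of dynamically expressed genes and
#' a fixed set of anchor regulators (by default the core pluripotency factors
#' Pou5f1, Nanog, Sox2). Anchors are retained even when isolated; other nodes
#' left without edges are dropped unless `keep_isolated = TRUE`. Gene symbols
#' are matched case-insensitively.
#'
#' @param net An [interaction_network()].
#' @param dynamic_genes Character vector of dynamic gene symbols.
#' @param anchors Anchor regulators always retained (warned if absent from
#'   the network).
#' @param keep_isolated Keep non-anchor nodes without edges (default FALSE).
#' @return The reduced [interaction_network()].
#' @export
reduce_network <- function(net, dynamic_genes,
                           anchors = c("Pou5f1", "Nanog", "Sox2"),
                           keep_isolated = FALSE) {
  stopifnot(inherits(net, "interaction_network"))
  lower_nodes <- tolower(net$nodes)
  keep <- net$nodes[lower_nodes %in% tolower(c(dynamic_genes, anchors))]
  anchor_nodes <- net$nodes[lower_nodes %in% tolower(anchors)]
  missing_anchor <- anchors[!tolower(anchors) %in% lower_nodes]
  if (length(missing_anchor) > 0) {
    warn(paste0("Anchor(s) not in network: ",
                paste(missing_anchor, collapse = ", ")))
  }
  if (length(keep) == 0) {
    abort("No network node matches the dynamic genes or anchors.")
  }
  edges <- net$edges[net$edges$source %in% keep &
                       net$edges$target %in% keep, , drop = FALSE]
  connected <- unique(c(edges$source, edges$target))
  nodes <- if (keep_isolated) keep else
    union(connected, anchor_nodes)
  nodes <- intersect(keep, nodes)
  interaction_network(edges, nodes = nodes)
}

#' Stage-wise node activity
#'
#' A network node is preferentially active at a stage when its mean-relative
#' (stage-scaled, log-normalized) expression there is strictly positive.
#' Genes absent from the expression matrix are treated as inactive, with a
#' warning.
#'
#' @param rel_expr Numeric matrix of mean-relative expression, genes x stages
#'   (see [scale_to_stage_mean()]).
#' @param stage Stage label (a column of `rel_expr`).
#' @param net An [interaction_network()].
#' @return Character vector of active nodes.
#' @export
node_activity <- function(rel_expr, stage, net) {
  stopifnot(inherits(net, "interaction_network"))
  if (!stage %in% colnames(rel_expr)) {
    abort(paste0("Unknown stage: ", stage))
  }
  idx <- match(tolower(net$nodes), tolower(rownames(rel_expr)))
  absent <- net$nodes[is.na(idx)]
  if (length(absent) > 0) {
    warn(paste0("Node(s) missing from expression, treated as inactive: ",
                paste(absent, collapse = ", ")))
  }
  vals <- rep(-Inf, length(net$nodes))
  vals[!is.na(idx)] <- rel_expr[idx[!is.na(idx)], stage]
  net$nodes[vals > 0]
}

#' Active edges given an active node set
#'
#' An edge is active exactly when both its source and its target are active;
#' the interaction sign is preserved.
#'
#' @param net An [interaction_network()].
#' @param active_nodes Character vector of active nodes.
#' @return Tibble of active edges (`source`, `target`, `sign`).
#' @export
active_edges <- function(net, active_nodes) {
  stopifnot(inherits(net, "interaction_network"))
  net$edges[net$edges$source %in% active_nodes &
              net$edges$target %in% active_nodes, , drop = FALSE]
}

#' Per-stage network connectivity profile
#'
#' Applies [node_activity()] and [active_edges()] at each stage and reports
#' active node and edge counts; the stage of maximal edge count is recorded
#' as the connectivity peak.
#'
#' @inheritParams node_activity
#' @param stages Ordered stage labels (default: columns of `rel_expr`).
#' @return Tibble (class `connectivity_profile`) with `stage`,
#'   `n_active_nodes`, `n_active_edges`; attribute `peak_stage` holds the
#'   stage with the most active edges (ties broken by stage order).
#' @export
connectivity_profile <- function(net, rel_expr,
                                 stages = colnames(rel_expr)) {
  stopifnot(inherits(net, "interaction_network"))
  if (!all(stages %in% colnames(rel_expr))) {
    abort("All `stages` must be columns of `rel_expr`.")
  }
  rows <- lapply(stages, function(s) {
    act <- suppressWarnings(node_activity(rel_expr, s, net))
    ed <- active_edges(net, act)
    tibble(stage = s, n_active_nodes = length(act),
           n_active_edges = nrow(ed))
  })
  out <- bind_rows(rows)
  out$stage <- factor(out$stage, levels = stages)
  attr(out, "peak_stage") <- as.character(out$stage[which.max(out$n_active_edges)])
  class(out) <- c("connectivity_profile", class(out))
  out
}

#' Stages at which all core regulators are coexpressed
#'
#' Returns the exact set of stages where every gene of a core regulatory set
#' exceeds an expression floor -- e.g. asking at which developmental stage all
#' components of the ESC self-renewal circuit are simultaneously present.
#'
#' @param stage_expr Numeric matrix of stage-mean expression (genes x stages,
#'   typically FPKM).
#' @param core_genes Character vector of core regulators; all must be present
#'   in `stage_expr` (case-insensitive), otherwise an error lists absentees.
#' @param floor Expression floor (value must be strictly greater).
#' @return Character vector of qualifying stages (possibly empty).
#' @export
core_coexpression_stages <- function(stage_expr, core_genes, floor = 10) {
  if (length(core_genes) == 0) abort("`core_genes` must be non-empty.")
  idx <- match(tolower(core_genes), tolower(rownames(stage_expr)))
  if (anyNA(idx)) {
    abort(paste0("Core gene(s) absent from expression matrix: ",
                 paste(core_genes[is.na(idx)], collapse = ", ")))
  }
  sub <- stage_expr[idx, , drop = FALSE]
  colnames(stage_expr)[colSums(sub > floor) == length(core_genes)]
}
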