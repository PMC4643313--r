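#' Simulate a directed signed interaction network over dynamic genes
#'
#' Selects `n_nodes` dynamic genes whose planted stage profiles peak (exceed
#' their cross-stage mean) at a common `peak_stage`, and wires them with
#' random directed, signed edges at the requested density. Projected onto
#' stage-wise relative expression, such a network attains maximal
#' interconnectivity at the peak stage -- the structure of a pluripotency
#' network that is most active in the preimplantation epiblast.
#'
#' @param sim A `sim_experiment` from [simulate_counts()].
#' @param n_nodes Number of nodes (must not exceed the number of dynamic genes
#'   peaking at `peak_stage`).
#' @param edge_density Fraction in (0, 1] of all possible directed edges
#'   (self-loops excluded).
#' @param peak_stage Stage at which all node profiles must peak. Default: the
#'   stage where most dynamic genes peak.
#' @param seed Integer seed; defaults to the simulation seed plus one.
#' @return An [interaction_network()] with attribute `peak_stage`.
#' @export
simulate_network <- function(sim, n_nodes, edge_density, peak_stage = NULL,
                             seed = NULL) {
  if (!inherits(sim, "sim_experiment")) {
    abort("`sim` must come from simulate_counts().")
  }
  if (edge_density <= 0 || edge_density > 1) {
    abort("`edge_density` must lie in (0, 1].")
  }
  cf <- sim$truth$config
  dyn <- sim$genes$gene_id[sim$genes$dynamic]
  if (length(dyn) == 0) abort("Simulation contains no dynamic genes.")
  sm <- sim$truth$stage_means[dyn, , drop = FALSE]
  peaks <- sm > rowMeans(sm)              # profile exceeds cross-stage mean
  if (is.null(peak_stage)) {
    peak_stage <- colnames(peaks)[which.max(colSums(peaks))]
  }
  if (!peak_stage %in% cf$stages) abort("Unknown `peak_stage`.")
  candidates <- dyn[peaks[, peak_stage]]
  if (n_nodes > length(candidates)) {
    abort(sprintf(
      "Only %d dynamic genes peak at stage '%s'; cannot place %d nodes.",
      length(candidates), peak_stage, n_nodes))
  }
  if (is.null(seed)) seed <- cf$seed + 1L
  set.seed(seed)
  nodes <- sort(sample(candidates, n_nodes))
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  m <- round(edge_density * nrow(pairs))
  keep <- sort(sample.int(nrow(pairs), m))
  edges <- tibble(
    source = pairs$source[keep], target = pairs$target[keep],
    sign = sample(c("activation", "inhibition"), m, replace = TRUE))
  net <- interaction_network(edges, nodes = nodes)
  attr(net, "peak_stage") <- peak_stage
  net
}
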