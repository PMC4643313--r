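#' Simulate a stage-structured count matrix with recorded ground truth
#'
#' Draws a gene-by-sample matrix of negative-binomial counts under the design
#' described by a [sim_config()]: per-gene baseline means, stage-profile
#' multipliers for dynamic genes organized in modules, log-normal library-size
#' factors with geometric mean 1, and a planted pseudotime equal to stage
#' order. Everything needed to score downstream recovery (dynamic flags,
#' module labels, true stage means, size factors, pseudotime) is returned as
#' ground truth.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_experiment`: a list with
#' \describe{
#'   \item{counts}{integer matrix, genes x samples.}
#'   \item{samples}{tibble of sample metadata (`sample_id`, `stage`,
#'     `lineage`, `condition`, `replicate`, `pseudotime`).}
#'   \item{genes}{tibble of gene annotation (`gene_id`, `length_bp`,
#'     `detectable`, `dynamic`, `module`).}
#'   \item{truth}{list with `stage_means` (true per-stage NB means, genes x
#'     stages), `lib_factors`, `pseudotime`, and the `config`.}
#' }
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 100, seed = 7))
#' dim(sim$counts)
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by sim_config().")
  }
  cf <- config
  set.seed(cf$seed)
  n_stage <- length(cf$stages)
  n_samp <- n_stage * cf$replicates_per_stage
  gene_ids <- sprintf("gene%05d", seq_len(cf$n_genes))
  sample_stage <- rep(cf$stages, each = cf$replicates_per_stage)
  sample_ids <- paste0(
    gsub("[^A-Za-z0-9]+", "_", sample_stage), "_r",
    rep(seq_len(cf$replicates_per_stage), times = n_stage))

  # gene-level structure -----------------------------------------------------
  n_dynamic <- round(cf$frac_dynamic * cf$n_genes)
  n_detect <- round(cf$frac_detectable * cf$n_genes)
  dynamic_idx <- if (n_dynamic > 0) sort(sample.int(cf$n_genes, n_dynamic)) else integer(0)
  detectable <- logical(cf$n_genes)
  detectable[dynamic_idx] <- TRUE
  pool <- setdiff(seq_len(cf$n_genes), dynamic_idx)
  extra <- n_detect - n_dynamic
  if (extra > 0) detectable[sort(sample(pool, extra))] <- TRUE

  module <- rep(NA_integer_, cf$n_genes)
  if (n_dynamic > 0) {
    # every module gets at least one gene; remainder spread evenly
    lab <- rep(seq_len(cf$n_modules), length.out = n_dynamic)
    module[dynamic_idx] <- sample(lab)
  }

  base_mean <- rlnorm(cf$n_genes,
                      meanlog = log(cf$baseline_mean) - cf$baseline_log_sd^2 / 2,
                      sdlog = cf$baseline_log_sd)
  base_mean[!detectable] <- 0

  length_bp <- round(runif(cf$n_genes, cf$gene_length_range[1],
                           cf$gene_length_range[2]))

  # true stage-mean matrix (before library-size scaling) ---------------------
  stage_means <- matrix(base_mean, nrow = cf$n_genes, ncol = n_stage,
                        dimnames = list(gene_ids, cf$stages))
  for (g in dynamic_idx) {
    stage_means[g, ] <- base_mean[g] * cf$module_profiles[[module[g]]]
  }

  # library-size factors, geometric mean 1 -----------------------------------
  log_s <- rnorm(n_samp, 0, cf$libsize_log_sd)
  log_s <- log_s - mean(log_s)
  lib_factors <- setNames(exp(log_s), sample_ids)

  mu <- sweep(stage_means[, match(sample_stage, cf$stages), drop = FALSE],
              2, lib_factors, `*`)
  colnames(mu) <- sample_ids

  counts <- matrix(0L, cf$n_genes, n_samp,
                   dimnames = list(gene_ids, sample_ids))
  pos <- mu > 0
  if (cf$dispersion > 0) {
    counts[pos] <- rnbinom(sum(pos), mu = mu[pos], size = 1 / cf$dispersion)
  } else {
    counts[pos] <- rpois(sum(pos), lambda = mu[pos])
  }
  storage.mode(counts) <- "integer"

  samples <- tibble(
    sample_id = sample_ids,
    stage = factor(sample_stage, levels = cf$stages),
    lineage = ifelse(grepl("PrE", sample_stage, ignore.case = TRUE),
                     "PrE", "EPI"),
    condition = sample_stage,
    replicate = rep(seq_len(cf$replicates_per_stage), times = n_stage),
    pseudotime = match(sample_stage, cf$stages))

  genes <- tibble(
    gene_id = gene_ids, length_bp = length_bp, detectable = detectable,
    dynamic = seq_len(cf$n_genes) %in% dynamic_idx, module = module)

  structure(
    list(counts = counts, samples = samples, genes = genes,
         truth = list(stage_means = stage_means, lib_factors = lib_factors,
                      pseudotime = setNames(samples$pseudotime, sample_ids),
                      config = cf)),
    class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("<sim_experiment> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples; ", sum(x$genes$dynamic), " dynamic genes in ",
      length(unique(stats::na.omit(x$genes$module))), " modules\n", sep = "")
  invisible(x)
}
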