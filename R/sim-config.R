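#' Simulation configuration for stage-structured embryo RNA-seq counts
#'
#' Describes a synthetic experiment: an ordered developmental stage series with
#' replicated samples per stage, negative-binomial counts whose per-gene means
#' follow stage profiles, a minority of "dynamic" genes organized into
#' expression modules, sample-level library-size variation, and a fraction of
#' genes that are transcriptionally silent (so detection rates resemble real
#' small-cell-number libraries rather than saturating at 100%).
#'
#' Counts for gene \eqn{i} in sample \eqn{j} are drawn from a negative binomial
#' with mean \eqn{\mu_{ij} = b_i \, f_{i,\mathrm{stage}(j)} \, s_j} and variance
#' \eqn{\mu + \alpha \mu^2}, where \eqn{b_i} is the gene's baseline mean,
#' \eqn{f} its stage profile (flat for non-dynamic genes), \eqn{s_j} the
#' library-size factor, and \eqn{\alpha} the dispersion. \eqn{\alpha = 0} gives
#' Poisson counts.
#'
#' @param n_genes Number of genes.
#' @param stages Ordered character vector of stage labels. The default mirrors
#'   a mouse preimplantation-to-postimplantation series with cultured and
#'   diapaused states appended; any ordered label set is accepted.
#' @param replicates_per_stage Samples per stage.
#' @param frac_dynamic Fraction of genes given non-flat stage profiles.
#' @param n_modules Number of planted expression modules among dynamic genes.
#' @param module_profiles Optional list of `n_modules` numeric vectors (one
#'   multiplier per stage, all positive). Defaults to
#'   [default_module_profiles()].
#' @param baseline_mean Expected count for an average expressed gene (> 0).
#'   Per-gene baselines are drawn log-normal around this value.
#' @param dispersion Negative-binomial dispersion \eqn{\alpha \ge 0}
#'   (variance \eqn{\mu + \alpha\mu^2}).
#' @param libsize_log_sd Standard deviation of the log library-size factor
#'   (\eqn{\ge 0}). Factors are mean-centered in log space so their geometric
#'   mean is exactly 1.
#' @param gene_length_range Length-2 vector of exonic lengths (bp, > 0); gene
#'   lengths are drawn uniformly on this range and recorded in the annotation.
#' @param frac_detectable Fraction of genes with nonzero expression; the
#'   remainder are silent in every sample. Default 0.65, emulating the
#'   60--70% detection typical of libraries from small numbers of cells.
#' @param fold Peak-to-baseline fold change used by the default module
#'   profiles.
#' @param baseline_log_sd Log-normal spread of per-gene baseline means.
#' @param seed Integer seed; identical configurations give byte-identical
#'   simulations.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_counts()], [simulate_network()], [simulate_if_cells()]
#' @export
sim_config <- function(n_genes = 2000,
                       stages = c("E2.5", "E3.5", "E4.5-EPI", "E4.5-PrE",
                                  "E5.5", "ESC", "diapause"),
                       replicates_per_stage = 4,
                       frac_dynamic = 0.1,
                       n_modules = 10,
                       module_profiles = NULL,
                       baseline_mean = 50,
                       dispersion = 0.1,
                       libsize_log_sd = 0.15,
                       gene_length_range = c(500, 5000),
                       frac_detectable = 0.65,
                       fold = 4,
                       baseline_log_sd = 1,
                       seed = 1L) {
  if (length(n_genes) != 1 || n_genes < 1) {
    abort("`n_genes` must be a single positive integer.")
  }
  stages <- as.character(stages)
  if (length(stages) < 1 || anyDuplicated(stages)) {
    abort("`stages` must be a non-empty set of unique labels.")
  }
  if (replicates_per_stage < 1) abort("`replicates_per_stage` must be >= 1.")
  if (frac_dynamic < 0 || frac_dynamic > 1) {
    abort("`frac_dynamic` must lie in [0, 1].")
  }
  if (baseline_mean <= 0) abort("`baseline_mean` must be > 0.")
  if (dispersion < 0) abort("`dispersion` must be >= 0.")
  if (libsize_log_sd < 0) abort("`libsize_log_sd` must be >= 0.")
  if (length(gene_length_range) != 2 || any(gene_length_range <= 0)) {
    abort("`gene_length_range` must be two positive lengths (bp).")
  }
  if (frac_detectable <= 0 || frac_detectable > 1) {
    abort("`frac_detectable` must lie in (0, 1].")
  }
  n_dynamic <- round(frac_dynamic * n_genes)
  if (frac_dynamic > 0 && n_dynamic < n_modules) {
    abort("`frac_dynamic * n_genes` must be at least `n_modules`.")
  }
  if (round(frac_detectable * n_genes) < n_dynamic) {
    abort("`frac_detectable * n_genes` must cover all dynamic genes.")
  }
  if (is.null(module_profiles)) {
    if (frac_dynamic == 0) {
      n_modules <- 1L
      module_profiles <- list(rep(1, length(stages)))
    } else {
      module_profiles <- default_module_profiles(n_modules, length(stages),
                                                 fold)
    }
  }
  if (length(module_profiles) != n_modules) {
    abort("`module_profiles` must contain one profile per module.")
  }
  ok <- vapply(module_profiles,
               function(p) length(p) == length(stages) && all(p > 0),
               logical(1))
  if (!all(ok)) {
    abort("Each module profile needs one positive multiplier per stage.")
  }
  structure(
    list(n_genes = as.integer(n_genes), stages = stages,
         replicates_per_stage = as.integer(replicates_per_stage),
         frac_dynamic = frac_dynamic, n_modules = as.integer(n_modules),
         module_profiles = module_profiles, baseline_mean = baseline_mean,
         dispersion = dispersion, libsize_log_sd = libsize_log_sd,
         gene_length_range = gene_length_range,
         frac_detectable = frac_detectable, fold = fold,
         baseline_log_sd = baseline_log_sd, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Canonical stage profiles for planted expression modules
#'
#' Builds a catalogue of mutually well-separated stage-wise mean profiles:
#' one peak per stage, one valley per stage (the log-scale antipode of the
#' peak), early/late half plateaus, then adjacent plateaus and monotone
#' ramps. The first `n_modules` distinct profiles are returned. These emulate
#' module semantics such as "maximally expressed in morulae" or "common to
#' morula and ICM", and their centered log profiles have low pairwise
#' correlation so that planted modules are identifiable by shape.
#'
#' @param n_modules Number of profiles requested.
#' @param n_stages Number of stages.
#' @param fold Peak-to-baseline ratio (> 1).
#' @return List of `n_modules` positive numeric vectors of length `n_stages`.
#' @export
default_module_profiles <- function(n_modules, n_stages, fold = 4) {
  if (fold <= 1) abort("`fold` must exceed 1.")
  profs <- list()
  add <- function(p) {
    dup <- any(vapply(profs, function(q) isTRUE(all.equal(p, q)), logical(1)))
    if (!dup) profs[[length(profs) + 1L]] <<- p
  }
  for (s in seq_len(n_stages)) {            # single-stage peaks
    p <- rep(1, n_stages); p[s] <- fold; add(p)
  }
  for (s in seq_len(n_stages)) {            # single-stage valleys
    p <- rep(fold, n_stages); p[s] <- 1; add(p)
  }
  if (n_stages >= 2) {
    h <- floor(n_stages / 2)                # early / late halves
    p <- rep(1, n_stages); p[seq_len(h)] <- fold; add(p)
    p <- rep(fold, n_stages); p[seq_len(h)] <- 1; add(p)
    for (s in seq_len(n_stages - 1)) {      # adjacent plateaus
      p <- rep(1, n_stages); p[c(s, s + 1)] <- fold; add(p)
    }
    add(exp(seq(0, log(fold), length.out = n_stages)))  # ramps
    add(exp(seq(log(fold), 0, length.out = n_stages)))
  }
  if (n_modules > length(profs)) {
    abort(sprintf(
      "Only %d distinct default profiles exist for %d stages; supply `module_profiles` explicitly.",
      length(profs), n_stages))
  }
  profs[seq_len(n_modules)]
}

#' Smooth developmental-wave profiles
#'
#' Gaussian-bump stage profiles whose peak positions sweep the stage range,
#' so consecutive stages share partially overlapping modules and the
#' transcriptome drifts smoothly along the stage series. Use these when the
#' planted structure of interest is a developmental trajectory (e.g. for
#' staging by diffusion map) rather than maximally distinct module shapes.
#'
#' @param n_modules Number of profiles.
#' @param n_stages Number of stages.
#' @param fold Peak-to-baseline ratio (> 1).
#' @param width Bump width in stage units (default 0.75).
#' @return List of `n_modules` positive numeric vectors of length `n_stages`.
#' @export
wave_module_profiles <- function(n_modules, n_stages, fold = 4,
                                 width = 0.75) {
  if (fold <= 1) abort("`fold` must exceed 1.")
  centers <- seq(1, n_stages, length.out = n_modules)
  t <- seq_len(n_stages)
  lapply(centers, function(cc) {
    1 + (fold - 1) * exp(-(t - cc)^2 / (2 * width^2))
  })
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_genes, " genes x ",
      length(x$stages) * x$replicates_per_stage, " samples (",
      length(x$stages), " stages x ", x$replicates_per_stage,
      " replicates)\n", sep = "")
  cat("  dynamic fraction ", x$frac_dynamic, " in ", x$n_modules,
      " modules; dispersion ", x$dispersion, "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}
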