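#' Pipeline configuration
#'
#' Validates paths and thresholds for an end-to-end run: quantification,
#' pairwise differential expression, dynamic-gene selection, module
#' clustering, diffusion-map embedding, and (when the inputs are supplied)
#' network activity projection and pathway scoring/enrichment.
#'
#' @param counts Path to a counts TSV (or MTX, see `dialect`).
#' @param annotation Path to the gene-annotation TSV (`gene_id`, `length_bp`).
#' @param design Path to the sample-metadata TSV (`sample_id`, `stage`, ...).
#' @param out_dir Output directory (created if absent).
#' @param gmt,sif Optional pathway-collection / network paths.
#' @param dialect Counts dialect, `"tsv"` or `"mtx"`.
#' @param alpha Significance level for dynamic-gene selection (default 0.05).
#' @param fpkm_min Robust-detection FPKM floor (default 10).
#' @param k Number of expression modules (default 10).
#' @param n_components Diffusion components (default 3).
#' @param anchors Network anchor regulators.
#' @param p_col `"padj"` or `"pval"` for the selection gate.
#' @param seed Integer seed recorded in the manifest.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(counts, annotation, design, out_dir,
                            gmt = NULL, sif = NULL, dialect = "tsv",
                            alpha = 0.05, fpkm_min = 10, k = 10,
                            n_components = 3,
                            anchors = c("Pou5f1", "Nanog", "Sox2"),
                            p_col = "padj", seed = 1L) {
  paths <- c(counts = counts, annotation = annotation, design = design,
             gmt = gmt, sif = sif)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("Input file(s) not found: ",
                 paste(names(missing), "=", missing, collapse = "; ")))
  }
  if (alpha <= 0 || fpkm_min < 0 || k < 1 || n_components < 1) {
    abort("Thresholds must be positive.")
  }
  structure(list(counts = counts, annotation = annotation, design = design,
                 gmt = gmt, sif = sif, out_dir = out_dir, dialect = dialect,
                 alpha = alpha, fpkm_min = fpkm_min, k = as.integer(k),
                 n_components = as.integer(n_components), anchors = anchors,
                 p_col = p_col, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full transcriptome pipeline
#'
#' Executes, in order: size factors, FPKM, common dispersion and VST,
#' detection rates; all-pairs NB exact tests; dynamic-gene selection;
#' mean-relative expression and module clustering; diffusion-map embedding on
#' the VST values of dynamic genes; optionally network activity projection
#' (SIF input) and pathway scores plus hypergeometric enrichment of the
#' dynamic set (GMT input). All tables are written under `out_dir` and listed
#' in a JSON manifest together with every threshold applied, so a run is
#' reproducible from the manifest alone.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (invisibly), a list written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cf <- config
  dir.create(cf$out_dir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  outputs <- character(0)
  emit <- function(obj, file, writer) {
    p <- file.path(cf$out_dir, file)
    writer(obj, p)
    outputs[[length(outputs) + 1]] <<- file
    p
  }

  counts <- step("read", read_counts(cf$counts, cf$dialect))
  annot <- step("read", read_annotation(cf$annotation))
  design <- step("read", read_design(cf$design))
  if (!setequal(design$sample_id, colnames(counts))) {
    abort("Design samples do not match count matrix columns.")
  }
  design <- design[match(colnames(counts), design$sample_id), ]
  stages <- factor(design$stage, levels = unique(design$stage))

  sf <- step("quantify", size_factors(counts))
  fk <- step("quantify", fpkm(counts, annot))
  alpha_hat <- step("quantify",
                    estimate_common_dispersion(counts, sf, stages))
  vs <- step("quantify", vst(counts, sf, alpha_hat))
  det <- step("quantify", detection_rate(counts))
  emit(fk, "fpkm.tsv", write_layer)
  emit(vs, "vst.tsv", write_layer)
  emit(det, "detection_rate.tsv", readr::write_tsv)

  dispersions <- step("differential",
                      estimate_dispersion(counts, sf, stages))
  de <- step("differential",
             de_all_pairs(counts, sf, dispersions, stages))
  emit(de, "de_all_pairs.tsv", readr::write_tsv)

  stage_fp <- stage_mean(fk, stages)
  sel <- step("dynamic_modules",
              select_dynamic_genes(de, stage_fp, alpha = cf$alpha,
                                   fpkm_min = cf$fpkm_min,
                                   p_col = cf$p_col))
  emit(sel, "dynamic_genes.tsv", readr::write_tsv)
  dyn <- sel$gene_id[sel$dynamic]
  rel <- scale_to_stage_mean(fk, stages)
  modules <- NULL
  if (length(dyn) >= cf$k) {
    modules <- step("dynamic_modules",
                    cluster_modules(rel[dyn, , drop = FALSE], k = cf$k))
    emit(modules$assignment, "modules.tsv", readr::write_tsv)
  }

  emb_genes <- if (length(dyn) >= 2) dyn else rownames(vs)
  dm <- step("embedding",
             diffusion_map(t(vs[emb_genes, , drop = FALSE]),
                           n_components = min(cf$n_components,
                                              ncol(counts) - 1),
                           stage = stages))
  emit(tidy(dm), "embedding.tsv", readr::write_tsv)

  if (!is.null(cf$sif)) {
    net <- step("network", read_sif(cf$sif))
    red <- step("network",
                suppressWarnings(reduce_network(net, dyn, cf$anchors)))
    prof <- step("network", connectivity_profile(red, rel))
    emit(prof, "connectivity_profile.tsv", readr::write_tsv)
    emit(red, "network_reduced.sif", write_sif)
  }

  if (!is.null(cf$gmt)) {
    gmt <- step("pathways", read_gmt(cf$gmt))
    scores <- step("pathways", scale_scores(pathway_score(stage_fp, gmt)))
    emit(scores$scaled, "pathway_scores_scaled.tsv", write_layer)
    enr <- step("pathways",
                hypergeom_enrichment(dyn, gmt, rownames(counts)))
    emit(enr, "pathway_enrichment.tsv", readr::write_tsv)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lineagemap")),
    seed = cf$seed,
    parameters = list(alpha = cf$alpha, fpkm_min = cf$fpkm_min, k = cf$k,
                      n_components = cf$n_components, p_col = cf$p_col,
                      anchors = cf$anchors,
                      common_dispersion = alpha_hat),
    inputs = list(counts = cf$counts, annotation = cf$annotation,
                  design = cf$design, gmt = cf$gmt, sif = cf$sif),
    n_genes = nrow(counts), n_samples = ncol(counts),
    n_dynamic = length(dyn),
    outputs = unlist(outputs))
  jsonlite::write_json(manifest, file.path(cf$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
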