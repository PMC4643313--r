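#' Read and write count matrices
#'
#' Counts travel as tab-separated text (first column `gene_id`, one column
#' per sample) or as MatrixMarket `.mtx` with `<file>.rownames` /
#' `<file>.colnames` sidecars (one identifier per line). Reading validates
#' that counts are nonnegative integers and that sidecar lengths match the
#' matrix header; round-trips are lossless.
#'
#' @param path File path (`.tsv` or `.mtx` depending on `dialect`).
#' @param dialect `"tsv"` or `"mtx"`.
#' @return `read_counts()`: integer matrix with dimnames.
#' @export
read_counts <- function(path, dialect = c("tsv", "mtx")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  } else {
    mm <- Matrix::readMM(path)
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    if (length(rn) != nrow(mm) || length(cn) != ncol(mm)) {
      abort(sprintf(
        "Sidecar name counts (%d rows, %d cols) do not match matrix header (%d x %d).",
        length(rn), length(cn), nrow(mm), ncol(mm)))
    }
    m <- as.matrix(mm)
    dimnames(m) <- list(rn, cn)
  }
  if (any(m < 0)) abort("Counts must be nonnegative.")
  if (any(m != round(m))) abort("Counts must be integers.")
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts
#' @param counts Integer matrix, genes x samples.
#' @export
write_counts <- function(counts, path, dialect = c("tsv", "mtx")) {
  dialect <- match.arg(dialect)
  counts <- as_count_matrix(counts)
  if (dialect == "tsv") {
    df <- as.data.frame(counts)
    df <- cbind(gene_id = rownames(counts), df)
    readr::write_tsv(as_tibble(df), path)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".rownames"))
    writeLines(colnames(counts), paste0(path, ".colnames"))
  }
  invisible(path)
}

#' Read/write sample metadata, gene annotation, and expression layers
#'
#' Tab-separated tables: the design holds `sample_id`, `stage`, `lineage`,
#' `condition`, `replicate`; the annotation holds `gene_id`, `length_bp`.
#' Expression layers (FPKM, VST, relative expression) are written like count
#' tables but with real values.
#'
#' @param path File path.
#' @return A tibble (design/annotation) or numeric matrix (layer).
#' @export
read_design <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  req <- c("sample_id", "stage")
  if (!all(req %in% names(df))) {
    abort("Design must contain at least sample_id and stage columns.")
  }
  df
}

#' @rdname read_design
#' @param design Tibble of sample metadata.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design, path)
  invisible(path)
}

#' @rdname read_design
#' @export
read_annotation <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (!all(c("gene_id", "length_bp") %in% names(df))) {
    abort("Annotation must contain gene_id and length_bp columns.")
  }
  if (any(df$length_bp <= 0)) abort("Gene lengths must be positive.")
  df
}

#' @rdname read_design
#' @param annotation Tibble with `gene_id`, `length_bp`.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation, path)
  invisible(path)
}

#' @rdname read_design
#' @export
read_layer <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_design
#' @param layer Numeric matrix with row names.
#' @export
write_layer <- function(layer, path) {
  df <- as.data.frame(layer)
  df <- cbind(gene_id = rownames(layer), df)
  readr::write_tsv(as_tibble(df), path)
  invisible(path)
}

#' Read and write gene-set collections in GMT format
#'
#' One pathway per line: name, description, then member genes, all
#' tab-separated.
#'
#' @param path File path.
#' @return Named list of character vectors; descriptions in attribute
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3)
  if (length(bad) > 0) {
    abort(paste0("GMT line(s) without members: ",
                 paste(bad, collapse = ", ")))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1)
  if (anyDuplicated(names(sets))) abort("Duplicate pathway names in GMT.")
  attr(sets, "descriptions") <- vapply(fields, `[`, "", 2)
  sets
}

#' @rdname read_gmt
#' @param collection Named list of gene sets.
#' @param descriptions Optional character vector of descriptions.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(collection, "descriptions") %||%
      rep("na", length(collection))
  }
  lines <- mapply(function(nm, ds, genes) {
    paste(c(nm, ds, genes), collapse = "\t")
  }, names(collection), descriptions, collection)
  writeLines(lines, path)
  invisible(path)
}

#' Read and write interaction networks in SIF format
#'
#' Simple interaction format: `source<TAB>interaction<TAB>target` with
#' interaction `activates` or `inhibits` (mapped to edge signs `activation` /
#' `inhibition`).
#'
#' @param path File path.
#' @return An [interaction_network()].
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  singletons <- vapply(fields, length, integer(1)) == 1
  bad <- which(!singletons & vapply(fields, length, integer(1)) != 3)
  if (length(bad) > 0) {
    abort(paste0("Malformed SIF line(s): ", paste(bad, collapse = ", ")))
  }
  iso <- unlist(lapply(fields[singletons], `[`, 1))
  tri <- fields[!singletons]
  inter <- vapply(tri, `[`, "", 2)
  if (!all(inter %in% c("activates", "inhibits"))) {
    abort("SIF interaction must be 'activates' or 'inhibits'.")
  }
  edges <- tibble(
    source = vapply(tri, `[`, "", 1),
    target = vapply(tri, `[`, "", 3),
    sign = ifelse(inter == "activates", "activation", "inhibition"))
  interaction_network(edges, nodes = iso)
}

#' @rdname read_sif
#' @param net An [interaction_network()].
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "interaction_network"))
  inter <- ifelse(net$edges$sign == "activation", "activates", "inhibits")
  lines <- paste(net$edges$source, inter, net$edges$target, sep = "\t")
  iso <- setdiff(net$nodes, c(net$edges$source, net$edges$target))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Read and write per-cell intensity tables
#'
#' Comma-separated with columns `cell_id`, `embryo_id`, `treatment`,
#' `nanog`, `gata6`, `cdx2`, `dapi` (extra columns are preserved).
#'
#' @param path File path.
#' @return Tibble of cells.
#' @export
read_cells <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  req <- c("cell_id", "embryo_id", "treatment", "nanog", "gata6", "cdx2",
           "dapi")
  if (!all(req %in% names(df))) {
    abort(paste0("Cell table must contain columns: ",
                 paste(req, collapse = ", ")))
  }
  df
}

#' @rdname read_cells
#' @param cells Tibble of cells.
#' @export
write_cells <- function(cells, path) {
  readr::write_csv(cells, path)
  invisible(path)
}

#' Write simulation ground truth as JSON
#'
#' @param sim A `sim_experiment`.
#' @param path Output path.
#' @export
write_ground_truth <- function(sim, path) {
  stopifnot(inherits(sim, "sim_experiment"))
  truth <- list(
    genes = sim$genes,
    lib_factors = as.list(sim$truth$lib_factors),
    pseudotime = as.list(sim$truth$pseudotime),
    stage_means = as.data.frame(sim$truth$stage_means),
    config = sim$truth$config[setdiff(names(sim$truth$config),
                                      "module_profiles")],
    module_profiles = sim$truth$config$module_profiles)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
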