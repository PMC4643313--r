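#' Pathway expression scores across conditions
#'
#' Scores each pathway in each condition as the sum of member FPKM values
#' normalized for pathway size, i.e. the mean expression of constituent
#' genes. Members absent from the expression matrix are reported; by default
#' they are excluded from the size normalization (set
#' `count_missing = TRUE` to count them as zeros).
#'
#' @param expr Numeric matrix of condition-mean expression (genes x
#'   conditions, typically FPKM).
#' @param collection Named list of gene sets (see [read_gmt()]), or a single
#'   character vector of members for one pathway.
#' @param count_missing Include absent members at expression 0 in the size
#'   normalization.
#' @return Object of class `pathway_scores`: list with `scores` (pathway x
#'   condition matrix), `n_members`, `n_present`, `missing` (named list).
#' @export
pathway_score <- function(expr, collection, count_missing = FALSE) {
  if (!is.list(collection)) collection <- list(pathway = collection)
  if (is.null(names(collection)) || anyDuplicated(names(collection))) {
    abort("`collection` must have unique pathway names.")
  }
  rn <- rownames(expr)
  rows <- matrix(NA_real_, length(collection), ncol(expr),
                 dimnames = list(names(collection), colnames(expr)))
  n_members <- integer(length(collection))
  n_present <- integer(length(collection))
  missing <- vector("list", length(collection))
  names(missing) <- names(collection)
  for (i in seq_along(collection)) {
    members <- unique(collection[[i]])
    idx <- match(tolower(members), tolower(rn))
    present <- members[!is.na(idx)]
    if (length(present) == 0) {
      abort(paste0("No member of pathway '", names(collection)[i],
                   "' is present in the expression matrix."))
    }
    missing[[i]] <- members[is.na(idx)]
    denom <- if (count_missing) length(members) else length(present)
    sums <- colSums(expr[idx[!is.na(idx)], , drop = FALSE])
    rows[i, ] <- sums / denom
    n_members[i] <- length(members)
    n_present[i] <- length(present)
  }
  structure(list(scores = rows, n_members = n_members,
                 n_present = n_present, missing = missing),
            class = "pathway_scores")
}

#' Scale pathway scores to the cross-condition mean
#'
#' Divides each pathway's score row by its mean across conditions, so a value
#' of 1 is the pathway's average level; rows with zero mean are set to 0 and
#' flagged.
#'
#' @param scores A `pathway_scores` object or a pathway x condition matrix.
#' @return Same shape as the input with a `scaled` matrix (for
#'   `pathway_scores` input the object gains a `scaled` element and
#'   `zero_mean` flags).
#' @export
scale_scores <- function(scores) {
  m <- if (inherits(scores, "pathway_scores")) scores$scores else as.matrix(scores)
  if (ncol(m) < 2) abort("At least two conditions are required.")
  mu <- rowMeans(m)
  scaled <- m / mu
  zero <- mu == 0
  scaled[zero, ] <- 0
  if (inherits(scores, "pathway_scores")) {
    scores$scaled <- scaled
    scores$zero_mean <- zero
    scores
  } else {
    attr(scaled, "zero_mean") <- zero
    scaled
  }
}

#' @export
print.pathway_scores <- function(x, ...) {
  cat("<pathway_scores> ", nrow(x$scores), " pathways x ", ncol(x$scores),
      " conditions\n", sep = "")
  invisible(x)
}

#' Hypergeometric over-representation test
#'
#' For each pathway, tests whether the overlap between a query gene set and
#' the pathway is larger than expected by chance, with the upper-tail
#' hypergeometric probability
#' \eqn{P(X \ge k)} for \eqn{X \sim \mathrm{Hypergeom}(N, K, n)} where
#' \eqn{N} is the universe size, \eqn{K} the pathway size within the
#' universe, and \eqn{n} the query size. All sets are intersected with the
#' universe first; query genes outside the universe are dropped with a
#' warning. BH adjustment is applied across the collection.
#'
#' @param query Character vector of genes of interest (e.g. dynamic genes).
#' @param collection Named list of gene sets.
#' @param universe Character vector of all assayed genes.
#' @return Tibble with `pathway`, `n_pathway`, `n_query`, `n_overlap`,
#'   `expected`, `pval`, `padj`, ordered by `pval`.
#' @export
hypergeom_enrichment <- function(query, collection, universe) {
  if (length(universe) == 0) abort("`universe` must be non-empty.")
  if (length(query) == 0) abort("`query` must be non-empty.")
  universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(sprintf("%d query gene(s) outside the universe were dropped.",
                 length(outside)))
  }
  query <- intersect(unique(query), universe)
  if (length(query) == 0) abort("No query gene lies in the universe.")
  n_u <- length(universe)
  n_q <- length(query)
  rows <- lapply(names(collection), function(nm) {
    pw <- intersect(unique(collection[[nm]]), universe)
    k <- length(intersect(pw, query))
    # P(X >= k) with X ~ Hypergeom(N = n_u, K = |pw|, n = n_q)
    p <- phyper(k - 1, length(pw), n_u - length(pw), n_q,
                lower.tail = FALSE)
    tibble(pathway = nm, n_pathway = length(pw), n_query = n_q,
           n_overlap = k, expected = n_q * length(pw) / n_u, pval = p)
  })
  out <- bind_rows(rows)
  out$padj <- bh_adjust(out$pval)
  arrange(out, .data$pval)
}
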