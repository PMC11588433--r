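#' Marker-mean immune abundance scores (MCP-counter style)
#'
#' The abundance score of a population in a sample is the arithmetic mean of
#' the log2 expression of that population's marker genes. Markers absent
#' from the matrix are dropped with a warning; a population losing all of
#' its markers is an error.
#'
#' @param expr Genes x samples log2 matrix.
#' @param marker_table Named list: population -> marker gene ids.
#' @return Tibble of class `immune_scores`: `sample` plus one column per
#'   population; attribute `method = "mcp"`.
#' @export
mcp_score <- function(expr, marker_table) {
  assert_expression_matrix(expr)
  if (is.null(names(marker_table))) abort("`marker_table` must be named by population.")
  cols <- purrr::imap(marker_table, function(markers, pop) {
    present <- intersect(markers, rownames(expr))
    if (length(present) == 0) {
      abort(sprintf("Population '%s' has no markers present in the matrix.", pop))
    }
    if (length(present) < length(markers)) {
      warn(sprintf("Population '%s': %d of %d markers absent, dropped.",
                   pop, length(markers) - length(present), length(markers)))
    }
    unname(colMeans(expr[present, , drop = FALSE]))
  })
  out <- dplyr::bind_cols(tibble(sample = colnames(expr)), as_tibble(cols))
  attr(out, "method") <- "mcp"
  class(out) <- c("immune_scores", class(out))
  out
}

#' Convert a score tibble to a samples x features matrix
#'
#' @param scores Tibble with a `sample` column and numeric feature columns.
#' @return Numeric matrix with sample ids as rownames.
#' @export
score_matrix <- function(scores) {
  stopifnot(is.data.frame(scores), "sample" %in% names(scores))
  m <- as.matrix(scores[, setdiff(names(scores), "sample"), drop = FALSE])
  rownames(m) <- scores$sample
  m
}

ssgsea_one <- function(x, in_set, alpha) {
  # x: expression of one sample (named); in_set: logical aligned to x
  r <- rank(x, ties.method = "average")
  ord <- order(-x, names(x))            # walk from highest expression down
  in_ord <- in_set[ord]
  w <- r[ord]^alpha
  n <- length(x)
  m <- sum(in_set)
  p_in <- cumsum(ifelse(in_ord, w, 0)) / sum(w[in_ord])
  p_out <- cumsum(!in_ord) / (n - m)
  sum(p_in - p_out)
}

#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' For each sample, genes are ranked by expression (ties receive average
#' ranks) and a weighted Kolmogorov-Smirnov random walk is run down the
#' ranked list: in-set steps are weighted by rank^alpha, out-of-set steps
#' are uniform. The score is the sum over list positions of the difference
#' between the in-set and out-of-set cumulative curves (the area between
#' them). Depends only on within-sample ranks, so it is invariant to any
#' monotone per-sample transform.
#'
#' @param expr Genes x samples matrix.
#' @param gene_set Character vector of set members (a strict, non-empty
#'   subset of the genes).
#' @param alpha Rank-weighting exponent.
#' @param normalize Min-max normalise scores across samples?
#' @return Tibble: `sample`, `score`.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25, normalize = FALSE) {
  assert_expression_matrix(expr)
  in_set <- rownames(expr) %in% gene_set
  if (sum(in_set) == 0) abort("No gene-set members present in the matrix.")
  if (all(in_set)) abort("Gene set covers every gene; enrichment undefined.")
  sc <- apply(expr, 2, function(x) {
    names(x) <- rownames(expr)
    ssgsea_one(x, in_set, alpha)
  })
  if (normalize) {
    rng <- range(sc)
    if (diff(rng) > 0) sc <- (sc - rng[1]) / diff(rng)
  }
  tibble(sample = colnames(expr), score = as.numeric(sc))
}

#' Bin-matched module score (control-subtracted set mean)
#'
#' Genes are binned by average expression; each set gene contributes
#' `n_ctrl` control genes drawn from its bin (excluding the set gene
#' itself). The per-sample score is the mean expression of the set genes
#' minus the mean expression of the drawn controls, so a score near zero
#' means "no enrichment beyond expression level".
#'
#' @param expr Genes x samples matrix.
#' @param gene_set Character vector of set members present in `expr`.
#' @param n_bins Number of average-expression bins.
#' @param n_ctrl Controls drawn per set gene.
#' @param seed Integer seed making the control draw reproducible.
#' @param control_pool Optional explicit control gene pool; when supplied it
#'   is used verbatim instead of the bin-matched draw.
#' @return Tibble: `sample`, `score`.
#' @export
module_score <- function(expr, gene_set, n_bins = 24, n_ctrl = 100, seed = 1,
                         control_pool = NULL) {
  assert_expression_matrix(expr)
  if (n_bins < 2) abort("`n_bins` must be at least 2.")
  set <- intersect(gene_set, rownames(expr))
  if (length(set) == 0) abort("No gene-set members present in the matrix.")
  set_mean <- colMeans(expr[set, , drop = FALSE])
  if (!is.null(control_pool)) {
    pool <- intersect(control_pool, rownames(expr))
    if (length(pool) == 0) abort("`control_pool` has no genes present in the matrix.")
    ctrl_mean <- colMeans(expr[pool, , drop = FALSE])
    return(tibble(sample = colnames(expr), score = as.numeric(set_mean - ctrl_mean)))
  }
  avg <- rowMeans(expr)
  bins <- as.integer(cut(rank(avg, ties.method = "first"),
                         breaks = n_bins, labels = FALSE, include.lowest = TRUE))
  names(bins) <- rownames(expr)
  ctrl <- with_seed(substream_seed(seed, "module_score"), {
    unlist(lapply(set, function(g) {
      pool <- names(bins)[bins == bins[g]]
      pool <- setdiff(pool, g)
      if (length(pool) == 0) {
        warn(sprintf("Bin of gene %s has no control genes; using the gene's bin with replacement.", g))
        pool <- names(bins)[bins == bins[g]]
      }
      if (length(pool) < n_ctrl) {
        warn(sprintf("Bin of gene %s has %d candidate controls (< %d); sampling with replacement.",
                     g, length(pool), n_ctrl))
        sample(pool, n_ctrl, replace = TRUE)
      } else {
        sample(pool, n_ctrl)
      }
    }))
  })
  ctrl_mean <- colMeans(expr[ctrl, , drop = FALSE])
  tibble(sample = colnames(expr), score = as.numeric(set_mean - ctrl_mean))
}

#' Correlate gene expression with immune abundance scores
#'
#' Computes the correlation (Spearman by default, Pearson optionally) and
#' two-sided p-value for every gene x population pair, with
#' Benjamini-Hochberg adjustment across the whole grid. Constant vectors
#' yield `NA` correlations, recorded with a warning.
#'
#' @param expr Genes x samples matrix.
#' @param genes Genes to correlate (must be present in `expr`).
#' @param scores An `immune_scores` tibble (or any `sample` + numeric
#'   columns tibble aligned with `expr`'s samples).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Tibble: `gene`, `population`, `estimate`, `p_value`, `adj_p`.
#' @export
correlate_gene_immune <- function(expr, genes, scores,
                                  method = c("spearman", "pearson")) {
  assert_expression_matrix(expr)
  method <- match.arg(method)
  if (ncol(expr) < 3) abort("Need at least 3 samples for correlation.")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0) {
    abort(sprintf("Gene(s) absent from the matrix: %s.", paste(missing, collapse = ", ")))
  }
  sm <- score_matrix(scores)
  if (!identical(rownames(sm), colnames(expr))) {
    sm <- sm[colnames(expr), , drop = FALSE]
  }
  grid <- tidyr::expand_grid(gene = genes, population = colnames(sm))
  res <- purrr::map2(grid$gene, grid$population, function(g, p) {
    x <- expr[g, ]
    y <- sm[, p]
    if (sd(x) == 0 || sd(y) == 0) {
      return(c(NA_real_, NA_real_))
    }
    ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  })
  out <- mutate(grid,
                estimate = map_dbl(res, 1),
                p_value = map_dbl(res, 2))
  if (anyNA(out$estimate)) {
    warn(sprintf("%d correlation(s) undefined (constant vectors), recorded NA.",
                 sum(is.na(out$estimate))))
  }
  out$adj_p <- p.adjust(out$p_value, method = "BH")
  out
}
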