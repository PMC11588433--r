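#' Build per-sample gene-immune ratio portraits
#'
#' The portrait of a sample is the hub-gene x population matrix
#' `P[i, j] = expr(gene_i) / max(score(pop_j), epsilon)` — expression of each
#' signature gene relative to the abundance of each immune population. Rows
#' follow the supplied hub-gene order, columns the population order of the
#' score table. Portraits are per-sample constructs: a sample's portrait
#' does not depend on the other samples (normalisation, when wanted, is a
#' separate step fitted on training data; see [portrait_normalizer()]).
#'
#' @param expr Genes x samples log2 matrix.
#' @param hub_genes Hub gene ids (rows of the portrait); all must be present.
#' @param immune_scores An `immune_scores` tibble covering the same samples.
#' @param epsilon Floor applied to denominators.
#' @return Object of class `portrait_stack`: 3-d array
#'   `[sample, gene, population]` with dimnames.
#' @export
build_portraits <- function(expr, hub_genes, immune_scores, epsilon = 1e-6) {
  assert_expression_matrix(expr)
  missing <- setdiff(hub_genes, rownames(expr))
  if (length(missing) > 0) {
    abort(sprintf("Hub gene(s) missing from the matrix: %s.",
                  paste(missing, collapse = ", ")))
  }
  sm <- score_matrix(immune_scores)
  missing_s <- setdiff(colnames(expr), rownames(sm))
  if (length(missing_s) > 0) {
    abort(sprintf("Sample(s) without immune scores: %s.",
                  paste(head(missing_s, 5), collapse = ", ")))
  }
  sm <- sm[colnames(expr), , drop = FALSE]
  n <- ncol(expr)
  stack <- array(
    NA_real_,
    dim = c(n, length(hub_genes), ncol(sm)),
    dimnames = list(colnames(expr), hub_genes, colnames(sm))
  )
  denom <- pmax(sm, epsilon)             # samples x populations
  g <- t(expr[hub_genes, , drop = FALSE])  # samples x genes
  for (j in seq_len(ncol(sm))) {
    stack[, , j] <- g / denom[, j]
  }
  class(stack) <- c("portrait_stack", class(stack))
  stack
}

#' Fit a portrait z-normaliser on training portraits
#'
#' Computes per-cell (gene x population) means and standard deviations
#' across the training samples. Apply with [normalize_portraits()]; fitting
#' on training data only and applying to test data keeps evaluation
#' leakage-free.
#'
#' @param stack A training `portrait_stack`.
#' @return List with `center` and `scale` gene x population matrices.
#' @export
portrait_normalizer <- function(stack) {
  center <- apply(stack, c(2, 3), mean)
  scale <- apply(stack, c(2, 3), sd)
  scale[scale == 0] <- 1
  list(center = center, scale = scale)
}

#' Apply a fitted portrait normaliser
#'
#' @param stack A `portrait_stack`.
#' @param normalizer Output of [portrait_normalizer()].
#' @return Normalised `portrait_stack`.
#' @export
normalize_portraits <- function(stack, normalizer) {
  out <- stack
  for (s in seq_len(dim(stack)[1])) {
    out[s, , ] <- (stack[s, , ] - normalizer$center) / normalizer$scale
  }
  out
}

#' Write portraits to per-sample TSV files
#'
#' @param stack A `portrait_stack`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_portraits <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(dimnames(stack)[[1]], function(s) {
    p <- file.path(dir, paste0("portrait_", s, ".tsv"))
    df <- as_tibble(stack[s, , ], rownames = "gene")
    readr::write_tsv(df, p)
    p
  }, character(1))
  invisible(paths)
}
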