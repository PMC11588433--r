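drop_constant_genes <- function(expr) {
  sds <- apply(expr, 1, sd)
  if (all(sds == 0)) abort("All genes are constant; no co-expression structure to analyse.")
  if (any(sds == 0)) {
    warn(sprintf("Removed %d constant gene(s) before network construction.", sum(sds == 0)))
    expr <- expr[sds > 0, , drop = FALSE]
  }
  expr
}

#' Correlation-based network adjacency
#'
#' Unsigned adjacency raises the absolute gene-gene Pearson correlation to
#' the soft-threshold power, `a_ij = |cor|^power`; signed adjacency uses
#' `((1 + cor)/2)^power`. The diagonal is set to zero so that row sums give
#' network connectivity directly.
#'
#' @param expr Genes x samples log2 expression matrix.
#' @param power Soft-threshold exponent (beta), >= 1.
#' @param signed Use the signed transformation?
#' @return Symmetric gene x gene adjacency matrix with zero diagonal.
#' @export
adjacency_matrix <- function(expr, power, signed = FALSE) {
  assert_expression_matrix(expr)
  if (power < 1) abort("`power` must be >= 1.")
  sds <- apply(expr, 1, sd)
  if (any(sds == 0)) {
    abort(sprintf("Constant gene(s) give undefined correlations: %s.",
                  paste(head(rownames(expr)[sds == 0], 5), collapse = ", ")))
  }
  cc <- cor(t(expr))
  a <- if (signed) ((1 + cc) / 2)^power else abs(cc)^power
  diag(a) <- 0
  a
}

scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- as.vector(table(bin)) / length(k)
  keep <- !is.na(dk) & pk > 0 & dk > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(fit)$r.squared
  -sign(coef(fit)[2]) * r2     # signed convention: positive slope counts against
}

#' Scan soft-threshold powers for scale-free topology
#'
#' For each candidate power, builds the adjacency, computes per-gene
#' connectivity `k_i = sum_j a_ij`, and measures the scale-free topology fit
#' as the signed R-squared of the `log10 p(k)` versus `log10 k` regression
#' over binned connectivity (R-squared multiplied by minus the sign of the
#' slope, so topologies with the wrong slope direction score negatively).
#' The chosen power is the smallest one whose fit reaches `r2_threshold`;
#' when none does, the power with the maximal fit is used and the scan is
#' flagged as a fallback.
#'
#' @param expr Genes x samples matrix.
#' @param powers Candidate integer powers.
#' @param r2_threshold Fit threshold for accepting a power.
#' @param n_bins Connectivity bins for the fit.
#' @param signed Signed adjacency?
#' @return Object of class `soft_threshold_scan`: a list with a `scan`
#'   tibble (`power`, `fit_r2`, `mean_connectivity`), `chosen_power` and
#'   `fallback`.
#' @export
soft_threshold_scan <- function(expr, powers = 1:20, r2_threshold = 0.80,
                                n_bins = 10, signed = FALSE) {
  assert_expression_matrix(expr)
  if (nrow(expr) < 10) abort("Need at least 10 genes for a soft-threshold scan.")
  if (ncol(expr) < 4) abort("Need at least 4 samples for a soft-threshold scan.")
  expr <- drop_constant_genes(expr)
  cc <- cor(t(expr))
  base <- if (signed) (1 + cc) / 2 else abs(cc)
  diag(base) <- 0
  rows <- purrr::map(powers, function(p) {
    a <- base^p
    diag(a) <- 0
    k <- rowSums(a)
    tibble(power = p, fit_r2 = scale_free_fit(k, n_bins),
           mean_connectivity = mean(k))
  })
  scan <- bind_rows(rows)
  if (all(is.na(scan$fit_r2))) {
    warn("Scale-free fit undefined at every power (degenerate connectivity); using the smallest power.")
    chosen <- scan$power[1]
    fallback <- TRUE
  } else {
    ok <- which(!is.na(scan$fit_r2) & scan$fit_r2 >= r2_threshold)
    if (length(ok) > 0) {
      chosen <- scan$power[ok[1]]
      fallback <- FALSE
    } else {
      chosen <- scan$power[which.max(scan$fit_r2)]
      fallback <- TRUE
    }
  }
  structure(list(scan = scan, chosen_power = chosen, fallback = fallback,
                 r2_threshold = r2_threshold, signed = signed),
            class = "soft_threshold_scan")
}

#' @export
print.soft_threshold_scan <- function(x, ...) {
  cat("<soft_threshold_scan> chosen power:", x$chosen_power,
      if (x$fallback) "(fallback: no power reached the fit threshold)" else "",
      "\n")
  print(x$scan)
  invisible(x)
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_k a_ik a_kj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i` the connectivity of gene i; the diagonal is 1. Genes sharing many
#' neighbours score high even when their direct adjacency is modest.
#'
#' @param adj Symmetric adjacency matrix, values in `[0, 1]`, zero diagonal.
#' @return Symmetric TOM matrix with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) abort("`adj` must be square.")
  if (max(abs(adj - t(adj))) > 1e-8) abort("`adj` must be symmetric.")
  if (any(adj < 0) || any(adj > 1)) abort("Adjacency values must lie in [0, 1].")
  if (any(diag(adj) != 0)) abort("`adj` must have a zero diagonal.")
  k <- rowSums(adj)
  shared <- adj %*% adj          # diag is zero, so this is sum over k != i, j
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (shared + adj) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect co-expression modules by static tree cut
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a single absolute height. Clusters smaller than `min_size` are
#' relabelled 0 (unassigned); remaining modules are numbered in decreasing
#' size order.
#'
#' @param tom TOM similarity matrix (from [tom_similarity()]).
#' @param min_size Minimum module size; smaller clusters become unassigned.
#' @param cut_height Absolute cut height on the `1 - TOM` dendrogram.
#' @return Object of class `module_assignment`: list with `assignment`
#'   tibble (`gene`, `module`) and `sizes`.
#' @export
detect_modules <- function(tom, min_size = 10, cut_height = 0.95) {
  if (min_size < 2) abort("`min_size` must be at least 2.")
  if (is.null(rownames(tom))) abort("`tom` must carry gene ids as dimnames.")
  hc <- hclust(as.dist(1 - tom), method = "average")
  raw <- cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  lab <- setNames(rep(0L, length(raw)), names(raw))
  if (length(keep) > 0) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(ord)) lab[raw == as.integer(ord[i])] <- i
  }
  assignment <- tibble(gene = rownames(tom), module = unname(lab[rownames(tom)]))
  mods <- sort(setdiff(unique(assignment$module), 0L))
  structure(
    list(assignment = assignment,
         sizes = setNames(
           vapply(mods, function(m) sum(assignment$module == m), integer(1)),
           mods),
         cut_height = cut_height, min_size = min_size),
    class = "module_assignment"
  )
}

#' @export
print.module_assignment <- function(x, ...) {
  cat("<module_assignment>", length(x$sizes), "module(s);",
      sum(x$assignment$module == 0), "unassigned gene(s)\n")
  if (length(x$sizes) > 0) print(x$sizes)
  invisible(x)
}

#' Module eigengene (first principal component sample scores)
#'
#' The eigengene is the first principal component of the gene-standardised
#' member submatrix, scaled to unit variance, with its sign fixed so that
#' the mean correlation with the member genes is non-negative.
#'
#' @param expr Genes x samples matrix.
#' @param members Character vector of member gene ids (>= 2 present).
#' @return Named numeric vector of per-sample eigengene scores.
#' @export
module_eigengene <- function(expr, members) {
  assert_expression_matrix(expr)
  members <- intersect(members, rownames(expr))
  if (length(members) < 2) abort("Need at least 2 member genes present in `expr`.")
  x <- expr[members, , drop = FALSE]
  xs <- t(scale(t(x)))              # standardise each gene
  if (anyNA(xs)) abort("Constant member gene; eigengene undefined.")
  pc <- prcomp(t(xs), center = FALSE, scale. = FALSE)
  e <- pc$x[, 1]
  e <- e / sd(e)
  if (mean(cor(e, t(x))) < 0) e <- -e
  setNames(as.numeric(e), colnames(expr))
}

#' Eigengenes for every module in an assignment
#'
#' @param expr Genes x samples matrix.
#' @param assignment A `module_assignment`.
#' @return Samples x modules matrix of eigengene scores (columns `M1`, ...).
#' @export
module_eigengenes <- function(expr, assignment) {
  stopifnot(inherits(assignment, "module_assignment"))
  mods <- sort(setdiff(unique(assignment$assignment$module), 0L))
  if (length(mods) == 0) abort("No modules in the assignment.")
  eg <- vapply(mods, function(m) {
    module_eigengene(expr, assignment$assignment$gene[assignment$assignment$module == m])
  }, numeric(ncol(expr)))
  colnames(eg) <- paste0("M", mods)
  rownames(eg) <- colnames(expr)
  eg
}

#' Eigengene-based connectivity (kME)
#'
#' `kME[g, m]` is the Pearson correlation between gene g's expression and
#' module m's eigengene. Constant genes get `NA` with a warning.
#'
#' @param expr Genes x samples matrix.
#' @param eigengenes Samples x modules eigengene matrix
#'   (from [module_eigengenes()]).
#' @return Tibble of class `kme_table`: column `gene` plus one kME column
#'   per module.
#' @export
kme_table <- function(expr, eigengenes) {
  assert_expression_matrix(expr)
  if (nrow(eigengenes) != ncol(expr)) {
    abort("`eigengenes` rows must match `expr` samples.")
  }
  sds <- apply(expr, 1, sd)
  kme <- suppressWarnings(cor(t(expr), eigengenes))
  if (any(sds == 0)) {
    warn(sprintf("kME undefined (recorded NA) for %d constant gene(s).", sum(sds == 0)))
    kme[sds == 0, ] <- NA_real_
  }
  out <- as_tibble(kme)
  out <- dplyr::bind_cols(tibble(gene = rownames(expr)), out)
  class(out) <- c("kme_table", class(out))
  out
}

#' Select hub genes: top-k members per hub module by kME
#'
#' For each hub module, takes its `k` member genes with the highest kME for
#' that module (ties broken by gene id, ascending), then returns the
#' de-duplicated union in stable module-then-rank order. Four disjoint hub
#' modules at the default `k = 25` give the 100-gene hub list used
#' downstream.
#'
#' @param kme A [kme_table()].
#' @param assignment A `module_assignment`.
#' @param hub_modules Integer module labels to treat as hub modules.
#' @param k Genes to take per module.
#' @return Character vector of hub gene ids.
#' @export
select_hub_genes <- function(kme, assignment, hub_modules, k = 25) {
  stopifnot(inherits(assignment, "module_assignment"))
  if (length(hub_modules) == 0) abort("`hub_modules` must be non-empty.")
  present <- sort(setdiff(unique(assignment$assignment$module), 0L))
  missing <- setdiff(hub_modules, present)
  if (length(missing) > 0) {
    abort(sprintf("Hub module(s) not in the assignment: %s.",
                  paste(missing, collapse = ", ")))
  }
  out <- character()
  for (m in hub_modules) {
    col <- paste0("M", m)
    if (!col %in% names(kme)) abort(sprintf("kME table lacks column %s.", col))
    members <- assignment$assignment$gene[assignment$assignment$module == m]
    sub <- kme[kme$gene %in% members, c("gene", col)]
    sub <- sub[order(-sub[[col]], sub$gene), ]
    out <- c(out, head(sub$gene, k))
  }
  out[!duplicated(out)]
}

#' Denoise samples by k-nearest-neighbour aggregation in PC space
#'
#' Each output column is the mean of a sample and its `k_neighbors` nearest
#' neighbours in principal-component space (a simplified metacell step).
#' `k_neighbors = 0` disables aggregation and returns the input.
#'
#' @param expr Genes x samples matrix.
#' @param k_neighbors Neighbours per sample; must be < number of samples.
#' @param n_pcs Principal components used for the neighbour search.
#' @return Matrix with the same dimensions as `expr`.
#' @export
metacell_aggregate <- function(expr, k_neighbors, n_pcs = 10) {
  assert_expression_matrix(expr)
  if (k_neighbors == 0) return(expr)
  if (k_neighbors < 1) abort("`k_neighbors` must be >= 1 (or 0 to disable).")
  n <- ncol(expr)
  if (k_neighbors >= n) abort("`k_neighbors` must be smaller than the number of samples.")
  npc <- min(n_pcs, n - 1, nrow(expr))
  pcs <- prcomp(t(expr), rank. = npc)$x
  d <- as.matrix(dist(pcs))
  out <- expr
  for (j in seq_len(n)) {
    nn <- order(d[j, ])[seq_len(k_neighbors + 1)]   # self is nearest
    out[, j] <- rowMeans(expr[, nn, drop = FALSE])
  }
  out
}
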