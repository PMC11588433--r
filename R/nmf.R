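nmf_objective <- function(V, W, H) sum((V - W %*% H)^2)

nmf_run <- function(V, rank, max_iter, tol, eps = 1e-12) {
  n <- nrow(V); m <- ncol(V)
  W <- matrix(runif(n * rank, 0.1, 1), n, rank)
  H <- matrix(runif(rank * m, 0.1, 1), rank, m)
  obj <- nmf_objective(V, W, H)
  trace <- obj
  for (it in seq_len(max_iter)) {
    H <- H * (t(W) %*% V) / (t(W) %*% W %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% (H %*% t(H)) + eps)
    new_obj <- nmf_objective(V, W, H)
    trace <- c(trace, new_obj)
    if (obj - new_obj < tol * max(obj, eps)) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  list(W = W, H = H, objective = obj, trace = trace)
}

#' Non-negative matrix factorisation (Frobenius, multiplicative updates)
#'
#' Minimises `||V - W H||_F^2` by Lee-Seung multiplicative updates; the best
#' of `n_restarts` random restarts (by final objective) is kept. A matrix
#' with negative entries is shifted by its global minimum first, preserving
#' between-gene contrasts; the shift is recorded.
#'
#' @param V Genes x samples matrix (e.g. expression on hub-module genes).
#' @param rank Factorisation rank (number of subtypes).
#' @param n_restarts Random restarts.
#' @param max_iter Maximum iterations per restart.
#' @param tol Relative objective-change stopping tolerance.
#' @param seed Integer master seed; each restart uses a derived substream.
#' @return Object of class `nmf_fit`: `W`, `H`, `rank`, `objective_trace`
#'   (best restart), `best_restart`, `shift`.
#' @export
nmf_factorize <- function(V, rank = 2, n_restarts = 30, max_iter = 500,
                          tol = 1e-9, seed = 1) {
  if (!is.matrix(V) || !is.numeric(V)) abort("`V` must be a numeric matrix.")
  shift <- 0
  if (min(V) < 0) {
    shift <- -min(V)
    message(sprintf("Input shifted by +%.4g to make it non-negative.", shift))
    V <- V + shift
  }
  if (rank >= min(dim(V))) abort("`rank` must be smaller than both matrix dimensions.")
  if (rank < 1) abort("`rank` must be >= 1.")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    run <- with_seed(substream_seed(seed, paste0("nmf_restart_", r)),
                     nmf_run(V, rank, max_iter, tol))
    if (is.null(best) || run$objective < best$objective) {
      best <- run
      best$restart <- r
    }
  }
  dimnames(best$W) <- list(rownames(V), paste0("basis_", seq_len(rank)))
  dimnames(best$H) <- list(paste0("basis_", seq_len(rank)), colnames(V))
  structure(
    list(W = best$W, H = best$H, rank = rank,
         objective = best$objective, objective_trace = best$trace,
         n_restarts = n_restarts, best_restart = best$restart,
         shift = shift, seed = seed),
    class = "nmf_fit"
  )
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat("<nmf_fit> rank", x$rank, "| final objective", signif(x$objective, 6),
      "| best of", x$n_restarts, "restart(s)\n")
  invisible(x)
}

#' @rdname nmf_factorize
#' @param x An `nmf_fit`.
#' @param ... Unused.
#' @method glance nmf_fit
#' @export
glance.nmf_fit <- function(x, ...) {
  tibble(rank = x$rank, objective = x$objective,
         iterations = length(x$objective_trace) - 1,
         n_restarts = x$n_restarts, best_restart = x$best_restart,
         shift = x$shift)
}

#' Assign samples to subtypes by dominant NMF component
#'
#' Each sample's coefficient column is normalised to sum 1 and the sample is
#' assigned to the component with the largest weight (ties go to the lower
#' index).
#'
#' @param fit An `nmf_fit`.
#' @return Tibble: `sample`, `subtype` (integer in `1..rank`), plus the
#'   normalised component weights.
#' @export
assign_subtypes <- function(fit) {
  stopifnot(inherits(fit, "nmf_fit"))
  H <- fit$H
  csum <- colSums(H)
  if (any(csum == 0)) {
    abort(sprintf("All-zero coefficient column for sample(s): %s.",
                  paste(colnames(H)[csum == 0], collapse = ", ")))
  }
  Hn <- sweep(H, 2, csum, "/")
  subtype <- apply(Hn, 2, which.max)    # which.max takes the lower index on ties
  out <- tibble(sample = colnames(H), subtype = as.integer(subtype))
  w <- t(Hn)
  colnames(w) <- paste0("weight_", seq_len(fit$rank))
  dplyr::bind_cols(out, as_tibble(w))
}

#' Cophenetic rank diagnostic for NMF
#'
#' For each candidate rank, builds a consensus matrix over random restarts
#' (entry = fraction of restarts in which two samples share a dominant
#' component) and reports the cophenetic correlation of its average-linkage
#' dendrogram — near 1 indicates stable clustering at that rank.
#'
#' @param V Non-negative matrix.
#' @param ranks Candidate ranks.
#' @param n_restarts Restarts per rank.
#' @param max_iter,tol,seed Passed to the individual factorisations.
#' @return Tibble: `rank`, `cophenetic`.
#' @export
cophenetic_rank_scan <- function(V, ranks = 2:5, n_restarts = 20,
                                 max_iter = 300, tol = 1e-7, seed = 1) {
  rows <- purrr::map(ranks, function(r) {
    n <- ncol(V)
    consensus <- matrix(0, n, n)
    for (i in seq_len(n_restarts)) {
      fit <- nmf_factorize(V, rank = r, n_restarts = 1, max_iter = max_iter,
                           tol = tol, seed = substream_seed(seed, paste0("coph_", r, "_", i)))
      s <- assign_subtypes(fit)$subtype
      consensus <- consensus + outer(s, s, "==")
    }
    consensus <- consensus / n_restarts
    d <- as.dist(1 - consensus)
    coph <- suppressWarnings(cor(d, cophenetic(hclust(d, method = "average"))))
    tibble(rank = r, cophenetic = coph)
  })
  bind_rows(rows)
}

#' Per-feature contrast between two subtypes
#'
#' Runs the normality-gated two-group test ([two_group_test()]) on each
#' feature column of a score table, comparing subtype 1 against subtype 2,
#' with Benjamini-Hochberg adjustment across features. `direction` is
#' positive when the feature is higher in subtype 1.
#'
#' @param scores Tibble with a `sample` column and numeric feature columns
#'   (e.g. [mcp_score()] output), or a single-set score tibble with a
#'   `score` column.
#' @param assignment Tibble with `sample` and `subtype` (two subtypes, each
#'   with >= 2 samples).
#' @return Tibble: `feature`, `statistic`, `p_value`, `adj_p`, `test_used`,
#'   `direction`.
#' @export
subtype_contrast <- function(scores, assignment) {
  stopifnot(is.data.frame(scores), is.data.frame(assignment))
  sm <- score_matrix(scores)
  assignment <- assignment[match(rownames(sm), assignment$sample), ]
  if (anyNA(assignment$subtype)) abort("Every scored sample needs a subtype.")
  st <- sort(unique(assignment$subtype))
  if (length(st) != 2) abort("Exactly two subtypes are required.")
  if (any(table(assignment$subtype) < 2)) {
    abort("Each subtype needs at least 2 samples.")
  }
  rows <- purrr::map(colnames(sm), function(f) {
    x <- sm[assignment$subtype == st[1], f]
    y <- sm[assignment$subtype == st[2], f]
    tt <- two_group_test(x, y)
    mutate(tt, feature = f, .before = 1)
  })
  out <- bind_rows(rows)
  out$adj_p <- p.adjust(out$p_value, method = "BH")
  out
}
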