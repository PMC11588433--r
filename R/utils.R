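#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select group_by summarise ungroup
#'   bind_rows left_join desc across all_of n
#' @importFrom purrr map map_dbl map2 imap
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom stats cor prcomp hclust cutree as.dist cophenetic quantile
#'   sd var median rnorm runif rgamma binomial glm coef predict anova
#'   shapiro.test t.test wilcox.test fisher.test p.adjust cor.test
#'   complete.cases setNames dist lm pchisq
#' @importFrom utils head
#' @importFrom Rcpp evalCpp
#' @useDynLib plaqsig, .registration = TRUE
NULL

# Deterministic substream: every stage draws from its own seed derived from a
# single master seed, so stages can be re-run independently without
# perturbing each other's random numbers. Kept below 2^31 - 1.
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  offs <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 48271 + offs * 7919) %% 2147483647L)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_expression_matrix <- function(expr, arg = "expr") {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort(sprintf("`%s` must be a numeric genes x samples matrix.", arg))
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    abort(sprintf("`%s` must carry gene ids as rownames and sample ids as colnames.", arg))
  }
  if (anyDuplicated(rownames(expr)) || anyDuplicated(colnames(expr))) {
    abort(sprintf("`%s` has duplicated gene or sample ids.", arg))
  }
  if (anyNA(expr) || any(!is.finite(expr))) {
    abort(sprintf("`%s` contains missing or non-finite values.", arg))
  }
  invisible(expr)
}

assert_binary_labels <- function(labels, n_samples = NULL, arg = "labels") {
  lv <- unique(as.character(labels))
  if (length(lv) != 2) {
    abort(sprintf("`%s` must contain exactly two classes, got %d.", arg, length(lv)))
  }
  if (!is.null(n_samples) && length(labels) != n_samples) {
    abort(sprintf("`%s` length (%d) does not match the number of samples (%d).",
                  arg, length(labels), n_samples))
  }
  invisible(labels)
}

# Canonical binary encoding: advanced/case class -> 1. If labels already use
# the early/advanced vocabulary we honour it, otherwise the second sorted
# level is the positive class.
label_to_binary <- function(labels) {
  l <- as.character(labels)
  lv <- sort(unique(l))
  pos <- if ("advanced" %in% lv) "advanced" else lv[2]
  as.integer(l == pos)
}

positive_class <- function(labels) {
  lv <- sort(unique(as.character(labels)))
  if ("advanced" %in% lv) "advanced" else lv[2]
}
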