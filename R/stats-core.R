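#' Normality-gated two-group test
#'
#' Follows the convention of gating the parametric test on normality: if
#' both groups pass a Shapiro-Wilk test at 0.05 and both are larger than
#' `min_n_for_t`, a two-sided Welch t-test is used; otherwise a two-sided
#' Wilcoxon rank-sum test (exact p for small untied samples, normal
#' approximation with tie correction otherwise). Constant groups fail the
#' gate safely to Wilcoxon with a warning.
#'
#' @param x,y Numeric vectors (each >= 2 values).
#' @param min_n_for_t Both groups must exceed this size for the t-test.
#' @return One-row tibble: `statistic`, `p_value`, `test_used`
#'   (`"t"` or `"wilcoxon"`), `direction` (sign of `mean(x) - mean(y)`).
#' @export
two_group_test <- function(x, y, min_n_for_t = 3) {
  if (length(x) < 2 || length(y) < 2) abort("Each group needs at least 2 values.")
  normal_gate <- function(v) {
    if (length(v) < 3 || length(v) > 5000) return(FALSE)
    if (sd(v) == 0) {
      warn("Constant group: normality gate fails safely to Wilcoxon.")
      return(FALSE)
    }
    shapiro.test(v)$p.value > 0.05
  }
  use_t <- length(x) > min_n_for_t && length(y) > min_n_for_t &&
    normal_gate(x) && normal_gate(y)
  if (use_t) {
    tt <- t.test(x, y)                         # Welch by default
    stat <- unname(tt$statistic)
    p <- tt$p.value
    used <- "t"
  } else {
    wt <- suppressWarnings(wilcox.test(x, y))  # exact when small and untied
    stat <- unname(wt$statistic)
    p <- wt$p.value
    used <- "wilcoxon"
  }
  tibble(statistic = stat, p_value = p, test_used = used,
         direction = sign(mean(x) - mean(y)))
}

#' Fisher's exact tests with post-hoc multiplicity adjustment
#'
#' Two-sided Fisher's exact p-value per 2x2 table, adjusted across the
#' family of tables. Tables with a zero margin are degenerate: their p is 1
#' and they are flagged.
#'
#' @param tables A single 2x2 matrix or a list of them.
#' @param adjust Adjustment method (`"BH"` default; any [stats::p.adjust()]
#'   method).
#' @return Tibble: `table`, `p_value`, `adj_p`, `degenerate`.
#' @export
fisher_posthoc <- function(tables, adjust = "BH") {
  if (is.matrix(tables)) tables <- list(tables)
  rows <- purrr::imap(tables, function(tb, i) {
    if (!is.matrix(tb) || !all(dim(tb) == 2)) abort("Each table must be 2x2.")
    if (any(tb < 0) || any(tb != round(tb))) abort("Tables must hold non-negative integers.")
    degen <- any(rowSums(tb) == 0) || any(colSums(tb) == 0)
    p <- if (degen) 1 else fisher.test(tb)$p.value
    tibble(table = if (is.character(i)) i else as.character(i),
           p_value = p, degenerate = degen)
  })
  out <- bind_rows(rows)
  out$adj_p <- p.adjust(out$p_value, method = adjust)
  out[, c("table", "p_value", "adj_p", "degenerate")]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}
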