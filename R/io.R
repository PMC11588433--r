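#' Read a genes x samples expression matrix from TSV/CSV
#'
#' Expects the first column to hold gene identifiers and the header to hold
#' sample identifiers. Duplicate gene ids are collapsed by their mean with a
#' warning; non-numeric cells and ragged rows are parse errors. Decimal
#' commas are rejected.
#'
#' @param path Path to a TSV (default) or CSV file.
#' @return Numeric matrix, genes x samples, with dimnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  if (file.size(path) == 0) abort(sprintf("Empty expression file: %s", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE,
                          locale = readr::locale(grouping_mark = " "))
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(sprintf("Parse error in %s at line %d: expected %s, got %s.",
                  path, prob$row[1] + 1, prob$expected[1], prob$actual[1]))
  }
  if (ncol(df) < 2) abort(sprintf("%s has no sample columns.", path))
  if (nrow(df) == 0) abort(sprintf("%s contains a header but no genes.", path))
  genes <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad) > 0) {
    comma_like <- vapply(vals[bad], function(v) any(grepl("^-?[0-9]+,[0-9]+$", v)), logical(1))
    if (any(comma_like)) {
      abort(sprintf("Decimal commas detected in column(s) %s of %s; use '.' decimals.",
                    paste(bad[comma_like], collapse = ", "), path))
    }
    abort(sprintf("Non-numeric expression values in column(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (anyDuplicated(genes)) {
    n_dup <- length(genes) - length(unique(genes))
    warn(sprintf("%d duplicated gene id(s) collapsed by mean in %s.", n_dup, basename(path)))
    sums <- rowsum(m, group = genes)
    cnt <- table(genes)
    m <- sums / as.vector(cnt[rownames(sums)])
    m <- m[unique(genes), , drop = FALSE]
  }
  if (anyNA(m)) abort(sprintf("Missing expression values in %s.", path))
  m
}

#' Write an expression matrix as TSV
#'
#' @param expr Genes x samples numeric matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  assert_expression_matrix(expr)
  df <- tibble(gene = rownames(expr))
  df <- dplyr::bind_cols(df, as_tibble(expr))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a two-column sample label table
#'
#' @param path TSV with columns `sample` and `label`.
#' @return Tibble with character columns `sample`, `label`.
#' @export
read_labels <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample", "label") %in% names(df))) {
    abort(sprintf("%s must have columns `sample` and `label`.", path))
  }
  mutate(df, sample = as.character(.data$sample), label = as.character(.data$label))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Member order is preserved; duplicate members are dropped.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(sprintf("GMT parse error at line %d of %s: fewer than 3 fields.", i, path))
    }
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, description = "plaqsig") {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("All gene sets must be named.")
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, unique(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
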