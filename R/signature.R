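#' Univariate logistic screen of candidate genes
#'
#' Fits an intercept-plus-slope logistic model per gene and keeps genes whose
#' Wald p-value on the slope falls below `alpha`. Genes showing complete
#' separation (the Wald statistic degenerates) are re-tested with a
#' likelihood-ratio test under capped iterations and flagged. Constant genes
#' get p = 1 and are never kept.
#'
#' @param expr Genes x samples matrix.
#' @param labels Binary class labels, one per sample (advanced = positive).
#' @param alpha Screening significance level.
#' @return Tibble: `gene`, `estimate`, `p_value`, `kept`, `separation`.
#' @export
univariate_screen <- function(expr, labels, alpha = 0.05) {
  assert_expression_matrix(expr)
  assert_binary_labels(labels, ncol(expr))
  y <- label_to_binary(labels)
  res <- purrr::map(rownames(expr), function(g) {
    x <- expr[g, ]
    if (sd(x) == 0) {
      return(tibble(gene = g, estimate = NA_real_, p_value = 1,
                    kept = FALSE, separation = FALSE))
    }
    fit <- suppressWarnings(glm(y ~ x, family = binomial(),
                                control = list(maxit = 50)))
    sm <- suppressWarnings(summary(fit)$coefficients)
    est <- sm["x", "Estimate"]
    p <- sm["x", "Pr(>|z|)"]
    # Complete/quasi-separation: huge coefficient with collapsed Wald test.
    sep <- !fit$converged || abs(est) > 15 || sm["x", "Std. Error"] > 100
    if (sep) {
      null <- glm(y ~ 1, family = binomial())
      lr <- null$deviance - fit$deviance
      p <- pchisq(lr, df = 1, lower.tail = FALSE)
    }
    tibble(gene = g, estimate = est, p_value = p, kept = FALSE, separation = sep)
  })
  out <- bind_rows(res)
  const <- is.na(out$estimate)
  if (any(const)) {
    warn(sprintf("%d constant gene(s) screened out (p set to 1).", sum(const)))
  }
  out$kept <- out$p_value < alpha
  out
}

stratified_folds <- function(y, n_folds, seed) {
  if (n_folds > min(table(y))) {
    abort("`n_folds` exceeds the size of the smaller class.")
  }
  foldid <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  foldid
}

#' LASSO signature selection by cross-validated penalised logistic regression
#'
#' L1-penalised logistic regression along a decreasing lambda path
#' (internally standardised features; coefficients reported on the original
#' scale), with the penalty chosen by stratified cross-validated binomial
#' deviance. `lambda_rule = "min"` takes the deviance-minimising lambda,
#' `"1se"` the sparsest lambda within one standard error of it.
#'
#' @param expr Genes x samples matrix (typically restricted to screened
#'   genes).
#' @param labels Binary class labels.
#' @param n_folds Cross-validation folds (stratified).
#' @param seed Integer seed controlling fold assignment.
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @return Object of class `lasso_result`: lambda path, CV deviance curve,
#'   chosen lambda, coefficient tibble and selected genes.
#' @export
lasso_select <- function(expr, labels, n_folds = 10, seed = 1,
                         lambda_rule = c("min", "1se")) {
  assert_expression_matrix(expr)
  assert_binary_labels(labels, ncol(expr))
  lambda_rule <- match.arg(lambda_rule)
  if (nrow(expr) < 2) abort("LASSO selection needs at least 2 candidate genes.")
  y <- label_to_binary(labels)
  x <- t(expr)                          # samples x genes
  foldid <- stratified_folds(y, n_folds, substream_seed(seed, "lasso_folds"))
  cvfit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                             type.measure = "deviance", foldid = foldid,
                             standardize = TRUE)
  lam <- if (lambda_rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  beta <- coef(cvfit, s = lam)
  coefs <- tibble(
    gene = rownames(beta)[-1],
    coefficient = as.numeric(beta)[-1]
  )
  structure(
    list(
      lambda_path = cvfit$lambda,
      cv_mean_deviance = cvfit$cvm,
      cv_sd_deviance = cvfit$cvsd,
      chosen_lambda = lam,
      lambda_rule = lambda_rule,
      intercept = as.numeric(beta)[1],
      coefficients = coefs,
      selected_genes = coefs$gene[coefs$coefficient != 0],
      n_folds = n_folds,
      glmnet_fit = cvfit$glmnet.fit
    ),
    class = "lasso_result"
  )
}

#' @export
print.lasso_result <- function(x, ...) {
  cat("<lasso_result> lambda (", x$lambda_rule, ") = ",
      signif(x$chosen_lambda, 4), "; ", length(x$selected_genes),
      " gene(s) selected\n", sep = "")
  if (length(x$selected_genes) > 0) {
    print(x$coefficients[x$coefficients$coefficient != 0, ])
  }
  invisible(x)
}

#' @rdname lasso_select
#' @param x A `lasso_result`.
#' @param ... Unused.
#' @method tidy lasso_result
#' @export
tidy.lasso_result <- function(x, ...) {
  mutate(x$coefficients, selected = .data$coefficient != 0)
}

#' @rdname lasso_select
#' @method glance lasso_result
#' @export
glance.lasso_result <- function(x, ...) {
  tibble(
    chosen_lambda = x$chosen_lambda,
    lambda_rule = x$lambda_rule,
    n_selected = length(x$selected_genes),
    cv_deviance = x$cv_mean_deviance[which.min(abs(x$lambda_path - x$chosen_lambda))],
    n_folds = x$n_folds
  )
}

#' Reference eight-gene diagnostic signature
#'
#' The published eight-gene plaque-progression signature, shipped as a
#' reference fixture. Reproducing this exact gene identity requires the
#' original GEO cohorts; it is provided for annotation, not asserted by the
#' pipeline.
#'
#' @return Character vector of eight gene symbols.
#' @export
reference_signature <- function() {
  c("PARK7", "RPS24", "FTH1", "SLC7A8", "CYFIP1", "OLFML2B", "HSD17B14", "TIMP2")
}
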