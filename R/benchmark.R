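benchmark_models <- function() {
  c("random_forest", "penalized_logistic", "knn", "naive_bayes", "svm_linear")
}

# Fit one model on the training split and score the test split with the
# probability (or monotone decision value) of the positive class.
fit_and_score <- function(model, x_train, y_train, x_test, pos, seed) {
  y_f <- factor(y_train, levels = c(0, 1))
  scale_pair <- function() {
    mu <- colMeans(x_train)
    sdv <- apply(x_train, 2, sd)
    sdv[sdv == 0] <- 1
    list(train = scale(x_train, mu, sdv), test = scale(x_test, mu, sdv))
  }
  with_seed(seed, switch(
    model,
    random_forest = {
      fit <- randomForest::randomForest(
        x = x_train, y = y_f, ntree = 500,
        mtry = max(1, floor(sqrt(ncol(x_train)))))
      predict(fit, x_test, type = "prob")[, "1"]
    },
    penalized_logistic = {
      foldid <- stratified_folds(y_train, n_folds = 3, seed = seed)
      fit <- glmnet::cv.glmnet(x_train, y_f, family = "binomial", alpha = 1,
                               foldid = foldid, nfolds = 3)
      as.numeric(predict(fit, x_test, s = "lambda.min", type = "response"))
    },
    knn = {
      sc <- scale_pair()
      pred <- class::knn(sc$train, sc$test, cl = y_f, k = 5, prob = TRUE)
      pr <- attr(pred, "prob")
      ifelse(pred == "1", pr, 1 - pr)
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(x_train, y_f)
      predict(fit, x_test, type = "raw")[, "1"]
    },
    svm_linear = {
      sc <- scale_pair()
      fit <- e1071::svm(sc$train, y_f, kernel = "linear", scale = FALSE)
      dv <- attr(predict(fit, sc$test, decision.values = TRUE), "decision.values")
      # decision values are oriented towards the first named class
      first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
      if (first == "1") as.numeric(dv) else -as.numeric(dv)
    },
    abort(sprintf("Unknown model '%s'.", model))
  ))
}

#' Repeated stratified cross-validation benchmark of classifiers
#'
#' Runs `reps` repetitions of stratified `k`-fold cross-validation
#' (re-randomised each repetition) for each model, recording the held-out
#' AUC of every fold. A model that fails on a fold leaves that cell missing
#' with a warning; more than 20% missing cells is an error. The default
#' model set is random forest, L1-penalised logistic regression, k-nearest
#' neighbours, naive Bayes and a linear SVM.
#'
#' @param X Samples x features numeric matrix (rownames = sample ids).
#' @param labels Binary class labels, one per row of `X`.
#' @param models Models to benchmark (see `benchmark_models()` defaults).
#' @param k Folds.
#' @param reps Repetitions.
#' @param seed Integer master seed.
#' @return Object of class `cv_benchmark`: `grid` tibble (`model`, `rep`,
#'   `fold`, `auc`), `summary` tibble (`model`, `mean_auc`), `best_model`.
#' @export
repeated_cv_benchmark <- function(X, labels, models = benchmark_models(),
                                  k = 5, reps = 10, seed = 1) {
  if (!is.matrix(X)) X <- as.matrix(X)
  assert_binary_labels(labels, nrow(X))
  y <- label_to_binary(labels)
  if (min(table(y)) < k) abort("Each class needs at least `k` samples.")
  rows <- list()
  for (r in seq_len(reps)) {
    foldid <- stratified_folds(y, k, substream_seed(seed, paste0("cv_rep_", r)))
    for (f in seq_len(k)) {
      te <- foldid == f
      for (m in models) {
        sc <- tryCatch(
          fit_and_score(m, X[!te, , drop = FALSE], y[!te],
                        X[te, , drop = FALSE], pos = 1,
                        seed = substream_seed(seed, paste0(m, "_", r, "_", f))),
          error = function(e) {
            warn(sprintf("Model %s failed on rep %d fold %d: %s", m, r, f,
                         conditionMessage(e)))
            NULL
          })
        a <- if (is.null(sc)) NA_real_ else auc_score(sc, y[te])
        rows[[length(rows) + 1]] <- tibble(model = m, rep = r, fold = f, auc = a)
      }
    }
  }
  grid <- bind_rows(rows)
  if (mean(is.na(grid$auc)) > 0.2) {
    abort("More than 20% of benchmark folds failed to fit.")
  }
  summary <- grid |>
    group_by(.data$model) |>
    summarise(mean_auc = mean(.data$auc, na.rm = TRUE), .groups = "drop") |>
    arrange(desc(.data$mean_auc))
  structure(list(grid = grid, summary = summary,
                 best_model = summary$model[1], k = k, reps = reps, seed = seed),
            class = "cv_benchmark")
}

#' @export
print.cv_benchmark <- function(x, ...) {
  cat("<cv_benchmark>", x$reps, "x", x$k, "fold CV; best model:",
      x$best_model, "\n")
  print(x$summary)
  invisible(x)
}

#' @rdname repeated_cv_benchmark
#' @param x A `cv_benchmark`.
#' @param ... Unused.
#' @method tidy cv_benchmark
#' @export
tidy.cv_benchmark <- function(x, ...) x$grid

#' @rdname repeated_cv_benchmark
#' @method glance cv_benchmark
#' @export
glance.cv_benchmark <- function(x, ...) {
  tibble(best_model = x$best_model,
         best_mean_auc = x$summary$mean_auc[1],
         k = x$k, reps = x$reps)
}

#' Fit a final model on the training cohort and evaluate on a test cohort
#'
#' Refits the chosen model on all training samples and reports ROC, AUC and
#' the Youden operating point on the held-out cohort only. Overlapping
#' sample ids between the cohorts are refused (leakage guard) unless
#' explicitly allowed.
#'
#' @param X_train,X_test Samples x features matrices with sample ids as
#'   rownames.
#' @param y_train,y_test Binary labels.
#' @param model One of `benchmark_models()`.
#' @param seed Integer seed.
#' @param allow_overlap Disable the disjointness guard (for optimism
#'   diagnostics only).
#' @param ci Include a DeLong confidence interval in the report?
#' @return An [evaluation_report()] computed on the test scores.
#' @export
fit_final_and_test <- function(X_train, y_train, X_test, y_test,
                               model = "random_forest", seed = 1,
                               allow_overlap = FALSE, ci = FALSE) {
  if (!is.matrix(X_train)) X_train <- as.matrix(X_train)
  if (!is.matrix(X_test)) X_test <- as.matrix(X_test)
  overlap <- intersect(rownames(X_train), rownames(X_test))
  if (length(overlap) > 0 && !allow_overlap) {
    abort(sprintf("Train and test cohorts share sample id(s): %s.",
                  paste(head(overlap, 5), collapse = ", ")))
  }
  y_tr <- label_to_binary(y_train)
  scores <- fit_and_score(model, X_train, y_tr, X_test, pos = 1,
                          seed = substream_seed(seed, paste0("final_", model)))
  evaluation_report(scores, y_test, ci = ci)
}
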