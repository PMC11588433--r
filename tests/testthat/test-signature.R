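test_that("the univariate screen keeps discriminating genes and drops flat ones", {
  set.seed(1)
  n <- 100
  y <- rep(c("early", "advanced"), each = n / 2)
  flat <- rnorm(n / 2)
  expr <- rbind(
    same = c(flat, flat),                                  # identical in both classes
    const = rep(4, n),                                     # constant
    signal = 1.5 * (y == "advanced") + rnorm(n, sd = 0.5)
  )
  colnames(expr) <- sprintf("s%03d", seq_len(n))
  expect_warning(res <- univariate_screen(expr, y), "constant")
  expect_false(res$kept[res$gene == "same"])
  expect_false(res$kept[res$gene == "const"])
  expect_equal(res$p_value[res$gene == "const"], 1)
  expect_true(res$kept[res$gene == "signal"])
})

test_that("a planted 1.5 log2 effect is detected in almost every draw", {
  kept <- vapply(1:20, function(sd_) {
    set.seed(sd_)
    y <- rep(c("early", "advanced"), each = 50)
    x <- 1.5 * (y == "advanced") + rnorm(100, sd = 0.3)
    expr <- matrix(x, 1, 100, dimnames = list("g1", sprintf("s%03d", 1:100)))
    univariate_screen(expr, y)$kept
  }, logical(1))
  expect_gte(mean(kept), 0.95)
})

test_that("complete separation falls back to a flagged likelihood-ratio test", {
  y <- rep(c("early", "advanced"), each = 10)
  x <- c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1))
  expr <- matrix(x, 1, 20, dimnames = list("g1", sprintf("s%02d", 1:20)))
  res <- univariate_screen(expr, y)
  expect_true(res$separation)
  expect_true(res$kept)
  expect_lt(res$p_value, 0.01)
})

test_that("screen p-values agree with a permutation oracle on a toy gene", {
  set.seed(42)
  x <- rnorm(20)
  y <- rep(0:1, each = 10)
  expr <- matrix(x, 1, 20, dimnames = list("g1", sprintf("s%02d", 1:20)))
  p_screen <- univariate_screen(expr, y)$p_value
  # frozen permutation p-value: mean over 10,000 label permutations
  # (set.seed(1)) of |Wald z| >= |observed z| for this exact fixture
  p_perm <- 0.2415
  expect_lt(abs(p_screen - p_perm), 0.01)
})

test_that("the LASSO path shrinks to zero genes at its sparse end", {
  sc <- standard_cohort(n_per_class = 30, seed = 7)
  lab <- sc$cohort$truth$labels$label
  cand <- c(names(sc$spec$signature_genes), rownames(sc$cohort$expr)[101:130])
  lr <- lasso_select(sc$cohort$expr[cand, ], lab, n_folds = 5, seed = 1)
  beta_first <- coef(lr$glmnet_fit, s = lr$lambda_path[1])
  expect_equal(sum(as.numeric(beta_first)[-1] != 0), 0)
  expect_equal(lr$coefficients$gene[lr$coefficients$coefficient != 0],
               lr$selected_genes)
})

test_that("selection recovers the planted signature and is reproducible", {
  sc <- standard_cohort(n_per_class = 30, seed = 3)
  sig <- names(sc$spec$signature_genes)
  lab <- sc$cohort$truth$labels$label
  cand <- c(sig, setdiff(rownames(sc$cohort$expr),
                         c(sig, unlist(sc$spec$marker_table)))[1:40])
  a <- lasso_select(sc$cohort$expr[cand, ], lab, n_folds = 5, seed = 9)
  b <- lasso_select(sc$cohort$expr[cand, ], lab, n_folds = 5, seed = 9)
  expect_identical(a$coefficients, b$coefficients)
  expect_gte(sum(sig %in% a$selected_genes), 7)
})

test_that("selection is invariant to gene scaling and sample order", {
  sc <- standard_cohort(n_per_class = 25, seed = 5)
  sig <- names(sc$spec$signature_genes)
  lab <- sc$cohort$truth$labels$label
  cand <- c(sig, setdiff(rownames(sc$cohort$expr),
                         c(sig, unlist(sc$spec$marker_table)))[1:30])
  x <- sc$cohort$expr[cand, ]
  base <- lasso_select(x, lab, n_folds = 5, seed = 2)

  x_scaled <- x
  x_scaled[cand[1], ] <- x_scaled[cand[1], ] * 10
  scaled <- lasso_select(x_scaled, lab, n_folds = 5, seed = 2)
  expect_setequal(base$selected_genes, scaled$selected_genes)

  perm <- sample(ncol(x))
  permuted <- lasso_select(x[, perm], lab[perm], n_folds = 5, seed = 2)
  expect_setequal(base$selected_genes, permuted$selected_genes)
})

test_that("pure-noise cohorts do not produce runaway selections", {
  n_sel <- vapply(1:10, function(sd_) {
    set.seed(sd_)
    expr <- named_matrix(rnorm(100 * 80, 8, 1), 100, 80)
    lab <- rep(c("early", "advanced"), each = 40)
    scr <- suppressWarnings(univariate_screen(expr, lab))
    kept <- scr$gene[scr$kept]
    if (length(kept) < 2) return(0L)
    length(lasso_select(expr[kept, , drop = FALSE], lab,
                        seed = sd_, lambda_rule = "1se")$selected_genes)
  }, integer(1))
  expect_lte(median(n_sel), 8)
})

test_that("lasso_select guards its inputs", {
  x <- random_expr(5, 20, seed = 1)
  expect_error(lasso_select(x, rep("early", 20)), "two classes")
  expect_error(lasso_select(x, rep(c("early", "advanced"), each = 10),
                            n_folds = 15), "exceeds")
  expect_error(lasso_select(x[1, , drop = FALSE],
                            rep(c("early", "advanced"), each = 10)),
               "at least 2")
})

test_that("tidy and glance summarise a lasso fit", {
  sc <- standard_cohort(n_per_class = 25, seed = 13)
  lab <- sc$cohort$truth$labels$label
  cand <- c(names(sc$spec$signature_genes), rownames(sc$cohort$expr)[101:120])
  lr <- lasso_select(sc$cohort$expr[cand, ], lab, n_folds = 5, seed = 1)
  td <- tidy(lr)
  expect_named(td, c("gene", "coefficient", "selected"))
  gl <- glance(lr)
  expect_equal(sum(td$selected), gl$n_selected)
  expect_equal(gl$n_selected, length(lr$selected_genes))
  expect_equal(gl$lambda_rule, "min")
})
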