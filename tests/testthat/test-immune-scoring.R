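test_that("marker-mean scores behave like means", {
  x <- random_expr(10, 8, seed = 1)
  mk <- list(solo = "g001", duo = c("g002", "g003"))
  sc <- mcp_score(x, mk)
  expect_equal(sc$solo, unname(x["g001", ]))
  expect_equal(sc$duo, unname(colMeans(x[c("g002", "g003"), ])))

  # adding a constant to expression adds it to every score
  sc2 <- mcp_score(x + 3, mk)
  expect_equal(sc2$solo, sc$solo + 3)
  expect_equal(sc2$duo, sc$duo + 3)

  expect_warning(mcp_score(x, list(p = c("g001", "absent"))), "absent")
  expect_error(mcp_score(x, list(p = "missing_gene")), "no markers")
})

test_that("marker scores track planted mixing proportions", {
  spec <- cohort_spec(n_per_class = 20, n_genes = 200, noise_sd = 0.3, seed = 4)
  co <- generate_cohort(spec)
  sc <- mcp_score(co$expr, spec$marker_table)
  rho <- vapply(mcp_populations(), function(p) {
    cor(sc[[p]], co$truth$proportions[, p], method = "spearman")
  }, numeric(1))
  expect_true(all(rho >= 0.8))
})

test_that("ssGSEA matches the step-by-step random-walk oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- random_expr(5, 1, seed = seed)[, 1]
    names(x) <- paste0("g", 1:5)
    expr <- matrix(x, 5, 2, dimnames = list(names(x), c("s1", "s2")))
    set <- names(sort(x, decreasing = TRUE))[1:2]   # the top-2 ranked genes
    got <- ssgsea_score(expr, set)
    expect_lt(abs(got$score[1] - oracle_ssgsea(x, set)), 1e-10)
    expect_equal(got$score[1], got$score[2], tolerance = 1e-12)
  }
  # larger random toys with arbitrary sets
  for (seed in 11:20) {
    set.seed(seed)
    x <- setNames(rnorm(9), paste0("g", 1:9))
    expr <- matrix(x, 9, 1, dimnames = list(names(x), "s1"))
    set <- sample(names(x), 3)
    expect_lt(abs(ssgsea_score(expr, set)$score - oracle_ssgsea(x, set)), 1e-10)
  }
})

test_that("ssGSEA depends only on within-sample ranks", {
  x <- random_expr(40, 6, seed = 21)
  set <- rownames(x)[c(3, 9, 17)]
  base <- ssgsea_score(x, set)
  # strictly monotone per-sample transform preserves every score
  transformed <- 2^x + 1
  expect_equal(ssgsea_score(transformed, set)$score, base$score,
               tolerance = 1e-12)
  # sample reordering permutes scores identically
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(ssgsea_score(x[, perm], set)$score, base$score[perm],
               tolerance = 1e-12)
})

test_that("top-ranked sets outscore bottom-ranked sets in every sample", {
  x <- random_expr(30, 5, seed = 22)
  for (j in 1:5) {
    ord <- rownames(x)[order(-x[, j])]
    top <- ssgsea_score(x, ord[1:5])$score[j]
    bottom <- ssgsea_score(x, rev(ord)[1:5])$score[j]
    expect_gt(top, bottom)
  }
  expect_error(ssgsea_score(x, character()), "No gene-set members")
  expect_error(ssgsea_score(x, rownames(x)), "every gene")
})

test_that("module scores subtract bin-matched controls", {
  x <- random_expr(60, 10, seed = 23)
  set <- rownames(x)[1:5]
  # control pool forced to the set itself: exact zero
  zero <- module_score(x, set, control_pool = set)
  expect_true(all(zero$score == 0))

  a <- module_score(x, set, n_bins = 6, n_ctrl = 8, seed = 5)
  b <- module_score(x, set, n_bins = 6, n_ctrl = 8, seed = 5)
  expect_identical(a, b)

  w <- capture_warnings(module_score(x, set, n_bins = 6, n_ctrl = 50, seed = 1))
  expect_true(all(grepl("replacement", w)))
  expect_error(module_score(x, set, n_bins = 1), "n_bins")
})

test_that("planted upregulated sets score higher in the advanced class", {
  higher <- vapply(1:10, function(sd_) {
    spec <- cohort_spec(n_per_class = 20, n_genes = 200, noise_sd = 0.3, seed = sd_)
    co <- generate_cohort(spec)
    ms <- suppressWarnings(module_score(co$expr, names(spec$signature_genes),
                                        n_ctrl = 20, seed = sd_))
    adv <- co$truth$labels$label == "advanced"
    mean(ms$score[adv]) > mean(ms$score[!adv])
  }, logical(1))
  expect_true(all(higher))
})

test_that("gene-immune correlations report r, p and BH-adjusted p", {
  spec <- cohort_spec(n_per_class = 15, n_genes = 120, noise_sd = 0.3, seed = 30)
  co <- generate_cohort(spec)
  sc <- mcp_score(co$expr, spec$marker_table)
  genes <- names(spec$signature_genes)[1:3]
  tab <- correlate_gene_immune(co$expr, genes, sc)
  expect_equal(nrow(tab), 3 * 10)
  expect_true(all(tab$adj_p >= tab$p_value - 1e-12, na.rm = TRUE))

  # a gene equal to a score column correlates perfectly
  x2 <- rbind(co$expr, mirror = sc[["T cells"]])
  tab2 <- correlate_gene_immune(x2, "mirror", sc, method = "pearson")
  row <- tab2[tab2$population == "T cells", ]
  expect_equal(row$estimate, 1, tolerance = 1e-12)
  expect_lt(row$p_value, 1e-12)

  # constant vector: NA with warning
  x3 <- rbind(co$expr, flat = rep(2, ncol(co$expr)))
  expect_warning(tab3 <- correlate_gene_immune(x3, "flat", sc), "undefined")
  expect_true(all(is.na(tab3$estimate)))
})

test_that("spearman correlation agrees with an exhaustive permutation oracle", {
  set.seed(7)
  xa <- rnorm(10)
  xb <- 0.5 * xa + rnorm(10)
  expr <- matrix(xa, 1, 10, dimnames = list("g1", sprintf("s%02d", 1:10)))
  sc <- tibble::tibble(sample = colnames(expr), pop = xb)
  got <- correlate_gene_immune(expr, "g1", sc, method = "spearman")
  # frozen oracle: mean over 10,000 permutations (set.seed(2)) of
  # |spearman rho| >= |observed rho| for this exact fixture
  p_perm <- 0.6014
  expect_lt(abs(got$p_value - p_perm), 0.02)

  # rank invariance: monotone transform of either variable changes nothing
  got2 <- correlate_gene_immune(2^expr, "g1", sc, method = "spearman")
  expect_equal(got$estimate, got2$estimate, tolerance = 1e-12)
  expect_equal(got$p_value, got2$p_value, tolerance = 1e-12)
})
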