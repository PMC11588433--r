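two_gene_matrix_with_cor <- function(rho, n = 20) {
  # construct two rows whose sample correlation is exactly rho
  x <- scale(seq_len(n))[, 1]
  z <- stats::residuals(lm(rnorm(n) ~ x))
  z <- z / sqrt(sum(z^2) / (n - 1))
  y <- rho * x + sqrt(1 - rho^2) * z
  m <- rbind(x, y, x + y)
  dimnames(m) <- list(c("gx", "gy", "gz"), sprintf("s%02d", seq_len(n)))
  m
}

test_that("adjacency follows the analytic unsigned and signed forms", {
  set.seed(1)
  m <- two_gene_matrix_with_cor(-0.8)
  expect_equal(cor(m["gx", ], m["gy", ]), -0.8, tolerance = 1e-12)
  a_u <- adjacency_matrix(m, power = 2)
  expect_equal(a_u["gx", "gy"], 0.64, tolerance = 1e-10)
  a_s <- adjacency_matrix(m, power = 2, signed = TRUE)
  expect_equal(a_s["gx", "gy"], 0.01, tolerance = 1e-10)
  expect_true(all(diag(a_u) == 0))

  r <- random_expr(20, 15, seed = 2)
  a <- adjacency_matrix(r, 6)
  expect_equal(a, t(a))
  expect_equal(adjacency_matrix(r, 1), {
    cc <- abs(cor(t(r))); diag(cc) <- 0; cc
  })

  r["g001", ] <- 5
  expect_error(adjacency_matrix(r, 2), "g001")
})

test_that("TOM matches hand computation and the triple-loop oracle", {
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 0
  dimnames(a3) <- list(paste0("g", 1:3), paste0("g", 1:3))
  tom3 <- tom_similarity(a3)
  expect_equal(tom3[1, 2], (0.25 + 0.5) / (1 + 1 - 0.5), tolerance = 1e-15)

  a0 <- a3 * 0
  expect_true(all(tom_similarity(a0)[upper.tri(a0)] == 0))

  for (seed in 1:10) {
    a <- random_adjacency(15, seed)
    tom <- tom_similarity(a)
    expect_lt(max(abs(tom - oracle_tom(a))), 1e-10)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }

  bad <- random_adjacency(5, 1)
  bad[1, 2] <- bad[1, 2] + 0.1
  expect_error(tom_similarity(bad), "symmetric")
})

test_that("soft-threshold choice matches an independent exhaustive scan", {
  spec <- cohort_spec(n_per_class = 25, n_genes = 60, noise_sd = 0.3,
                      module_spec = data.frame(size = c(25, 25),
                                               loading = c(0.9, 0.9)), seed = 6)
  mm <- generate_module_matrix(spec)
  scan <- soft_threshold_scan(mm$expr, powers = 1:12)
  expect_equal(scan$chosen_power, oracle_choose_power(mm$expr, 1:12))
  expect_true(scan$chosen_power %in% 1:12)
})

test_that("null data follow the scan rule; the argmax fallback is flagged", {
  r <- random_expr(60, 40, seed = 9, mean = 0, sd = 1)
  scan <- soft_threshold_scan(r, powers = 1:10)
  expect_equal(scan$chosen_power, oracle_choose_power(r, 1:10))
  # with an unreachable acceptance threshold the scan falls back to the
  # best-fitting power and says so
  strict <- soft_threshold_scan(r, powers = 1:10, r2_threshold = 0.999)
  expect_true(strict$fallback)
  expect_equal(strict$chosen_power,
               strict$scan$power[which.max(strict$scan$fit_r2)])
})

test_that("constant genes are dropped with a warning; all-constant errors", {
  r <- random_expr(20, 12, seed = 3)
  r["g002", ] <- 1
  expect_warning(soft_threshold_scan(r, powers = 1:3), "constant")
  flat <- named_matrix(1, 12, 10)
  expect_error(suppressWarnings(soft_threshold_scan(flat, powers = 1:3)),
               "constant")
})

test_that("planted modules are recovered with high membership agreement", {
  spec <- cohort_spec(n_per_class = 25, n_genes = 60, noise_sd = 0.1,
                      module_spec = data.frame(size = c(30, 30),
                                               loading = c(0.95, 0.95)), seed = 8)
  mm <- generate_module_matrix(spec)
  tom <- tom_similarity(adjacency_matrix(mm$expr, 6))
  ma <- detect_modules(tom, min_size = 10)
  expect_equal(length(ma$sizes), 2)
  truth <- mm$truth$module_membership$module
  found <- ma$assignment$module[match(mm$truth$module_membership$gene,
                                      ma$assignment$gene)]
  agree <- max(mean(found == truth), mean(found == 3 - truth))
  expect_gte(agree, 0.9)
})

test_that("module detection is invariant to gene order and rescaling", {
  spec <- cohort_spec(n_per_class = 20, n_genes = 40, noise_sd = 0.2,
                      module_spec = data.frame(size = c(20, 20),
                                               loading = c(0.9, 0.9)), seed = 10)
  mm <- generate_module_matrix(spec)
  tom <- tom_similarity(adjacency_matrix(mm$expr, 6))
  ma <- detect_modules(tom, min_size = 5)

  set.seed(1)
  perm <- sample(nrow(mm$expr))
  tom_p <- tom_similarity(adjacency_matrix(mm$expr[perm, ], 6))
  ma_p <- detect_modules(tom_p, min_size = 5)
  merged <- merge(ma$assignment, ma_p$assignment, by = "gene")
  expect_equal(length(unique(paste(merged$module.x, merged$module.y))),
               length(unique(merged$module.x)))

  tom_s <- tom_similarity(adjacency_matrix(mm$expr * 3, 6))
  expect_identical(detect_modules(tom_s, min_size = 5)$assignment, ma$assignment)

  expect_error(detect_modules(tom, min_size = 1), "min_size")
})

test_that("null matrices yield no modules at the default cut", {
  r <- random_expr(50, 40, seed = 11, mean = 0, sd = 1)
  tom <- tom_similarity(adjacency_matrix(r, 7))
  ma <- detect_modules(tom)
  expect_true(all(ma$assignment$module == 0))
})

test_that("module eigengene is the unit-variance, sign-fixed first PC", {
  # identical member genes: eigengene correlates perfectly with each
  base <- random_expr(1, 20, seed = 12)
  m <- rbind(base, base, base)
  rownames(m) <- c("a", "b", "c")
  e <- module_eigengene(m, c("a", "b", "c"))
  expect_equal(abs(cor(e, m["a", ])), 1, tolerance = 1e-12)
  expect_gt(cor(e, m["a", ]), 0)
  expect_equal(sd(e), 1, tolerance = 1e-12)

  # PC1 optimality: explains at least as much standardized variance as any
  # single member's direction
  x <- random_expr(10, 25, seed = 13)
  e2 <- module_eigengene(x, rownames(x))
  xs <- t(scale(t(x)))
  explained <- function(direction) {
    d <- direction / sd(direction)
    sum(apply(xs, 1, function(g) cov(g, d))^2)
  }
  best_single <- max(apply(xs, 1, explained))
  expect_gte(explained(e2) + 1e-10, best_single)

  # negating every member leaves kME structure unchanged
  x_neg <- -x
  e3 <- module_eigengene(x_neg, rownames(x_neg))
  expect_equal(abs(cor(e2, e3)), 1, tolerance = 1e-10)
  expect_error(module_eigengene(x, "g001"), "at least 2")
})

test_that("kME is the gene-eigengene correlation with planted ordering", {
  spec <- cohort_spec(n_per_class = 20, n_genes = 50, noise_sd = 0.3,
                      module_spec = data.frame(size = 20, loading = 0.9), seed = 14)
  mm <- generate_module_matrix(spec)
  members <- mm$truth$module_membership$gene[mm$truth$module_membership$module == 1]
  e <- module_eigengene(mm$expr, members)
  km <- kme_table(mm$expr, cbind(M1 = e))
  expect_true(all(km$M1 >= -1 & km$M1 <= 1))
  expect_gt(min(km$M1[km$gene %in% members]),
            max(km$M1[!km$gene %in% members]))

  # a gene equal to the eigengene has kME 1
  m2 <- rbind(mm$expr, eig_gene = e)
  km2 <- kme_table(m2, cbind(M1 = e))
  expect_equal(km2$M1[km2$gene == "eig_gene"], 1, tolerance = 1e-12)

  m3 <- mm$expr
  m3["g00002", ] <- 7
  expect_warning(km3 <- kme_table(m3, cbind(M1 = e)), "constant")
  expect_true(is.na(km3$M1[km3$gene == "g00002"]))
})

test_that("hub-gene selection takes top-k per module with stable semantics", {
  spec <- cohort_spec(n_per_class = 25, n_genes = 120, noise_sd = 0.2,
                      module_spec = data.frame(size = rep(30, 4),
                                               loading = rep(0.9, 4)), seed = 15)
  mm <- generate_module_matrix(spec)
  tom <- tom_similarity(adjacency_matrix(mm$expr, 6))
  ma <- detect_modules(tom, min_size = 10)
  expect_equal(length(ma$sizes), 4)
  eig <- module_eigengenes(mm$expr, ma)
  km <- kme_table(mm$expr, eig)

  hubs <- select_hub_genes(km, ma, hub_modules = 1:4, k = 25)
  expect_length(hubs, 100)
  expect_false(anyDuplicated(hubs) > 0)

  # k larger than the module returns the whole module
  all_m1 <- select_hub_genes(km, ma, hub_modules = 1, k = 1000)
  expect_setequal(all_m1, ma$assignment$gene[ma$assignment$module == 1])

  # requesting the same module twice de-duplicates the union
  twice <- select_hub_genes(km, ma, hub_modules = c(1, 1), k = 25)
  expect_length(twice, 25)

  expect_error(select_hub_genes(km, ma, hub_modules = integer()), "non-empty")
  expect_error(select_hub_genes(km, ma, hub_modules = 99), "99")
})

test_that("hub genes recall the strongest planted members across seeds", {
  recalls <- vapply(1:10, function(sd_) {
    spec <- cohort_spec(n_per_class = 20, n_genes = 40, noise_sd = 0.3,
                        module_spec = data.frame(size = c(20, 20),
                                                 loading = c(0.9, 0.9)),
                        seed = sd_)
    mm <- generate_module_matrix(spec)
    tom <- tom_similarity(adjacency_matrix(mm$expr, 6))
    ma <- detect_modules(tom, min_size = 8)
    if (length(ma$sizes) < 2) return(NA_real_)
    eig <- module_eigengenes(mm$expr, ma)
    km <- kme_table(mm$expr, eig)
    hubs <- select_hub_genes(km, ma, hub_modules = seq_along(ma$sizes), k = 15)
    planted <- mm$truth$module_membership$gene[mm$truth$module_membership$module > 0]
    mean(hubs %in% planted)
  }, numeric(1))
  expect_gte(mean(recalls, na.rm = TRUE), 0.9)
})

test_that("metacell aggregation denoises without changing dimensions", {
  r <- random_expr(30, 20, seed = 16)
  expect_identical(metacell_aggregate(r, 0), r)
  agg <- metacell_aggregate(r, 3)
  expect_identical(dim(agg), dim(r))

  reduced <- vapply(1:10, function(sd_) {
    x <- random_expr(30, 20, seed = 100 + sd_)
    mean(apply(metacell_aggregate(x, 4), 1, var)) < mean(apply(x, 1, var))
  }, logical(1))
  expect_true(all(reduced))

  expect_error(metacell_aggregate(r, 20), "smaller")
  expect_error(metacell_aggregate(r, -1), ">= 1")
})
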