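test_that("a one-population, noise-free cohort reproduces the population profile", {
  mk <- list("Monocytic lineage" = c("g00001", "g00002"))
  spec <- cohort_spec(
    n_per_class = 5, n_genes = 20,
    signature_genes = setNames(numeric(0), character(0)),
    marker_table = mk,
    mixing_concentration = list(early = c("Monocytic lineage" = 1),
                                advanced = c("Monocytic lineage" = 1)),
    noise_sd = 0, seed = 3
  )
  co <- generate_cohort(spec)
  expected <- log2(2^co$truth$profiles[, 1] + 1)
  for (j in seq_len(ncol(co$expr))) {
    expect_equal(unname(co$expr[, j]), unname(expected), tolerance = 1e-12)
  }
})

test_that("planted class shifts are recovered in the group mean difference", {
  diffs <- vapply(1:20, function(sd_) {
    spec <- cohort_spec(n_per_class = 50, n_genes = 120, noise_sd = 0.3, seed = sd_)
    co <- generate_cohort(spec)
    adv <- co$truth$labels$label == "advanced"
    sig <- names(spec$signature_genes)
    mean(rowMeans(co$expr[sig, adv]) - rowMeans(co$expr[sig, !adv]))
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 1.5), 0.2)
})

test_that("generation is deterministic, balanced, finite and non-negative", {
  spec <- cohort_spec(n_per_class = 10, n_genes = 80, seed = 42)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth$proportions, b$truth$proportions)
  tab <- table(a$truth$labels$label)
  expect_equal(unname(tab["early"]), unname(tab["advanced"]))
  expect_true(all(is.finite(a$expr)) && all(a$expr >= 0))
  expect_true(all(abs(rowSums(a$truth$proportions) - 1) < 1e-9))
  expect_true(all(names(spec$signature_genes) %in%
                    names(a$truth$signature_effects)))
})

test_that("invalid cohort specs are refused", {
  expect_error(cohort_spec(n_per_class = 0), "positive")
  expect_error(
    cohort_spec(n_genes = 60, signature_genes = c(g99999 = 1.5)),
    "universe"
  )
  expect_error(
    cohort_spec(mixing_concentration = list(
      early = setNames(rep(-1, 10), mcp_populations()),
      advanced = setNames(rep(1, 10), mcp_populations())
    )),
    "positive"
  )
  expect_error(
    cohort_spec(n_genes = 60, marker_table = list(a = "g00001"),
                signature_genes = c(g00002 = 1),
                mixing_concentration = list(early = c(a = 1), advanced = c(a = 1)),
                module_spec = data.frame(size = 100, loading = 1)),
    "exceed"
  )
  expect_error(generate_module_matrix(cohort_spec(n_genes = 60)), "non-empty")
})

test_that("module matrices carry the planted correlation structure", {
  # loading 1, no noise: within-module correlation is exactly 1
  spec0 <- cohort_spec(n_per_class = 10, n_genes = 30, noise_sd = 0,
                       module_spec = data.frame(size = 10, loading = 1), seed = 2)
  mm0 <- generate_module_matrix(spec0)
  members <- mm0$truth$module_membership$gene[mm0$truth$module_membership$module == 1]
  cc <- cor(t(mm0$expr[members, ]))
  expect_equal(max(abs(cc - 1)), 0, tolerance = 1e-12)

  # loading 0.9, noise 0.3: within-module correlation beats between-module
  ok <- vapply(1:10, function(sd_) {
    spec <- cohort_spec(n_per_class = 20, n_genes = 60, noise_sd = 0.3,
                        module_spec = data.frame(size = c(20, 20),
                                                 loading = c(0.9, 0.9)),
                        seed = sd_)
    mm <- generate_module_matrix(spec)
    lab <- mm$truth$module_membership
    m1 <- lab$gene[lab$module == 1]
    m2 <- lab$gene[lab$module == 2]
    cc <- abs(cor(t(mm$expr[c(m1, m2), ])))
    within <- mean(cc[m1, m1][upper.tri(cc[m1, m1])])
    between <- mean(cc[m1, m2])
    within > between
  }, logical(1))
  expect_true(all(ok))
})

test_that("single-gene modules stay below the detection size threshold", {
  spec <- cohort_spec(n_per_class = 15, n_genes = 25, noise_sd = 0.2,
                      module_spec = data.frame(size = c(1, 1), loading = c(1, 1)),
                      seed = 4)
  mm <- generate_module_matrix(spec)
  tom <- tom_similarity(adjacency_matrix(mm$expr, 6))
  ma <- detect_modules(tom, min_size = 5)
  expect_equal(length(ma$sizes), 0)
  expect_true(all(ma$assignment$module == 0))
})

test_that("fixtures round-trip losslessly and refuse bad writes", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_per_class = 6, n_genes = 70,
                      module_spec = data.frame(size = 5, loading = 0.8), seed = 5)
  co <- generate_cohort(spec)
  paths <- write_fixture(co, dir)
  back <- read_expression(paths[["expr"]])
  expect_equal(back, co$expr, tolerance = 1e-9)
  expect_identical(read_labels(paths[["labels"]]), co$truth$labels)

  sets <- read_gmt(paths[["sets"]])
  n_expected <- length(spec$marker_table) + 1 + 1   # markers + module + signature
  expect_length(readLines(paths[["sets"]]), n_expected)
  expect_setequal(sets[["signature"]], names(spec$signature_genes))

  expect_error(write_fixture(co, dir), "already exist")
  expect_silent(suppressMessages(write_fixture(co, dir, overwrite = TRUE)))

  empty <- co
  empty$expr <- co$expr[, 0, drop = FALSE]
  expect_error(write_fixture(empty, dir, prefix = "x"), "empty")
})
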