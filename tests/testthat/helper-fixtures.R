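# Shared fixture builders (all generated in code, nothing read from disk).

named_matrix <- function(values, n_genes, n_samples) {
  matrix(values, n_genes, n_samples,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}

random_expr <- function(n_genes, n_samples, seed, mean = 8, sd = 1) {
  set.seed(seed)
  named_matrix(rnorm(n_genes * n_samples, mean, sd), n_genes, n_samples)
}

# Two planted, well-separated sample groups on a non-negative matrix (for
# NMF subtyping checks): group-1 samples load on the first gene block.
separable_nmf_fixture <- function(n_genes = 40, n_per_group = 15, seed = 1) {
  set.seed(seed)
  grp <- rep(1:2, each = n_per_group)
  v <- matrix(2, n_genes, 2 * n_per_group) +
    outer(rep(c(1, 0), each = n_genes / 2), as.numeric(grp == 1)) * 3 +
    matrix(rnorm(n_genes * 2 * n_per_group, 0, 0.3), n_genes)
  v <- pmax(v, 0)
  dimnames(v) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%03d", seq_len(2 * n_per_group)))
  list(v = v, groups = grp)
}

# Standard signature-recovery cohort: the acceptance conditions for the
# screen + LASSO and CNN analyses (effect 1.5 log2, noise 0.3).
standard_cohort <- function(n_per_class, seed, effect = 1.5) {
  spec <- cohort_spec(n_per_class = n_per_class, n_genes = 300,
                      noise_sd = 0.3, seed = seed)
  spec$signature_genes[] <- effect
  list(spec = spec, cohort = generate_cohort(spec))
}

# Portraits for a cohort on its planted signature genes.
cohort_portraits <- function(cohort, spec, normalizer = NULL) {
  stack <- build_portraits(cohort$expr, names(spec$signature_genes),
                           mcp_score(cohort$expr, spec$marker_table))
  if (!is.null(normalizer)) stack <- normalize_portraits(stack, normalizer)
  stack
}
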