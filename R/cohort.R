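#' The ten immune and stromal populations scored by marker means
#'
#' The standard output set of marker-based microenvironment scoring
#' (MCP-counter): eight immune and two stromal populations.
#'
#' @return Character vector of ten population names.
#' @export
mcp_populations <- function() {
  c("T cells", "CD8 T cells", "Cytotoxic lymphocytes", "B lineage",
    "NK cells", "Monocytic lineage", "Myeloid dendritic cells",
    "Neutrophils", "Endothelial cells", "Fibroblasts")
}

gene_universe <- function(n_genes) sprintf("g%05d", seq_len(n_genes))

#' Build a synthetic marker table over the gene universe
#'
#' Assigns `n_markers` disjoint marker genes to each of the ten standard
#' populations, taken from the front of the gene universe.
#'
#' @param n_genes Size of the gene universe.
#' @param n_markers Markers per population; defaults to 5, reduced on tiny
#'   universes so the ten populations always fit.
#' @return Named list mapping population to marker gene ids.
#' @export
default_marker_table <- function(n_genes, n_markers = NULL) {
  pops <- mcp_populations()
  if (is.null(n_markers)) n_markers <- max(1L, min(5L, n_genes %/% 10L))
  need <- length(pops) * n_markers
  if (n_genes < need) abort("Gene universe too small for the marker table.")
  ids <- gene_universe(n_genes)
  setNames(
    lapply(seq_along(pops), function(i) ids[((i - 1) * n_markers + 1):(i * n_markers)]),
    pops
  )
}

#' Specify a synthetic two-class plaque cohort
#'
#' Describes a cohort whose samples are mixtures of cell-population
#' expression profiles with class-dependent mixing, a planted diagnostic
#' signature shifted in the advanced class, planted co-expression modules
#' driven by latent factors, and Gaussian measurement noise on the log2
#' scale. The default mixing gives the advanced class twice the Dirichlet
#' concentration on the monocytic lineage and neutrophils, matching the
#' direction of immune-infiltration differences reported for advanced
#' plaques.
#'
#' @param n_per_class Samples per class (early / advanced).
#' @param n_genes Size of the gene universe.
#' @param signature_genes Named numeric vector: planted diagnostic genes and
#'   their log2 shift in the advanced class. Defaults to 8 genes at +1.5.
#' @param marker_table Named list population -> marker gene ids (10
#'   populations by default).
#' @param mixing_concentration List with elements `early` and `advanced`,
#'   each a positive numeric vector of Dirichlet concentrations named by
#'   population.
#' @param module_spec Data frame with columns `size` and `loading` (and
#'   optionally `class_delta`, a shift of the module's latent factor in the
#'   advanced class, making the module disease-associated the way hub
#'   modules are); may have zero rows.
#' @param noise_sd Log2-scale Gaussian noise standard deviation.
#' @param infiltration_populations Populations driven by the advanced-class
#'   infiltration gradient (see Details).
#' @param infiltration_range Range of the per-sample multiplier applied to
#'   the infiltration populations' Dirichlet weight in advanced samples.
#'   Advanced plaques differ mainly in how much inflammatory infiltrate they
#'   carry, which makes monocytic and neutrophil abundance rise and fall
#'   together across patients; a shared per-sample multiplier reproduces
#'   that positive coupling, which independent Dirichlet draws cannot
#'   (mixture proportions are otherwise negatively correlated). Set to
#'   `c(1, 1)` to disable.
#' @param marker_boost Log2 elevation of a population's markers in its own
#'   profile.
#' @param seed Integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = 50,
                        n_genes = 500,
                        signature_genes = NULL,
                        marker_table = NULL,
                        mixing_concentration = NULL,
                        module_spec = NULL,
                        noise_sd = 0.3,
                        marker_boost = 5,
                        infiltration_populations = c("Monocytic lineage", "Neutrophils"),
                        infiltration_range = c(0.25, 4),
                        seed = 1) {
  if (n_per_class < 1 || n_genes < 1) abort("Counts in a cohort spec must be positive.")
  ids <- gene_universe(n_genes)
  if (is.null(marker_table)) marker_table <- default_marker_table(n_genes)
  pops <- names(marker_table)
  if (is.null(pops) || anyDuplicated(pops)) abort("`marker_table` must be a uniquely named list.")
  if (is.null(signature_genes)) {
    reserved <- unlist(marker_table, use.names = FALSE)
    free <- setdiff(ids, reserved)
    n_sig <- min(8L, length(free))
    signature_genes <- setNames(rep(1.5, n_sig), free[seq_len(n_sig)])
  }
  if (length(signature_genes) > 0 &&
      (is.null(names(signature_genes)) || anyDuplicated(names(signature_genes)))) {
    abort("`signature_genes` must be a uniquely named numeric vector of log2 effects.")
  }
  if (any(!is.finite(signature_genes))) abort("Signature effect sizes must be finite.")
  if (is.null(mixing_concentration)) {
    base <- setNames(rep(8, length(pops)), pops)
    adv <- base
    adv[names(adv) %in% c("Monocytic lineage", "Neutrophils")] <-
      2 * adv[names(adv) %in% c("Monocytic lineage", "Neutrophils")]
    mixing_concentration <- list(early = base, advanced = adv)
  }
  if (!setequal(names(mixing_concentration), c("early", "advanced"))) {
    abort("`mixing_concentration` needs elements `early` and `advanced`.")
  }
  mixing_concentration <- lapply(mixing_concentration, function(a) {
    if (is.null(names(a))) names(a) <- pops
    if (!setequal(names(a), pops)) abort("Mixing concentrations must be named by population.")
    if (any(a <= 0) || any(!is.finite(a))) abort("Dirichlet concentrations must be strictly positive.")
    a[pops]
  })
  if (is.null(module_spec)) {
    module_spec <- tibble(size = integer(), loading = numeric())
  }
  module_spec <- as_tibble(module_spec)
  if (!all(c("size", "loading") %in% names(module_spec))) {
    abort("`module_spec` must have columns `size` and `loading`.")
  }
  if (!"class_delta" %in% names(module_spec)) {
    module_spec$class_delta <- rep(0, nrow(module_spec))
  }
  if (nrow(module_spec) > 0 && any(module_spec$size < 1)) {
    abort("Module sizes must be positive.")
  }
  outside <- setdiff(
    c(names(signature_genes), unlist(marker_table, use.names = FALSE)),
    ids
  )
  if (length(outside) > 0) {
    abort(sprintf("Identifiers outside the declared gene universe: %s.",
                  paste(head(outside, 5), collapse = ", ")))
  }
  if (sum(module_spec$size) > n_genes) {
    abort("Module sizes exceed the gene universe.")
  }
  structure(
    list(
      n_per_class = as.integer(n_per_class), n_genes = as.integer(n_genes),
      signature_genes = signature_genes, marker_table = marker_table,
      mixing_concentration = mixing_concentration, module_spec = module_spec,
      noise_sd = noise_sd, marker_boost = marker_boost,
      infiltration_populations = intersect(infiltration_populations, pops),
      infiltration_range = infiltration_range,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", 2 * x$n_per_class, " samples (", x$n_per_class,
      "/class), ", x$n_genes, " genes, ", length(x$signature_genes),
      " signature genes, ", nrow(x$module_spec), " planted modules, noise_sd = ",
      x$noise_sd, "\n", sep = "")
  invisible(x)
}

rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Generate a synthetic two-class cohort
#'
#' Samples are built as linear-scale mixtures of population profiles
#' (`log2(sum_k p_k 2^profile_k + 1)`), then the advanced class receives the
#' planted log2 shifts on the signature genes, module genes receive
#' latent-factor terms, and log2-scale Gaussian noise is added. Expression is
#' floored at zero. The ground truth (labels, mixing proportions, module
#' membership, signature effects) is returned alongside.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `plaq_cohort` with elements `expr` (genes x
#'   samples log2 matrix) and `truth` (labels tibble, `proportions` matrix,
#'   `module_membership` tibble, `signature_effects`, `profiles`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (sum(spec$module_spec$size) + length(spec$signature_genes) +
      length(unlist(spec$marker_table)) > spec$n_genes) {
    abort("Signature, marker and module genes exceed the gene universe.")
  }
  ids <- gene_universe(spec$n_genes)
  pops <- names(spec$marker_table)
  n <- 2L * spec$n_per_class
  samples <- sprintf("s%03d", seq_len(n))
  labels <- rep(c("early", "advanced"), each = spec$n_per_class)

  with_seed(substream_seed(spec$seed, "cohort"), {
    baseline <- runif(spec$n_genes, min = 3, max = 7)
    names(baseline) <- ids
    profiles <- matrix(baseline, nrow = spec$n_genes, ncol = length(pops),
                       dimnames = list(ids, pops))
    for (p in pops) {
      profiles[spec$marker_table[[p]], p] <-
        profiles[spec$marker_table[[p]], p] + spec$marker_boost
    }
    props <- matrix(0, n, length(pops), dimnames = list(samples, pops))
    props[labels == "early", ] <-
      rdirichlet(spec$n_per_class, spec$mixing_concentration$early)
    infil <- runif(spec$n_per_class, spec$infiltration_range[1],
                   spec$infiltration_range[2])
    adv_rows <- which(labels == "advanced")
    for (s_i in seq_along(adv_rows)) {
      a <- spec$mixing_concentration$advanced
      a[spec$infiltration_populations] <- a[spec$infiltration_populations] * infil[s_i]
      props[adv_rows[s_i], ] <- rdirichlet(1, a)
    }

    linear <- 2^profiles %*% t(props)          # genes x samples
    expr <- log2(linear + 1)

    sig <- names(spec$signature_genes)
    expr[sig, labels == "advanced"] <-
      expr[sig, labels == "advanced"] + spec$signature_genes

    used <- c(sig, unlist(spec$marker_table, use.names = FALSE))
    free <- setdiff(ids, used)
    membership <- setNames(rep(0L, spec$n_genes), ids)
    if (nrow(spec$module_spec) > 0) {
      # module membership is a property of the spec, not of the draw:
      # consecutive blocks of the free universe, identical across cohorts
      # generated from the same spec (train/test siblings share modules)
      for (m in seq_len(nrow(spec$module_spec))) {
        sz <- spec$module_spec$size[m]
        if (sz > length(free)) abort("Module sizes exceed the available gene universe.")
        pick <- free[seq_len(sz)]
        free <- setdiff(free, pick)
        membership[pick] <- m
        f <- rnorm(n) + spec$module_spec$class_delta[m] * (labels == "advanced")
        expr[pick, ] <- expr[pick, ] +
          spec$module_spec$loading[m] * matrix(f, nrow = sz, ncol = n, byrow = TRUE)
      }
    }
    if (spec$noise_sd > 0) {
      expr <- expr + matrix(rnorm(length(expr), sd = spec$noise_sd),
                            nrow = nrow(expr))
    }
    expr <- pmax(expr, 0)
  })

  truth <- structure(
    list(
      labels = tibble(sample = samples, label = labels),
      proportions = props,
      module_membership = tibble(gene = ids, module = unname(membership)),
      signature_effects = spec$signature_genes,
      profiles = profiles
    ),
    class = "cohort_truth"
  )
  structure(list(expr = expr, truth = truth, spec = spec), class = "plaq_cohort")
}

#' @export
print.plaq_cohort <- function(x, ...) {
  cat("<plaq_cohort> ", nrow(x$expr), " genes x ", ncol(x$expr), " samples; ",
      sum(x$truth$labels$label == "advanced"), " advanced / ",
      sum(x$truth$labels$label == "early"), " early\n", sep = "")
  invisible(x)
}

#' Generate a matrix with planted co-expression modules only
#'
#' Each module's genes are `loading * latent factor + noise` around a common
#' baseline; latent factors are independent between modules and genes outside
#' any module are independent unit-variance noise. Intended as the fixture
#' for the co-expression stage.
#'
#' @param spec A [cohort_spec()] with a non-empty `module_spec`.
#' @return A `plaq_cohort` (labels carry no planted signal here).
#' @export
generate_module_matrix <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (nrow(spec$module_spec) == 0) abort("`module_spec` must be non-empty.")
  if (sum(spec$module_spec$size) > spec$n_genes) {
    abort("Module sizes exceed the gene universe.")
  }
  ids <- gene_universe(spec$n_genes)
  n <- 2L * spec$n_per_class
  samples <- sprintf("s%03d", seq_len(n))
  labels <- rep(c("early", "advanced"), each = spec$n_per_class)
  baseline <- 8

  with_seed(substream_seed(spec$seed, "module_matrix"), {
    expr <- matrix(baseline, nrow = spec$n_genes, ncol = n,
                   dimnames = list(ids, samples))
    membership <- setNames(rep(0L, spec$n_genes), ids)
    at <- 1L
    for (m in seq_len(nrow(spec$module_spec))) {
      sz <- spec$module_spec$size[m]
      pick <- ids[at:(at + sz - 1L)]
      at <- at + sz
      membership[pick] <- m
      f <- rnorm(n)
      expr[pick, ] <- expr[pick, ] +
        spec$module_spec$loading[m] * matrix(f, nrow = sz, ncol = n, byrow = TRUE) +
        matrix(rnorm(sz * n, sd = spec$noise_sd), nrow = sz)
    }
    rest <- membership == 0L
    if (any(rest)) {
      expr[rest, ] <- expr[rest, ] + matrix(rnorm(sum(rest) * n), nrow = sum(rest))
    }
    expr <- pmax(expr, 0)
  })

  truth <- structure(
    list(
      labels = tibble(sample = samples, label = labels),
      proportions = NULL,
      module_membership = tibble(gene = ids, module = unname(membership)),
      signature_effects = setNames(numeric(), character()),
      profiles = NULL
    ),
    class = "cohort_truth"
  )
  structure(list(expr = expr, truth = truth, spec = spec), class = "plaq_cohort")
}

#' Write a cohort to plain-text fixture files
#'
#' Writes the expression matrix as TSV (`<prefix>_expr.tsv`), the labels as a
#' two-column TSV (`<prefix>_labels.tsv`) and the marker table, planted
#' modules and signature as GMT gene sets (`<prefix>_sets.gmt`).
#'
#' @param cohort A `plaq_cohort`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @param overwrite Overwrite existing files?
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_fixture <- function(cohort, dir, prefix = "cohort", overwrite = FALSE) {
  stopifnot(inherits(cohort, "plaq_cohort"))
  if (ncol(cohort$expr) == 0 || nrow(cohort$expr) == 0) {
    abort("Refusing to write an empty cohort (0 genes or 0 samples).")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    expr = file.path(dir, paste0(prefix, "_expr.tsv")),
    labels = file.path(dir, paste0(prefix, "_labels.tsv")),
    sets = file.path(dir, paste0(prefix, "_sets.gmt"))
  )
  clash <- paths[file.exists(paths)]
  if (length(clash) > 0 && !overwrite) {
    abort(sprintf("Files already exist (use overwrite = TRUE): %s",
                  paste(basename(clash), collapse = ", ")))
  }
  write_expression(cohort$expr, paths[["expr"]])
  readr::write_tsv(cohort$truth$labels, paths[["labels"]])
  sets <- cohort$spec$marker_table
  mm <- cohort$truth$module_membership
  for (m in setdiff(unique(mm$module), 0L)) {
    sets[[paste0("module_", m)]] <- mm$gene[mm$module == m]
  }
  if (length(cohort$spec$signature_genes) > 0) {
    sets[["signature"]] <- names(cohort$spec$signature_genes)
  }
  write_gmt(sets, paths[["sets"]])
  invisible(paths)
}
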