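pipeline_schema <- function() {
  list(
    seed = NULL, out_dir = NULL,
    stages = c("simulate", "coexpress", "select", "score", "subtype",
               "benchmark", "portrait_cnn"),
    cohort = c("n_per_class", "n_test_per_class", "n_genes", "effect",
               "noise_sd", "module_sizes", "module_loadings",
               "module_class_delta"),
    coexpress = c("powers", "power", "min_size", "cut_height", "signed",
                  "n_hub_modules", "hub_k"),
    select = c("alpha", "n_folds", "lambda_rule"),
    score = c("ssgsea_alpha", "n_bins", "n_ctrl"),
    subtype = c("rank", "n_restarts", "max_iter", "tol"),
    benchmark = c("k", "reps", "models"),
    portrait_cnn = c("epochs", "learning_rate", "hidden_units", "epsilon",
                     "normalize")
  )
}

#' Default pipeline configuration
#'
#' A demo-scale configuration: a 200-gene, 40+40-sample synthetic training
#' cohort plus a 15+15 test cohort, all stages on.
#'
#' @param seed Master seed.
#' @param out_dir Run directory.
#' @return Nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1, out_dir = tempfile("plaqsig_run_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    stages = list(simulate = TRUE, coexpress = TRUE, select = TRUE,
                  score = TRUE, subtype = TRUE, benchmark = TRUE,
                  portrait_cnn = TRUE),
    cohort = list(n_per_class = 40, n_test_per_class = 15, n_genes = 200,
                  effect = 1.5, noise_sd = 0.3,
                  module_sizes = c(25, 25), module_loadings = c(0.9, 0.9),
                  module_class_delta = c(1.5, 0)),
    coexpress = list(powers = 1:12, min_size = 10, cut_height = 0.95,
                     signed = FALSE, n_hub_modules = 4, hub_k = 25),
    select = list(alpha = 0.05, n_folds = 10, lambda_rule = "min"),
    score = list(ssgsea_alpha = 0.25, n_bins = 24, n_ctrl = 25),
    subtype = list(rank = 2, n_restarts = 10, max_iter = 300, tol = 1e-7),
    benchmark = list(k = 5, reps = 5, models = benchmark_models()),
    portrait_cnn = list(epochs = 300, learning_rate = 1e-3, hidden_units = 16,
                        epsilon = 1e-6, normalize = TRUE)
  )
}

validate_config <- function(config) {
  schema <- pipeline_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown configuration key(s): %s.", paste(unknown, collapse = ", ")))
  }
  for (sec in setdiff(names(schema), c("seed", "out_dir"))) {
    if (!is.null(config[[sec]])) {
      bad <- setdiff(names(config[[sec]]), schema[[sec]])
      if (length(bad) > 0) {
        abort(sprintf("Unknown key(s) in `%s`: %s.", sec, paste(bad, collapse = ", ")))
      }
    }
  }
  if (is.null(config$seed)) abort("Configuration needs a `seed`.")
  if (is.null(config$out_dir)) abort("Configuration needs an `out_dir`.")
  config
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys are schema-validated (unknown keys rejected).
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

write_manifest <- function(out_dir, stage, params, seed, inputs, outputs) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("plaqsig")),
    seed = seed,
    parameters = params,
    inputs = as.list(if (length(inputs)) tools::md5sum(inputs) else character()),
    outputs = as.list(if (length(outputs)) tools::md5sum(outputs) else character())
  )
  names(manifest$inputs) <- basename(names(manifest$inputs) %||% character())
  names(manifest$outputs) <- basename(names(manifest$outputs) %||% character())
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  path
}

need_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    abort(sprintf("Stage `%s` needs missing upstream artifact: %s.",
                  stage, basename(path)))
  }
  path
}

#' Run the full plaque-staging pipeline
#'
#' Executes, as toggled: cohort simulation, co-expression module discovery,
#' signature selection, immune and gene-set scoring, NMF subtyping, the
#' multi-model CV benchmark, and the portrait-CNN train/test evaluation.
#' Every stage writes plain-text outputs plus a JSON manifest (parameters,
#' seed, input/output checksums), so a rerun with the same configuration
#' and seed reproduces identical tables and a run can resume from any
#' completed stage.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or a
#'   path to a YAML file.
#' @return Invisibly, the run directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_config(config)
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  seed <- config$seed
  on <- function(s) isTRUE(config$stages[[s]])
  p_expr <- file.path(out, "cohort_expr.tsv")
  p_lab <- file.path(out, "cohort_labels.tsv")
  p_sets <- file.path(out, "cohort_sets.gmt")
  p_texpr <- file.path(out, "test_expr.tsv")
  p_tlab <- file.path(out, "test_labels.tsv")

  make_spec <- function(sd) {
    cc <- config$cohort
    ms <- tibble(size = cc[["module_sizes"]] %||% integer(),
                 loading = cc[["module_loadings"]] %||% numeric(),
                 class_delta = cc[["module_class_delta"]] %||%
                   rep(0, length(cc[["module_sizes"]] %||% integer())))
    spec0 <- cohort_spec(n_per_class = cc[["n_per_class"]], n_genes = cc[["n_genes"]],
                         noise_sd = cc[["noise_sd"]], module_spec = ms, seed = sd)
    spec0$signature_genes[] <- cc[["effect"]] %||% 1.5
    spec0
  }

  if (on("simulate")) {
    spec <- make_spec(seed)
    cohort <- generate_cohort(spec)
    write_fixture(cohort, out, "cohort", overwrite = TRUE)
    tspec <- make_spec(substream_seed(seed, "test_cohort"))
    tspec$n_per_class <- as.integer(config$cohort$n_test_per_class %||% 15)
    test <- generate_cohort(tspec)
    write_expression(test$expr, p_texpr)
    readr::write_tsv(test$truth$labels, p_tlab)
    write_manifest(out, "simulate", config$cohort, seed, character(),
                   c(p_expr, p_lab, p_sets, p_texpr, p_tlab))
    message(sprintf("simulate: %d genes x %d samples (+%d test samples)",
                    nrow(cohort$expr), ncol(cohort$expr), ncol(test$expr)))
  }

  read_inputs <- function(stage) {
    list(expr = read_expression(need_artifact(p_expr, stage)),
         labels = read_labels(need_artifact(p_lab, stage)))
  }

  p_modules <- file.path(out, "modules.tsv")
  p_eigen <- file.path(out, "eigengenes.tsv")
  p_power <- file.path(out, "soft_threshold.tsv")
  p_hubs <- file.path(out, "hub_genes.txt")
  if (on("coexpress")) {
    inp <- read_inputs("coexpress")
    cx <- config$coexpress
    scan <- soft_threshold_scan(inp$expr, powers = cx[["powers"]] %||% 1:12,
                                signed = isTRUE(cx[["signed"]]))
    power <- cx[["power"]] %||% scan$chosen_power
    adj <- adjacency_matrix(inp$expr, power, signed = isTRUE(cx[["signed"]]))
    tom <- tom_similarity(adj)
    assignment <- detect_modules(tom, min_size = cx[["min_size"]] %||% 10,
                                 cut_height = cx[["cut_height"]] %||% 0.95)
    if (length(assignment$sizes) == 0) {
      abort("No co-expression modules detected; cannot continue to hub selection.")
    }
    eig <- module_eigengenes(inp$expr, assignment)
    kme <- kme_table(inp$expr, eig)
    y <- label_to_binary(inp$labels$label[match(colnames(inp$expr), inp$labels$sample)])
    assoc <- abs(cor(eig, y))
    mods <- as.integer(sub("^M", "", colnames(eig)))
    hub_modules <- mods[order(-assoc)][seq_len(min(cx[["n_hub_modules"]] %||% 4, length(mods)))]
    hubs <- select_hub_genes(kme, assignment, hub_modules, k = cx[["hub_k"]] %||% 25)
    readr::write_tsv(left_join(assignment$assignment, kme, by = "gene"), p_modules)
    readr::write_tsv(as_tibble(eig, rownames = "sample"), p_eigen)
    readr::write_tsv(scan$scan, p_power)
    writeLines(hubs, p_hubs)
    write_manifest(out, "coexpress",
                   c(cx, list(chosen_power = power, hub_modules = hub_modules)),
                   seed, c(p_expr, p_lab), c(p_modules, p_eigen, p_power, p_hubs))
    message(sprintf("coexpress: power %d, %d module(s), %d hub gene(s)",
                    power, length(assignment$sizes), length(hubs)))
  }

  p_sig <- file.path(out, "signature.tsv")
  if (on("select")) {
    inp <- read_inputs("select")
    hubs <- readLines(need_artifact(p_hubs, "select"))
    sl <- config$select
    lab <- inp$labels$label[match(colnames(inp$expr), inp$labels$sample)]
    screen <- univariate_screen(inp$expr[hubs, , drop = FALSE], lab,
                                alpha = sl[["alpha"]] %||% 0.05)
    kept <- screen$gene[screen$kept]
    if (length(kept) < 2) {
      warn("Fewer than 2 genes passed the screen; using the best 2 by p-value.")
      kept <- screen$gene[order(screen$p_value)][1:2]
    }
    lres <- lasso_select(inp$expr[kept, , drop = FALSE], lab,
                         n_folds = min(sl[["n_folds"]] %||% 10, min(table(lab))),
                         seed = seed, lambda_rule = sl[["lambda_rule"]] %||% "min")
    sig <- left_join(
      screen |> select("gene", screen_p = "p_value", "kept"),
      lres$coefficients |> dplyr::rename(lasso_coefficient = "coefficient"),
      by = "gene")
    readr::write_tsv(sig, p_sig)
    write_manifest(out, "select", sl, seed, c(p_expr, p_lab, p_hubs), p_sig)
    message(sprintf("select: %d screened in, %d selected by LASSO",
                    sum(screen$kept), length(lres$selected_genes)))
  }

  p_imm <- file.path(out, "immune_scores.tsv")
  p_hubscore <- file.path(out, "hub_module_score.tsv")
  if (on("score")) {
    inp <- read_inputs("score")
    sets <- read_gmt(need_artifact(p_sets, "score"))
    markers <- sets[intersect(mcp_populations(), names(sets))]
    if (length(markers) == 0) abort("No marker sets found in the cohort GMT.")
    imm <- mcp_score(inp$expr, markers)
    hubs <- readLines(need_artifact(p_hubs, "score"))
    hub_sc <- ssgsea_score(inp$expr, hubs,
                           alpha = config$score$ssgsea_alpha %||% 0.25)
    readr::write_tsv(imm, p_imm)
    readr::write_tsv(hub_sc, p_hubscore)
    write_manifest(out, "score", config$score, seed,
                   c(p_expr, p_sets, p_hubs), c(p_imm, p_hubscore))
    message(sprintf("score: %d population(s), hub set of %d gene(s)",
                    ncol(imm) - 1, length(hubs)))
  }

  p_subtype <- file.path(out, "subtypes.tsv")
  if (on("subtype")) {
    inp <- read_inputs("subtype")
    hubs <- readLines(need_artifact(p_hubs, "subtype"))
    st <- config$subtype
    lab <- inp$labels$label[match(colnames(inp$expr), inp$labels$sample)]
    adv <- inp$expr[hubs, lab == "advanced", drop = FALSE]
    fit <- nmf_factorize(adv, rank = st[["rank"]] %||% 2,
                         n_restarts = st[["n_restarts"]] %||% 10,
                         max_iter = st[["max_iter"]] %||% 300,
                         tol = st[["tol"]] %||% 1e-7, seed = seed)
    assign <- assign_subtypes(fit)
    readr::write_tsv(assign, p_subtype)
    write_manifest(out, "subtype", st, seed, c(p_expr, p_hubs), p_subtype)
    message(sprintf("subtype: %s", paste(sprintf("subtype %d: n=%d",
                                                 sort(unique(assign$subtype)),
                                                 table(assign$subtype)),
                                         collapse = ", ")))
  }

  p_bench <- file.path(out, "benchmark.tsv")
  if (on("benchmark")) {
    inp <- read_inputs("benchmark")
    sig <- readr::read_tsv(need_artifact(p_sig, "benchmark"), show_col_types = FALSE)
    sel <- sig$gene[!is.na(sig$lasso_coefficient) & sig$lasso_coefficient != 0]
    if (length(sel) < 1) {
      warn("No LASSO-selected genes; benchmarking the 8 best screened genes.")
      sel <- sig$gene[order(sig$screen_p)][seq_len(min(8, nrow(sig)))]
    }
    bm <- config$benchmark
    lab <- inp$labels$label[match(colnames(inp$expr), inp$labels$sample)]
    bench <- repeated_cv_benchmark(t(inp$expr[sel, , drop = FALSE]), lab,
                                   models = bm[["models"]] %||% benchmark_models(),
                                   k = bm[["k"]] %||% 5, reps = bm[["reps"]] %||% 10,
                                   seed = seed)
    readr::write_tsv(bench$grid, p_bench)
    write_manifest(out, "benchmark", c(bm, list(best_model = bench$best_model)),
                   seed, c(p_expr, p_lab, p_sig), p_bench)
    message(sprintf("benchmark: best model %s (mean AUC %.3f)",
                    bench$best_model, bench$summary$mean_auc[1]))
  }

  p_report <- file.path(out, "cnn_report.json")
  if (on("portrait_cnn")) {
    inp <- read_inputs("portrait_cnn")
    sig <- readr::read_tsv(need_artifact(p_sig, "portrait_cnn"), show_col_types = FALSE)
    sel <- sig$gene[!is.na(sig$lasso_coefficient) & sig$lasso_coefficient != 0]
    if (length(sel) < 8) {
      # portraits use an 8-gene panel (and the CNN needs >= 4 rows); top up
      # a smaller LASSO selection with the best-screened remaining genes
      extra <- setdiff(sig$gene[order(sig$screen_p)], sel)
      sel <- c(sel, head(extra, 8 - length(sel)))
      warn(sprintf("Portrait panel topped up to %d genes from the screen ranking.",
                   length(sel)))
    }
    sets <- read_gmt(need_artifact(p_sets, "portrait_cnn"))
    markers <- sets[intersect(mcp_populations(), names(sets))]
    te_expr <- read_expression(need_artifact(p_texpr, "portrait_cnn"))
    te_lab <- read_labels(need_artifact(p_tlab, "portrait_cnn"))
    pc <- config$portrait_cnn
    lab <- inp$labels$label[match(colnames(inp$expr), inp$labels$sample)]
    tr_stack <- build_portraits(inp$expr, sel, mcp_score(inp$expr, markers),
                                epsilon = pc[["epsilon"]] %||% 1e-6)
    te_stack <- build_portraits(te_expr, sel, mcp_score(te_expr, markers),
                                epsilon = pc[["epsilon"]] %||% 1e-6)
    if (isTRUE(pc[["normalize"]] %||% TRUE)) {
      norm <- portrait_normalizer(tr_stack)
      tr_stack <- normalize_portraits(tr_stack, norm)
      te_stack <- normalize_portraits(te_stack, norm)
    }
    cfg <- cnn_config(epochs = pc[["epochs"]] %||% 500,
                      learning_rate = pc[["learning_rate"]] %||% 1e-3,
                      hidden_units = pc[["hidden_units"]] %||% 16,
                      seed = substream_seed(seed, "cnn"))
    fit <- train_cnn(tr_stack, lab, cfg)
    te_y <- te_lab$label[match(rownames(te_stack), te_lab$sample)]
    report <- evaluation_report(predict(fit, te_stack), te_y, ci = TRUE)
    jsonlite::write_json(
      list(auc = report$auc, threshold = report$threshold,
           sensitivity = report$sensitivity, specificity = report$specificity,
           train_final_accuracy = fit$accuracy_trace[cfg$epochs],
           roc = report$roc$points,
           ci = report$ci),
      p_report, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_manifest(out, "portrait_cnn", config$portrait_cnn, seed,
                   c(p_expr, p_lab, p_sig, p_texpr, p_tlab), p_report)
    message(sprintf("portrait_cnn: test AUC %.3f at threshold %.3f", report$auc,
                    report$threshold))
  }

  invisible(out)
}
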