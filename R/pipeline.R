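#' Run configuration
#'
#' Validates a configuration for [run_pipeline()]. Exactly one input source
#' must be present: either real-data paths (`counts`, optionally `metadata`,
#' plus `gaf` and `obo`) or a `simulation` spec.
#'
#' @param config Named list, or path to a YAML/JSON file holding one.
#' @return A validated `run_config` list with defaults filled in.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  defaults <- list(methods = "pcc",
                   k_grid = c(1, 3, 5, 11, 21, 51),
                   alpha_grid = c(0.5, 0.9, 0.99, 0.999),
                   outer_folds = 3L, inner_folds = 3L,
                   min_pos = 5L, hybrid_threshold = 0.8,
                   batch_method = "none",
                   min_reads = 1e7, max_expr_min = 100, median_expr_min = 1,
                   pseudocount = 0.125,
                   seed = NULL, out_dir = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  has_real <- !is.null(config$counts)
  has_sim <- !is.null(config$simulation)
  if (has_real == has_sim)
    stop("exactly one of a real input ('counts' + 'gaf' + 'obo') or a 'simulation' spec must be given")
  if (has_real && (is.null(config$gaf) || is.null(config$obo)))
    stop("real-data runs need 'gaf' and 'obo' paths")
  if (is.null(config$seed)) stop("a 'seed' must be set for reproducibility")
  if (is.null(config$out_dir)) stop("an 'out_dir' must be set")
  if (length(config$k_grid) == 0L || length(config$alpha_grid) == 0L)
    stop("parameter grids must be non-empty")
  if (has_sim) config$simulation <- do.call(simulation_spec, config$simulation)
  structure(config, class = "run_config")
}

#' Run the full pipeline from a configuration
#'
#' Executes input preparation (simulation, or preprocessing plus annotation
#' labelling), nested cross-validation over the configured methods, and
#' writes predictions, per-term evaluation, a run summary and a content-hash
#' manifest into the output directory. Identical configuration and seed
#' reproduce identical artifacts.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @return Invisibly, a list with the `nested_cv` result, the evaluation
#'   table and the manifest data.frame (`file`, `md5`).
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ic <- NULL
  if (!is.null(config$simulation)) {
    ds <- simulate_dataset(config$simulation)
    Xs <- center_scale(ds$expression)
    Y <- ds$labels
  } else {
    x <- read_expression(config$counts, metadata = config$metadata)
    prep <- preprocess_counts(x, min_reads = config$min_reads,
                              max_expr_min = config$max_expr_min,
                              median_expr_min = config$median_expr_min,
                              pseudocount = config$pseudocount,
                              batch_method = config$batch_method)
    Xs <- prep$scaled
    ont <- read_obo(config$obo)
    ann <- propagate(read_gaf(config$gaf), ont)
    genes <- intersect(rownames(Xs), names(ann$gene_terms))
    if (length(genes) < 10L)
      stop("fewer than 10 annotated genes overlap the expression matrix")
    Xs <- Xs[genes, , drop = FALSE]
    Y <- term_label_matrix(ann, genes, min_pos = config$min_pos)
    ic <- resnik_ic(ann, ont)
  }
  res <- nested_cv(Xs, Y, methods = config$methods,
                   k_grid = config$k_grid, alpha_grid = config$alpha_grid,
                   outer_folds = config$outer_folds,
                   inner_folds = config$inner_folds,
                   seed = config$seed, min_pos = config$min_pos, ic = ic,
                   hybrid_threshold = config$hybrid_threshold)
  eval_dt <- .evaluation_table(res, Y, ic)
  pred_dt <- .prediction_table(res)
  paths <- c(predictions = file.path(config$out_dir, "predictions.tsv"),
             evaluation = file.path(config$out_dir, "evaluation.tsv"),
             summary = file.path(config$out_dir, "summary.json"))
  data.table::fwrite(pred_dt, paths["predictions"], sep = "\t")
  data.table::fwrite(eval_dt, paths["evaluation"], sep = "\t")
  jsonlite::write_json(
    list(seed = config$seed, methods = config$methods,
         n_genes = nrow(Xs), n_samples = ncol(Xs), n_terms = ncol(Y),
         summary = cv_summary(res)),
    paths["summary"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- data.frame(file = basename(unname(paths)),
                         md5 = unname(tools::md5sum(unname(paths))),
                         stringsAsFactors = FALSE)
  data.table::fwrite(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t")
  invisible(list(result = res, evaluation = eval_dt, manifest = manifest))
}

.prediction_table <- function(res) {
  rows <- list()
  for (f in res$folds) {
    for (m in names(f$methods)) {
      sc <- f$methods[[m]]$scores
      if (is.null(sc)) next
      rows[[length(rows) + 1L]] <- data.table::data.table(
        gene = rep(rownames(sc), ncol(sc)),
        term = rep(colnames(sc), each = nrow(sc)),
        score = as.vector(sc), method = m, fold = f$fold)
    }
  }
  data.table::rbindlist(rows)
}

.evaluation_table <- function(res, Y, ic = NULL) {
  rows <- list()
  for (f in res$folds) {
    for (m in names(f$methods)) {
      auc <- f$methods[[m]]$per_term_auc
      rows[[length(rows) + 1L]] <- data.table::data.table(
        fold = f$fold, method = m, term = names(auc),
        n_pos = colSums(Y)[names(auc)], auc = unname(auc),
        ic = if (!is.null(ic)) unname(ic[names(auc)]) else NA_real_)
    }
  }
  data.table::rbindlist(rows)
}

#' Write a fitted model as TSV plus JSON sidecar
#'
#' @param model An `mlc_model`.
#' @param path Output TSV path (`sample_id`, `weight`); a `.json` sidecar
#'   with the term, alpha, objective, t value and selected-sample count is
#'   written next to it.
#' @return Invisibly, the TSV path.
#' @export
write_mlc_model <- function(model, path) {
  stopifnot(inherits(model, "mlc_model"))
  dt <- data.table::data.table(
    sample_id = names(model$weights) %||% seq_along(model$weights),
    weight = unname(model$weights))
  data.table::fwrite(dt, path, sep = "\t")
  side <- sub("\\.tsv$", "", path)
  jsonlite::write_json(
    list(term = model$term, alpha = model$alpha,
         objective_value = model$objective_value, t_value = model$t_value,
         converged = model$converged, n_selected = model$n_selected),
    paste0(side, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
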