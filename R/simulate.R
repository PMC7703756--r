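#' Specification of a synthetic co-expression dataset
#'
#' Describes a dataset in which each GO-like term has a disjoint block of
#' informative samples over which — and only over which — its positive genes
#' are correlated. Defaults are desk-scale; [paper_scale_spec()] gives the
#' full-replication scale.
#'
#' @param n_genes,n_samples Matrix dimensions (default 1000 x 600).
#' @param n_terms Number of terms (default 3).
#' @param positives_per_term Genes annotated with each term (default 50;
#'   positive sets are disjoint).
#' @param informative_block_size Samples in each term's informative block
#'   (default 100; blocks are disjoint, so
#'   `n_terms * informative_block_size <= n_samples`).
#' @param within_block_correlation Target pairwise correlation `rho` of a
#'   term's positive genes across its block, in `[0, 1)` (default 0.7).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_genes = 1000L, n_samples = 600L, n_terms = 3L,
                            positives_per_term = 50L,
                            informative_block_size = 100L,
                            within_block_correlation = 0.7, seed = 1L) {
  spec <- structure(list(n_genes = as.integer(n_genes),
                         n_samples = as.integer(n_samples),
                         n_terms = as.integer(n_terms),
                         positives_per_term = as.integer(positives_per_term),
                         informative_block_size = as.integer(informative_block_size),
                         within_block_correlation = within_block_correlation,
                         seed = as.integer(seed)),
                    class = "simulation_spec")
  validate_simulation_spec(spec)
  spec
}

validate_simulation_spec <- function(spec) {
  with(spec, {
    if (n_terms * informative_block_size > n_samples)
      stop("informative blocks must not overlap: n_terms * informative_block_size <= n_samples")
    if (n_terms * positives_per_term > n_genes)
      stop("positive gene sets must fit: n_terms * positives_per_term <= n_genes")
    if (within_block_correlation < 0 || within_block_correlation >= 1)
      stop("within_block_correlation must lie in [0, 1)")
    if (positives_per_term < 2L) stop("at least 2 positives per term")
  })
  invisible(spec)
}

#' Full-replication scale preset
#'
#' The validation design at publication scale: 7000 genes, 3000 samples,
#' three terms.
#'
#' @param informative_block_size Block size (the published sweep varies it
#'   from 10 to 500).
#' @param ... Overrides passed to [simulation_spec()].
#' @return A `simulation_spec`.
#' @export
paper_scale_spec <- function(informative_block_size = 100L, ...) {
  simulation_spec(n_genes = 7000L, n_samples = 3000L, n_terms = 3L,
                  informative_block_size = informative_block_size, ...)
}

#' Generate a synthetic dataset with known informative-sample blocks
#'
#' One-factor Gaussian model: every entry is standard normal noise, except
#' that within term `l`'s informative block the term's positive genes share a
#' per-sample latent factor,
#' `x[i, m] = sqrt(rho) * s[m] + sqrt(1 - rho) * eps[i, m]`,
#' so that every pair of positive genes has expected correlation `rho` over
#' the block and 0 elsewhere. Values are emitted as an already log-space
#' expression matrix (the generator models the post-transform scale, not
#' counts).
#'
#' @param spec A [simulation_spec()].
#' @return A `simulated_dataset`: list with `expression` (log-space
#'   [expression_matrix()]), `labels` (binary gene x term matrix), `blocks`
#'   (named list of informative sample indices per term) and `spec`.
#' @export
simulate_dataset <- function(spec) {
  validate_simulation_spec(spec)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  samples <- sprintf("s%04d", seq_len(spec$n_samples))
  terms <- sprintf("SIM:%07d", seq_len(spec$n_terms))
  X <- matrix(stats::rnorm(spec$n_genes * spec$n_samples),
              spec$n_genes, spec$n_samples, dimnames = list(genes, samples))
  Y <- matrix(0L, spec$n_genes, spec$n_terms, dimnames = list(genes, terms))
  blocks <- vector("list", spec$n_terms); names(blocks) <- terms
  rho <- spec$within_block_correlation
  b <- spec$informative_block_size
  for (l in seq_len(spec$n_terms)) {
    pos <- ((l - 1L) * spec$positives_per_term + 1L):(l * spec$positives_per_term)
    B <- ((l - 1L) * b + 1L):(l * b)
    Y[pos, l] <- 1L
    blocks[[l]] <- B
    s <- stats::rnorm(b)
    X[pos, B] <- sqrt(rho) * matrix(s, length(pos), b, byrow = TRUE) +
      sqrt(1 - rho) * matrix(stats::rnorm(length(pos) * b), length(pos), b)
  }
  stopifnot(!any(duplicated(unlist(blocks))))  # disjointness, by construction
  structure(list(expression = expression_matrix(X, space = "log"),
                 labels = Y, blocks = blocks, spec = spec),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset: %d genes x %d samples, %d terms, block size %d, rho = %g, seed %d\n",
              x$spec$n_genes, x$spec$n_samples, x$spec$n_terms,
              x$spec$informative_block_size, x$spec$within_block_correlation,
              x$spec$seed))
  invisible(x)
}

#' Sweep the number of informative samples
#'
#' Generates `reps` seeded datasets for every block size, with seeds derived
#' deterministically (and distinctly) from the base spec's seed.
#'
#' @param base A [simulation_spec()] providing all other parameters.
#' @param sizes Integer vector of informative block sizes.
#' @param reps Repetitions per size (default 5).
#' @return A list of `simulated_dataset`s with attributes `sizes` and `reps`.
#' @export
sweep_informative_sizes <- function(base, sizes, reps = 5L) {
  out <- list()
  for (s in sizes) {
    for (r in seq_len(reps)) {
      spec <- base
      spec$informative_block_size <- as.integer(s)
      spec$seed <- substream_seed(base$seed, sprintf("sweep_%d_%d", s, r))
      validate_simulation_spec(spec)
      out[[length(out) + 1L]] <- simulate_dataset(spec)
    }
  }
  structure(out, sizes = sizes, reps = reps)
}

#' Ground-truth correlation reference
#'
#' The Pearson correlation matrix computed only over a term's informative
#' samples — the oracle similarity an all-knowing observer would use, and
#' the upper reference for the learned metric.
#'
#' @param ds A [simulate_dataset()] result.
#' @param term Term identifier or index.
#' @return A `similarity_matrix` (kind `"inner"`) over all genes.
#' @export
ground_truth_pcc_reference <- function(ds, term) {
  stopifnot(inherits(ds, "simulated_dataset"))
  B <- ds$blocks[[term]]
  if (is.null(B)) stop("unknown term: ", term)
  if (length(B) < 3L) stop("informative block has fewer than 3 samples")
  Xs <- center_scale(ds$expression$values[, B, drop = FALSE])
  pairwise_similarity(Xs)
}

#' Weight-recovery diagnostics for a fitted model on simulated data
#'
#' Compares the learned weights inside and outside a term's ground-truth
#' informative block: mean weights, a Wilcoxon rank-sum location test, and
#' the 2 x 2 selected-vs-informative enrichment table with Fisher's exact
#' odds ratio.
#'
#' @param model A fitted `mlc_model` for the simulated term.
#' @param ds The `simulated_dataset` the model was trained on.
#' @param term Term identifier or index.
#' @param eps Selected-sample threshold, see [selected_samples()].
#' @return A `weight_recovery_report` list: `mean_w_in`, `mean_w_out`,
#'   `rank_sum_stat`, `rank_sum_p`, `table` (2 x 2), `odds_ratio`,
#'   `fisher_p`, `n_selected`. When no (or all) samples are selected the
#'   enrichment is reported as undefined (`NA` odds ratio, with a note).
#' @export
weight_recovery_report <- function(model, ds, term, eps = NULL) {
  stopifnot(inherits(model, "mlc_model"), inherits(ds, "simulated_dataset"))
  B <- ds$blocks[[term]]
  if (is.null(B)) stop("unknown term: ", term)
  w <- model$weights
  f <- length(w)
  inb <- seq_len(f) %in% B
  sel <- seq_len(f) %in% selected_samples(model, eps)
  rs <- if (stats::sd(w) == 0) {
    list(statistic = c(W = sum(inb) * sum(!inb) / 2), p.value = 1)
  } else {
    suppressWarnings(stats::wilcox.test(w[inb], w[!inb]))
  }
  tab <- table(factor(sel, c(TRUE, FALSE)), factor(inb, c(TRUE, FALSE)),
               dnn = c("selected", "informative"))
  note <- NULL
  if (!any(sel)) {
    or <- NA_real_; fp <- NA_real_
    note <- "no samples selected; enrichment undefined"
  } else if (all(sel)) {
    or <- 1; fp <- 1
    note <- "all samples selected; no enrichment possible"
  } else if (all(sel == inb)) {
    or <- Inf; fp <- 0
    note <- "selection coincides exactly with the informative block"
  } else {
    ft <- stats::fisher.test(tab)
    or <- unname(ft$estimate); fp <- ft$p.value
  }
  structure(list(term = term,
                 mean_w_in = mean(w[inb]), mean_w_out = mean(w[!inb]),
                 rank_sum_stat = unname(rs$statistic), rank_sum_p = rs$p.value,
                 table = tab, odds_ratio = or, fisher_p = fp,
                 n_selected = sum(sel), note = note),
            class = "weight_recovery_report")
}

#' @export
print.weight_recovery_report <- function(x, ...) {
  cat(sprintf("weight_recovery_report (%s): mean w in-block %.4g, out-of-block %.4g\n",
              x$term, x$mean_w_in, x$mean_w_out))
  cat(sprintf("  rank-sum p = %.3g; selected %d samples; enrichment OR = %s (p = %.3g)\n",
              x$rank_sum_p, x$n_selected, format(x$odds_ratio), x$fisher_p))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Write a simulated dataset to TSV files
#'
#' Writes the expression matrix, the label matrix, the ground-truth blocks
#' and a reproducibility sidecar (the spec, including the seed) into a
#' directory.
#'
#' @param ds A `simulated_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulated_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "simulated_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             blocks = file.path(dir, "blocks.tsv"),
             spec = file.path(dir, "spec.json"))
  write_expression(ds$expression, paths["expression"])
  lab <- data.table::data.table(gene_id = rownames(ds$labels))
  lab <- cbind(lab, data.table::as.data.table(ds$labels))
  data.table::fwrite(lab, paths["labels"], sep = "\t")
  blk <- data.table::data.table(
    term = rep(names(ds$blocks), lengths(ds$blocks)),
    sample_index = unlist(ds$blocks, use.names = FALSE))
  blk$sample_id <- colnames(ds$expression$values)[blk$sample_index]
  data.table::fwrite(blk, paths["blocks"], sep = "\t")
  jsonlite::write_json(unclass(ds$spec), paths["spec"], auto_unbox = TRUE)
  invisible(paths)
}
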