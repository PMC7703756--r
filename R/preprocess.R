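#' Remove low-depth samples
#'
#' Drops every sample whose number of mapped reads is strictly below
#' `min_reads` (retention is therefore `>= min_reads`). When no explicit
#' mapped-read counts are available the column sums of the count matrix are
#' used as a proxy.
#'
#' @param x An [expression_matrix()] in counts space.
#' @param min_reads Depth threshold; default 1e7 mapped reads.
#' @param mapped_reads Optional named numeric vector of mapped-read counts per
#'   sample, overriding the column-sum proxy. Defaults to the `mapped_reads`
#'   attribute set by [read_expression()], if any.
#' @return The filtered `expression_matrix` (gene set unchanged).
#' @export
filter_samples_by_depth <- function(x, min_reads = 1e7, mapped_reads = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$space != "counts")
    stop("depth filtering applies to counts-space matrices")
  if (is.null(mapped_reads)) mapped_reads <- attr(x, "mapped_reads")
  depth <- if (is.null(mapped_reads)) {
    colSums(x$values)
  } else {
    d <- mapped_reads[sample_ids(x)]
    if (anyNA(d)) stop("mapped_reads is missing values for some samples")
    d
  }
  keep <- depth >= min_reads
  if (!any(keep))
    stop(sprintf("all samples have fewer than %g mapped reads", min_reads))
  out <- expression_matrix(x$values[, keep, drop = FALSE],
                           batch_ids = x$batch_ids[keep], space = "counts")
  attr(out, "mapped_reads") <- attr(x, "mapped_reads")
  attr(out, "samples_removed_low_depth") <- sum(!keep)
  out
}

#' Remove lowly-expressed genes
#'
#' Drops genes whose maximum expression over the retained samples is strictly
#' below `max_expr_min`, then genes whose median expression is strictly below
#' `median_expr_min` (the zero-inflation filter).
#'
#' @param x An [expression_matrix()] in counts space, sample-filtered.
#' @param max_expr_min Minimum allowed row maximum; default 100.
#' @param median_expr_min Minimum allowed row median; default 1.
#' @return A list with elements `expression` (the filtered matrix) and
#'   `report` (a [filter_report()]).
#' @export
filter_genes <- function(x, max_expr_min = 100, median_expr_min = 1) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$space != "counts")
    stop("gene expression filters apply to counts-space matrices")
  row_max <- apply(x$values, 1, max)
  keep_max <- row_max >= max_expr_min
  row_med <- apply(x$values[keep_max, , drop = FALSE], 1, stats::median)
  keep_med <- row_med >= median_expr_min
  removed_max <- sum(!keep_max)
  removed_med <- sum(!keep_med)
  keep <- rownames(x$values)[keep_max][keep_med]
  if (length(keep) == 0L)
    stop("no genes pass the expression filters")
  out <- expression_matrix(x$values[keep, , drop = FALSE],
                           batch_ids = x$batch_ids, space = "counts")
  attr(out, "mapped_reads") <- attr(x, "mapped_reads")
  list(expression = out,
       report = filter_report(genes_removed_max_expr = removed_max,
                              genes_removed_median_expr = removed_med))
}

#' Log-transform counts
#'
#' `log(count + pseudocount)` elementwise. The base defaults to 2 with a
#' pseudocount of 0.125, so a zero count maps to exactly -3.
#'
#' @param x An [expression_matrix()] in counts space.
#' @param pseudocount Added before taking the log; default 0.125.
#' @param base Logarithm base; default 2. The base only rescales all values
#'   uniformly and does not affect correlations or the scaled matrix.
#' @return An `expression_matrix` in log space.
#' @export
log_transform <- function(x, pseudocount = 0.125, base = 2) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$space != "counts") stop("input is already log-transformed")
  if (any(x$values < 0)) stop("negative counts cannot be log-transformed")
  out <- expression_matrix(log(x$values + pseudocount, base = base),
                           batch_ids = x$batch_ids, space = "log")
  attr(out, "mapped_reads") <- attr(x, "mapped_reads")
  out
}

#' Remove singleton studies
#'
#' Drops all samples belonging to a study (batch) with only one sample, so
#' that within-batch variances are estimable.
#'
#' @param x An [expression_matrix()].
#' @return The filtered `expression_matrix`; unchanged if no batch is a
#'   singleton. The number of removed batches is recorded in the
#'   `singleton_batches_removed` attribute.
#' @export
drop_singleton_batches <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  tab <- table(x$batch_ids)
  keep <- x$batch_ids %in% names(tab)[tab >= 2L]
  out <- expression_matrix(x$values[, keep, drop = FALSE],
                           batch_ids = x$batch_ids[keep], space = x$space)
  attr(out, "mapped_reads") <- attr(x, "mapped_reads")
  attr(out, "singleton_batches_removed") <- sum(tab == 1L)
  out
}

#' Per-batch location/scale standardization
#'
#' A lightweight batch-effect adjustment: within every batch each gene is
#' centred and scaled to unit variance, then restored to the gene's overall
#' mean and standard deviation. An empirical-Bayes alternative is available
#' through `method = "combat"` (delegated to `sva::ComBat` when installed);
#' `method = "none"` passes the matrix through for pipelines whose input is
#' already batch-corrected.
#'
#' @param x An [expression_matrix()] in log space.
#' @param method One of `"standardize"`, `"combat"`, `"none"`.
#' @return A batch-adjusted `expression_matrix` in log space.
#' @export
batch_correct <- function(x, method = c("standardize", "combat", "none")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "expression_matrix"))
  if (x$space != "log") stop("batch correction expects a log-space matrix")
  if (method == "none") return(x)
  v <- x$values
  if (method == "combat") {
    if (!requireNamespace("sva", quietly = TRUE))
      stop("method = 'combat' requires the 'sva' package")
    v <- sva::ComBat(dat = v, batch = factor(x$batch_ids))
  } else {
    gmean <- rowMeans(v)
    gsd <- apply(v, 1, stats::sd)
    for (b in unique(x$batch_ids)) {
      cols <- which(x$batch_ids == b)
      bm <- rowMeans(v[, cols, drop = FALSE])
      bs <- apply(v[, cols, drop = FALSE], 1, stats::sd)
      bs[bs == 0] <- 1  # constant-within-batch genes: centre only
      v[, cols] <- (v[, cols, drop = FALSE] - bm) / bs * gsd + gmean
    }
  }
  out <- expression_matrix(v, batch_ids = x$batch_ids, space = "log")
  attr(out, "mapped_reads") <- attr(x, "mapped_reads")
  out
}

#' Centre and scale each gene
#'
#' Subtracts the row mean and divides by the row L2 norm, producing the
#' substrate of all co-expression measures: on the resulting rows the plain
#' inner product equals the Pearson correlation of the original vectors.
#'
#' @param x An [expression_matrix()] in log space, or a plain numeric matrix.
#' @return A `scaled_expression`: a numeric matrix (genes x samples) with each
#'   row having mean 0 and L2 norm 1.
#' @export
center_scale <- function(x) {
  v <- if (inherits(x, "expression_matrix")) {
    if (x$space != "log")
      stop("center_scale expects a log-space matrix; apply log_transform first")
    x$values
  } else {
    as.matrix(x)
  }
  if (ncol(v) < 2L) stop("at least two samples are required")
  centred <- v - rowMeans(v)
  norms <- sqrt(rowSums(centred^2))
  bad <- norms == 0
  if (any(bad))
    stop("constant expression rows cannot be scaled: ",
         paste(rownames(v)[bad], collapse = ", "))
  out <- centred / norms
  class(out) <- c("scaled_expression", class(out))
  out
}

#' @export
print.scaled_expression <- function(x, ...) {
  cat(sprintf("scaled_expression: %d genes x %d samples (row mean 0, row L2 norm 1)\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Filter report
#'
#' Audit counts for the preprocessing filters.
#'
#' @param samples_removed_low_depth,genes_removed_max_expr,genes_removed_median_expr,singleton_batches_removed
#'   Non-negative removal counts.
#' @return A `filter_report` list.
#' @export
filter_report <- function(samples_removed_low_depth = 0L,
                          genes_removed_max_expr = 0L,
                          genes_removed_median_expr = 0L,
                          singleton_batches_removed = 0L) {
  counts <- c(samples_removed_low_depth, genes_removed_max_expr,
              genes_removed_median_expr, singleton_batches_removed)
  if (any(counts < 0)) stop("filter counts must be non-negative")
  structure(list(samples_removed_low_depth = as.integer(samples_removed_low_depth),
                 genes_removed_max_expr = as.integer(genes_removed_max_expr),
                 genes_removed_median_expr = as.integer(genes_removed_median_expr),
                 singleton_batches_removed = as.integer(singleton_batches_removed)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:\n")
  for (nm in names(x)) cat(sprintf("  %s: %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Full count-matrix preprocessing pipeline
#'
#' Applies, in order: the sample depth filter, the gene maximum- and
#' median-expression filters, the log transform, singleton-batch removal,
#' optional batch correction, and per-gene centering/scaling. The order is
#' fixed because the gene filters depend on the retained sample set.
#'
#' @param x An [expression_matrix()] in counts space.
#' @param min_reads,max_expr_min,median_expr_min,pseudocount,base Filter and
#'   transform parameters; see the individual steps.
#' @param batch_method Passed to [batch_correct()]; `"none"` by default (use
#'   `"standardize"` or `"combat"` when multiple studies are present).
#' @param mapped_reads Optional per-sample mapped-read counts for the depth
#'   filter.
#' @return A list with `scaled` (the [center_scale()] output), `expression`
#'   (the filtered log-space matrix) and `report` (a [filter_report()]).
#' @export
preprocess_counts <- function(x, min_reads = 1e7, max_expr_min = 100,
                              median_expr_min = 1, pseudocount = 0.125,
                              base = 2, batch_method = "none",
                              mapped_reads = NULL) {
  s <- filter_samples_by_depth(x, min_reads, mapped_reads)
  g <- filter_genes(s, max_expr_min, median_expr_min)
  lg <- log_transform(g$expression, pseudocount, base)
  lg <- drop_singleton_batches(lg)
  singletons <- attr(lg, "singleton_batches_removed") %||% 0L
  lg <- batch_correct(lg, batch_method)
  report <- filter_report(
    samples_removed_low_depth = attr(s, "samples_removed_low_depth"),
    genes_removed_max_expr = g$report$genes_removed_max_expr,
    genes_removed_median_expr = g$report$genes_removed_median_expr,
    singleton_batches_removed = singletons)
  list(scaled = center_scale(lg), expression = lg, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
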