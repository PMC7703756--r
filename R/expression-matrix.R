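#' Expression matrix container
#'
#' A light container for a genes x samples expression matrix together with
#' per-sample study (batch) labels and a flag recording whether the values are
#' raw counts or log-transformed.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Character vector of gene identifiers (defaults to
#'   `rownames(values)`).
#' @param sample_ids Character vector of sample identifiers (defaults to
#'   `colnames(values)`).
#' @param batch_ids Character vector with one study/batch label per sample.
#'   Defaults to a single shared batch.
#' @param space Either `"counts"` (non-negative raw counts) or `"log"`.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (matrix with gene/sample dimnames), `batch_ids` and `space`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              batch_ids = NULL,
                              space = c("counts", "log")) {
  space <- match.arg(space)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(values)))
  if (length(gene_ids) != nrow(values))
    stop("length of 'gene_ids' does not match the number of rows")
  if (length(sample_ids) != ncol(values))
    stop("length of 'sample_ids' does not match the number of columns")
  if (is.null(batch_ids)) batch_ids <- rep("batch1", ncol(values))
  if (length(batch_ids) != ncol(values))
    stop("length of 'batch_ids' does not match the number of samples")
  if (space == "counts" && any(values < 0, na.rm = TRUE))
    stop("counts-space expression must be non-negative")
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  structure(list(values = values,
                 batch_ids = as.character(batch_ids),
                 space = space),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s space, %d batches)\n",
              nrow(x$values), ncol(x$values), x$space,
              length(unique(x$batch_ids))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Read a count matrix and optional sample metadata from TSV/CSV
#'
#' The matrix file must have genes as rows, a header of sample identifiers and
#' gene identifiers in the first column. The optional metadata file needs
#' columns `sample_id` and `batch_id`; a `mapped_reads` column, when present,
#' is attached for use by [filter_samples_by_depth()].
#'
#' @param path Path to the expression table (TSV or CSV; inferred by
#'   `data.table::fread`).
#' @param metadata Optional path to the sample-metadata table.
#' @param space Value space of the stored matrix, `"counts"` by default.
#' @return An [expression_matrix()]; mapped-read counts, when supplied, are
#'   stored in the `mapped_reads` attribute.
#' @export
read_expression <- function(path, metadata = NULL, space = "counts") {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  genes <- as.character(dt[[1]])
  values <- as.matrix(dt[, -1, drop = FALSE])
  rownames(values) <- genes
  batch <- NULL
  mapped <- NULL
  if (!is.null(metadata)) {
    md <- data.table::fread(metadata, header = TRUE, data.table = FALSE)
    if (!all(c("sample_id", "batch_id") %in% names(md)))
      stop("metadata must contain columns 'sample_id' and 'batch_id'")
    idx <- match(colnames(values), md$sample_id)
    if (anyNA(idx))
      stop("metadata is missing samples: ",
           paste(colnames(values)[is.na(idx)], collapse = ", "))
    batch <- md$batch_id[idx]
    if ("mapped_reads" %in% names(md)) {
      mapped <- md$mapped_reads[idx]
      names(mapped) <- colnames(values)
    }
  }
  x <- expression_matrix(values, batch_ids = batch, space = space)
  attr(x, "mapped_reads") <- mapped
  x
}

#' Write an expression or scaled matrix as TSV
#'
#' @param x An `expression_matrix` or `scaled_expression` (or plain matrix).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(x, path) {
  values <- if (is.list(x)) x$values else x
  dt <- data.table::data.table(gene_id = rownames(values))
  dt <- cbind(dt, data.table::as.data.table(values))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
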