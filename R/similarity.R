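#' Pearson correlation between two expression vectors
#'
#' @param a,b Numeric vectors of equal length (>= 2), neither constant.
#' @return The correlation, in `[-1, 1]`; invariant to affine rescaling of
#'   either vector.
#' @export
pcc <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 2L) stop("at least two samples are required")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation is undefined for constant vectors")
  stats::cor(a, b)
}

#' Weighted inner product similarity
#'
#' `sum(w * a * b)` over centred, unit-norm expression vectors. With all-ones
#' weights on scaled data this equals the Pearson correlation of the original
#' vectors.
#'
#' @param a,b Scaled expression vectors of equal length.
#' @param w Non-negative weight vector of the same length.
#' @return The weighted similarity (a scalar).
#' @export
weighted_inner <- function(a, b, w) {
  if (length(a) != length(b) || length(a) != length(w))
    stop("vectors and weights must have equal length")
  if (any(w < 0)) stop("weights must be non-negative")
  sum(w * a * b)
}

#' Pairwise similarity matrix
#'
#' Computes all pairwise (weighted) inner products between the rows of a
#' scaled expression matrix in one matrix product.
#'
#' @param X A [center_scale()] matrix (genes x samples), or any numeric matrix.
#' @param w Optional non-negative weight vector (length = samples). `NULL`
#'   means all-ones, i.e. the plain inner product (= PCC on scaled data).
#' @return A `similarity_matrix`: symmetric genes x genes matrix with a
#'   `kind` attribute (`"inner"` or `"weighted_inner"`).
#' @export
pairwise_similarity <- function(X, w = NULL) {
  X <- as.matrix(X)
  if (is.null(w)) {
    S <- tcrossprod(X)
    kind <- "inner"
  } else {
    if (length(w) != ncol(X))
      stop("weight length must equal the number of samples")
    if (any(w < 0)) stop("weights must be non-negative")
    S <- tcrossprod(X * rep(sqrt(w), each = nrow(X)))
    kind <- "weighted_inner"
  }
  similarity_matrix(S, kind)
}

#' Cross-set weighted similarity
#'
#' Weighted inner products between every row of `A` (e.g. test genes) and
#' every row of `B` (e.g. training genes).
#'
#' @param A,B Scaled expression matrices sharing the same sample columns.
#' @param w Optional non-negative weight vector.
#' @return A `nrow(A)` x `nrow(B)` matrix.
#' @export
cross_similarity <- function(A, B, w = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("matrices must share sample columns")
  if (is.null(w)) return(tcrossprod(A, B))
  if (any(w < 0)) stop("weights must be non-negative")
  A %*% (t(B) * w)
}

similarity_matrix <- function(S, kind) {
  if (nrow(S) != ncol(S)) stop("similarity matrix must be square")
  structure(S, kind = kind, class = c("similarity_matrix", class(S)))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix (%s): %d x %d\n", attr(x, "kind"),
              nrow(x), ncol(x)))
  invisible(x)
}

#' Mutual Rank co-expression
#'
#' Converts a similarity matrix into Mutual Ranks: for each gene the other
#' genes are ranked by decreasing similarity (best rank = 1, ties receive
#' average ranks) and the two reciprocal ranks of a pair are combined, by
#' default with their geometric mean. Lower values mean stronger
#' co-expression; the output depends only on the similarity ranking, so it is
#' invariant to strictly monotone transforms of the input.
#'
#' @param S Square symmetric similarity matrix (larger = more similar), at
#'   least 3 x 3. The diagonal is excluded from ranking.
#' @param agg Rank aggregation: `"geometric"` (default) or `"arithmetic"`.
#' @return A `similarity_matrix` of kind `"mutual_rank"`, with values >= 1
#'   off-diagonal and 0 on the diagonal (a gene is trivially closest to
#'   itself).
#' @export
mutual_rank <- function(S, agg = c("geometric", "arithmetic")) {
  agg <- match.arg(agg)
  S <- unclass(as.matrix(S))
  n <- nrow(S)
  if (n != ncol(S)) stop("mutual_rank requires a square matrix")
  if (n < 3L) stop("mutual_rank requires at least 3 genes")
  R <- matrix(NA_real_, n, n, dimnames = dimnames(S))
  idx <- seq_len(n)
  for (i in idx) {
    others <- idx[-i]
    R[i, others] <- rank(-S[i, others], ties.method = "average")
  }
  MR <- if (agg == "geometric") sqrt(R * t(R)) else (R + t(R)) / 2
  diag(MR) <- 0
  similarity_matrix(MR, "mutual_rank")
}
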