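#' k-NN guilt-by-association scores
#'
#' For each test gene, the fraction of its `k` nearest training genes (under
#' the supplied similarity) annotated with the term. Only the similarity
#' ranking matters, so scores are invariant to strictly increasing transforms
#' of the similarities. Ties are broken by ascending training-gene index
#' (stable, deterministic).
#'
#' @param sim_to_train Numeric test x train similarity matrix.
#' @param train_labels A [term_labels()] or binary vector over the training
#'   genes.
#' @param k Neighbour count, `1 <= k <= ncol(sim_to_train)`.
#' @param order `"desc_similarity"` for correlation-like similarities (larger
#'   = closer) or `"asc_mutual_rank"` for Mutual Rank (smaller = closer).
#' @param self_index Optional integer vector giving, for each test row, the
#'   training column holding the same gene (dropped before ranking); `NA`
#'   entries mean no self-match. Used when scoring training genes against
#'   themselves.
#' @return Numeric score vector in `[0, 1]`, one entry per test gene.
#' @export
knn_scores <- function(sim_to_train, train_labels, k,
                       order = c("desc_similarity", "asc_mutual_rank"),
                       self_index = NULL) {
  order <- match.arg(order)
  y <- if (inherits(train_labels, "term_labels")) train_labels$y else train_labels
  sim_to_train <- as.matrix(sim_to_train)
  if (length(y) != ncol(sim_to_train))
    stop("train label length must equal the number of training columns")
  if (k < 1L) stop("k must be at least 1")
  scores <- .knn_scores_multi(sim_to_train, cbind(y), k, order, self_index)
  drop(scores[, 1L, 1L])
}

# Vectorized scorer: one sort per test gene serves every term and every k.
# Returns an array test x terms x length(ks).
.knn_scores_multi <- function(sim, Y, ks, order, self_index = NULL) {
  n_test <- nrow(sim); n_train <- ncol(sim)
  usable <- n_train - as.integer(!is.null(self_index))
  if (max(ks) > usable)
    stop(sprintf("k = %d exceeds the number of usable training genes (%d)",
                 max(ks), usable))
  sgn <- if (order == "desc_similarity") -1 else 1
  out <- array(NA_real_, c(n_test, ncol(Y), length(ks)),
               dimnames = list(rownames(sim), colnames(Y), ks))
  for (i in seq_len(n_test)) {
    s <- sgn * sim[i, ]
    cols <- seq_len(n_train)
    if (!is.null(self_index) && !is.na(self_index[i])) {
      cols <- cols[-self_index[i]]
      s <- s[cols]
    }
    ord <- cols[order(s, seq_along(s))]
    cum <- apply(Y[ord, , drop = FALSE], 2, cumsum)
    out[i, , ] <- t(cum[ks, , drop = FALSE] / ks)
  }
  out
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney formulation with average ranks for tied scores, equal to the
#' probability that a random positive outscores a random negative (ties
#' counting one half).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels of the same length; both classes must be
#'   present.
#' @return The AUC in `[0, 1]`, or `NA` with a warning when only one class is
#'   present.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("lengths differ")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("ROC AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' IC-weighted mean of per-term AUCs
#'
#' `sum(ic_t * auc_t) / sum(ic_t)` over the evaluated terms, so specific
#' (high-IC) terms contribute more than near-root ones.
#'
#' @param per_term_auc Named numeric vector of per-term AUCs.
#' @param ic Named numeric vector of information contents covering those
#'   terms.
#' @return The weighted mean AUC.
#' @export
weighted_mean_auc <- function(per_term_auc, ic) {
  terms <- names(per_term_auc)
  if (is.null(terms) || !all(terms %in% names(ic)))
    stop("every evaluated term needs an IC value")
  w <- ic[terms]
  ok <- !is.na(per_term_auc)
  if (sum(w[ok]) == 0) stop("all IC weights are zero")
  sum(w[ok] * per_term_auc[ok]) / sum(w[ok])
}

#' Apply Mutual Rank to a learned similarity
#'
#' Mutual Rank is not restricted to correlation input: this converts a
#' weighted inner-product similarity matrix into Mutual Ranks, after which it
#' is handled exactly like correlation-based Mutual Rank.
#'
#' @param sim_mlc Square symmetric similarity matrix (larger = more similar).
#' @param ... Passed to [mutual_rank()].
#' @return A Mutual Rank `similarity_matrix`.
#' @export
mr_on_mlc <- function(sim_mlc, ...) mutual_rank(sim_mlc, ...)

#' Per-term hybrid of Mutual Rank and learned-metric predictions
#'
#' For each term, uses the Mutual Rank predictions when the MR training AUC
#' is strictly larger than `threshold`, and the learned-metric predictions
#' otherwise.
#'
#' @param train_auc_mr Named numeric vector: MR training AUC per term.
#' @param mr_scores,mlc_scores Numeric test x term score matrices with
#'   identical dimnames.
#' @param threshold Selection threshold on the MR training AUC; default 0.8
#'   ("larger than" is strict, so a training AUC of exactly 0.8 selects the
#'   learned metric).
#' @return A list with `scores` (test x term matrix) and `method_used`
#'   (named character vector, `"mr"` or `"mlc"`).
#' @export
hybrid_mlc_mr <- function(train_auc_mr, mr_scores, mlc_scores, threshold = 0.8) {
  mr_scores <- as.matrix(mr_scores); mlc_scores <- as.matrix(mlc_scores)
  terms <- colnames(mr_scores)
  if (!identical(dim(mr_scores), dim(mlc_scores)) ||
      !identical(terms, colnames(mlc_scores)))
    stop("MR and MLC prediction matrices must cover identical genes and terms")
  missing <- setdiff(terms, names(train_auc_mr))
  if (length(missing) > 0L)
    stop("terms missing a training AUC: ", paste(missing, collapse = ", "))
  use_mr <- !is.na(train_auc_mr[terms]) & train_auc_mr[terms] > threshold
  scores <- mlc_scores
  scores[, use_mr] <- mr_scores[, use_mr]
  list(scores = scores,
       method_used = stats::setNames(ifelse(use_mr, "mr", "mlc"), terms))
}
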