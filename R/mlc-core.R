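#' Positive/negative pair partition for one term
#'
#' Splits genes into positives `P` (annotated with the term) and negatives
#' `Q`, and counts the positive-positive and positive-negative pairs that
#' enter the separability objective. Negative-negative pairs are excluded by
#' construction.
#'
#' @param y A [term_labels()] object or a binary 0/1 vector.
#' @return A `pair_partition`: list with `positives`, `negatives` (integer
#'   index sets), `n_pp` and `n_pn`.
#' @export
partition_pairs <- function(y) {
  yv <- if (inherits(y, "term_labels")) y$y else y
  if (!all(yv %in% c(0L, 1L))) stop("labels must be binary")
  P <- which(yv == 1L)
  Q <- which(yv == 0L)
  if (length(P) < 2L)
    stop("at least 2 positive genes are required (positive-pair variance)")
  if (length(Q) < 1L)
    stop("at least 1 negative gene is required")
  structure(list(positives = P, negatives = Q,
                 n_pp = length(P) * (length(P) - 1) / 2,
                 n_pn = as.numeric(length(P)) * length(Q)),
            class = "pair_partition")
}

#' Global pair partition: pairs sharing at least one informative term
#'
#' For the non-term-specific (global) variant, positive-positive pairs are
#' pairs of genes sharing at least one informative GO term and
#' positive-negative pairs share none. Terms with zero information content
#' (annotated to every gene, e.g. the root) are excluded from "sharing",
#' otherwise every annotated pair would be positive-positive. Pairs in which
#' neither gene carries any informative annotation are the analogue of
#' negative-negative pairs and are excluded from the objective.
#'
#' @param Y Binary gene x term label matrix (e.g. from
#'   [term_label_matrix()]), rows ordered as the expression matrix.
#' @param ic Optional named IC vector; terms with `ic <= min_ic` are dropped.
#'   When `NULL`, terms annotated to every gene are dropped.
#' @param min_ic Informative-term cutoff on IC; default 0.
#' @return A `global_pair_partition`: list with the logical `share` matrix
#'   (upper-triangle meaningful), pair counts `n_pp`, `n_pn` and the retained
#'   `terms`.
#' @export
partition_pairs_global <- function(Y, ic = NULL, min_ic = 0) {
  Y <- as.matrix(Y)
  keep <- if (!is.null(ic)) {
    colnames(Y) %in% names(ic)[ic > min_ic]
  } else {
    colSums(Y) < nrow(Y)
  }
  Yi <- Y[, keep, drop = FALSE]
  share <- tcrossprod(Yi) > 0
  # pairs of two unannotated genes are the negative-negative analogue and
  # carry no term-specific information: excluded (NA)
  unann <- rowSums(Yi) == 0L
  share[outer(unann, unann, "&")] <- NA
  diag(share) <- NA
  ut <- share[upper.tri(share)]
  structure(list(share = share, terms = colnames(Yi),
                 n_pp = sum(ut, na.rm = TRUE),
                 n_pn = sum(!ut, na.rm = TRUE)),
            class = "global_pair_partition")
}

#' Sufficient statistics for the Welch-t separability objective
#'
#' Builds per-sample first-moment vectors and per-sample-pair second-moment
#' matrices from which the mean and variance of the weighted inner-product
#' similarity over all positive-positive and positive-negative gene pairs —
#' and hence the Welch t-statistic and its gradient — can be evaluated for
#' any weight vector without enumerating pairs.
#'
#' With `p = colSums(X[P,])`, `q = colSums(X[Q,])`, `GP = crossprod(X[P,])`,
#' `GQ = crossprod(X[Q,])` and `H = crossprod(X[P,]^2)`:
#' `U = (p^2 - diag(GP))/2`, `V = p*q`, `M_pp = (GP^2 - H)/2`,
#' `M_pn = GP * GQ` (elementwise products). Then for weights `w`,
#' `mu_pp = (w'U)/n_pp` and the unbiased variance is
#' `(w' M_pp w - n_pp mu_pp^2)/(n_pp - 1)`; analogously for p-n pairs.
#'
#' @param X Scaled expression matrix (genes x samples).
#' @param part A [partition_pairs()] result.
#' @param xtx Optional precomputed `crossprod(X)` over all genes, which lets
#'   the negative-set Gram matrix be obtained by subtraction — useful when
#'   fitting many terms on the same matrix.
#' @param max_moment_dim Memory guard: when the number of samples exceeds
#'   this cap the dense sample x sample moment matrices are not formed and a
#'   seeded pair-subsampling estimator is used instead (see
#'   [build_pair_moments_sampled()]).
#' @param n_pairs,seed Subsample size per pair class and seed for the
#'   fallback estimator.
#' @return A `pair_moments` object: `U`, `V` (length f), `M_pp`, `M_pn`
#'   (f x f symmetric), and the pair counts `n_pp`, `n_pn`.
#' @export
build_pair_moments <- function(X, part, xtx = NULL, max_moment_dim = 5000L,
                               n_pairs = 20000L, seed = 1L) {
  stopifnot(inherits(part, "pair_partition"))
  X <- as.matrix(X)
  if (ncol(X) > max_moment_dim)
    return(build_pair_moments_sampled(X, part, n_pairs = n_pairs, seed = seed))
  P <- part$positives; Q <- part$negatives
  XP <- X[P, , drop = FALSE]
  p <- colSums(XP)
  GP <- crossprod(XP)
  GQ <- if (is.null(xtx)) crossprod(X[Q, , drop = FALSE]) else xtx - GP
  q <- if (is.null(xtx)) colSums(X[Q, , drop = FALSE]) else colSums(X) - p
  H <- crossprod(XP^2)
  structure(list(U = (p^2 - diag(GP)) / 2,
                 V = p * q,
                 M_pp = (GP^2 - H) / 2,
                 M_pn = GP * GQ,
                 n_pp = part$n_pp, n_pn = part$n_pn),
            class = "pair_moments")
}

# Moments from explicit pair index matrices (n x 2). Exact when given all
# pairs; the basis of the subsampled estimator and of the global variant.
.moments_from_pairs <- function(X, pp, pn, n_pp = nrow(pp), n_pn = nrow(pn)) {
  Zpp <- X[pp[, 1], , drop = FALSE] * X[pp[, 2], , drop = FALSE]
  Zpn <- X[pn[, 1], , drop = FALSE] * X[pn[, 2], , drop = FALSE]
  scale_pp <- n_pp / nrow(Zpp)  # rescale subsample sums to population size
  scale_pn <- n_pn / nrow(Zpn)
  structure(list(U = colSums(Zpp) * scale_pp,
                 V = colSums(Zpn) * scale_pn,
                 M_pp = crossprod(Zpp) * scale_pp,
                 M_pn = crossprod(Zpn) * scale_pn,
                 n_pp = n_pp, n_pn = n_pn),
            class = "pair_moments")
}

#' Pair-subsampling moment estimator
#'
#' Estimates the Welch-t sufficient statistics from a uniform seeded
#' subsample of positive-positive and positive-negative pairs, avoiding the
#' dense sample x sample moment matrices' full-pair sums. Used automatically
#' by [build_pair_moments()] past its memory cap.
#'
#' @inheritParams build_pair_moments
#' @param n_pairs Maximum number of pairs sampled per class.
#' @param seed Seed for the pair subsample.
#' @return A `pair_moments` object (estimates rescaled to the full pair
#'   counts).
#' @export
build_pair_moments_sampled <- function(X, part, n_pairs = 20000L, seed = 1L) {
  stopifnot(inherits(part, "pair_partition"))
  X <- as.matrix(X)
  P <- part$positives; Q <- part$negatives
  pp_all <- t(utils::combn(P, 2))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (nrow(pp_all) > n_pairs)
    pp_all <- pp_all[sample.int(nrow(pp_all), n_pairs), , drop = FALSE]
  n_pn_all <- length(P) * length(Q)
  if (n_pn_all > n_pairs) {
    flat <- sample.int(n_pn_all, n_pairs) - 1L
    pn <- cbind(P[flat %% length(P) + 1L], Q[flat %/% length(P) + 1L])
  } else {
    pn <- cbind(rep(P, times = length(Q)), rep(Q, each = length(P)))
  }
  .moments_from_pairs(X, pp_all, pn, n_pp = part$n_pp, n_pn = part$n_pn)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Shared evaluation of t(w), its gradient and the class moments.
.t_eval <- function(w, mo, grad = TRUE, var_floor = 1e-12) {
  mu_pp <- sum(w * mo$U) / mo$n_pp
  mu_pn <- sum(w * mo$V) / mo$n_pn
  Mw_pp <- drop(mo$M_pp %*% w)
  Mw_pn <- drop(mo$M_pn %*% w)
  s2_pp <- (sum(w * Mw_pp) - mo$n_pp * mu_pp^2) / (mo$n_pp - 1)
  s2_pn <- (sum(w * Mw_pn) - mo$n_pn * mu_pn^2) / (mo$n_pn - 1)
  s2_pp <- max(s2_pp, 0)  # numerical floor against tiny negative round-off
  s2_pn <- max(s2_pn, 0)
  Vt <- s2_pp / mo$n_pp + s2_pn / mo$n_pn
  D <- mu_pp - mu_pn
  degenerate <- s2_pp < var_floor && s2_pn < var_floor
  out <- list(mu_pp = mu_pp, mu_pn = mu_pn, s2_pp = s2_pp, s2_pn = s2_pn,
              Vt = Vt, D = D, degenerate = degenerate)
  if (degenerate) {
    out$t <- 0
    if (grad) out$dt <- rep(0, length(w))
    return(out)
  }
  out$t <- D / sqrt(Vt)
  if (grad) {
    dD <- mo$U / mo$n_pp - mo$V / mo$n_pn
    dVt <- (2 * Mw_pp - 2 * mu_pp * mo$U) / ((mo$n_pp - 1) * mo$n_pp) +
           (2 * Mw_pn - 2 * mu_pn * mo$V) / ((mo$n_pn - 1) * mo$n_pn)
    out$dt <- dD / sqrt(Vt) - D / (2 * Vt^1.5) * dVt
  }
  out
}

#' Welch t-statistic of the weighted similarity separation
#'
#' `t(w) = (mu_pp - mu_pn) / sqrt(s2_pp/n_pp + s2_pn/n_pn)`, where the means
#' and unbiased variances of the weighted inner-product similarity over the
#' positive-positive and positive-negative gene pairs are evaluated from the
#' precomputed sufficient statistics. The statistic is invariant to positive
#' rescaling of `w`.
#'
#' @param w Non-negative weight vector.
#' @param moments A [build_pair_moments()] object.
#' @param var_floor Degeneracy floor: when both variances fall below it the
#'   statistic is defined as 0 if the means also coincide, otherwise an error
#'   is raised (division by a vanishing denominator).
#' @return The t value (a scalar).
#' @export
welch_t <- function(w, moments, var_floor = 1e-12) {
  if (any(w < 0)) stop("weights must be non-negative")
  ev <- .t_eval(w, moments, grad = FALSE, var_floor = var_floor)
  if (ev$degenerate && abs(ev$D) > 1e-12)
    stop("both pair-similarity variances vanish while the means differ; t is undefined")
  ev$t
}

#' Regularized separability objective and gradient
#'
#' The fitting objective `-alpha * t(w) + (1 - alpha) * sum(w)`: maximizing
#' class separability traded off against an L1 penalty that drives the
#' weights of uninformative samples to zero (weights are kept non-negative by
#' the optimizer's box constraint, so `sum(w)` is the L1 norm).
#'
#' @param w Non-negative weight vector.
#' @param moments A [build_pair_moments()] object.
#' @param alpha Trade-off in (0, 1); larger values favour separability over
#'   sparsity.
#' @return `mlc_objective`: the scalar objective. `mlc_objective_grad`: its
#'   analytic gradient (length f).
#' @export
mlc_objective <- function(w, moments, alpha) {
  .check_alpha(alpha)
  ev <- .t_eval(w, moments, grad = FALSE)
  -alpha * ev$t + (1 - alpha) * sum(w)
}

#' @rdname mlc_objective
#' @export
mlc_objective_grad <- function(w, moments, alpha) {
  .check_alpha(alpha)
  ev <- .t_eval(w, moments, grad = TRUE)
  -alpha * ev$dt + (1 - alpha)
}

.check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
}

#' Fit per-sample weights for one term
#'
#' Minimizes [mlc_objective()] over non-negative weights with the
#' box-constrained limited-memory quasi-Newton optimizer (`optim` method
#' `"L-BFGS-B"`, lower bound 0 per coordinate), starting from all-ones
#' weights — i.e. from unweighted-correlation behaviour. Fitting is
#' deterministic given the inputs: no randomness is involved.
#'
#' Because `t(w)` is scale-invariant, the L1 term continually shrinks the
#' overall weight scale while the optimizer improves the weight direction;
#' runs that stop at the iteration cap therefore still carry a useful weight
#' profile and are returned with `converged = FALSE`.
#'
#' @param X Scaled expression matrix over the training genes.
#' @param y A [term_labels()] or binary vector aligned with `rownames(X)`.
#' @param alpha Separability/sparsity trade-off in (0, 1).
#' @param init Initial weights; default all-ones.
#' @param maxit,factr,pgtol `optim` L-BFGS-B controls.
#' @param xtx Optional precomputed `crossprod(X)` (see
#'   [build_pair_moments()]).
#' @param moments Optional precomputed [build_pair_moments()] object,
#'   overriding `X`/`y`.
#' @param term Term identifier recorded in the model.
#' @param eps Zero-weight threshold for the selected-sample count; default
#'   `1e-8 * max(w)`.
#' @param verbose Emit a message when the optimizer stops at the iteration
#'   cap (the scale-invariance of `t(w)` means the L1 term keeps shrinking
#'   the overall scale indefinitely, so hitting the cap with a settled
#'   weight direction is routine).
#' @return An `mlc_model`: list with `term`, `weights` (named, non-negative),
#'   `alpha`, `objective_value`, `t_value`, `converged`, `n_selected`,
#'   `iterations`.
#' @export
fit_mlc <- function(X, y, alpha, init = NULL, maxit = 200L, factr = 1e10,
                    pgtol = 0, xtx = NULL, moments = NULL,
                    term = if (inherits(y, "term_labels")) y$term else "term",
                    eps = NULL, verbose = FALSE) {
  .check_alpha(alpha)
  if (is.null(moments)) {
    part <- partition_pairs(y)
    moments <- build_pair_moments(X, part, xtx = xtx)
  }
  f <- length(moments$U)
  if (is.null(init)) init <- rep(1, f)
  if (any(init < 0)) stop("initial weights must be non-negative")
  cache <- new.env(parent = emptyenv())
  evalpt <- function(w) {
    if (!is.null(cache$w) && identical(cache$w, w)) return(invisible())
    ev <- .t_eval(w, moments, grad = TRUE)
    cache$w <- w
    cache$f <- -alpha * ev$t + (1 - alpha) * sum(w)
    cache$g <- -alpha * ev$dt + (1 - alpha)
    invisible()
  }
  fit <- stats::optim(init,
                      fn = function(w) { evalpt(w); cache$f },
                      gr = function(w) { evalpt(w); cache$g },
                      method = "L-BFGS-B", lower = 0,
                      control = list(maxit = maxit, factr = factr,
                                     pgtol = pgtol))
  w <- pmax(fit$par, 0)  # guard against epsilon bound violations
  sample_names <- colnames(moments$M_pp) %||%
    (if (!is.null(X)) colnames(X) else NULL)
  if (!is.null(sample_names)) names(w) <- sample_names
  converged <- fit$convergence == 0L
  if (!converged && verbose)
    message(sprintf("fit_mlc (%s, alpha = %g): optimizer stopped early (%s); returning best iterate",
                    term, alpha,
                    if (fit$convergence == 1L) "iteration cap" else trimws(fit$message)))
  model <- structure(list(term = term, weights = w, alpha = alpha,
                          objective_value = fit$value,
                          t_value = welch_t(w, moments),
                          converged = converged,
                          iterations = unname(fit$counts[1])),
                     class = "mlc_model")
  model$n_selected <- length(selected_samples(model, eps))
  model
}

#' @export
print.mlc_model <- function(x, ...) {
  cat(sprintf("mlc_model '%s': alpha = %g, t = %.4g, objective = %.4g, %d/%d samples selected%s\n",
              x$term, x$alpha, x$t_value, x$objective_value,
              x$n_selected, length(x$weights),
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Fit global (non-term-specific) weights
#'
#' Shares one weight vector across all terms by redefining positive-positive
#' pairs as gene pairs sharing at least one informative GO term and
#' positive-negative pairs as pairs sharing none; the objective and optimizer
#' are unchanged. The moment statistics are estimated from a seeded uniform
#' subsample of pairs from each class (the general share-a-term pair set has
#' no closed-form moment reduction).
#'
#' @param X Scaled expression matrix over the training genes.
#' @param Y Binary gene x term label matrix aligned with `rownames(X)`.
#' @param alpha Trade-off in (0, 1).
#' @param ic,min_ic Informative-term filter, see [partition_pairs_global()].
#' @param n_pairs Pairs sampled per class; default 20000.
#' @param seed Seed for the pair subsample.
#' @param ... Passed on to [fit_mlc()] (`maxit`, `factr`, ...).
#' @return An `mlc_model` with `term = "global"`.
#' @export
fit_mlc_global <- function(X, Y, alpha, ic = NULL, min_ic = 0,
                           n_pairs = 20000L, seed = 1L, ...) {
  .check_alpha(alpha)
  part <- partition_pairs_global(Y, ic = ic, min_ic = min_ic)
  if (part$n_pp < 2L) stop("fewer than 2 term-sharing gene pairs")
  if (part$n_pn < 2L) stop("fewer than 2 non-sharing gene pairs")
  ut <- which(upper.tri(part$share), arr.ind = TRUE)
  is_pp <- part$share[ut]
  pp <- ut[is_pp %in% TRUE, , drop = FALSE]
  pn <- ut[is_pp %in% FALSE, , drop = FALSE]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (nrow(pp) > n_pairs) pp <- pp[sample.int(nrow(pp), n_pairs), , drop = FALSE]
  if (nrow(pn) > n_pairs) pn <- pn[sample.int(nrow(pn), n_pairs), , drop = FALSE]
  mo <- .moments_from_pairs(as.matrix(X), pp, pn,
                            n_pp = part$n_pp, n_pn = part$n_pn)
  colnames(mo$M_pp) <- colnames(X)
  fit_mlc(X = NULL, y = NULL, alpha = alpha, moments = mo, term = "global", ...)
}

#' Samples selected by a fitted model
#'
#' @param model An `mlc_model`.
#' @param eps Threshold; weights strictly above it count as selected. Default
#'   `1e-8 * max(weights)` (numerical optimizers rarely return exact zeros).
#' @return Integer vector of selected sample indices (named when the weights
#'   are named).
#' @export
selected_samples <- function(model, eps = NULL) {
  w <- model$weights
  if (is.null(eps)) eps <- 1e-8 * max(w, 0)
  which(w > eps)
}
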