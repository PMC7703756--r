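#' Deterministic sub-seed derivation
#'
#' Derives a 31-bit sub-seed from a root seed and a stream tag, so that every
#' randomized stage (fold splits, pair subsampling, simulation repetitions)
#' draws from its own named stream and is independently reproducible.
#'
#' @param seed Integer root seed.
#' @param tag Character stream tag.
#' @return An integer in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.double(seed) * 69069 + h * 30103 + 1013904223) %% 2147483647)
}

.usable_ks <- function(k_grid, usable) {
  ks <- sort(unique(as.integer(k_grid[k_grid <= usable])))
  if (length(ks) == 0L) ks <- as.integer(usable)
  ks
}

# Per-term AUC array (terms x k) for one validation split of a
# similarity-based method; NA where a term has a single class.
.auc_by_k <- function(sim_block, Y_train, Y_valid, ks, order, self_index = NULL) {
  sc <- .knn_scores_multi(sim_block, Y_train, ks, order, self_index)
  out <- matrix(NA_real_, ncol(Y_train), length(ks),
                dimnames = list(colnames(Y_train), ks))
  for (t in seq_len(ncol(Y_train))) {
    yv <- Y_valid[, t]
    if (length(unique(yv)) < 2L) next
    for (j in seq_along(ks))
      out[t, j] <- roc_auc(sc[, t, j], yv)
  }
  out
}

#' Nested cross-validation of co-expression function predictors
#'
#' Gene-level nested cross-validation: the outer loop holds out test genes,
#' the inner loop (on training genes only) selects the neighbour count `k` —
#' and for the learned-metric methods also the trade-off `alpha` — by mean
#' term-centric ROC AUC. Available methods:
#'
#' * `"pcc"` — k-NN on the unweighted inner product of the scaled matrix
#'   (equal to Pearson correlation), one `k` for all terms;
#' * `"pcc_k"` — the same similarity with `k` tuned per term;
#' * `"mr"` — k-NN on Mutual Rank of the correlation matrix (ascending);
#' * `"mlc"` — per-term learned sample weights, `alpha` and `k` tuned per
#'   term;
#' * `"mlc_global"` — one shared weight vector, `alpha` and `k` tuned
#'   globally;
#' * `"hybrid"` — per term, Mutual Rank predictions when MR's training AUC
#'   exceeds the threshold, otherwise the learned-metric predictions
#'   (implies `"mr"` and `"mlc"`).
#'
#' A term enters a fold only when it has at least `min_pos` positive training
#' genes; terms with a single class among the test genes are skipped (and
#' recorded) so per-fold averages are comparable across methods.
#'
#' @param X Scaled expression matrix (genes x samples, rows named).
#' @param Y Binary gene x term label matrix aligned with `rownames(X)`.
#' @param methods Character vector of method names (above).
#' @param k_grid Candidate neighbour counts; capped at the usable training
#'   size.
#' @param alpha_grid Candidate trade-off values in (0, 1) for the learned
#'   metric.
#' @param outer_folds,inner_folds Fold counts (default 3/3).
#' @param seed Root seed; fold assignments derive from named substreams.
#' @param min_pos Minimum positive training genes per term (default 5).
#' @param ic Optional named IC vector enabling IC-weighted mean AUCs.
#' @param hybrid_threshold MR training-AUC threshold for the hybrid rule.
#' @param maxit,factr Optimizer controls passed to [fit_mlc()].
#' @param n_pairs Pair subsample size for `"mlc_global"`.
#' @param keep_models Keep fitted `mlc_model` objects per fold (memory-heavy).
#' @return A `nested_cv_result`: list of per-fold results, each holding per
#'   method the named per-term AUC vector, `mean_auc`, `weighted_auc`, the
#'   selected parameters and the skipped terms. Summarize with
#'   [cv_summary()].
#' @export
nested_cv <- function(X, Y, methods = "pcc",
                      k_grid = c(1, 3, 5, 11, 21, 51),
                      alpha_grid = c(0.5, 0.9, 0.99, 0.999),
                      outer_folds = 3L, inner_folds = 3L, seed = 1L,
                      min_pos = 5L, ic = NULL, hybrid_threshold = 0.8,
                      maxit = 150L, factr = 1e10, n_pairs = 20000L,
                      keep_models = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must cover the same genes")
  methods <- match.arg(methods,
                       c("pcc", "pcc_k", "mr", "mlc", "mlc_global", "hybrid"),
                       several.ok = TRUE)
  run_methods <- methods
  if ("hybrid" %in% methods)
    run_methods <- unique(c(setdiff(run_methods, "hybrid"), "mr", "mlc", "hybrid"))
  n <- nrow(X)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, "outer_folds"))
  outer_assign <- sample(rep(seq_len(outer_folds), length.out = n))
  need_S <- length(intersect(run_methods,
                             c("pcc", "pcc_k", "mr", "hybrid"))) > 0
  S <- if (need_S) tcrossprod(X) else NULL
  MR <- if (any(c("mr", "hybrid") %in% run_methods)) unclass(mutual_rank(S)) else NULL

  folds <- vector("list", outer_folds)
  for (o in seq_len(outer_folds)) {
    test <- which(outer_assign == o)
    train <- which(outer_assign != o)
    n_tr <- length(train)
    pos_tr <- colSums(Y[train, , drop = FALSE])
    trainable <- which(pos_tr >= max(min_pos, 2L) & pos_tr <= n_tr - 1L)
    if (length(trainable) == 0L) {
      folds[[o]] <- list(fold = o, methods = list(),
                         note = "no trainable terms")
      next
    }
    Yt <- Y[, trainable, drop = FALSE]
    set.seed(substream_seed(seed, paste0("inner_folds_", o)))
    inner_assign <- sample(rep(seq_len(inner_folds), length.out = n_tr))
    inner_splits <- lapply(seq_len(inner_folds), function(i)
      list(tr = train[inner_assign != i], va = train[inner_assign == i]))
    xtx_tr <- if (any(c("mlc", "mlc_global", "hybrid") %in% run_methods))
      crossprod(X[train, , drop = FALSE]) else NULL

    test_single_class <- vapply(seq_len(ncol(Yt)), function(t)
      length(unique(Yt[test, t])) < 2L, TRUE)
    skipped <- colnames(Yt)[test_single_class]

    res_o <- list()

    ## ---- similarity-based baselines -------------------------------------
    inner_auc_sim <- function(sim_full, order) {
      # mean over inner folds of the per-term AUC-by-k matrix
      acc <- NULL; cnt <- NULL
      for (sp in inner_splits) {
        usable <- length(sp$tr)
        ks <- .usable_ks(k_grid, usable)
        a <- .auc_by_k(sim_full[sp$va, sp$tr, drop = FALSE],
                       Y[sp$tr, trainable, drop = FALSE],
                       Y[sp$va, trainable, drop = FALSE], ks, order)
        if (is.null(acc)) { acc <- array(0, dim(a), dimnames(a)); cnt <- acc }
        ok <- !is.na(a)
        acc[ok] <- acc[ok] + a[ok]
        cnt <- cnt + ok
      }
      acc / pmax(cnt, 1) + ifelse(cnt == 0, NA, 0)
    }
    eval_outer_sim <- function(sim_full, order, k_per_term) {
      ks <- sort(unique(k_per_term))
      sc <- .knn_scores_multi(sim_full[test, train, drop = FALSE],
                              Yt[train, , drop = FALSE], ks, order)
      scores <- vapply(seq_along(k_per_term), function(t)
        sc[, t, as.character(k_per_term[t])], numeric(length(test)))
      dimnames(scores) <- list(rownames(X)[test], colnames(Yt))
      auc <- vapply(seq_along(k_per_term), function(t) {
        if (test_single_class[t]) return(NA_real_)
        roc_auc(scores[, t], Yt[test, t])
      }, 1.0)
      list(scores = scores, auc = auc)
    }
    pick_k <- function(mean_auc_by_k) {
      # global k: maximize the term-average; ties -> smallest k
      avg <- colMeans(mean_auc_by_k, na.rm = TRUE)
      as.integer(names(avg)[which.max(avg)])
    }
    pick_k_per_term <- function(mean_auc_by_k) {
      ks <- as.integer(colnames(mean_auc_by_k))
      vapply(seq_len(nrow(mean_auc_by_k)), function(t) {
        row <- mean_auc_by_k[t, ]
        if (all(is.na(row))) ks[1] else ks[which.max(row)]
      }, 1L)
    }

    if (any(c("pcc", "pcc_k") %in% run_methods)) {
      ia <- inner_auc_sim(S, "desc_similarity")
      if ("pcc" %in% run_methods) {
        k_star <- pick_k(ia)
        ev <- eval_outer_sim(S, "desc_similarity", rep(k_star, ncol(Yt)))
        res_o$pcc <- .method_result(ev$auc, colnames(Yt), ic,
                                    params = list(k = k_star),
                                    skipped = skipped, scores = ev$scores)
      }
      if ("pcc_k" %in% run_methods) {
        k_terms <- pick_k_per_term(ia)
        ev <- eval_outer_sim(S, "desc_similarity", k_terms)
        res_o$pcc_k <- .method_result(ev$auc, colnames(Yt), ic,
                                      params = list(k = stats::setNames(
                                        k_terms, colnames(Yt))),
                                      skipped = skipped, scores = ev$scores)
      }
    }

    k_mr <- NULL
    if (any(c("mr", "hybrid") %in% run_methods)) {
      ia <- inner_auc_sim(MR, "asc_mutual_rank")
      k_mr <- pick_k(ia)
      ev <- eval_outer_sim(MR, "asc_mutual_rank", rep(k_mr, ncol(Yt)))
      res_o$mr <- .method_result(ev$auc, colnames(Yt), ic,
                                 params = list(k = k_mr), skipped = skipped,
                                 scores = ev$scores)
    }

    ## ---- term-specific learned metric -----------------------------------
    if (any(c("mlc", "hybrid") %in% run_methods)) {
      ks_inner <- lapply(inner_splits, function(sp)
        .usable_ks(k_grid, length(sp$tr)))
      # accumulator: term x alpha x k (union grid)
      ks_all <- sort(unique(unlist(ks_inner)))
      acc <- array(0, c(ncol(Yt), length(alpha_grid), length(ks_all)),
                   dimnames = list(colnames(Yt), alpha_grid, ks_all))
      cnt <- acc
      for (si in seq_along(inner_splits)) {
        sp <- inner_splits[[si]]
        xtx_in <- crossprod(X[sp$tr, , drop = FALSE])
        ks <- ks_inner[[si]]
        for (t in seq_len(ncol(Yt))) {
          ytr <- Y[sp$tr, trainable[t]]
          yva <- Y[sp$va, trainable[t]]
          if (sum(ytr) < max(min_pos, 2L) || sum(ytr) > length(ytr) - 1L) next
          if (length(unique(yva)) < 2L) next
          mo <- build_pair_moments(X[sp$tr, , drop = FALSE],
                                   partition_pairs(ytr), xtx = xtx_in)
          for (ai in seq_along(alpha_grid)) {
            m <- fit_mlc(NULL, NULL, alpha_grid[ai], moments = mo,
                         maxit = maxit, factr = factr, term = colnames(Yt)[t])
            sw <- cross_similarity(X[sp$va, , drop = FALSE],
                                   X[sp$tr, , drop = FALSE], m$weights)
            a <- .auc_by_k(sw, cbind(ytr), cbind(yva), ks, "desc_similarity")
            kc <- as.character(ks)
            ok <- !is.na(a[1, ])
            acc[t, ai, kc[ok]] <- acc[t, ai, kc[ok]] + a[1, ok]
            cnt[t, ai, kc[ok]] <- cnt[t, ai, kc[ok]] + 1
          }
        }
      }
      mean_auc <- acc / pmax(cnt, 1)
      mean_auc[cnt == 0] <- NA
      # per-term (alpha, k): maximize mean inner AUC; ties -> first alpha,
      # then smallest k (grid order)
      sel <- lapply(seq_len(ncol(Yt)), function(t) {
        m <- mean_auc[t, , , drop = FALSE][1, , ]
        m <- matrix(m, length(alpha_grid), length(ks_all))
        if (all(is.na(m)))
          return(list(alpha = alpha_grid[1], k = ks_all[1]))
        best <- which(m == max(m, na.rm = TRUE), arr.ind = TRUE)
        best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
        list(alpha = alpha_grid[best[1]], k = ks_all[best[2]])
      })
      # refit on the full outer-training set and score the test genes
      auc <- rep(NA_real_, ncol(Yt))
      scores_mlc <- matrix(NA_real_, length(test), ncol(Yt),
                           dimnames = list(rownames(X)[test], colnames(Yt)))
      models <- if (keep_models) vector("list", ncol(Yt)) else NULL
      ks_out <- .usable_ks(k_grid, n_tr)
      for (t in seq_len(ncol(Yt))) {
        ytr <- Yt[train, t]
        m <- fit_mlc(X[train, , drop = FALSE], ytr, sel[[t]]$alpha,
                     maxit = maxit, factr = factr, xtx = xtx_tr,
                     term = colnames(Yt)[t])
        if (keep_models) models[[t]] <- m
        sw <- cross_similarity(X[test, , drop = FALSE],
                               X[train, , drop = FALSE], m$weights)
        kk <- min(sel[[t]]$k, max(ks_out))
        scores_mlc[, t] <- knn_scores(sw, ytr, kk)
        if (!test_single_class[t])
          auc[t] <- roc_auc(scores_mlc[, t], Yt[test, t])
      }
      res_o$mlc <- .method_result(auc, colnames(Yt), ic,
                                  params = list(alpha = vapply(sel, `[[`, 1.0, "alpha"),
                                                k = vapply(sel, `[[`, 1L, "k")),
                                  skipped = skipped, scores = scores_mlc)
      if (keep_models) {
        names(models) <- colnames(Yt)
        res_o$mlc$models <- models
      }
    }

    ## ---- global learned metric ------------------------------------------
    if ("mlc_global" %in% run_methods) {
      ks_all <- .usable_ks(k_grid, n_tr)
      acc <- matrix(0, length(alpha_grid), length(ks_all),
                    dimnames = list(alpha_grid, ks_all))
      cnt <- acc
      for (si in seq_along(inner_splits)) {
        sp <- inner_splits[[si]]
        ks <- .usable_ks(k_grid, length(sp$tr))
        for (ai in seq_along(alpha_grid)) {
          m <- tryCatch(
            fit_mlc_global(X[sp$tr, , drop = FALSE],
                           Y[sp$tr, trainable, drop = FALSE],
                           alpha_grid[ai], ic = ic, n_pairs = n_pairs,
                           seed = substream_seed(seed, paste0("gpairs_", o, "_", si)),
                           maxit = maxit, factr = factr),
            error = function(e) NULL)
          if (is.null(m)) next
          sw <- cross_similarity(X[sp$va, , drop = FALSE],
                                 X[sp$tr, , drop = FALSE], m$weights)
          a <- .auc_by_k(sw, Y[sp$tr, trainable, drop = FALSE],
                         Y[sp$va, trainable, drop = FALSE], ks,
                         "desc_similarity")
          by_k <- colMeans(a, na.rm = TRUE)
          kc <- as.character(ks)
          ok <- !is.na(by_k)
          acc[ai, kc[ok]] <- acc[ai, kc[ok]] + by_k[ok]
          cnt[ai, kc[ok]] <- cnt[ai, kc[ok]] + 1
        }
      }
      mean_auc <- acc / pmax(cnt, 1)
      mean_auc[cnt == 0] <- NA
      best <- which(mean_auc == max(mean_auc, na.rm = TRUE), arr.ind = TRUE)
      best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
      alpha_star <- alpha_grid[best[1]]; k_star <- ks_all[best[2]]
      m <- fit_mlc_global(X[train, , drop = FALSE], Yt[train, , drop = FALSE],
                          alpha_star, ic = ic, n_pairs = n_pairs,
                          seed = substream_seed(seed, paste0("gpairs_", o, "_final")),
                          maxit = maxit, factr = factr)
      sw <- cross_similarity(X[test, , drop = FALSE],
                             X[train, , drop = FALSE], m$weights)
      scg <- .knn_scores_multi(sw, Yt[train, , drop = FALSE], k_star,
                               "desc_similarity")[, , 1]
      scg <- matrix(scg, length(test), ncol(Yt),
                    dimnames = list(rownames(X)[test], colnames(Yt)))
      aucg <- vapply(seq_len(ncol(Yt)), function(t) {
        if (test_single_class[t]) return(NA_real_)
        roc_auc(scg[, t], Yt[test, t])
      }, 1.0)
      res_o$mlc_global <- .method_result(aucg, colnames(Yt), ic,
                                         params = list(alpha = alpha_star,
                                                       k = k_star),
                                         skipped = skipped, scores = scg)
      if (keep_models) res_o$mlc_global$models <- list(global = m)
    }

    ## ---- hybrid ----------------------------------------------------------
    if ("hybrid" %in% run_methods) {
      # per-term MR training AUC on the outer-training genes (self excluded)
      a_tr <- .auc_by_k(MR[train, train, drop = FALSE], Yt[train, , drop = FALSE],
                        Yt[train, , drop = FALSE],
                        min(k_mr, n_tr - 1L), "asc_mutual_rank",
                        self_index = seq_along(train))
      train_auc_mr <- stats::setNames(a_tr[, 1], colnames(Yt))
      hyb <- hybrid_mlc_mr(train_auc_mr, res_o$mr$scores, res_o$mlc$scores,
                           threshold = hybrid_threshold)
      auc <- ifelse(hyb$method_used == "mr",
                    res_o$mr$per_term_auc, res_o$mlc$per_term_auc)
      res_o$hybrid <- .method_result(auc, colnames(Yt), ic,
                                     params = list(threshold = hybrid_threshold,
                                                   train_auc_mr = train_auc_mr,
                                                   method_used = hyb$method_used),
                                     skipped = skipped, scores = hyb$scores)
    }

    folds[[o]] <- list(fold = o, test_genes = rownames(X)[test],
                       methods = res_o[intersect(names(res_o), methods)])
  }
  structure(list(folds = folds, methods = methods, seed = seed,
                 outer_folds = outer_folds, inner_folds = inner_folds),
            class = "nested_cv_result")
}

.method_result <- function(auc, terms, ic, params, skipped, scores = NULL) {
  auc <- stats::setNames(as.numeric(auc), terms)
  list(per_term_auc = auc,
       mean_auc = mean(auc, na.rm = TRUE),
       weighted_auc = if (!is.null(ic) && all(terms %in% names(ic)))
         weighted_mean_auc(auc, ic) else NA_real_,
       params = params, skipped = skipped, scores = scores)
}

#' Summarize a nested cross-validation run
#'
#' @param res A [nested_cv()] result.
#' @return A data.frame with one row per method: mean and standard error of
#'   the per-fold mean term-centric AUC, and the IC-weighted counterpart.
#' @export
cv_summary <- function(res) {
  stopifnot(inherits(res, "nested_cv_result"))
  rows <- lapply(res$methods, function(m) {
    per_fold <- vapply(res$folds, function(f)
      if (!is.null(f$methods[[m]])) f$methods[[m]]$mean_auc else NA_real_, 1.0)
    per_fold_w <- vapply(res$folds, function(f)
      if (!is.null(f$methods[[m]])) f$methods[[m]]$weighted_auc else NA_real_, 1.0)
    data.frame(method = m,
               mean_auc = mean(per_fold, na.rm = TRUE),
               se_auc = stats::sd(per_fold) / sqrt(sum(!is.na(per_fold))),
               weighted_auc = mean(per_fold_w, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf("nested_cv_result: %d outer folds, methods: %s\n",
              x$outer_folds, paste(x$methods, collapse = ", ")))
  print(cv_summary(x))
  invisible(x)
}

#' Label-permutation null of the cross-validated pipeline
#'
#' Randomly permutes the gene-to-annotation assignment and reruns the nested
#' cross-validation; with labels carrying no information the mean held-out
#' term-centric ROC AUC of any method should fluctuate around 0.5. A sanity
#' check that the learned metric does not manufacture signal from noise.
#'
#' @param X Scaled expression matrix.
#' @param Y Binary gene x term label matrix.
#' @param methods,\dots Passed to [nested_cv()].
#' @param n_perm Number of label permutations (default 20).
#' @param seed Root seed; each permutation uses a derived substream.
#' @return A `n_perm` x `length(methods)` matrix of mean held-out AUCs, with
#'   a `summary` attribute holding per-method means.
#' @export
permutation_null <- function(X, Y, methods = c("pcc", "mlc"), n_perm = 20L,
                             seed = 1L, ...) {
  out <- matrix(NA_real_, n_perm, length(methods),
                dimnames = list(NULL, methods))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  for (r in seq_len(n_perm)) {
    set.seed(substream_seed(seed, paste0("perm_", r)))
    Yp <- Y[sample.int(nrow(Y)), , drop = FALSE]
    rownames(Yp) <- rownames(Y)
    res <- nested_cv(X, Yp, methods = methods,
                     seed = substream_seed(seed, paste0("cv_", r)), ...)
    s <- cv_summary(res)
    out[r, ] <- s$mean_auc[match(methods, s$method)]
  }
  attr(out, "summary") <- colMeans(out, na.rm = TRUE)
  out
}
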