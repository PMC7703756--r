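# Independent brute-force oracles: plain loops over enumerated pairs, kept
# deliberately free of the package's vectorized code paths.

# Random scaled expression fixture (rows centred, unit L2 norm).
random_scaled <- function(n_genes, n_samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  X <- X - rowMeans(X)
  X / sqrt(rowSums(X^2))
}

# Welch two-sample t-statistic from explicit enumeration of every p-p and
# p-n pair's weighted inner-product similarity (unbiased variances).
brute_welch_t <- function(X, pos, w) {
  neg <- setdiff(seq_len(nrow(X)), pos)
  s_pp <- c()
  for (i in seq_along(pos)) {
    for (j in seq_along(pos)) {
      if (i < j) s_pp <- c(s_pp, sum(w * X[pos[i], ] * X[pos[j], ]))
    }
  }
  s_pn <- c()
  for (i in pos) for (j in neg) s_pn <- c(s_pn, sum(w * X[i, ] * X[j, ]))
  (mean(s_pp) - mean(s_pn)) /
    sqrt(var(s_pp) / length(s_pp) + var(s_pn) / length(s_pn))
}

# Mutual rank by explicit sorting, geometric aggregation, average-tie ranks.
brute_mutual_rank <- function(S) {
  n <- nrow(S)
  R <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    R[i, others] <- rank(-S[i, others], ties.method = "average")
  }
  MR <- sqrt(R * t(R))
  diag(MR) <- 0
  MR
}

# AUC by exhaustive pair counting: concordant pairs plus half the ties.
brute_auc <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  total / (length(pos) * length(neg))
}

# k-NN score by explicit sort with index tie-break.
brute_knn_scores <- function(sim, ytrain, k, decreasing = TRUE) {
  apply(sim, 1, function(s) {
    key <- if (decreasing) -s else s
    ord <- order(key, seq_along(s))
    mean(ytrain[ord[seq_len(k)]])
  })
}

# Transitive closure of an ancestor relation by iterated expansion.
brute_ancestors <- function(parents, term) {
  out <- character()
  frontier <- parents[[term]]
  while (length(frontier) > 0) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier])), out)
  }
  out
}

# Small programmatic ontology: root -> a -> b -> c chain plus a diamond
# (d is_a a and d is_a b2; b2 is_a root).
toy_ontology <- function() {
  ontology(
    terms = c("GO:0008150", "a", "b", "c", "b2", "d"),
    parents = list(a = "GO:0008150", b = "a", c = "b",
                   b2 = "GO:0008150", d = c("a", "b2")),
    namespace = "biological_process")
}

# Write a small GAF 2.2 file; rows = list of c(gene, term, evidence,
# aspect, qualifier).
write_toy_gaf <- function(rows, path = tempfile(fileext = ".gaf")) {
  hdr <- "!gaf-version: 2.2"
  lines <- vapply(rows, function(r) {
    f <- rep("", 17)
    f[1] <- "DB"; f[2] <- r[1]; f[3] <- r[1]
    f[4] <- if (length(r) >= 5) r[5] else "involved_in"
    f[5] <- r[2]; f[6] <- "REF"; f[7] <- r[3]
    f[9] <- r[4]; f[14] <- "20240101"; f[15] <- "DB"
    paste(f, collapse = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
  path
}

# Counts fixture used by the preprocessing tests.
toy_counts <- function() {
  set.seed(42)
  v <- matrix(rpois(8 * 6, lambda = 150), 8, 6)
  v[1, ] <- c(0, 1, 0, 2, 1, 0)        # fails the max-expression filter
  v[2, ] <- c(150, 0, 0, 0, 0, 1)      # passes max, fails the median filter
  expression_matrix(v, gene_ids = paste0("g", 1:8),
                    sample_ids = paste0("s", 1:6),
                    batch_ids = c("A", "A", "B", "B", "C", "A"))
}
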