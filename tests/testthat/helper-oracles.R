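# Independent oracles used across tests. These deliberately use brute-force
# dense / double-loop formulations, never the package's own code paths.

# dense normalized biadjacency D_m^{-1/2} A D_d^{-1/2} (degree-0 rows/cols 0)
dense_norm_adj <- function(A) {
  dm <- rowSums(A)
  dd <- colSums(A)
  S <- A
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      S[i, j] <- if (A[i, j] == 1) 1 / sqrt(dm[i] * dd[j]) else 0
    }
  }
  S
}

# InfoNCE by explicit double loop: anchors[i] positive is cands[pos_idx[i]]
brute_infonce <- function(anchors, cands, pos_idx, tau) {
  total <- 0
  for (i in seq_len(nrow(anchors))) {
    sims <- numeric(nrow(cands))
    for (j in seq_len(nrow(cands))) {
      sims[j] <- sum(anchors[i, ] * cands[j, ]) / tau
    }
    total <- total - (sims[pos_idx[i]] - log(sum(exp(sims))))
  }
  total
}

unit_rows <- function(X) {
  t(apply(X, 1, function(r) if (sum(r^2) > 0) r / sqrt(sum(r^2)) else r))
}

# AUC by exhaustive pairwise comparison, ties at 1/2
brute_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}

random_graph <- function(n_m, n_d, density, seed) {
  set.seed(seed)
  A <- matrix(rbinom(n_m * n_d, 1, density), n_m, n_d)
  if (sum(A) == 0) A[1, 1] <- 1
  mda_graph(A)
}

# a tiny planted instance reused by several end-to-end tests
tiny_planted <- function(seed = 1) {
  planted_graph(30, 24, n_blocks = 2, p_in = 0.7, p_out = 0.05, seed = seed)
}

# fast training settings for tests that only need an end-to-end run
fast_config <- function(...) {
  mda_config(dim = 8L, epochs = 15L, classifier_epochs = 40L,
             hidden = c(16L, 8L), n_clusters = 3L, early_stop = FALSE, ...)
}
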