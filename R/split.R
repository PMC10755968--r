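#' k-fold edge split with negative sampling
#'
#' Partitions the positive associations into `k` near-equal folds (sizes
#' differ by at most one) and samples, per fold, negative (non-associated)
#' pairs uniformly without replacement: `neg_ratio` negatives per positive
#' for the test part and for the training part, disjoint from each other and
#' never overlapping a known positive. Folds split edges, not nodes; the
#' fold's test positives are meant to be removed from the graph used to train
#' during that fold.
#'
#' @param graph an [mda_graph].
#' @param k number of folds (`>= 2`).
#' @param seed integer seed; the same seed reproduces the split exactly.
#' @param neg_ratio negatives sampled per positive.
#' @return object of class `mda_folds`: list of `k` folds, each a list with
#'   `fold_id`, `train_pos`, `test_pos`, `train_neg`, `test_neg` (two-column
#'   index matrices), plus attributes `k`, `seed`, `neg_ratio`.
#' @export
kfold_split <- function(graph, k = 5, seed = 1, neg_ratio = 1) {
  n_pos <- nrow(graph$edges)
  if (k < 2) stop_arg("`k` must be >= 2")
  if (n_pos < k) stop_arg("fewer positive edges (", n_pos, ") than folds")
  n_cells <- as.numeric(graph$n_mirna) * graph$n_disease
  pos_keys <- edge_keys(graph$edges, graph$n_mirna)
  with_seed(seed, {
    perm <- sample.int(n_pos)
    fold_of <- rep(seq_len(k), length.out = n_pos)[order(perm)]
    folds <- vector("list", k)
    for (f in seq_len(k)) {
      test_idx <- which(fold_of == f)
      train_idx <- which(fold_of != f)
      n_test_neg <- round(neg_ratio * length(test_idx))
      n_train_neg <- round(neg_ratio * length(train_idx))
      neg <- sample_nonedges(graph, n_test_neg + n_train_neg, pos_keys,
                             n_cells)
      folds[[f]] <- list(
        fold_id = f,
        train_pos = graph$edges[train_idx, , drop = FALSE],
        test_pos = graph$edges[test_idx, , drop = FALSE],
        test_neg = neg[seq_len(n_test_neg), , drop = FALSE],
        train_neg = neg[n_test_neg + seq_len(n_train_neg), , drop = FALSE]
      )
    }
    structure(folds, class = "mda_folds", k = k, seed = seed,
              neg_ratio = neg_ratio)
  })
}

# Uniform sample of `n` distinct non-edge cells. Enumerates the complement
# when the matrix is small; otherwise rejection-samples (association graphs
# are sparse, so acceptance is near 1).
sample_nonedges <- function(graph, n, pos_keys = NULL, n_cells = NULL) {
  if (is.null(pos_keys)) pos_keys <- edge_keys(graph$edges, graph$n_mirna)
  if (is.null(n_cells)) n_cells <- as.numeric(graph$n_mirna) * graph$n_disease
  n_free <- n_cells - length(pos_keys)
  if (n > n_free) {
    stop_arg("requested ", n, " negatives but only ", n_free,
             " non-edges exist")
  }
  if (n == 0) return(keys_to_edges(numeric(0), graph$n_mirna))
  if (n_cells <= 4e6) {
    free <- setdiff(seq_len(n_cells), pos_keys)
    keys <- sample(free, n)
  } else {
    keys <- numeric(0)
    avoid <- pos_keys
    while (length(keys) < n) {
      cand <- unique(ceiling(runif(2 * (n - length(keys))) * n_cells))
      cand <- cand[!(cand %in% avoid)]
      keys <- c(keys, cand)
      avoid <- c(avoid, cand)
    }
    keys <- keys[seq_len(n)]
  }
  keys_to_edges(keys, graph$n_mirna)
}

#' @export
print.mda_folds <- function(x, ...) {
  cat(sprintf("%d-fold edge split (seed %d, neg_ratio %g)\n",
              attr(x, "k"), attr(x, "seed"), attr(x, "neg_ratio")))
  for (f in x) {
    cat(sprintf("  fold %d: %d train / %d test positives\n", f$fold_id,
                nrow(f$train_pos), nrow(f$test_pos)))
  }
  invisible(x)
}

#' Serialize / restore fold splits
#'
#' Folds are written as JSON so a split can be reproduced exactly across
#' machines and sessions.
#'
#' @param folds an `mda_folds` object.
#' @param path JSON file path.
#' @return `write_folds` returns `path` invisibly; `read_folds` returns the
#'   restored `mda_folds`.
#' @export
write_folds <- function(folds, path) {
  payload <- list(
    k = attr(folds, "k"), seed = attr(folds, "seed"),
    neg_ratio = attr(folds, "neg_ratio"),
    folds = lapply(folds, function(f) {
      lapply(f, function(x) if (is.matrix(x)) unclass(x) else x)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_folds
#' @export
read_folds <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  folds <- lapply(seq_len(payload$k), function(i) {
    f <- payload$folds[[i]]
    as_mat <- function(x) {
      m <- do.call(rbind, lapply(x, function(r) as.integer(unlist(r))))
      if (is.null(m)) m <- matrix(integer(0), 0, 2)
      colnames(m) <- c("mirna", "disease")
      m
    }
    list(fold_id = as.integer(f$fold_id), train_pos = as_mat(f$train_pos),
         test_pos = as_mat(f$test_pos), test_neg = as_mat(f$test_neg),
         train_neg = as_mat(f$train_neg))
  })
  structure(folds, class = "mda_folds", k = payload$k, seed = payload$seed,
            neg_ratio = payload$neg_ratio)
}

#' Sample BPR training triples
#'
#' For every training positive (m, i), draws `per_positive` diseases j with
#' which miRNA m has no association in the training graph, giving the paired
#' set O = \{(m, i, j) : A[m,i] = 1, A[m,j] = 0\} used by the ranking loss.
#' A miRNA associated with every disease is skipped with a warning (no valid
#' j exists).
#'
#' @param graph the training-graph [mda_graph] (defines which pairs count as
#'   non-associations).
#' @param train_pos two-column matrix of training positives.
#' @param per_positive negatives per positive.
#' @param seed integer seed.
#' @return integer matrix with columns `m`, `i`, `j`.
#' @export
sample_triples <- function(graph, train_pos, per_positive = 1, seed = 1) {
  if (nrow(train_pos) == 0) stop_arg("`train_pos` is empty")
  assoc <- split(graph$edges[, 2], graph$edges[, 1])
  with_seed(seed, {
    m_all <- rep(train_pos[, 1], each = per_positive)
    i_all <- rep(train_pos[, 2], each = per_positive)
    j_all <- integer(length(m_all))
    keep <- rep(TRUE, length(m_all))
    for (m in unique(m_all)) {
      rows <- which(m_all == m)
      cand <- setdiff(seq_len(graph$n_disease), assoc[[as.character(m)]])
      if (length(cand) == 0) {
        warning("miRNA ", m, " is associated with every disease; skipped",
                call. = FALSE)
        keep[rows] <- FALSE
        next
      }
      j_all[rows] <- cand[sample.int(length(cand), length(rows),
                                     replace = TRUE)]
    }
    cbind(m = m_all[keep], i = i_all[keep], j = j_all[keep])
  })
}
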