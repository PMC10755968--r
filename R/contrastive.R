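# Row-wise L2 normalization. Zero rows (isolated nodes after propagation)
# stay zero; their gradient through the normalization is defined as zero.
l2_normalize <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  nz <- nrm > 0
  Y <- X
  Y[nz, ] <- X[nz, , drop = FALSE] / nrm[nz]
  Y
}

# Backward pass of row normalization: given dL/dY with Y = X / ||X||,
# dL/dX = (dL/dY - Y * <Y, dL/dY>) / ||X||, zero on zero rows.
l2_normalize_backprop <- function(X, gY) {
  nrm <- sqrt(rowSums(X^2))
  nz <- nrm > 0
  Y <- X
  Y[nz, ] <- X[nz, , drop = FALSE] / nrm[nz]
  gX <- gY - Y * rowSums(Y * gY)
  gX[nz, ] <- gX[nz, , drop = FALSE] / nrm[nz]
  gX[!nz, ] <- 0
  gX
}

# Shared InfoNCE core over a similarity matrix S (anchors x candidates)
# already divided by tau: returns per-anchor softmax probabilities and loss
# sum -log P[anchor, positive].
softmax_rows <- function(S) {
  mx <- apply(S, 1, max)
  E <- exp(S - mx)
  E / rowSums(E)
}

#' Structure-contrastive (topology-neighbor) InfoNCE loss
#'
#' Even-length propagation walks stay on one side of the bipartite graph, so
#' a node's layer-k embedding (k even) aggregates its structurally similar
#' same-side neighbors. The loss treats each node's layer-k embedding as the
#' anchor, its own layer-0 embedding as the positive, and all other same-side
#' nodes' layer-0 embeddings as negatives:
#' \deqn{\sum_n -\log \frac{\exp(z_n^{(k)} \cdot z_n^{(0)} / \tau)}
#'   {\sum_{n'} \exp(z_n^{(k)} \cdot z_{n'}^{(0)} / \tau)}}
#' Embeddings are L2-normalized before the dot products when
#' `normalize = TRUE` (the default, and the convention used in training).
#'
#' @param layerk,layer0 embedding tables over the same node set (anchor
#'   layer-k, candidate layer-0).
#' @param tau temperature (> 0) of the softmax.
#' @param normalize L2-normalize rows before computing similarities.
#' @param grad also return gradients with respect to both input tables.
#' @return the scalar loss, or (with `grad = TRUE`) a list
#'   `list(loss, g_layerk, g_layer0)`.
#' @export
structure_contrast_loss <- function(layerk, layer0, tau = 0.1,
                                    normalize = TRUE, grad = FALSE) {
  if (tau <= 0) stop_arg("`tau` must be > 0")
  if (!all(is.finite(layerk)) || !all(is.finite(layer0))) {
    stop_arg("non-finite embedding values")
  }
  if (nrow(layerk) != nrow(layer0)) stop_arg("tables cover different nodes")
  A <- if (normalize) l2_normalize(layerk) else layerk
  B <- if (normalize) l2_normalize(layer0) else layer0
  S <- tcrossprod(A, B) / tau
  P <- softmax_rows(S)
  loss <- -sum(log(pmax(diag(P), .Machine$double.xmin)))
  if (!grad) return(loss)
  D <- P
  diag(D) <- diag(D) - 1          # dL/dS = P - I
  gA <- (D %*% B) / tau
  gB <- crossprod(D, A) / tau
  if (normalize) {
    gA <- l2_normalize_backprop(layerk, gA)
    gB <- l2_normalize_backprop(layer0, gB)
  }
  list(loss = loss, g_layerk = gA, g_layer0 = gB)
}

#' Combine the two sides of a contrastive loss
#'
#' Both contrastive objectives are computed once per node side and combined
#' as `miRNA-side + alpha * disease-side`, with a single shared balance
#' weight `alpha`.
#'
#' @param loss_m,loss_d the miRNA-side and disease-side scalar losses.
#' @param alpha side-balance weight (default 1).
#' @return the combined scalar.
#' @export
combine_side_losses <- function(loss_m, loss_d, alpha = 1) {
  if (!is.finite(loss_m) || !is.finite(loss_d)) {
    stop_arg("loss components must be finite")
  }
  loss_m + alpha * loss_d
}

#' k-means prototypes (Lloyd iteration)
#'
#' Clusters one side's node embeddings into `n_clusters` prototypes — the
#' cluster centers used as positive/negative anchors by the prototype
#' contrast. Plain Lloyd iterations run until the assignment reaches a fixed
#' point or `iter_max` iterations; an emptied cluster is re-seeded from the
#' point farthest from its current center (so exactly `n_clusters` centers
#' always survive). Deterministic under `seed`.
#'
#' @param embeddings numeric matrix (nodes x dim).
#' @param n_clusters number of prototypes (`<= nrow(embeddings)`).
#' @param seed integer seed for the initial center draw.
#' @param iter_max maximum Lloyd iterations.
#' @return object of class `mda_prototypes`: list with `centers`
#'   (`n_clusters x dim`), `labels` (node to cluster index), `sizes`,
#'   `iterations`, `converged`.
#' @export
cluster_prototypes <- function(embeddings, n_clusters, seed = 1,
                               iter_max = 100) {
  n <- nrow(embeddings)
  if (n_clusters < 1 || n_clusters > n) {
    stop_arg("`n_clusters` must be in [1, number of nodes]")
  }
  with_seed(seed, {
    centers <- embeddings[sample.int(n, n_clusters), , drop = FALSE]
    labels <- integer(n)
    converged <- FALSE
    it <- 0
    while (it < iter_max) {
      it <- it + 1
      d2 <- cross_dist2(embeddings, centers)
      new_labels <- max.col(-d2, ties.method = "first")
      # re-seed emptied clusters from the globally farthest point
      empty <- setdiff(seq_len(n_clusters), unique(new_labels))
      for (cl in empty) {
        far <- which.max(d2[cbind(seq_len(n), new_labels)])
        centers[cl, ] <- embeddings[far, ]
        d2 <- cross_dist2(embeddings, centers)
        new_labels <- max.col(-d2, ties.method = "first")
      }
      if (it > 1 && all(new_labels == labels)) {
        converged <- TRUE
        labels <- new_labels
        break
      }
      labels <- new_labels
      for (cl in seq_len(n_clusters)) {
        members <- labels == cl
        # a cluster can stay empty only when points are degenerate
        # (e.g. all identical); keep its previous center then
        if (any(members)) {
          centers[cl, ] <- colMeans(embeddings[members, , drop = FALSE])
        }
      }
    }
    structure(list(centers = centers, labels = labels,
                   sizes = tabulate(labels, n_clusters),
                   iterations = it, converged = converged),
              class = "mda_prototypes")
  })
}

cross_dist2 <- function(X, C) {
  outer(rowSums(X^2), rep(1, nrow(C))) - 2 * tcrossprod(X, C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
}

#' @export
print.mda_prototypes <- function(x, ...) {
  cat(sprintf("%d prototypes over %d nodes (sizes: %s; %d iterations%s)\n",
              nrow(x$centers), length(x$labels),
              paste(x$sizes, collapse = ", "), x$iterations,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Serialize a prototype assignment
#'
#' Labels go to JSON, centers to a TSV table, for inspection and exact
#' reconstruction.
#'
#' @param proto an `mda_prototypes` object.
#' @param path_json,path_centers output paths.
#' @return `path_json`, invisibly.
#' @export
write_prototypes <- function(proto, path_json, path_centers) {
  jsonlite::write_json(list(labels = proto$labels, sizes = proto$sizes),
                       path_json, auto_unbox = TRUE, digits = NA)
  write.table(proto$centers, path_centers, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path_json)
}

#' Prototype-contrastive (semantic-neighbor) InfoNCE loss
#'
#' Semantic neighbors are nodes with similar embeddings that may be
#' unreachable in the graph. Each node is pulled toward its own cluster's
#' prototype and pushed from the other prototypes of the same node side:
#' \deqn{\sum_n -\log \frac{\exp(e_n \cdot c_{own} / \tau)}
#'   {\sum_{t} \exp(e_n \cdot c_t / \tau)}}
#' Prototypes are treated as constants (no gradient flows into the centers;
#' they are refreshed by the E-step of the training loop).
#'
#' @param embeddings node embedding table (the clustered side).
#' @param assignment an `mda_prototypes` object covering all rows.
#' @param tau temperature (> 0).
#' @param normalize L2-normalize embeddings before the dot products.
#' @param grad also return the gradient with respect to `embeddings`.
#' @return scalar loss, or `list(loss, g_embeddings)` with `grad = TRUE`.
#' @export
prototype_contrast_loss <- function(embeddings, assignment, tau = 0.1,
                                    normalize = TRUE, grad = FALSE) {
  if (tau <= 0) stop_arg("`tau` must be > 0")
  n <- nrow(embeddings)
  if (length(assignment$labels) != n) {
    stop_arg("assignment does not cover all nodes")
  }
  E <- if (normalize) l2_normalize(embeddings) else embeddings
  C <- assignment$centers
  S <- tcrossprod(E, C) / tau
  P <- softmax_rows(S)
  own <- cbind(seq_len(n), assignment$labels)
  loss <- -sum(log(pmax(P[own], .Machine$double.xmin)))
  if (!grad) return(loss)
  D <- P
  D[own] <- D[own] - 1
  gE <- (D %*% C) / tau
  if (normalize) gE <- l2_normalize_backprop(embeddings, gE)
  list(loss = loss, g_embeddings = gE)
}
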