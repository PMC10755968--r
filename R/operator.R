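#' Degree-normalized bipartite propagation operator
#'
#' Builds the sparse operator used by the collaborative-filtering encoder.
#' Each association (m, d) carries the symmetric coefficient
#' \deqn{c(m,d) = 1 / \sqrt{|N_m| |N_d|}}{c(m,d) = 1/sqrt(|N_m||N_d|)}
#' where \eqn{|N_m|}, \eqn{|N_d|} are node degrees. The same coefficient is
#' applied in both propagation directions, so the operator equals
#' \eqn{D_m^{-1/2} A D_d^{-1/2}} in matrix form. Degree-0 nodes receive no
#' coefficients: they neither send nor receive mass during propagation.
#'
#' @param graph an [mda_graph].
#' @return object of class `mda_operator`: list with `S` (sparse
#'   `n_mirna x n_disease` [Matrix::dgCMatrix-class]), `deg_mirna`,
#'   `deg_disease`.
#' @export
propagation_operator <- function(graph) {
  deg <- mda_degrees(graph)
  e <- graph$edges
  if (nrow(e) > 0) {
    w <- 1 / sqrt(deg$mirna[e[, 1]] * deg$disease[e[, 2]])
  } else {
    w <- numeric(0)
  }
  S <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = w,
                            dims = c(graph$n_mirna, graph$n_disease))
  structure(list(S = S, deg_mirna = deg$mirna, deg_disease = deg$disease),
            class = "mda_operator")
}

#' One propagation layer
#'
#' Applies the normalized neighborhood sum once, in both directions, from the
#' same input layer (no in-place sequential update):
#' \deqn{X_m^{(l+1)} = \sum_{d \in N_m} c(m,d) X_d^{(l)}, \quad
#'       X_d^{(l+1)} = \sum_{m \in N_d} c(m,d) X_m^{(l)}}
#'
#' @param op an `mda_operator` from [propagation_operator()].
#' @param X_m,X_d embedding matrices (`n_mirna x dim`, `n_disease x dim`).
#' @return list with `X_m` and `X_d`, the next-layer tables.
#' @export
propagate_layer <- function(op, X_m, X_d) {
  if (nrow(X_m) != nrow(op$S) || nrow(X_d) != ncol(op$S)) {
    stop_arg("embedding tables do not match graph dimensions")
  }
  if (ncol(X_m) != ncol(X_d)) stop_arg("embedding dimensions differ")
  list(X_m = as.matrix(op$S %*% X_d),
       X_d = as.matrix(Matrix::crossprod(op$S, X_m)))
}

#' Multi-layer encoding with mean readout
#'
#' Runs `L` propagation layers from the base embeddings and combines all
#' layers with the uniform readout
#' \eqn{X = \frac{1}{L+1}\sum_{l=0}^{L} X^{(l)}}. There are no feature
#' transforms, nonlinearities or self-loops between layers (LightGCN
#' convention): the whole encoder is linear in the base embeddings.
#'
#' @param op an `mda_operator`.
#' @param X_m0,X_d0 base (layer-0) embedding tables.
#' @param L number of propagation layers (`>= 0`).
#' @return object of class `mda_embedding`: list with `layers_m`, `layers_d`
#'   (lists of length `L + 1`, layer 0 first), `readout_m`, `readout_d`, `L`.
#' @export
encode <- function(op, X_m0, X_d0, L = 4) {
  if (L < 0) stop_arg("`L` must be >= 0")
  layers_m <- vector("list", L + 1)
  layers_d <- vector("list", L + 1)
  layers_m[[1]] <- X_m0
  layers_d[[1]] <- X_d0
  if (L > 0) {
    for (l in seq_len(L)) {
      nxt <- propagate_layer(op, layers_m[[l]], layers_d[[l]])
      layers_m[[l + 1]] <- nxt$X_m
      layers_d[[l + 1]] <- nxt$X_d
    }
  }
  readout_m <- Reduce(`+`, layers_m) / (L + 1)
  readout_d <- Reduce(`+`, layers_d) / (L + 1)
  if (!all(is.finite(readout_m)) || !all(is.finite(readout_d))) {
    stop_arg("non-finite values produced during propagation")
  }
  structure(list(layers_m = layers_m, layers_d = layers_d,
                 readout_m = readout_m, readout_d = readout_d, L = L),
            class = "mda_embedding")
}

# Reverse-mode pass through the encoder: given gradients on every layer
# output (lists of length L+1; NULL entries mean zero), accumulate back to
# the base tables. Mirrors the forward recursion exactly.
encoder_backprop <- function(op, g_layers_m, g_layers_d, L) {
  d <- 0
  for (g in c(g_layers_m, g_layers_d)) if (!is.null(g)) { d <- ncol(g); break }
  zm <- matrix(0, nrow(op$S), d)
  zd <- matrix(0, ncol(op$S), d)
  nil0_m <- function(g) if (is.null(g)) zm else g
  nil0_d <- function(g) if (is.null(g)) zd else g
  gm <- nil0_m(g_layers_m[[L + 1]])
  gd <- nil0_d(g_layers_d[[L + 1]])
  if (L > 0) {
    for (l in seq(L, 1)) {
      # X_m^{(l-1)} feeds X_d^{(l)} = S^T X_m^{(l-1)} and
      # X_d^{(l-1)} feeds X_m^{(l)} = S X_d^{(l-1)}
      gm_new <- nil0_m(g_layers_m[[l]]) + as.matrix(op$S %*% gd)
      gd_new <- nil0_d(g_layers_d[[l]]) + as.matrix(Matrix::crossprod(op$S, gm))
      gm <- gm_new
      gd <- gd_new
    }
  }
  list(g_m0 = gm, g_d0 = gd)
}

#' Inner-product association scores
#'
#' The correlation score of a pair is the inner product of the two readout
#' embeddings, \eqn{\hat y(m,d) = X_m^\top X_d}.
#'
#' @param X_m,X_d readout embedding tables.
#' @param pairs two-column matrix of (miRNA index, disease index), 1-based.
#' @return numeric vector of scores, one per pair row.
#' @export
score_inner <- function(X_m, X_d, pairs) {
  pairs <- as.matrix(pairs)
  if (any(pairs[, 1] < 1) || any(pairs[, 1] > nrow(X_m)) ||
      any(pairs[, 2] < 1) || any(pairs[, 2] > nrow(X_d))) {
    stop_arg("pair index out of range")
  }
  rowSums(X_m[pairs[, 1], , drop = FALSE] * X_d[pairs[, 2], , drop = FALSE])
}
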