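#' Concatenated pair features
#'
#' Builds the classifier input for each (miRNA, disease) pair: the miRNA
#' readout embedding followed by the disease readout embedding, always in
#' that order.
#'
#' @param X_m,X_d readout embedding tables.
#' @param pairs two-column index matrix (miRNA, disease).
#' @return numeric matrix, one row per pair, `ncol(X_m) + ncol(X_d)` columns.
#' @export
concat_pairs <- function(X_m, X_d, pairs) {
  pairs <- as.matrix(pairs)
  if (any(pairs[, 1] < 1) || any(pairs[, 1] > nrow(X_m)) ||
      any(pairs[, 2] < 1) || any(pairs[, 2] > nrow(X_d))) {
    stop_arg("pair index out of range")
  }
  cbind(X_m[pairs[, 1], , drop = FALSE], X_d[pairs[, 2], , drop = FALSE])
}

#' Logistic function
#'
#' \eqn{S(x) = 1 / (1 + e^{-x})}; satisfies S(0) = 0.5 and
#' S(-x) = 1 - S(x), saturating smoothly at the extremes.
#'
#' @param x numeric vector.
#' @return values in (0, 1).
#' @export
sigmoid <- function(x) plogis(x)

#' Binary cross-entropy
#'
#' Mean of \eqn{-y \log p - (1-y) \log(1-p)} over pairs; predictions are
#' clipped to `[1e-12, 1 - 1e-12]` before the logs.
#'
#' @param pred probability vector.
#' @param label 0/1 vector of the same length.
#' @return scalar mean loss.
#' @export
bce_loss <- function(pred, label) {
  if (length(pred) != length(label)) stop_arg("length mismatch")
  p <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
  -mean(label * log(p) + (1 - label) * log(1 - p))
}

# MLP with ReLU hidden layers and a single logit output.
mlp_init <- function(input_dim, hidden = c(128L, 32L), seed = 1) {
  sizes <- c(input_dim, hidden, 1L)
  with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1)) {
      # He-style scaling for the ReLU layers
      W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
                       sizes[l], sizes[l + 1])
      b[[l]] <- rep(0, sizes[l + 1])
    }
    structure(list(W = W, b = b, sizes = sizes), class = "mda_mlp")
  })
}

mlp_forward <- function(head, X, keep = FALSE) {
  nL <- length(head$W)
  acts <- vector("list", nL + 1)
  acts[[1]] <- X
  H <- X
  for (l in seq_len(nL)) {
    Z <- H %*% head$W[[l]]
    Z <- Z + matrix(head$b[[l]], nrow(Z), ncol(Z), byrow = TRUE)
    if (l < nL) Z[Z < 0] <- 0
    H <- Z
    acts[[l + 1]] <- H
  }
  logits <- drop(H)
  if (keep) list(logits = logits, acts = acts) else logits
}

# Gradient of mean BCE wrt logits is (p - y)/n; backprop through the stack.
mlp_backprop <- function(head, fw, label, weight_decay = 0) {
  nL <- length(head$W)
  n <- length(label)
  p <- plogis(fw$logits)
  delta <- matrix((p - label) / n, ncol = 1)
  gW <- vector("list", nL); gb <- vector("list", nL)
  for (l in seq(nL, 1)) {
    gW[[l]] <- crossprod(fw$acts[[l]], delta) + 2 * weight_decay * head$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- tcrossprod(delta, head$W[[l]]) * (fw$acts[[l]] > 0)
    }
  }
  list(W = gW, b = gb, p = p)
}

#' Train the MLP pair classifier
#'
#' Fits the prediction head on frozen pair features with mean binary
#' cross-entropy (plus an optional L2 weight penalty) using full-batch Adam.
#' Refuses single-class label vectors.
#'
#' @param features matrix from [concat_pairs()].
#' @param labels 0/1 vector.
#' @param hidden hidden-layer sizes.
#' @param epochs gradient steps.
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty weight on the MLP weights.
#' @param seed integer seed for weight initialization.
#' @return object of class `mda_mlp` with an added `loss_trace`.
#' @export
train_classifier <- function(features, labels, hidden = c(128L, 32L),
                             epochs = 200, lr = 1e-3, weight_decay = 0,
                             seed = 1) {
  if (length(unique(labels)) < 2) {
    stop_arg("training labels are single-class; need both positives and ",
             "negatives")
  }
  head <- mlp_init(ncol(features), hidden, seed)
  params <- c(setNames(head$W, paste0("W", seq_along(head$W))),
              setNames(head$b, paste0("b", seq_along(head$b))))
  state <- adam_init(params)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fw <- mlp_forward(head, features, keep = TRUE)
    bp <- mlp_backprop(head, fw, labels, weight_decay)
    trace[ep] <- bce_loss(bp$p, labels)
    grads <- c(setNames(bp$W, paste0("W", seq_along(bp$W))),
               setNames(bp$b, paste0("b", seq_along(bp$b))))
    upd <- adam_step(params, grads, state, lr)
    params <- upd$params
    state <- upd$state
    for (l in seq_along(head$W)) {
      head$W[[l]] <- params[[paste0("W", l)]]
      head$b[[l]] <- drop(params[[paste0("b", l)]])
    }
  }
  head$loss_trace <- trace
  head
}

#' Pair probabilities from a trained head
#'
#' @param head an `mda_mlp`.
#' @param features matrix from [concat_pairs()].
#' @return probabilities strictly inside (0, 1) (clipped at 1e-12).
#' @export
predict_head <- function(head, features) {
  p <- plogis(mlp_forward(head, features))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}
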