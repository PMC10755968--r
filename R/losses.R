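#' Bayesian personalized ranking loss
#'
#' Pairwise ranking objective over triples (m, i, j): pushes the score of the
#' observed association (m, i) above the sampled non-association (m, j),
#' \deqn{L_{BPR} = \sum -\log \sigma(\hat y_{m,i} - \hat y_{m,j})}
#' with \eqn{\sigma} the logistic function. Computed as a numerically stable
#' softplus of the negated margin.
#'
#' @param pos_scores,neg_scores equal-length numeric score vectors.
#' @return scalar loss (sum over triples).
#' @export
bpr_loss <- function(pos_scores, neg_scores) {
  if (length(pos_scores) != length(neg_scores)) {
    stop_arg("score vectors must have equal length")
  }
  sum(softplus(-(pos_scores - neg_scores)))
}

# BPR loss plus gradients accumulated on the readout tables.
bpr_loss_grad <- function(X_m, X_d, triples) {
  m <- triples[, 1]; i <- triples[, 2]; j <- triples[, 3]
  Xm <- X_m[m, , drop = FALSE]
  diffs <- X_d[i, , drop = FALSE] - X_d[j, , drop = FALSE]
  margin <- rowSums(Xm * diffs)
  loss <- sum(softplus(-margin))
  g <- -plogis(-margin)            # dL/dmargin = -sigma(-margin)
  gm <- accumulate_rows(g * diffs, m, nrow(X_m))
  gi <- accumulate_rows(g * Xm, i, nrow(X_d))
  gj <- accumulate_rows(-g * Xm, j, nrow(X_d))
  list(loss = loss, g_m = gm, g_d = gi + gj)
}

# Sum rows of `contrib` sharing an index into an n-row matrix.
accumulate_rows <- function(contrib, idx, n) {
  out <- matrix(0, n, ncol(contrib))
  agg <- rowsum(contrib, idx)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

#' Model configuration defaults
#'
#' Bundles every tunable of the model with its shipped default: embedding
#' dimension 64, L = 4 propagation layers, even contrast layer k = 2,
#' temperature tau = 0.1, 10 prototypes per side, side-balance alpha = 1.0
#' and loss weights beta1 = 1e-6 (structure contrast), beta2 = 1e-8
#' (prototype contrast), beta3 = 1e-6 (L2 penalty); Adam with learning rate
#' 1e-3, minibatches of 2048 triples, 200 epochs with early stopping on a 5%
#' validation split.
#'
#' @param ... named overrides of any default.
#' @return a list of configuration values (class `mda_config`).
#' @export
mda_config <- function(...) {
  cfg <- list(
    dim = 64L, layers = 4L, even_layer = 2L, tau = 0.1, n_clusters = 10L,
    alpha = 1.0, beta1 = 1e-6, beta2 = 1e-8, beta3 = 1e-6,
    lr = 1e-3, epochs = 200L, batch_size = 2048L, per_positive = 1L,
    init_sd = 0.1, normalize_contrast = TRUE,
    early_stop = TRUE, patience = 20L, val_fraction = 0.05,
    hidden = c(128L, 32L), classifier_epochs = 200L, seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop_arg("unknown config fields: ",
                                paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$even_layer %% 2 != 0 || cfg$even_layer > cfg$layers) {
    stop_arg("`even_layer` must be even and <= `layers`")
  }
  if (any(c(cfg$beta1, cfg$beta2, cfg$beta3) < 0)) {
    stop_arg("beta weights must be >= 0")
  }
  if (cfg$epochs < 1) stop_arg("`epochs` must be >= 1")
  structure(cfg, class = "mda_config")
}

#' Total training objective and its gradients
#'
#' Evaluates the complete objective
#' \deqn{L = L_{BPR} + \beta_1 L_S + \beta_2 L_P + \beta_3 \|\Theta\|^2}
#' for given base embeddings, training triples and a frozen prototype
#' assignment, where \eqn{L_S} is the structure contrast over layer
#' `even_layer` vs layer 0 on both sides (disease side weighted `alpha`),
#' \eqn{L_P} the prototype contrast on the base embeddings (same `alpha`
#' combination), and \eqn{\|\Theta\|^2} the squared L2 norm of the base
#' embedding tables. Gradients are exact reverse-mode derivatives through
#' readout, propagation and normalization; prototypes are constants.
#'
#' @param op an `mda_operator` for the training graph.
#' @param E_m,E_d base embedding tables.
#' @param triples integer matrix (m, i, j) from [sample_triples()].
#' @param proto_m,proto_d `mda_prototypes` for each side (may be `NULL` when
#'   `beta2 = 0`).
#' @param config an [mda_config()] list.
#' @param grad also return gradients on `E_m`, `E_d`.
#' @return list with `total`, `components` (named: `bpr`, `structure`,
#'   `prototype`, `l2`), and with `grad = TRUE` also `g_m`, `g_d`.
#' @export
total_loss <- function(op, E_m, E_d, triples, proto_m = NULL, proto_d = NULL,
                       config = mda_config(), grad = FALSE) {
  L <- config$layers
  k <- config$even_layer
  emb <- encode(op, E_m, E_d, L)
  comp <- c(bpr = 0, structure = 0, prototype = 0, l2 = 0)

  bpr <- bpr_loss_grad(emb$readout_m, emb$readout_d, triples)
  comp["bpr"] <- bpr$loss

  sm <- structure_contrast_loss(emb$layers_m[[k + 1]], emb$layers_m[[1]],
                                tau = config$tau,
                                normalize = config$normalize_contrast,
                                grad = grad)
  sd_ <- structure_contrast_loss(emb$layers_d[[k + 1]], emb$layers_d[[1]],
                                 tau = config$tau,
                                 normalize = config$normalize_contrast,
                                 grad = grad)
  loss_sm <- if (grad) sm$loss else sm
  loss_sd <- if (grad) sd_$loss else sd_
  comp["structure"] <- combine_side_losses(loss_sm, loss_sd, config$alpha)

  use_proto <- !is.null(proto_m) && !is.null(proto_d)
  if (use_proto) {
    pm <- prototype_contrast_loss(E_m, proto_m, tau = config$tau,
                                  normalize = config$normalize_contrast,
                                  grad = grad)
    pd <- prototype_contrast_loss(E_d, proto_d, tau = config$tau,
                                  normalize = config$normalize_contrast,
                                  grad = grad)
    loss_pm <- if (grad) pm$loss else pm
    loss_pd <- if (grad) pd$loss else pd
    comp["prototype"] <- combine_side_losses(loss_pm, loss_pd, config$alpha)
  }

  comp["l2"] <- sum(E_m^2) + sum(E_d^2)
  total <- comp["bpr"] + config$beta1 * comp["structure"] +
    config$beta2 * comp["prototype"] + config$beta3 * comp["l2"]
  names(total) <- NULL
  if (!is.finite(total)) {
    bad <- names(comp)[!is.finite(comp)]
    stop_arg("non-finite loss component: ", paste(bad, collapse = ", "))
  }
  if (!grad) return(list(total = total, components = as.list(comp)))

  # ---- reverse pass ----
  g_layers_m <- vector("list", L + 1)
  g_layers_d <- vector("list", L + 1)
  # BPR acts on the readouts; the uniform readout spreads 1/(L+1) to each layer
  w <- 1 / (L + 1)
  for (l in seq_len(L + 1)) {
    g_layers_m[[l]] <- w * bpr$g_m
    g_layers_d[[l]] <- w * bpr$g_d
  }
  # structure contrast touches layer k (anchor) and layer 0 (candidates)
  g_layers_m[[k + 1]] <- g_layers_m[[k + 1]] + config$beta1 * sm$g_layerk
  g_layers_m[[1]] <- g_layers_m[[1]] + config$beta1 * sm$g_layer0
  g_layers_d[[k + 1]] <- g_layers_d[[k + 1]] +
    config$beta1 * config$alpha * sd_$g_layerk
  g_layers_d[[1]] <- g_layers_d[[1]] +
    config$beta1 * config$alpha * sd_$g_layer0
  back <- encoder_backprop(op, g_layers_m, g_layers_d, L)
  g_m <- back$g_m0
  g_d <- back$g_d0
  if (use_proto) {
    g_m <- g_m + config$beta2 * pm$g_embeddings
    g_d <- g_d + config$beta2 * config$alpha * pd$g_embeddings
  }
  g_m <- g_m + 2 * config$beta3 * E_m
  g_d <- g_d + 2 * config$beta3 * E_d
  list(total = total, components = as.list(comp), g_m = g_m, g_d = g_d)
}

# One Adam update over a named list of parameter matrices.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
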