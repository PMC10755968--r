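#' Fit the contrastive graph collaborative-filtering model
#'
#' The single entry point that trains the full model on an association
#' graph, in two stages:
#'
#' \enumerate{
#' \item \strong{Encoder (EM schedule).} Base miRNA/disease embeddings are
#'   initialized from a zero-mean Gaussian (sd `init_sd`) and optimized with
#'   Adam on the total objective
#'   \eqn{L = L_{BPR} + \beta_1 L_S + \beta_2 L_P + \beta_3\|\Theta\|^2}.
#'   Each epoch first re-clusters both sides' base embeddings into
#'   prototypes (E-step, k-means with an epoch-indexed seed), then takes
#'   minibatch gradient steps over freshly resampled BPR triples (M-step;
#'   prototypes held constant). Optional early stopping monitors
#'   inner-product AUC on a held-out validation slice of training positives.
#' \item \strong{Classifier.} Readout embeddings are frozen; an MLP head is
#'   trained with binary cross-entropy on the concatenated embeddings of the
#'   training positives and an equal number of sampled non-associations.
#' }
#'
#' @param graph an [mda_graph] with at least one edge (the training graph).
#' @param config an [mda_config()]; individual fields can also be overridden
#'   through `...`.
#' @param classifier train the MLP head (stage 2); if `FALSE` only the
#'   encoder is fitted and predictions fall back to inner-product scores.
#' @param verbose print per-epoch loss lines.
#' @param ... overrides forwarded to [mda_config()].
#' @return an object of class `mdagcl` with components `config`, `params`
#'   (base embedding tables), `embedding` (final [encode()] output), `head`
#'   (the trained `mda_mlp` or `NULL`), `trace` (per-epoch loss components),
#'   `graph_info`, and the classifier's training pairs/fitted values.
#' @examples
#' pg <- planted_graph(30, 20, n_blocks = 2, p_in = 0.6, p_out = 0.05,
#'                     seed = 1)
#' fit <- mdagcl(pg$graph, dim = 8, epochs = 5, classifier_epochs = 20,
#'               seed = 1)
#' print(fit)
#' head(predict(fit, pairs = cbind(1:3, 1:3)))
#' @export
mdagcl <- function(graph, config = NULL, classifier = TRUE, verbose = FALSE,
                   ...) {
  if (is.null(config)) config <- mda_config(...)
  else if (length(list(...))) config[names(list(...))] <- list(...)
  if (nrow(graph$edges) < 1) stop_arg("graph has no training edges")
  cfg <- config
  seed <- cfg$seed

  # deterministic sub-seeds, one stream per purpose
  s_init <- derive_seed(seed, 1)
  s_val <- derive_seed(seed, 2)
  s_cls <- derive_seed(seed, 3)

  # validation holdout on training positives (skipped for tiny graphs)
  n_pos <- nrow(graph$edges)
  n_val <- floor(cfg$val_fraction * n_pos)
  use_val <- cfg$early_stop && n_val >= 5
  if (use_val) {
    val_idx <- with_seed(s_val, sample.int(n_pos, n_val))
    train_edges <- graph$edges[-val_idx, , drop = FALSE]
    val_pos <- graph$edges[val_idx, , drop = FALSE]
    val_neg <- with_seed(derive_seed(seed, 4),
                         sample_nonedges(graph, nrow(val_pos)))
  } else {
    train_edges <- graph$edges
    val_pos <- val_neg <- NULL
  }
  train_graph <- mda_graph(train_edges, n_mirna = graph$n_mirna,
                           n_disease = graph$n_disease,
                           mirna_names = graph$mirna_names,
                           disease_names = graph$disease_names)
  op <- propagation_operator(train_graph)

  E_m <- with_seed(s_init,
                   matrix(rnorm(graph$n_mirna * cfg$dim, sd = cfg$init_sd),
                          graph$n_mirna, cfg$dim))
  E_d <- with_seed(derive_seed(seed, 5),
                   matrix(rnorm(graph$n_disease * cfg$dim, sd = cfg$init_sd),
                          graph$n_disease, cfg$dim))

  params <- list(E_m = E_m, E_d = E_d)
  state <- adam_init(params)
  trace <- matrix(NA_real_, cfg$epochs, 5,
                  dimnames = list(NULL, c("total", "bpr", "structure",
                                          "prototype", "l2")))
  val_trace <- rep(NA_real_, cfg$epochs)
  best <- list(params = params, val = -Inf, epoch = 0)
  bad_epochs <- 0

  for (ep in seq_len(cfg$epochs)) {
    # E-step: refresh prototypes from current (normalized) base embeddings
    # prototypes fit on the normalized base embeddings; the loss normalizes
    # internally, so it receives raw embeddings plus these fitted centers.
    # Computed even when beta2 = 0 so the trace always reports the component.
    pm_emb <- if (cfg$normalize_contrast) l2_normalize(params$E_m) else
      params$E_m
    pd_emb <- if (cfg$normalize_contrast) l2_normalize(params$E_d) else
      params$E_d
    proto_m <- cluster_prototypes(pm_emb, min(cfg$n_clusters, graph$n_mirna),
                                  seed = derive_seed(seed, 100 + ep))
    proto_d <- cluster_prototypes(pd_emb,
                                  min(cfg$n_clusters, graph$n_disease),
                                  seed = derive_seed(seed, 200 + ep))
    # M-step: fresh triples, minibatch Adam over the total objective
    triples <- sample_triples(train_graph, train_edges,
                              per_positive = cfg$per_positive,
                              seed = derive_seed(seed, 300 + ep))
    n_tr <- nrow(triples)
    batches <- split(seq_len(n_tr),
                     ceiling(seq_len(n_tr) / max(cfg$batch_size, 1)))
    ep_loss <- c(total = 0, bpr = 0, structure = 0, prototype = 0, l2 = 0)
    for (b in batches) {
      res <- total_loss(op, params$E_m, params$E_d,
                        triples[b, , drop = FALSE], proto_m, proto_d,
                        cfg, grad = TRUE)
      upd <- adam_step(params, list(E_m = res$g_m, E_d = res$g_d), state,
                       lr = cfg$lr)
      params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + c(res$total, unlist(res$components))
    }
    trace[ep, ] <- ep_loss
    if (use_val) {
      embv <- encode(op, params$E_m, params$E_d, cfg$layers)
      sc <- c(score_inner(embv$readout_m, embv$readout_d, val_pos),
              score_inner(embv$readout_m, embv$readout_d, val_neg))
      val_trace[ep] <- auc_score(rep(c(1, 0), c(nrow(val_pos),
                                                nrow(val_neg))), sc)
      if (val_trace[ep] > best$val + 1e-12) {
        best <- list(params = params, val = val_trace[ep], epoch = ep)
        bad_epochs <- 0
      } else {
        bad_epochs <- bad_epochs + 1
        if (bad_epochs >= cfg$patience) break
      }
    }
    if (verbose) {
      message(sprintf("epoch %3d  total %.4f  bpr %.4f%s", ep,
                      ep_loss["total"], ep_loss["bpr"],
                      if (use_val) sprintf("  valAUC %.4f", val_trace[ep])
                      else ""))
    }
  }
  if (use_val && best$epoch > 0) params <- best$params

  embedding <- encode(op, params$E_m, params$E_d, cfg$layers)

  head <- NULL
  cls_pairs <- NULL
  cls_labels <- NULL
  fitted_p <- NULL
  if (classifier) {
    neg <- with_seed(s_cls, sample_nonedges(graph, n_pos))
    cls_pairs <- rbind(graph$edges, neg)
    cls_labels <- rep(c(1, 0), c(n_pos, nrow(neg)))
    feats <- concat_pairs(embedding$readout_m, embedding$readout_d,
                          cls_pairs)
    head <- train_classifier(feats, cls_labels, hidden = cfg$hidden,
                             epochs = cfg$classifier_epochs, lr = cfg$lr,
                             weight_decay = cfg$beta3,
                             seed = derive_seed(seed, 6))
    fitted_p <- predict_head(head, feats)
  }

  structure(list(
    config = cfg,
    params = params,
    embedding = embedding,
    operator = op,
    head = head,
    trace = trace[seq_len(max(which(!is.na(trace[, 1])))), , drop = FALSE],
    val_trace = val_trace,
    best_epoch = if (use_val) best$epoch else NA_integer_,
    graph_info = list(n_mirna = graph$n_mirna, n_disease = graph$n_disease,
                      n_edges = n_pos, mirna_names = graph$mirna_names,
                      disease_names = graph$disease_names),
    classifier_pairs = cls_pairs,
    classifier_labels = cls_labels,
    fitted_probabilities = fitted_p
  ), class = "mdagcl")
}

#' @export
print.mdagcl <- function(x, ...) {
  gi <- x$graph_info
  cat("Contrastive graph collaborative-filtering model\n")
  cat(sprintf("  graph: %d miRNAs x %d diseases, %d associations\n",
              gi$n_mirna, gi$n_disease, gi$n_edges))
  cat(sprintf("  dim %d, %d layers, contrast layer %d, tau %g, %d prototypes\n",
              x$config$dim, x$config$layers, x$config$even_layer,
              x$config$tau, x$config$n_clusters))
  cat(sprintf("  %d encoder epochs run (final total loss %.4f)\n",
              nrow(x$trace), x$trace[nrow(x$trace), "total"]))
  if (!is.null(x$head)) {
    cat(sprintf("  MLP head (%s) final BCE %.4f\n",
                paste(x$config$hidden, collapse = "-"),
                utils::tail(x$head$loss_trace, 1)))
  }
  invisible(x)
}

#' @export
summary.mdagcl <- function(object, ...) {
  out <- list(
    config = object$config,
    n_epochs = nrow(object$trace),
    best_epoch = object$best_epoch,
    final_components = as.list(object$trace[nrow(object$trace), ]),
    training_bce = if (is.null(object$head)) NULL else
      utils::tail(object$head$loss_trace, 1),
    training_accuracy = if (is.null(object$fitted_probabilities)) NULL else
      mean((object$fitted_probabilities >= 0.5) == object$classifier_labels)
  )
  class(out) <- "summary.mdagcl"
  out
}

#' @export
print.summary.mdagcl <- function(x, ...) {
  cat("Model summary\n")
  cat(sprintf("  encoder epochs: %d (best validation epoch: %s)\n",
              x$n_epochs, format(x$best_epoch)))
  comp <- x$final_components
  cat(sprintf("  final losses: total %.4f | bpr %.4f | structure %.4f | prototype %.4f | l2 %.6f\n",
              comp$total, comp$bpr, comp$structure, comp$prototype, comp$l2))
  if (!is.null(x$training_bce)) {
    cat(sprintf("  classifier: BCE %.4f, training accuracy %.3f\n",
                x$training_bce, x$training_accuracy))
  }
  invisible(x)
}

#' @export
coef.mdagcl <- function(object, type = c("readout", "base"), ...) {
  type <- match.arg(type)
  if (type == "readout") {
    list(mirna = object$embedding$readout_m,
         disease = object$embedding$readout_d)
  } else {
    list(mirna = object$params$E_m, disease = object$params$E_d)
  }
}

#' Predict association probabilities or scores
#'
#' @param object a fitted [mdagcl] model.
#' @param pairs two-column (miRNA, disease) index matrix; when `NULL`, all
#'   pairs are scored and a full `n_mirna x n_disease` matrix is returned.
#' @param type `"response"` for MLP probabilities (the reported scores),
#'   `"inner"` for the raw inner-product correlation scores used by the
#'   ranking objective.
#' @param ... unused.
#' @return numeric vector (one entry per pair row) or full matrix.
#' @export
predict.mdagcl <- function(object, pairs = NULL, type = c("response",
                                                          "inner"), ...) {
  type <- match.arg(type)
  X_m <- object$embedding$readout_m
  X_d <- object$embedding$readout_d
  full <- is.null(pairs)
  if (full) {
    pairs <- cbind(rep(seq_len(nrow(X_m)), nrow(X_d)),
                   rep(seq_len(nrow(X_d)), each = nrow(X_m)))
  }
  vals <- if (type == "inner" || is.null(object$head)) {
    score_inner(X_m, X_d, pairs)
  } else {
    predict_head(object$head, concat_pairs(X_m, X_d, pairs))
  }
  if (full) matrix(vals, nrow(X_m), nrow(X_d),
                   dimnames = list(object$graph_info$mirna_names,
                                   object$graph_info$disease_names))
  else vals
}

#' @export
fitted.mdagcl <- function(object, ...) object$fitted_probabilities

#' @export
residuals.mdagcl <- function(object, ...) {
  if (is.null(object$fitted_probabilities)) return(NULL)
  object$classifier_labels - object$fitted_probabilities
}

#' Simulate association matrices from the fitted model
#'
#' Draws each cell as an independent Bernoulli variable with the model's
#' predicted association probability.
#'
#' @param object a fitted [mdagcl] with a classifier head.
#' @param nsim number of matrices.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of 0/1 matrices.
#' @export
simulate.mdagcl <- function(object, nsim = 1, seed = 1, ...) {
  P <- predict(object)
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      (matrix(runif(length(P)), nrow(P), ncol(P)) < P) + 0L
    })
  })
}

#' Plot the training loss trace
#'
#' @param x a fitted [mdagcl].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mdagcl <- function(x, ...) {
  tr <- x$trace
  graphics::matplot(seq_len(nrow(tr)), cbind(tr[, "total"], tr[, "bpr"]),
                    type = "l", lty = 1, col = c("black", "steelblue"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", legend = c("total", "bpr"), lty = 1,
                   col = c("black", "steelblue"), bty = "n")
  invisible(x)
}

#' Serialize readout embeddings to TSV
#'
#' Writes two files, `<prefix>_mirna.tsv` and `<prefix>_disease.tsv`, each
#' with an id column followed by the embedding coordinates.
#'
#' @param object a fitted [mdagcl].
#' @param prefix output path prefix.
#' @return character vector of the two paths, invisibly.
#' @export
write_embeddings <- function(object, prefix) {
  emb <- coef(object)
  gi <- object$graph_info
  ids <- list(mirna = if (is.null(gi$mirna_names))
    seq_len(gi$n_mirna) else gi$mirna_names,
    disease = if (is.null(gi$disease_names)) seq_len(gi$n_disease) else
      gi$disease_names)
  paths <- character(2)
  for (i in seq_along(emb)) {
    side <- names(emb)[i]
    paths[i] <- paste0(prefix, "_", side, ".tsv")
    tab <- data.frame(id = ids[[side]], emb[[side]], check.names = FALSE)
    write.table(tab, paths[i], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
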