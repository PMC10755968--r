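#' Thresholded confusion counts
#'
#' Scores at or above the threshold are predicted positive (ties count as
#' positive).
#'
#' @param labels 0/1 vector.
#' @param scores numeric vector in `[0, 1]`.
#' @param threshold decision threshold (default 0.5).
#' @return list of class `mda_confusion` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(labels, scores, threshold = 0.5) {
  if (length(labels) == 0) stop_arg("empty input")
  if (length(labels) != length(scores)) stop_arg("length mismatch")
  if (!all(labels %in% c(0, 1))) stop_arg("labels must be 0/1")
  pred <- scores >= threshold
  structure(list(
    TP = sum(pred & labels == 1), FP = sum(pred & labels == 0),
    TN = sum(!pred & labels == 0), FN = sum(!pred & labels == 1)
  ), class = "mda_confusion")
}

#' Classification metrics from confusion counts
#'
#' Standard ratios: accuracy (TP+TN)/total, specificity TN/(TN+FP),
#' sensitivity/recall TP/(TP+FN), precision TP/(TP+FP), and
#' F1 = 2*Pre*Sen/(Pre+Sen). A zero denominator gives `NaN` with a warning
#' ("Sen" and "REC" name the same quantity; both labels are kept).
#'
#' @param counts an `mda_confusion` from [confusion()].
#' @return named numeric vector `ACC`, `SPE`, `SEN`, `PRE`, `F1`.
#' @export
eval_metrics <- function(counts) {
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  with(counts, {
    acc <- ratio(TP + TN, TP + TN + FP + FN, "ACC")
    spe <- ratio(TN, TN + FP, "SPE")
    sen <- ratio(TP, TP + FN, "SEN")
    pre <- ratio(TP, TP + FP, "PRE")
    f1 <- if (is.nan(pre) || is.nan(sen) || pre + sen == 0) {
      warning("F1 undefined", call. = FALSE)
      NaN
    } else 2 * pre * sen / (pre + sen)
    c(ACC = acc, SPE = spe, SEN = sen, PRE = pre, F1 = f1)
  })
}

#' Area under the ROC curve (rank estimator)
#'
#' The Mann-Whitney formulation: the probability that a uniformly drawn
#' positive outranks a uniformly drawn negative, with tied scores counted as
#' one half. Invariant under strictly monotone score transforms.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric score vector.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(labels, scores) {
  if (length(labels) != length(scores)) stop_arg("length mismatch")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop_arg("both classes must be present to compute AUC")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' k-fold cross-validated evaluation
#'
#' For every fold: the fold's test positives are removed from the graph, the
#' model is fitted on the remaining associations ([mdagcl()]), and the test
#' positives plus the fold's sampled negatives are scored with the
#' classifier head. Reports AUC and thresholded metrics per fold and their
#' arithmetic mean.
#'
#' Ablation switches zero the corresponding loss weights: `"no_tcl"` removes
#' the topology (structure) contrast (`beta1 = 0`), `"no_scl"` removes the
#' semantic (prototype) contrast (`beta2 = 0`), `"no_cl"` removes both.
#'
#' @param graph an [mda_graph].
#' @param k number of folds.
#' @param seed root seed controlling the split and all per-fold training.
#' @param ablation one of `"full"`, `"no_tcl"`, `"no_scl"`, `"no_cl"`.
#' @param neg_ratio test negatives per test positive.
#' @param threshold decision threshold for the confusion metrics.
#' @param config optional [mda_config()]; `...` overrides fields.
#' @param verbose print a line per fold.
#' @param ... forwarded to [mda_config()].
#' @return object of class `mda_cv`: a data.frame with one row per fold plus
#'   an `"Average"` row, columns `fold`, `AUC`, `ACC`, `SPE`, `PRE`, `REC`,
#'   `F1`; attributes `seed`, `ablation`, `config`.
#' @export
cross_validate <- function(graph, k = 5, seed = 1,
                           ablation = c("full", "no_tcl", "no_scl", "no_cl"),
                           neg_ratio = 1, threshold = 0.5, config = NULL,
                           verbose = FALSE, ...) {
  ablation <- match.arg(ablation)
  if (is.null(config)) config <- mda_config(...)
  else if (length(list(...))) config[names(list(...))] <- list(...)
  if (ablation %in% c("no_tcl", "no_cl")) config$beta1 <- 0
  if (ablation %in% c("no_scl", "no_cl")) config$beta2 <- 0

  folds <- kfold_split(graph, k = k, seed = derive_seed(seed, 11),
                       neg_ratio = neg_ratio)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    fold <- folds[[f]]
    train_graph <- mda_graph(fold$train_pos, n_mirna = graph$n_mirna,
                             n_disease = graph$n_disease,
                             mirna_names = graph$mirna_names,
                             disease_names = graph$disease_names)
    cfg <- config
    cfg$seed <- derive_seed(seed, 20 + f)
    fit <- mdagcl(train_graph, config = cfg)
    test_pairs <- rbind(fold$test_pos, fold$test_neg)
    test_labels <- rep(c(1, 0), c(nrow(fold$test_pos), nrow(fold$test_neg)))
    scores <- predict(fit, pairs = test_pairs)
    met <- eval_metrics(confusion(test_labels, scores, threshold))
    rows[[f]] <- data.frame(fold = as.character(f),
                            AUC = auc_score(test_labels, scores),
                            ACC = met[["ACC"]], SPE = met[["SPE"]],
                            PRE = met[["PRE"]], REC = met[["SEN"]],
                            F1 = met[["F1"]])
    if (verbose) {
      message(sprintf("fold %d: AUC %.4f ACC %.4f", f, rows[[f]]$AUC,
                      rows[[f]]$ACC))
    }
  }
  tab <- do.call(rbind, rows)
  avg <- data.frame(fold = "Average", t(colMeans(tab[, -1])))
  out <- rbind(tab, avg)
  rownames(out) <- NULL
  structure(out, class = c("mda_cv", "data.frame"), seed = seed,
            ablation = ablation, config = config, k = k)
}

#' @export
print.mda_cv <- function(x, digits = 4, ...) {
  cat(sprintf("%d-fold cross-validation (%s model, seed %s)\n",
              attr(x, "k"), attr(x, "ablation"), format(attr(x, "seed"))))
  df <- as.data.frame(x)
  df[, -1] <- round(df[, -1], digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a cross-validation report as CSV
#'
#' @param report an `mda_cv`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  df <- as.data.frame(report)
  write.csv(cbind(df, seed = attr(report, "seed"),
                  ablation = attr(report, "ablation")),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Leave-one-out candidate ranking for a target node
#'
#' Implements the case-study protocol: every association incident to the
#' target is deleted, the model is retrained on the remaining graph, and all
#' opposite-side candidates are scored against the target and sorted in
#' decreasing probability (ties broken by candidate index).
#'
#' @param graph the full [mda_graph].
#' @param target node index (1-based) on the `side` given.
#' @param side `"disease"` ranks miRNA candidates for a disease target,
#'   `"mirna"` the converse.
#' @param seed training seed.
#' @param config optional [mda_config()]; `...` overrides fields.
#' @param ... forwarded to [mda_config()].
#' @return data.frame with columns `rank`, `candidate`, `name` (if names are
#'   present), `probability`, `known` (1 if the pair was a deleted true
#'   association).
#' @export
rank_candidates <- function(graph, target, side = c("disease", "mirna"),
                            seed = 1, config = NULL, ...) {
  side <- match.arg(side)
  n_side <- if (side == "disease") graph$n_disease else graph$n_mirna
  if (target < 1 || target > n_side) stop_arg("unknown target index")
  inc <- if (side == "disease") graph$edges[, 2] == target else
    graph$edges[, 1] == target
  train_graph <- mda_graph(graph$edges[!inc, , drop = FALSE],
                           n_mirna = graph$n_mirna,
                           n_disease = graph$n_disease,
                           mirna_names = graph$mirna_names,
                           disease_names = graph$disease_names)
  if (is.null(config)) config <- mda_config(...)
  else if (length(list(...))) config[names(list(...))] <- list(...)
  config$seed <- derive_seed(seed, 31)
  fit <- mdagcl(train_graph, config = config)
  if (side == "disease") {
    cand <- seq_len(graph$n_mirna)
    pairs <- cbind(cand, target)
    names_vec <- graph$mirna_names
    known <- as.integer(cand %in% graph$edges[inc, 1])
  } else {
    cand <- seq_len(graph$n_disease)
    pairs <- cbind(target, cand)
    names_vec <- graph$disease_names
    known <- as.integer(cand %in% graph$edges[inc, 2])
  }
  prob <- predict(fit, pairs = pairs)
  ord <- order(-prob, cand)
  out <- data.frame(rank = seq_along(cand), candidate = cand[ord],
                    probability = prob[ord], known = known[ord])
  if (!is.null(names_vec)) out$name <- names_vec[out$candidate]
  out
}

#' Five-number stability summary across repeated runs
#'
#' Summarizes repeated evaluation reports the way a boxplot would: min, Q1,
#' median, Q3, max per metric (quantiles by linear interpolation,
#' `type = 7`), plus values flagged as outliers by the 1.5 IQR rule.
#'
#' @param reports list of `mda_cv` reports (their `"Average"` rows are used)
#'   or a numeric matrix with one row per run and one column per metric.
#' @return list per metric: `min`, `q1`, `median`, `q3`, `max`, `outliers`.
#' @export
stability_summary <- function(reports) {
  if (is.list(reports) && !is.matrix(reports)) {
    if (length(reports) < 2) stop_arg("need at least 2 reports")
    mat <- do.call(rbind, lapply(reports, function(r) {
      avg <- as.data.frame(r)[as.data.frame(r)$fold == "Average", -1]
      as.numeric(avg)
    }))
    colnames(mat) <- setdiff(colnames(as.data.frame(reports[[1]])), "fold")
  } else {
    mat <- as.matrix(reports)
    if (nrow(mat) < 2) stop_arg("need at least 2 runs")
  }
  out <- lapply(colnames(mat), function(mn) {
    v <- mat[, mn]
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    outl <- v[v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr]
    list(min = min(v), q1 = q[1], median = q[2], q3 = q[3], max = max(v),
         outliers = unname(outl))
  })
  setNames(out, colnames(mat))
}

#' Ablation comparison over repeated seeds
#'
#' Trains each model variant on the same single holdout split per seed
#' (one fold of a k-fold split) and records the test AUC, giving the
#' matched-seed comparison used to judge whether each contrastive term
#' helps.
#'
#' @param graph an [mda_graph].
#' @param seeds integer vector of run seeds.
#' @param variants character vector of ablation switches (see
#'   [cross_validate()]).
#' @param k folds for the underlying split (the first fold is the holdout).
#' @param config optional [mda_config()]; `...` overrides fields.
#' @param ... forwarded to [mda_config()].
#' @return numeric matrix, rows = seeds, columns = variants, entries = AUC.
#' @export
ablation_study <- function(graph, seeds = 1:10,
                           variants = c("full", "no_tcl", "no_scl", "no_cl"),
                           k = 5, config = NULL, ...) {
  if (is.null(config)) config <- mda_config(...)
  else if (length(list(...))) config[names(list(...))] <- list(...)
  out <- matrix(NA_real_, length(seeds), length(variants),
                dimnames = list(seeds, variants))
  for (si in seq_along(seeds)) {
    folds <- kfold_split(graph, k = k, seed = derive_seed(seeds[si], 11))
    fold <- folds[[1]]
    train_graph <- mda_graph(fold$train_pos, n_mirna = graph$n_mirna,
                             n_disease = graph$n_disease)
    test_pairs <- rbind(fold$test_pos, fold$test_neg)
    test_labels <- rep(c(1, 0), c(nrow(fold$test_pos), nrow(fold$test_neg)))
    for (vi in seq_along(variants)) {
      cfg <- config
      if (variants[vi] %in% c("no_tcl", "no_cl")) cfg$beta1 <- 0
      if (variants[vi] %in% c("no_scl", "no_cl")) cfg$beta2 <- 0
      cfg$seed <- derive_seed(seeds[si], 20)
      fit <- mdagcl(train_graph, config = cfg)
      out[si, vi] <- auc_score(test_labels, predict(fit, pairs = test_pairs))
    }
  }
  out
}
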