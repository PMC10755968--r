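test_that("confusion counts and derived metrics match hand computation", {
  cm <- confusion(c(1, 0), c(0.9, 0.1), 0.5)
  expect_equal(unclass(cm)[c("TP", "TN", "FP", "FN")],
               list(TP = 1L, TN = 1L, FP = 0L, FN = 0L),
               ignore_attr = TRUE)

  # boundary rule: a score equal to the threshold is predicted positive
  cm_tie <- confusion(c(1, 0), c(0.5, 0.5), 0.5)
  expect_equal(cm_tie$TP, 1)
  expect_equal(cm_tie$FP, 1)
  expect_equal(cm_tie$TN, 0)

  # random case vs explicit loop
  set.seed(4)
  y <- rbinom(50, 1, 0.4)
  s <- runif(50)
  cm50 <- confusion(y, s, 0.35)
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in 1:50) {
    if (s[i] >= 0.35) {
      if (y[i] == 1) tp <- tp + 1 else fp <- fp + 1
    } else {
      if (y[i] == 0) tn <- tn + 1 else fn <- fn + 1
    }
  }
  expect_equal(c(cm50$TP, cm50$FP, cm50$TN, cm50$FN), c(tp, fp, tn, fn))
  expect_equal(cm50$TP + cm50$FP + cm50$TN + cm50$FN, 50)
  expect_error(confusion(numeric(0), numeric(0)), "empty")

  perfect <- eval_metrics(structure(list(TP = 5, FP = 0, TN = 5, FN = 0),
                                    class = "mda_confusion"))
  expect_equal(unname(perfect), rep(1, 5))

  m <- eval_metrics(structure(list(TP = 3, FP = 1, TN = 4, FN = 2),
                              class = "mda_confusion"))
  expect_equal(m[["ACC"]], 0.7)
  expect_equal(m[["PRE"]], 0.75)
  expect_equal(m[["SEN"]], 0.6)
  expect_equal(m[["SPE"]], 0.8)
  expect_equal(m[["F1"]], 2 * 0.75 * 0.6 / (0.75 + 0.6), tolerance = 1e-6)
  expect_equal(round(m[["F1"]], 6), 0.666667)
  # F1 identity: harmonic mean of precision and sensitivity
  expect_equal(m[["F1"]], 2 / (1 / m[["PRE"]] + 1 / m[["SEN"]]))

  expect_warning(expect_warning(
    deg <- eval_metrics(structure(list(TP = 0, FP = 0, TN = 4, FN = 2),
                                  class = "mda_confusion")),
    "PRE"), "F1")
  expect_true(is.nan(deg[["PRE"]]))
  expect_equal(deg[["SPE"]], 1)
})

test_that("rank AUC matches exhaustive pairwise comparison", {
  expect_equal(auc_score(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auc_score(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)
  for (sd in 1:5) {
    set.seed(sd + 60)
    y <- c(rep(1, 15), rep(0, 25))
    s <- round(runif(40), 2)   # rounding forces some ties
    expect_lt(abs(auc_score(y, s) - brute_auc(y, s)), 1e-12)
  }
  # invariance under strictly monotone transforms
  set.seed(70)
  y <- rbinom(30, 1, 0.5)
  if (length(unique(y)) == 1) y[1] <- 1 - y[1]
  s <- rnorm(30)
  expect_equal(auc_score(y, s), auc_score(y, exp(s)))
  expect_equal(auc_score(y, s), auc_score(y, qlogis(plogis(s))))
  expect_error(auc_score(rep(1, 4), runif(4)), "both classes")
})

test_that("cross-validation reports have the documented shape and seeds", {
  pg <- tiny_planted(6)
  rep1 <- cross_validate(pg$graph, k = 3, seed = 2, config = fast_config())
  df <- as.data.frame(rep1)
  expect_equal(nrow(df), 4)          # 3 folds + average row
  expect_equal(df$fold[4], "Average")
  expect_true(all(c("AUC", "ACC", "SPE", "PRE", "REC", "F1") %in%
                    colnames(df)))
  expect_true(all(df$AUC >= 0 & df$AUC <= 1))
  expect_equal(df$AUC[4], mean(df$AUC[1:3]))

  # bit-reproducible under the same seed
  rep2 <- cross_validate(pg$graph, k = 3, seed = 2, config = fast_config())
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))

  # the no-CL ablation is exactly the full model with both weights zeroed
  rep_nc <- cross_validate(pg$graph, k = 3, seed = 2, ablation = "no_cl",
                           config = fast_config())
  rep_b0 <- cross_validate(pg$graph, k = 3, seed = 2,
                           config = fast_config(beta1 = 0, beta2 = 0))
  expect_equal(as.data.frame(rep_nc), as.data.frame(rep_b0),
               ignore_attr = TRUE)

  path <- tempfile(fileext = ".csv")
  write_cv_report(rep1, path)
  expect_true(file.exists(path))
  back <- read.csv(path)
  expect_equal(nrow(back), 4)
})

test_that("leave-one-out ranking scores every candidate deterministically", {
  pg <- planted_graph(24, 18, n_blocks = 2, p_in = 0.7, p_out = 0.05,
                      seed = 2)
  target <- which(pg$disease_blocks == 1)[1]
  r1 <- rank_candidates(pg$graph, target, side = "disease", seed = 3,
                        config = fast_config())
  expect_equal(nrow(r1), pg$graph$n_mirna)     # all candidates scored
  expect_equal(sort(r1$candidate), 1:24)
  expect_true(all(diff(r1$probability) <= 0))

  r2 <- rank_candidates(pg$graph, target, side = "disease", seed = 3,
                        config = fast_config())
  expect_identical(r1, r2)
  expect_true(all(r1$probability > 0 & r1$probability < 1))
  # the deleted true partners are reported in the `known` column
  expect_equal(sum(r1$known),
               sum(pg$graph$edges[, 2] == target))

  # the converse direction scores every disease for a miRNA target
  r3 <- rank_candidates(pg$graph, 1, side = "mirna", seed = 3,
                        config = fast_config())
  expect_equal(nrow(r3), pg$graph$n_disease)

  expect_error(rank_candidates(pg$graph, 99, side = "disease"), "unknown")
})

test_that("stability summaries follow the linear-interpolation quantiles", {
  mat <- matrix(rep(c(0.9, 0.8), each = 4), 4, 2,
                dimnames = list(NULL, c("AUC", "ACC")))
  s <- stability_summary(mat)
  expect_equal(s$AUC$q1, 0.9)
  expect_equal(s$AUC$q3 - s$AUC$q1, 0)         # zero IQR
  expect_length(s$AUC$outliers, 0)

  v <- matrix(1:5, 5, 1, dimnames = list(NULL, "AUC"))
  sv <- stability_summary(v)
  expect_equal(sv$AUC$median, 3)
  expect_equal(sv$AUC$q1, 2)                   # type-7 linear interpolation
  expect_equal(sv$AUC$q3, 4)

  # one extreme value among 20 flagged by the 1.5 IQR rule
  w <- matrix(c(rnorm(19, 0.9, 0.002), 0.5), 20, 1,
              dimnames = list(NULL, "AUC"))
  sw <- stability_summary(w)
  expect_equal(sw$AUC$outliers, 0.5)
})
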