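test_that("BPR loss analytic anchors hold", {
  # zero margin -> ln 2 per triple
  expect_equal(bpr_loss(1.3, 1.3), log(2), tolerance = 1e-12)
  expect_equal(bpr_loss(c(0, 0, 0), c(0, 0, 0)), 3 * log(2),
               tolerance = 1e-12)

  # closed form at margin 1
  expect_equal(bpr_loss(1, 0), log(1 + exp(-1)), tolerance = 1e-12)

  # strictly decreasing in the margin, with the right limits
  margins <- seq(-10, 10, length.out = 100)
  losses <- vapply(margins, function(m) bpr_loss(m, 0), numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_lt(bpr_loss(40, 0), 1e-15)
  expect_gt(bpr_loss(-40, 0), 39)

  expect_error(bpr_loss(c(1, 2), 1), "equal length")
})

test_that("total loss reduces to its components at zero weights", {
  pg <- tiny_planted(4)
  g <- pg$graph
  op <- propagation_operator(g)
  cfg <- mda_config(dim = 4, beta1 = 0, beta2 = 0, beta3 = 0)
  set.seed(2)
  Em <- matrix(rnorm(g$n_mirna * 4, sd = 0.2), g$n_mirna, 4)
  Ed <- matrix(rnorm(g$n_disease * 4, sd = 0.2), g$n_disease, 4)
  tri <- sample_triples(g, g$edges, seed = 3)
  pm <- cluster_prototypes(Em, 3, seed = 1)
  pd <- cluster_prototypes(Ed, 3, seed = 1)
  res <- total_loss(op, Em, Ed, tri, pm, pd, cfg)
  expect_equal(res$total, res$components$bpr)

  # all-zero embeddings: every anchor value is forced
  Z_m <- Em * 0
  Z_d <- Ed * 0
  pm0 <- cluster_prototypes(Z_m, 3, seed = 1)
  pd0 <- cluster_prototypes(Z_d, 3, seed = 1)
  cfg1 <- mda_config(dim = 4, beta1 = 1, beta2 = 1, beta3 = 1)
  res0 <- total_loss(op, Z_m, Z_d, tri, pm0, pd0, cfg1)
  expect_equal(res0$components$bpr, nrow(tri) * log(2), tolerance = 1e-10)
  # uniform softmax over all same-side candidates / prototypes
  expect_equal(res0$components$structure,
               g$n_mirna * log(g$n_mirna) + g$n_disease * log(g$n_disease),
               tolerance = 1e-8)
  expect_equal(res0$components$prototype,
               (g$n_mirna + g$n_disease) * log(3), tolerance = 1e-8)
  expect_equal(res0$components$l2, 0)

  # shipped defaults carry the documented weights
  cfg_def <- mda_config()
  expect_equal(cfg_def$alpha, 1.0)
  expect_equal(cfg_def$beta1, 1e-6)
  expect_equal(cfg_def$beta2, 1e-8)
  expect_equal(cfg_def$beta3, 1e-6)
})

test_that("analytic gradients match central finite differences", {
  pg <- planted_graph(6, 5, n_blocks = 2, p_in = 0.8, p_out = 0.2, seed = 3)
  g <- pg$graph
  op <- propagation_operator(g)
  set.seed(1)
  Em <- matrix(rnorm(6 * 4, sd = 0.3), 6, 4)
  Ed <- matrix(rnorm(5 * 4, sd = 0.3), 5, 4)
  tri <- sample_triples(g, g$edges, seed = 2)
  pm <- cluster_prototypes(unit_rows(Em), 2, seed = 1)
  pd <- cluster_prototypes(unit_rows(Ed), 2, seed = 1)

  # isolate each loss component via its weight, plus the combined objective
  weightings <- list(
    bpr = c(0, 0, 0), structure = c(1, 0, 0), prototype = c(0, 1, 0),
    l2 = c(0, 0, 1), combined = c(0.3, 0.2, 0.1)
  )
  h <- 1e-6
  for (nm in names(weightings)) {
    w <- weightings[[nm]]
    cfg <- mda_config(dim = 4, layers = 4, even_layer = 2, tau = 0.5,
                      beta1 = w[1], beta2 = w[2], beta3 = w[3])
    res <- total_loss(op, Em, Ed, tri, pm, pd, cfg, grad = TRUE)
    fd_err <- 0
    for (which in c("m", "d")) {
      M <- if (which == "m") Em else Ed
      G <- if (which == "m") res$g_m else res$g_d
      for (i in seq_len(nrow(M))) {
        for (j in seq_len(ncol(M))) {
          f <- function(v) {
            Em2 <- Em; Ed2 <- Ed
            if (which == "m") Em2[i, j] <- v else Ed2[i, j] <- v
            total_loss(op, Em2, Ed2, tri, pm, pd, cfg)$total
          }
          num <- (f(M[i, j] + h) - f(M[i, j] - h)) / (2 * h)
          fd_err <- max(fd_err,
                        abs(G[i, j] - num) / max(abs(num), 1e-6))
        }
      }
    }
    expect_lt(fd_err, 1e-4, label = paste("component", nm))
  }
})

test_that("training reduces the loss and obeys identity/ordering anchors", {
  pg <- tiny_planted(5)

  # zero learning rate leaves parameters at their initialization
  f0 <- mdagcl(pg$graph, config = fast_config(lr = 0, epochs = 1,
                                              seed = 7),
               classifier = FALSE)
  f0b <- mdagcl(pg$graph, config = fast_config(lr = 1e-3, epochs = 0 + 1,
                                               seed = 7),
                classifier = FALSE)
  # same seed, lr 0: embeddings equal the seeded Gaussian init of f0b's start
  expect_false(identical(f0$params$E_m, f0b$params$E_m))
  init <- mdagcl(pg$graph, config = fast_config(lr = 0, epochs = 5,
                                                seed = 7),
                 classifier = FALSE)
  expect_identical(f0$params$E_m, init$params$E_m)

  # loss decreases over epochs on a fixed instance
  fit <- mdagcl(pg$graph, config = fast_config(epochs = 10, seed = 3),
                classifier = FALSE)
  expect_lt(fit$trace[10, "total"], fit$trace[1, "total"])

  # single positive pair: the score margin grows monotonically at first
  g1 <- mda_graph(cbind(1, 1), n_mirna = 1, n_disease = 2)
  margins <- numeric(10)
  for (ep in 1:10) {
    f <- mdagcl(g1, config = mda_config(dim = 4, epochs = ep, lr = 0.05,
                                        layers = 2, n_clusters = 1,
                                        early_stop = FALSE, seed = 11),
                classifier = FALSE)
    sc <- predict(f, pairs = rbind(c(1, 1), c(1, 2)), type = "inner")
    margins[ep] <- sc[1] - sc[2]
  }
  expect_true(all(diff(margins) > 0))
})

test_that("fitting recovers planted block structure in held-out scores", {
  pg <- planted_graph(60, 45, n_blocks = 2, p_in = 0.5, p_out = 0.03,
                      seed = 0)
  folds <- kfold_split(pg$graph, k = 5, seed = 5)
  f <- folds[[1]]
  tg <- mda_graph(f$train_pos, n_mirna = 60, n_disease = 45)
  fit <- mdagcl(tg, config = mda_config(dim = 16, epochs = 40,
                                        early_stop = FALSE, seed = 1,
                                        hidden = c(32L, 8L),
                                        classifier_epochs = 80L))
  # held-out within-block pairs outscore cross-block pairs on average
  same <- outer(pg$mirna_blocks, pg$disease_blocks, `==`)
  P <- predict(fit, type = "inner")
  A <- as.matrix(pg$graph)
  held <- A == 0 | TRUE  # all pairs; compare block means on non-training cells
  trained <- matrix(FALSE, 60, 45)
  trained[f$train_pos] <- TRUE
  expect_gt(mean(P[same & !trained]), mean(P[!same & !trained]))
})
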