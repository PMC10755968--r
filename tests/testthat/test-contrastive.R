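test_that("structure contrast matches the brute-force softmax and anchors", {
  # single node: numerator equals denominator, loss 0
  one <- matrix(c(1, 2), 1, 2)
  expect_equal(structure_contrast_loss(one, one, tau = 0.5), 0)

  # two nodes, anchor equidistant from both candidates -> ln 2 per node
  layer0 <- rbind(c(1, 0), c(0, 1))
  layerk <- rbind(c(1, 1) / sqrt(2), c(1, 1) / sqrt(2))
  loss <- structure_contrast_loss(layerk, layer0, tau = 1, normalize = TRUE)
  expect_equal(loss, 2 * log(2), tolerance = 1e-12)

  # random instances vs the double-loop oracle (normalized convention)
  for (sd in 1:5) {
    set.seed(sd)
    Zk <- matrix(rnorm(10 * 4), 10, 4)
    Z0 <- matrix(rnorm(10 * 4), 10, 4)
    tau <- runif(1, 0.05, 2)
    got <- structure_contrast_loss(Zk, Z0, tau = tau, normalize = TRUE)
    want <- brute_infonce(unit_rows(Zk), unit_rows(Z0), 1:10, tau)
    expect_lt(abs(got - want), 1e-8)
  }

  expect_error(structure_contrast_loss(layerk, layer0, tau = 0), "tau")
  bad <- layerk
  bad[1, 1] <- NaN
  expect_error(structure_contrast_loss(bad, layer0, 0.1), "finite")
})

test_that("contrastive losses are positive, monotone and rotation-invariant", {
  set.seed(21)
  Zk <- matrix(rnorm(8 * 5), 8, 5)
  Z0 <- matrix(rnorm(8 * 5), 8, 5)
  loss <- structure_contrast_loss(Zk, Z0, tau = 0.2)
  expect_gt(loss, 0)

  # raising the positive-pair similarity (holding negatives fixed,
  # unnormalized so the perturbation is exact) strictly lowers the loss
  l_raw <- structure_contrast_loss(Zk, Z0, tau = 0.5, normalize = FALSE)
  Zk2 <- Zk
  Zk2[3, ] <- Zk[3, ] + 0.2 * Z0[3, ]   # move anchor 3 toward its positive
  S_before <- Zk %*% t(Z0)
  S_after <- Zk2 %*% t(Z0)
  expect_gt(S_after[3, 3], S_before[3, 3])
  l_after <- structure_contrast_loss(Zk2, Z0, tau = 0.5, normalize = FALSE)
  # only row 3 changed; check the effect isolated to its per-node term
  term <- function(S, i) -(S[i, i] / 0.5 - log(sum(exp(S[i, ] / 0.5))))
  expect_lt(term(S_after, 3), term(S_before, 3))

  # temperature limit: tau -> Inf gives the uniform softmax ln(n) per node
  l_hot <- structure_contrast_loss(Zk, Z0, tau = 1e6)
  expect_equal(l_hot, 8 * log(8), tolerance = 1e-3)

  # global rotation invariance under normalization
  qr_q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  l_rot <- structure_contrast_loss(Zk %*% qr_q, Z0 %*% qr_q, tau = 0.2)
  expect_equal(l_rot, loss, tolerance = 1e-10)
})

test_that("side combination is a weighted sum", {
  expect_equal(combine_side_losses(0.7, 5, alpha = 0), 0.7)
  expect_equal(combine_side_losses(0.3, 0.3, alpha = 1), 0.6)
  expect_equal(combine_side_losses(0.5, 0.25, alpha = 1.0), 0.75)
  expect_equal(combine_side_losses(1.0, 0.5, alpha = 2.0), 2.0)
  expect_error(combine_side_losses(Inf, 1, 1), "finite")
})

test_that("k-means prototypes reach sensible fixed points", {
  # duplicated points at two locations -> centers equal those locations
  pts <- rbind(matrix(rep(c(0, 0), 5), ncol = 2, byrow = TRUE),
               matrix(rep(c(3, 4), 5), ncol = 2, byrow = TRUE))
  proto <- cluster_prototypes(pts, 2, seed = 1)
  got <- proto$centers[order(proto$centers[, 1]), ]
  expect_equal(unname(got), rbind(c(0, 0), c(3, 4)))
  expect_equal(proto$sizes, c(5, 5))

  # k = 1 -> center is the global mean
  set.seed(5)
  X <- matrix(rnorm(30 * 3), 30, 3)
  p1 <- cluster_prototypes(X, 1, seed = 2)
  expect_equal(unname(p1$centers[1, ]), unname(colMeans(X)))

  # WSS beats 50 random assignments
  set.seed(6)
  X2 <- matrix(rnorm(30 * 8), 30, 8)
  p3 <- cluster_prototypes(X2, 3, seed = 3)
  wss <- function(labels) {
    sum(vapply(1:3, function(cl) {
      sub <- X2[labels == cl, , drop = FALSE]
      if (nrow(sub) == 0) return(0)
      sum(sweep(sub, 2, colMeans(sub))^2)
    }, numeric(1)))
  }
  wss_fit <- wss(p3$labels)
  rand_wss <- vapply(1:50, function(sd) {
    set.seed(sd + 500)
    wss(sample(1:3, 30, TRUE))
  }, numeric(1))
  expect_true(all(wss_fit <= rand_wss))

  # agrees with stats::kmeans on well-separated clusters
  sep <- rbind(matrix(rnorm(20, sd = 0.05), 10, 2),
               matrix(rnorm(20, mean = 5, sd = 0.05), 10, 2))
  ours <- cluster_prototypes(sep, 2, seed = 4)
  ref <- stats::kmeans(sep, 2, nstart = 5)
  agree <- max(mean((ours$labels == 1) == (ref$cluster == 1)),
               mean((ours$labels == 1) == (ref$cluster == 2)))
  expect_equal(agree, 1)
  expect_lt(abs(sum(ours$centers^2) - sum(ref$centers^2)), 1e-8)

  expect_identical(cluster_prototypes(X2, 3, seed = 9),
                   cluster_prototypes(X2, 3, seed = 9))
  expect_error(cluster_prototypes(X2, 31, seed = 1), "n_clusters")
})

test_that("prototype contrast matches the brute-force softmax and anchors", {
  # single prototype -> loss 0
  set.seed(31)
  E <- matrix(rnorm(12 * 4), 12, 4)
  p1 <- cluster_prototypes(unit_rows(E), 1, seed = 1)
  expect_equal(prototype_contrast_loss(E, p1, tau = 0.3), 0)

  # node equidistant from all 4 prototypes -> ln 4
  centers <- diag(4)
  assign4 <- structure(list(centers = centers, labels = 1L,
                            sizes = c(1L, 0L, 0L, 0L)),
                       class = "mda_prototypes")
  e <- matrix(rep(0.5, 4), 1)
  expect_equal(prototype_contrast_loss(e, assign4, tau = 1), log(4),
               tolerance = 1e-12)

  # random cases vs double-loop oracle
  for (sd in 1:5) {
    set.seed(sd + 40)
    E <- matrix(rnorm(10 * 4), 10, 4)
    proto <- cluster_prototypes(unit_rows(E), 3, seed = sd)
    tau <- runif(1, 0.05, 2)
    got <- prototype_contrast_loss(E, proto, tau = tau, normalize = TRUE)
    want <- brute_infonce(unit_rows(E), proto$centers, proto$labels, tau)
    expect_lt(abs(got - want), 1e-8)
  }

  expect_error(prototype_contrast_loss(E, proto, tau = -1), "tau")
})
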