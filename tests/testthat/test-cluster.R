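test_that("soft assignment follows the Student's-t kernel with exponent -1", {
  # equidistant from both centroids -> 0.5 / 0.5
  f <- matrix(c(0.5, 0), 1, 2)
  c2 <- rbind(c(0, 0), c(1, 0))
  expect_equal(soft_assign(f, c2, 1)[1, ], c(0.5, 0.5))

  # at centroid 1, squared distance 1 to centroid 2, alpha 1:
  # unnormalized kernels (1, 0.5) -> (2/3, 1/3)
  f0 <- matrix(c(0, 0), 1, 2)
  expect_equal(soft_assign(f0, c2, 1)[1, ], c(2 / 3, 1 / 3))

  set.seed(8)
  s <- soft_assign(matrix(rnorm(40), 10, 4), matrix(rnorm(12), 3, 4), 0.7)
  expect_equal(rowSums(s), rep(1, 10))
  expect_true(all(s > 0 & s <= 1))
})

test_that("target distribution sharpens and has the documented fixed points", {
  # one-hot rows are a fixed point
  one_hot <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(target_distribution(one_hot), one_hot)

  # fully uniform rows stay uniform
  u <- matrix(1 / 4, 5, 4)
  expect_equal(target_distribution(u), u)

  # single-cell case collapses the frequency term
  s1 <- matrix(c(0.8, 0.2), 1, 2)
  expect_equal(target_distribution(s1), s1)

  set.seed(2)
  s <- soft_assign(matrix(rnorm(30), 10, 3), matrix(rnorm(9), 3, 3), 1)
  t <- target_distribution(s)
  expect_equal(rowSums(t), rep(1, 10))
})

test_that("the loss vanishes exactly when t equals s squared", {
  set.seed(4)
  t <- matrix(runif(12), 4, 3)
  t <- t / rowSums(t)
  s <- sqrt(t)
  expect_equal(assignment_loss(s, t), 0)
})

test_that("one-hot targets give the closed-form log penalty", {
  s <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  t <- rbind(c(1, 0), c(0, 1))
  expect_equal(assignment_loss(s, t), log(1 / 0.9^2) + log(1 / 0.8^2))
})

test_that("vectorized loss matches a naive double loop", {
  set.seed(6)
  for (rep in 1:5) {
    f <- matrix(rnorm(30), 10, 3)
    cc <- matrix(rnorm(9), 3, 3)
    s <- soft_assign(f, cc, 1)
    t <- target_distribution(s)
    expect_equal(assignment_loss(s, t), naive_loss(s, t), tolerance = 1e-10)
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(11)
  worst <- 0
  for (rep in 1:20) {
    n <- sample(3:10, 1); K <- sample(2:3, 1); d <- sample(2:4, 1)
    alpha <- runif(1, 0.5, 2)
    f <- matrix(rnorm(n * d), n, d)
    cc <- matrix(rnorm(K * d), K, d)
    t <- target_distribution(soft_assign(f, cc, alpha))
    an <- assignment_gradients(f, cc, t, alpha)
    fd <- fd_gradients(f, cc, t, alpha)
    rel <- max(abs(an$d_f - fd$d_f) / pmax(abs(fd$d_f), 1e-3),
               abs(an$d_centroids - fd$d_centroids) /
                 pmax(abs(fd$d_centroids), 1e-3))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-5)
})

test_that("gradients respect symmetry and translation invariance", {
  # cell midway between two centroids with a symmetric target row:
  # no force along the inter-centroid axis
  f <- matrix(c(0.5, 0.3), 1, 2)
  cc <- rbind(c(0, 0.3), c(1, 0.3))
  t <- matrix(c(0.5, 0.5), 1, 2)
  g <- assignment_gradients(f, cc, t, 1)
  expect_equal(g$d_f[1, 1], 0)

  # loss depends only on f - k differences: total gradient sums to zero
  set.seed(12)
  f <- matrix(rnorm(20), 5, 4)
  cc <- matrix(rnorm(8), 2, 4)
  t <- target_distribution(soft_assign(f, cc, 1))
  g <- assignment_gradients(f, cc, t, 1)
  expect_equal(colSums(g$d_f) + colSums(g$d_centroids), rep(0, 4),
               tolerance = 1e-12)
})

test_that("tolerance is the exact fraction of changed labels", {
  expect_identical(compute_tolerance(1:5, 1:5), 0)
  v <- rep(1L, 100); w <- v; w[37] <- 2L
  expect_identical(compute_tolerance(w, v), 0.01)
  expect_identical(compute_tolerance(rep(1, 8), rep(2, 8)), 1)
  expect_error(compute_tolerance(1:3, 1:4), "lengths")
})

test_that("Louvain seeding recovers two separated blobs", {
  f <- two_blobs(n_per = 100, d = 16, sep = 5, sigma = 0.5, seed = 2)
  init <- init_centroids_louvain(f, knn_k = 15, resolution = 1.0, seed = 0)
  expect_identical(init$K, 2L)
  mu <- rbind(rep(0, 16), rep(5, 16))
  o <- order(init$centroids[, 1])
  rms <- sqrt(rowSums((init$centroids[o, ] - mu)^2) / 16)
  expect_true(all(rms < 3 * 0.5 / sqrt(100)))

  # duplicating every point must not change the community count
  dup <- init_centroids_louvain(rbind(f, f), 15, 1.0, 0)
  expect_identical(dup$K, init$K)

  # fixed seed -> identical partition
  again <- init_centroids_louvain(f, 15, 1.0, 0)
  expect_identical(again$labels, init$labels)

  expect_error(init_centroids_louvain(f[1:10, ], knn_k = 15), "knn_k")
})

test_that("full-batch descent on a fixed target does not increase the loss", {
  set.seed(13)
  f <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
             matrix(rnorm(40, 2, 0.3), 20, 2))
  cc <- rbind(c(0.2, 0.1), c(1.8, 2.1))
  t <- target_distribution(soft_assign(f, cc, 1))
  lr <- 1e-3
  prev <- assignment_loss(soft_assign(f, cc, 1), t)
  for (step in 1:25) {
    g <- assignment_gradients(f, cc, t, 1)
    f <- f - lr * g$d_f
    cc <- cc - lr * g$d_centroids
    cur <- assignment_loss(soft_assign(f, cc, 1), t)
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("permuting centroids permutes labels and nothing else", {
  set.seed(14)
  f <- matrix(rnorm(60), 20, 3)
  cc <- matrix(rnorm(12), 4, 3)
  s1 <- soft_assign(f, cc, 1)
  perm <- c(3L, 1L, 4L, 2L)
  s2 <- soft_assign(f, cc[perm, ], 1)
  expect_equal(s2, s1[, perm])
  expect_identical(perm[max.col(s2)], max.col(s1))
})

test_that("the iterative loop stops at a fixed point on the first check", {
  # encoder trained on two tight blobs, centroids placed at the blob means:
  # no labels can change, so the run must end after one epoch
  d <- 8
  set.seed(15)
  x <- rbind(matrix(rnorm(60 * d, -1, 0.05), 60, d),
             matrix(rnorm(60 * d, 1, 0.05), 60, d))
  cfg <- gdesce_config(seed = 1, pretrain_epochs = 30, finetune_epochs = 30,
                       minibatch_size = 32, learning_rate = 0.001,
                       knn_k = 10)
  model <- finetune(pretrain_layerwise(x, dims = c(d, 4), config = cfg), x, cfg)
  f <- encode(model, x)
  lab <- rep(1:2, each = 60)
  init <- list(centroids = rowsum(f, lab) / 60, labels = lab, K = 2L)
  fit <- gdesce_cluster(x, model, cfg, init = init)
  expect_identical(fit$n_epochs, 1L)
  expect_lt(fit$tol_trace[1], cfg$tol_threshold)

  # a tolerance ceiling of ~1 also ends the run at the first evaluation
  cfg2 <- gdesce_config(seed = 1, pretrain_epochs = 30, finetune_epochs = 30,
                        minibatch_size = 32, tol_threshold = 0.999, knn_k = 10)
  fit2 <- gdesce_cluster(x, model, cfg2, init = init)
  expect_identical(fit2$n_epochs, 1L)
})

test_that("soft assignments stay row-stochastic throughout a run", {
  d <- 6
  set.seed(16)
  x <- rbind(matrix(rnorm(50 * d, -1, 0.3), 50, d),
             matrix(rnorm(50 * d, 1, 0.3), 50, d))
  cfg <- gdesce_config(seed = 2, pretrain_epochs = 20, finetune_epochs = 20,
                       minibatch_size = 32, max_epochs = 5,
                       tol_threshold = 1e-6, knn_k = 10)
  fit <- gdesce_cluster(x, finetune(pretrain_layerwise(x, dims = c(d, 4),
                                                       config = cfg), x, cfg),
                        cfg)
  expect_equal(rowSums(fit$soft), rep(1, 100), tolerance = 1e-9)
  expect_lte(fit$n_epochs, 5L)
  expect_true(all(fit$labels %in% 0:(fit$K - 1)))
})
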