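test_that("library-size scaling matches the 10,000-factor convention", {
  m <- count_matrix(matrix(c(1, 1, 2), 1, 3), "c1", c("g1", "g2", "g3"))
  norm <- suppressWarnings(normalize_counts(m))  # 1 cell: every gene is constant
  # cell total 4 -> scaled values 2500, 2500, 5000 before the log transform
  expect_equal(unname(expm1(norm$log_values[1, ])), c(2500, 2500, 5000))
})

test_that("gene standardization yields mean 0, sd 1 per standardization group", {
  m <- tiny_counts(n = 40, g = 6, seed = 7)
  glob <- normalize_counts(m, by_batch = FALSE)
  expect_lt(max(abs(colMeans(glob$values))), 1e-10)
  expect_lt(max(abs(apply(glob$values, 2, sd) - 1)), 1e-6)

  bb <- normalize_counts(m, by_batch = TRUE)
  for (b in levels(m$batch)) {
    idx <- m$batch == b
    expect_lt(max(abs(colMeans(bb$values[idx, ]))), 1e-10)
    expect_lt(max(abs(apply(bb$values[idx, ], 2, sd) - 1)), 1e-6)
  }
})

test_that("standardization is affinely invertible per gene", {
  m <- tiny_counts(n = 30, g = 5, seed = 11)
  norm <- normalize_counts(m, by_batch = FALSE)
  rec <- sweep(sweep(norm$values, 2, norm$gene_sds[["all"]], "*"),
               2, norm$gene_means[["all"]], "+")
  expect_lt(max(abs(rec - norm$log_values)), 1e-10)
})

test_that("degenerate normalization inputs are handled explicitly", {
  zero_cell <- count_matrix(rbind(c(1, 2), c(0, 0)), c("ok", "empty"), c("g1", "g2"))
  expect_error(normalize_counts(zero_cell), "empty")

  const_gene <- count_matrix(cbind(c(5, 5, 5), c(1, 9, 4)),
                             paste0("c", 1:3), c("flat", "varies"))
  # constant column after library scaling is not exactly constant, so build one
  # that is: identical cells make every gene constant
  all_const <- count_matrix(matrix(3, 4, 2), paste0("c", 1:4), c("g1", "g2"))
  expect_warning(norm <- normalize_counts(all_const), "zero-variance")
  expect_true(all(norm$values == 0))
  expect_false(anyNA(norm$values))
  expect_no_error(normalize_counts(const_gene))
})

test_that("highly variable gene selection ranks by binned dispersion", {
  # flat genes plus one bimodal high-variance gene
  set.seed(3)
  n <- 60
  flat <- matrix(rpois(n * 9, 20), n, 9)
  bimodal <- c(rpois(n / 2, 2), rpois(n / 2, 60))
  m <- count_matrix(cbind(flat, bimodal), paste0("c", 1:n), paste0("g", 1:10))
  norm <- normalize_counts(m, by_batch = FALSE)
  mask <- select_hvg(norm, 1)
  expect_identical(which(mask), 10L)

  # ties broken by gene order when all genes are identical
  same <- count_matrix(matrix(rep(c(3, 8, 1, 6), each = 4), 4, 4),
                       paste0("c", 1:4), paste0("g", 1:4))
  ns <- suppressWarnings(normalize_counts(same, by_batch = FALSE))
  expect_identical(which(select_hvg(ns, 2)), c(1L, 2L))

  expect_identical(select_hvg(norm, 10), rep(TRUE, 10))
  expect_error(select_hvg(norm, 11), "exceeds")
})

test_that("euclidean distance is the plain 2-D formula", {
  expect_identical(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_identical(euclidean_distance(c(2.5, -1), c(2.5, -1)), 0)
  set.seed(1)
  for (i in 1:10) {
    a <- rnorm(2); b <- rnorm(2)
    expect_equal(euclidean_distance(a, b), euclidean_distance(b, a))
  }
})

test_that("grid partitioning assigns every point to exactly one cell", {
  # all points co-located
  pts <- matrix(rep(c(1, 2), each = 10), 10, 2)
  g <- build_grid(pts, cells_per_axis = 4, density_threshold = 5)
  expect_identical(sum(g$counts), 10L)
  expect_identical(sum(g$counts > 0), 1L)
  expect_true(g$dense_mask[g$counts > 0])

  # four corners of the unit square, 2 x 2 grid: one point per cell
  corners <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  g2 <- build_grid(corners, 2, 0)
  expect_identical(sort(g2$counts), c(1L, 1L, 1L, 1L))
  expect_true(all(g2$dense_mask))  # threshold 0: every occupied cell is dense

  set.seed(4)
  rnd <- matrix(rnorm(200), 100, 2)
  g3 <- build_grid(rnd, 7, 2)
  expect_identical(sum(g3$counts), 100L)
  expect_identical(g3$dense_mask, g3$counts > 2)
})

test_that("the grid filter removes exactly the planted straggler", {
  pts <- grid_fixture()
  keep <- remove_outliers(pts, cells_per_axis = 5, density_threshold = 3)
  expect_identical(keep, c(rep(TRUE, 20), FALSE))
})

test_that("a single dense blob passes the filter untouched", {
  blob <- generate_points2d(list(list(center = c(3, 3), count = 200, spread = 0.2)),
                            seed = 5)
  keep <- remove_outliers(blob, 5, 3)
  expect_true(all(keep))
})

test_that("the grid filter is idempotent and permutation-invariant", {
  pts <- grid_fixture()
  keep <- remove_outliers(pts, 5, 3)
  survivors <- pts[keep, , drop = FALSE]
  keep2 <- suppressWarnings(remove_outliers(survivors, 5, 3))
  expect_true(all(keep2))

  set.seed(9)
  perm <- sample(nrow(pts))
  keep_p <- remove_outliers(pts[perm, , drop = FALSE], 5, 3)
  expect_identical(keep_p, keep[perm])
})

test_that("the filter keeps everything when no cell is ever dense", {
  sparse <- rbind(c(0, 0), c(5, 5), c(10, 0), c(0, 10))
  expect_warning(keep <- remove_outliers(sparse, 4, 1), "no dense")
  expect_true(all(keep))
})
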