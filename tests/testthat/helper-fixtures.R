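# Shared fixtures, all built in code.

# tiny deterministic count matrix with batch and truth labels
tiny_counts <- function(n = 6, g = 4, seed = 42) {
  set.seed(seed)
  vals <- matrix(rpois(n * g, lambda = 5), n, g)
  vals[1, ] <- vals[1, ] + 1  # guard against a zero-count cell
  count_matrix(vals,
               cell_ids = paste0("c", seq_len(n)),
               gene_ids = paste0("g", seq_len(g)),
               batch = rep(c("b1", "b2"), length.out = n),
               truth = rep(c("t1", "t2"), each = n / 2))
}

# two well-separated Gaussian blobs in a d-dimensional feature space
two_blobs <- function(n_per = 100, d = 16, sep = 5, sigma = 0.5, seed = 2) {
  set.seed(seed)
  rbind(matrix(rnorm(n_per * d, 0, sigma), n_per),
        matrix(rnorm(n_per * d, sep, sigma), n_per, d))
}

# 21-point grid-filter fixture: a packed blob of 20 plus one far straggler
grid_fixture <- function() {
  generate_points2d(list(list(center = c(0, 0), count = 20, spread = 0.5)),
                    stragglers = matrix(c(10, 10), 1), seed = 1)
}

# naive double-loop references used as independent oracles
naive_soft_assign <- function(f, centroids, alpha) {
  n <- nrow(f); K <- nrow(centroids)
  s <- matrix(0, n, K)
  for (i in seq_len(n)) {
    for (j in seq_len(K))
      s[i, j] <- 1 / (1 + sum((f[i, ] - centroids[j, ])^2) / alpha)
    s[i, ] <- s[i, ] / sum(s[i, ])
  }
  s
}

naive_target <- function(s) {
  n <- nrow(s); K <- ncol(s)
  fr <- colSums(s)
  t <- matrix(0, n, K)
  for (i in seq_len(n)) {
    w <- numeric(K)
    for (j in seq_len(K)) w[j] <- s[i, j]^2 / fr[j]
    t[i, ] <- w / sum(w)
  }
  t
}

naive_loss <- function(s, t) {
  tot <- 0
  for (i in seq_len(nrow(s))) for (j in seq_len(ncol(s))) {
    if (t[i, j] > 0)
      tot <- tot + t[i, j]^2 * log(t[i, j] / max(s[i, j], 1e-12)^2)
  }
  tot
}

naive_batch_kl <- function(batch, clusters) {
  batch <- as.character(batch); clusters <- as.character(clusters)
  keep <- clusters != "-1"
  batch <- batch[keep]; clusters <- clusters[keep]
  bl <- sort(unique(batch))
  p <- vapply(bl, function(b) mean(batch == b), numeric(1))
  cl <- sort(unique(clusters))
  kl <- numeric(length(cl)); sz <- numeric(length(cl))
  for (ci in seq_along(cl)) {
    idx <- clusters == cl[ci]
    q <- vapply(bl, function(b) mean(batch[idx] == b), numeric(1))
    q <- pmax(q, 1e-10)
    kl[ci] <- sum(p * log(p / q))
    sz[ci] <- sum(idx)
  }
  sum(kl * sz) / sum(sz)
}

naive_entropy <- function(p) {
  e <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) e[i] <- e[i] - p[i, j] * log(p[i, j])
  e
}

# central finite differences of assignment_loss wrt f and centroids
fd_gradients <- function(f, centroids, t, alpha, h = 1e-6) {
  loss_at <- function(ff, cc) assignment_loss(soft_assign(ff, cc, alpha), t)
  d_f <- f * 0
  for (i in seq_len(nrow(f))) for (j in seq_len(ncol(f))) {
    fp <- f; fp[i, j] <- fp[i, j] + h
    fm <- f; fm[i, j] <- fm[i, j] - h
    d_f[i, j] <- (loss_at(fp, centroids) - loss_at(fm, centroids)) / (2 * h)
  }
  d_c <- centroids * 0
  for (i in seq_len(nrow(centroids))) for (j in seq_len(ncol(centroids))) {
    cp <- centroids; cp[i, j] <- cp[i, j] + h
    cm <- centroids; cm[i, j] <- cm[i, j] - h
    d_c[i, j] <- (loss_at(f, cp) - loss_at(f, cm)) / (2 * h)
  }
  list(d_f = d_f, d_centroids = d_c)
}
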