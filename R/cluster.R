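# Iterative deep-embedding clustering: Student's-t soft assignment, sharpened
# auxiliary target distribution, the squared-target-weighted KL objective, its
# analytic gradients, Louvain centroid seeding, and the self-training loop
# that jointly refines encoder weights and centroids by minibatch SGD.

squared_distances <- function(f, centroids) {
  # n x K matrix of ||f_i - k_j||^2
  d2 <- outer(rowSums(f^2), rowSums(centroids^2), "+") - 2 * f %*% t(centroids)
  pmax(d2, 0)
}

tkernel <- function(f, centroids, alpha) {
  1 / (1 + squared_distances(f, centroids) / alpha)
}

#' Soft cluster assignment under a Student's-t kernel
#'
#' Similarity of each cell's feature-space embedding to each centroid,
#' `(1 + ||f_i - k_j||^2 / alpha)^(-1)`, normalized per cell so each row is a
#' probability distribution over clusters.
#'
#' @param f n x d feature matrix.
#' @param centroids K x d centroid matrix.
#' @param alpha Degrees of freedom of the kernel (> 0); default 1.
#' @return n x K row-stochastic matrix of soft assignments.
#' @export
soft_assign <- function(f, centroids, alpha = 1) {
  stopifnot(alpha > 0)
  f <- as.matrix(f)
  centroids <- as.matrix(centroids)
  stopifnot(ncol(f) == ncol(centroids))
  u <- tkernel(f, centroids, alpha)
  u / rowSums(u)
}

#' Auxiliary target distribution
#'
#' Sharpens a soft assignment by squaring it and dividing by per-cluster soft
#' frequency, then renormalizing each row:
#' `t_ij = (s_ij^2 / sum_i s_ij) / sum_j (s_ij^2 / sum_i s_ij)`.
#' High-confidence cells are up-weighted and large clusters are discounted,
#' which is what drives the self-training iteration toward purer clusters.
#'
#' @param s n x K row-stochastic soft assignment matrix.
#' @return n x K row-stochastic target matrix.
#' @export
target_distribution <- function(s) {
  s <- as.matrix(s)
  w <- sweep(s^2, 2, colSums(s), "/")
  w / rowSums(w)
}

#' Clustering objective: squared-target-weighted KL divergence
#'
#' The loss driving the iterative optimization:
#' `sum_ij t_ij^2 * log(t_ij / s_ij^2)`. Squaring the target weight amplifies
#' the influence of confidently assigned cells (a label-entropy-motivated
#' reweighting of the classic KL self-training objective); squaring `s` inside
#' the log steepens the penalty on assignments that disagree with the target.
#' Terms with `t_ij = 0` contribute 0; `s` is floored at 1e-12 inside the log.
#'
#' @param s n x K soft assignment matrix.
#' @param t n x K target distribution matrix.
#' @return Scalar loss (unbounded; 0 when `t_ij = s_ij^2` elementwise).
#' @export
assignment_loss <- function(s, t) {
  s <- as.matrix(s); t <- as.matrix(t)
  stopifnot(identical(dim(s), dim(t)))
  s <- pmax(s, 1e-12)
  terms <- ifelse(t > 0, t^2 * (log(t) - 2 * log(s)), 0)
  sum(terms)
}

#' Analytic gradients of the clustering objective
#'
#' Gradients of [assignment_loss()] with respect to the feature embeddings and
#' the centroids, treating the target distribution as a constant (the
#' self-training convention). Writing `u_ij` for the unnormalized kernel and
#' `T_i = sum_j t_ij^2`, the chain rule through the row normalization gives
#' \deqn{\partial L/\partial f_i = (4/\alpha) \sum_j u_{ij} (t_{ij}^2 - T_i s_{ij}) (f_i - k_j)}
#' and the negated per-column sums for the centroids, so the total gradient is
#' translation-invariant.
#'
#' @param f n x d feature matrix.
#' @param centroids K x d centroid matrix.
#' @param t n x K target distribution (held fixed).
#' @param alpha Kernel degrees of freedom.
#' @return List with `d_f` (n x d) and `d_centroids` (K x d).
#' @export
assignment_gradients <- function(f, centroids, t, alpha = 1) {
  f <- as.matrix(f); centroids <- as.matrix(centroids); t <- as.matrix(t)
  u <- tkernel(f, centroids, alpha)
  s <- u / rowSums(u)
  w <- u * (t^2 - rowSums(t^2) * s)
  d_f <- (4 / alpha) * (rowSums(w) * f - w %*% centroids)
  d_c <- -(4 / alpha) * (crossprod(w, f) - colSums(w) * centroids)
  list(d_f = d_f, d_centroids = d_c)
}

#' Fraction of cells whose hard label changed
#'
#' The stopping statistic of the iterative clustering loop:
#' `#(curr != prev) / n`.
#'
#' @param curr,prev Equal-length label vectors from consecutive epochs.
#' @return Real in \[0, 1\].
#' @export
compute_tolerance <- function(curr, prev) {
  if (length(curr) != length(prev))
    stop("label vectors have different lengths (", length(curr), " vs ",
         length(prev), ")")
  mean(curr != prev)
}

#' Seed centroids by Louvain community detection
#'
#' Builds a Euclidean k-nearest-neighbour graph on the feature matrix,
#' weights each edge by the Jaccard overlap of the two endpoints'
#' neighbourhoods (the shared-nearest-neighbour graph standard in single-cell
#' practice, pruned at weight 1/15), and runs Louvain modularity optimization
#' at the given resolution. The number of communities becomes the cluster
#' count K and each centroid is the mean feature vector of its community.
#'
#' @param f n x d feature matrix.
#' @param knn_k Neighbourhood size; must be < n.
#' @param resolution Louvain resolution parameter.
#' @param seed Integer seed (Louvain visits vertices in random order).
#' @return List with `centroids` (K x d), `labels` (integer 1..K per cell),
#'   and `K`.
#' @export
init_centroids_louvain <- function(f, knn_k = 15, resolution = 1.0, seed = 0L) {
  f <- as.matrix(f)
  n <- nrow(f)
  if (n <= knn_k) stop("need more cells (", n, ") than knn_k (", knn_k, ")")
  d2 <- squared_distances(f, f)
  diag(d2) <- Inf
  nbr <- t(apply(d2, 1, function(row) order(row)[seq_len(knn_k)]))
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = knn_k),
                              j = as.vector(t(nbr)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)          # shared-neighbour counts
  jac <- shared / (2 * knn_k - shared)       # Jaccard overlap of kNN sets
  jac@x[jac@x < 1 / 15] <- 0                 # prune weak links
  jac <- Matrix::drop0(jac)
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(derive_seed(seed, "louvain"))
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- as.integer(igraph::membership(comm))
  K <- max(labels)
  if (K == 1) warning("Louvain found a single community (K = 1)")
  centroids <- rowsum(f, labels) / as.vector(table(labels))
  list(centroids = unname(centroids), labels = labels, K = K)
}

#' Iterative clustering of encoded cells
#'
#' The self-training loop. Each epoch: (1) the target distribution is
#' recomputed from the current soft assignment of all cells (the only point
#' where the target moves); (2) minibatch SGD jointly updates encoder weights
#' (gradients backpropagated through the encoder) and centroids on the
#' [assignment_loss()] with the target held fixed; (3) hard labels are
#' recomputed and the loop stops when the fraction of cells that changed label
#' falls below `config$tol_threshold`, or at `config$max_epochs`.
#'
#' @param x Cells x features matrix the model was trained on (standardized
#'   HVG expression of the retained cells).
#' @param model An `encoder_model` (pretrained and fine-tuned).
#' @param config A [gdesce_config].
#' @param init Optional initialization as returned by
#'   [init_centroids_louvain()]; computed from it when `NULL`.
#' @return A list of class `gdesce_cluster_fit`: `labels` (integer 0..K-1),
#'   `soft` (n x K), `centroids`, `K`, `loss_trace`, `tol_trace`,
#'   `entropy_trace` (mean label entropy at each target refresh), `n_epochs`,
#'   `init_labels`, and the updated `model`.
#' @export
gdesce_cluster <- function(x, model, config = gdesce_config(), init = NULL) {
  x <- as.matrix(x)
  stopifnot(inherits(model, "encoder_model"))
  alpha <- config$alpha
  f <- encode(model, x)
  if (is.null(init))
    init <- init_centroids_louvain(f, config$knn_k, config$louvain_resolution,
                                   config$seed)
  centroids <- as.matrix(init$centroids)
  K <- nrow(centroids)
  n <- nrow(x)
  if (n < K) stop("fewer cells than clusters after initialization")

  s <- soft_assign(f, centroids, alpha)
  # the first tolerance check compares against the initialization labels
  prev_labels <- init$labels
  loss_trace <- numeric(0)
  tol_trace <- numeric(0)
  entropy_trace <- numeric(0)

  vel_enc <- zero_like(model$enc)
  vel_c <- centroids * 0
  set.seed(derive_seed(config$seed, "cluster"))

  n_epochs <- 0L
  for (ep in seq_len(config$max_epochs)) {
    n_epochs <- ep
    # epoch boundary: refresh the auxiliary target from the full data
    f <- encode(model, x)
    s <- soft_assign(f, centroids, alpha)
    t_full <- target_distribution(s)
    entropy_trace <- c(entropy_trace, mean(label_entropy(t_full)$entropy))

    ord <- sample.int(n)
    for (start in seq(1, n, by = config$minibatch_size)) {
      idx <- ord[start:min(start + config$minibatch_size - 1, n)]
      a <- stack_forward(model$enc, model$enc_acts, x[idx, , drop = FALSE])
      fb <- a[[length(a)]]
      gr <- assignment_gradients(fb, centroids, t_full[idx, , drop = FALSE], alpha)
      nb <- length(idx)
      bw <- stack_backward(model$enc, model$enc_acts, a, gr$d_f / nb)
      upd <- sgd_step(model$enc, bw$grads, vel_enc,
                      config$learning_rate, config$momentum)
      model$enc <- upd$layers
      vel_enc <- upd$vel
      vel_c <- config$momentum * vel_c - config$learning_rate * gr$d_centroids / nb
      centroids <- centroids + vel_c
    }

    f <- encode(model, x)
    s <- soft_assign(f, centroids, alpha)
    ep_loss <- assignment_loss(s, t_full)
    if (!is.finite(ep_loss))
      stop("clustering loss became non-finite at epoch ", ep,
           " (learning rate too large?)")
    loss_trace <- c(loss_trace, ep_loss)
    labels <- max.col(s)
    tol <- compute_tolerance(labels, prev_labels)
    tol_trace <- c(tol_trace, tol)
    prev_labels <- labels
    if (tol < config$tol_threshold) break
  }

  structure(list(labels = prev_labels - 1L, soft = s, centroids = centroids,
                 K = K, loss_trace = loss_trace, tol_trace = tol_trace,
                 entropy_trace = entropy_trace, n_epochs = n_epochs,
                 init_labels = init$labels - 1L, model = model),
            class = "gdesce_cluster_fit")
}

#' @export
print.gdesce_cluster_fit <- function(x, ...) {
  cat(sprintf("<gdesce_cluster_fit> %d cells, K = %d, %d epoch(s), final tol %.4g\n",
              length(x$labels), x$K, x$n_epochs,
              if (length(x$tol_trace)) x$tol_trace[length(x$tol_trace)] else NA))
  invisible(x)
}
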