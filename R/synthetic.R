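# Synthetic single-cell count generator: negative-binomial counts over planted
# cluster expression programs, additive log-space batch offsets smaller than
# the biological separation, and diffuse outlier cells placed far from every
# cluster mean inside the span of the cluster marker directions (so they stay
# visible to a 2-D embedding).

#' Configuration for the synthetic single-cell generator
#'
#' Defaults describe the study conditions the rest of the package is tested
#' under: 2000 cells, 500 genes, 3 clusters, 2 batches, batch shifts well
#' below the biological separation, and 5% planted outliers.
#'
#' @param n_cells,n_genes,n_clusters,n_batches Problem dimensions.
#' @param cluster_sep Euclidean distance in log-expression space between every
#'   pair of cluster mean programs. Each cluster up-regulates its own disjoint
#'   block of `marker_frac * n_genes` marker genes; the per-gene log fold
#'   change is derived from `cluster_sep`.
#' @param batch_shift Euclidean norm in log space of the additive offset each
#'   batch applies to a random 10% subset of genes. Must stay below
#'   `cluster_sep` (technical variation smaller than biological variation —
#'   the validity regime of the clustering model) unless
#'   `enforce_regime = FALSE`.
#' @param outlier_frac Fraction of cells drawn from a diffuse background far
#'   from every cluster mean (placed at radius 6-8x `cluster_sep`, hence more
#'   than 5x `cluster_sep` from each cluster mean). In \[0, 0.2\].
#' @param library_size Mean per-cell total count; per-cell sizes are
#'   log-normal around it.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param marker_frac Fraction of genes in each cluster's marker block.
#' @param cluster_props Optional cluster mixing proportions (must sum to 1).
#' @param enforce_regime Enforce `batch_shift < cluster_sep`.
#' @param seed Integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cells = 2000, n_genes = 500, n_clusters = 3,
                             n_batches = 2, cluster_sep = 6, batch_shift = 1.5,
                             outlier_frac = 0.05, library_size = 2500,
                             dispersion = 0.25, marker_frac = 0.05,
                             cluster_props = NULL, enforce_regime = TRUE,
                             seed = 0L) {
  stopifnot(n_cells >= 1, n_genes >= 1, n_clusters >= 1, n_batches >= 1,
            cluster_sep > 0, batch_shift >= 0,
            outlier_frac >= 0, outlier_frac <= 0.2,
            library_size > 0, dispersion > 0,
            marker_frac > 0, marker_frac * n_genes * n_clusters <= n_genes)
  if (enforce_regime && batch_shift >= cluster_sep)
    stop("batch_shift must be below cluster_sep (technical < biological variation)")
  if (is.null(cluster_props)) cluster_props <- rep(1 / n_clusters, n_clusters)
  if (length(cluster_props) != n_clusters || abs(sum(cluster_props) - 1) > 1e-8)
    stop("cluster_props must have one entry per cluster and sum to 1")
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_clusters = as.integer(n_clusters),
                 n_batches = as.integer(n_batches),
                 cluster_sep = cluster_sep, batch_shift = batch_shift,
                 outlier_frac = outlier_frac,
                 library_size = library_size, dispersion = dispersion,
                 marker_frac = marker_frac, cluster_props = cluster_props,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic single-cell count matrix
#'
#' Draws per-cluster mean log-expression programs over disjoint marker-gene
#' blocks with pairwise distance `cluster_sep`, adds per-batch log offsets of
#' norm `batch_shift` on a random gene subset, converts each cell's log
#' program to relative expression by softmax, and samples counts from a
#' negative binomial at the cell's library size. Outlier cells replace their
#' cluster program with a point at radius 6-8x `cluster_sep` inside the span
#' of the marker directions; their truth label is `"outlier"`.
#'
#' @param config A [synthetic_config].
#' @return List with `counts` (a [count_matrix] carrying `batch` and `truth`
#'   labels), `outlier_mask` (logical per cell), `cluster_means` (K x genes
#'   log-space programs), and `batch_offsets`.
#' @export
generate_cells <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, "generate"))
  n <- config$n_cells; g <- config$n_genes; K <- config$n_clusters

  # baseline abundance profile shared by all cells
  base <- rnorm(g, mean = 0, sd = 0.5)

  # disjoint marker blocks: pairwise program distance = cluster_sep exactly
  m <- max(1L, as.integer(round(config$marker_frac * g)))
  lfc <- config$cluster_sep / sqrt(2 * m)
  marker_idx <- matrix(sample.int(g, m * K), nrow = K)
  delta <- matrix(0, K, g)
  for (k in seq_len(K)) delta[k, marker_idx[k, ]] <- lfc

  # per-batch additive offsets on a random 10% gene subset, norm = batch_shift
  B <- config$n_batches
  batch_offsets <- matrix(0, B, g)
  if (B > 1 && config$batch_shift > 0) {
    mb <- max(1L, as.integer(round(0.1 * g)))
    for (b in seq_len(B)) {
      idx <- sample.int(g, mb)
      batch_offsets[b, idx] <- sample(c(-1, 1), mb, replace = TRUE) *
        config$batch_shift / sqrt(mb)
    }
  }

  truth_k <- sample.int(K, n, replace = TRUE, prob = config$cluster_props)
  batch <- sample.int(B, n, replace = TRUE)
  n_out <- as.integer(round(config$outlier_frac * n))
  outlier_mask <- logical(n)
  if (n_out > 0) outlier_mask[sample.int(n, n_out)] <- TRUE

  # outlier programs: random point in the between-cluster plane (the span of
  # the centered cluster programs) at radius 6-8x cluster_sep from the
  # program centroid, hence > 5x cluster_sep from every cluster mean. Placing
  # them in this plane keeps them visible to any variance-based 2-D embedding
  # of the data, which is where the grid filter operates.
  eta <- matrix(rep(base, each = n), n, g) + delta[truth_k, , drop = FALSE]
  if (any(outlier_mask)) {
    ctr <- colMeans(delta)
    centered <- sweep(delta, 2, ctr)
    basis <- svd(t(centered))$u            # g x r orthonormal, r = K-1 (or K)
    basis <- basis[, seq_len(max(1, min(K - 1, ncol(basis)))), drop = FALSE]
    r_dim <- ncol(basis)
    for (i in which(outlier_mask)) {
      wdir <- rnorm(r_dim)
      wdir <- wdir / sqrt(sum(wdir^2))
      r <- runif(1, 6, 8) * config$cluster_sep
      # diffuse per-gene jitter so the background is a cloud, not a thin
      # shell; it is orthogonal-on-average to the cluster plane, so it adds
      # distance from the cluster means rather than removing any
      eta[i, ] <- base + ctr + r * as.vector(basis %*% wdir) + rnorm(g, 0, 1)
    }
  }
  eta <- eta + batch_offsets[batch, , drop = FALSE]

  # per-cell library sizes, log-normal with mean = library_size
  sdlog <- 0.25
  lib <- exp(rnorm(n, log(config$library_size) - sdlog^2 / 2, sdlog))

  pi_mat <- exp(eta)
  pi_mat <- pi_mat / rowSums(pi_mat)
  mu <- pi_mat * lib
  counts <- matrix(rnbinom(n * g, mu = mu, size = 1 / config$dispersion), n, g)

  truth <- ifelse(outlier_mask, "outlier", paste0("cluster", truth_k))
  cm <- count_matrix(counts,
                     cell_ids = sprintf("cell%04d", seq_len(n)),
                     gene_ids = sprintf("gene%03d", seq_len(g)),
                     batch = paste0("batch", batch),
                     truth = truth)
  list(counts = cm, outlier_mask = outlier_mask,
       cluster_means = delta, batch_offsets = batch_offsets)
}

#' Deterministic 2-D point clouds for grid-filter tests
#'
#' Builds hand-checkable point sets from blob specifications plus explicit
#' straggler points. With `spread = 0` all blob points sit exactly at the
#' center; with positive spread they are jittered uniformly in a square of
#' half-width `spread` (seeded, hence reproducible).
#'
#' @param blobs List of lists with fields `center` (length-2), `count`
#'   (integer), `spread` (nonnegative half-width).
#' @param stragglers Optional n x 2 matrix (or list of length-2 points) of
#'   isolated points appended after the blobs.
#' @param seed Integer seed for the jitter.
#' @return n x 2 coordinate matrix; blob points first, stragglers last.
#' @export
generate_points2d <- function(blobs, stragglers = NULL, seed = 0L) {
  stopifnot(length(blobs) >= 1)
  set.seed(derive_seed(seed, "points2d"))
  pts <- do.call(rbind, lapply(blobs, function(b) {
    stopifnot(length(b$center) == 2, b$count >= 1, b$spread >= 0)
    jitter_x <- runif(b$count, -b$spread, b$spread)
    jitter_y <- runif(b$count, -b$spread, b$spread)
    cbind(b$center[1] + jitter_x, b$center[2] + jitter_y)
  }))
  if (!is.null(stragglers)) {
    if (is.list(stragglers) && !is.matrix(stragglers))
      stragglers <- do.call(rbind, stragglers)
    pts <- rbind(pts, stragglers)
  }
  colnames(pts) <- c("x", "y")
  pts
}
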