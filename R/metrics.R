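# Evaluation metrics: adjusted Rand index from the exact contingency table,
# a KL-divergence score of batch mixing across clusters, and per-cell label
# entropy of the assignment probabilities. Natural logarithms throughout.

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement computed from the contingency table `n_uv` with
#' marginals `a_u`, `b_v` and pair counts `choose(., 2)`:
#' \deqn{ARI = \frac{\sum_{uv} \binom{n_{uv}}{2} - E}{\tfrac12[\sum_u \binom{a_u}{2} + \sum_v \binom{b_v}{2}] - E},\quad E = \frac{\sum_u \binom{a_u}{2} \sum_v \binom{b_v}{2}}{\binom{n}{2}}.}
#' Cells labeled -1 in either vector (outliers removed before clustering) are
#' excluded pairwise before the table is built. Pair counts are integers
#' represented exactly in doubles up to n ~ 9e7, so no rounding occurs at
#' single-cell scale.
#'
#' @param truth,pred Equal-length label vectors (any atomic type; -1 means
#'   "excluded").
#' @return ARI in \[-1, 1\]; 1 for identical partitions up to relabeling.
#' @export
adjusted_rand_index <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("label vectors differ in length")
  drop <- as.character(truth) == "-1" | as.character(pred) == "-1"
  truth <- truth[!drop]
  pred <- pred[!drop]
  n <- length(truth)
  if (n < 2) stop("need at least 2 cells after excluding removed ones")
  tab <- table(truth, pred)
  sum_nuv <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_nuv - expected) / (max_index - expected)
}

#' KL-divergence score of batch mixing across clusters
#'
#' For global batch proportions `p_b` and within-cluster batch proportions
#' `q_b`, each cluster scores `KL(p || q) = sum_b p_b log(p_b / q_b)` (with `q`
#' floored at 1e-10); the overall score is the cluster-size-weighted mean. A
#' perfectly batch-mixed clustering — every cluster reproducing the global
#' batch composition — scores 0; larger values mean clusters are batch-biased.
#' Cells labeled -1 are excluded.
#'
#' @param batch Per-cell batch labels.
#' @param clusters Per-cell cluster labels (-1 = excluded).
#' @return List with `overall` (weighted mean KL) and `per_cluster` (named
#'   vector of per-cluster KL values).
#' @export
batch_kl <- function(batch, clusters) {
  if (length(batch) != length(clusters)) stop("label vectors differ in length")
  keep <- !(as.character(clusters) == "-1")
  batch <- factor(batch[keep])
  clusters <- clusters[keep]
  if (length(batch) == 0) stop("no cells left after exclusion")
  p <- as.vector(table(batch)) / length(batch)
  kl <- vapply(split(seq_along(clusters), clusters), function(idx) {
    q <- as.vector(table(batch[idx])) / length(idx)
    q <- pmax(q, 1e-10)
    sum(p * log(p / q))
  }, numeric(1))
  sizes <- as.vector(table(clusters))
  list(overall = sum(kl * sizes) / sum(sizes), per_cluster = kl)
}

#' Per-cell label entropy of assignment probabilities
#'
#' Shannon entropy `E_i = -sum_j P_ij log P_ij` of each cell's cluster
#' assignment distribution, with the `0 log 0 = 0` convention. By default the
#' probabilities are the auxiliary target distribution; the soft assignment
#' can be passed instead. Low entropy means confident assignment; the
#' self-training iteration is expected to drive the mean down.
#'
#' @param p n x K row-stochastic matrix (target distribution or soft
#'   assignment).
#' @return List with `entropy` (per-cell vector, each in \[0, log K\]) and
#'   `mean`.
#' @export
label_entropy <- function(p) {
  p <- as.matrix(p)
  terms <- ifelse(p > 0, p * log(p), 0)
  e <- -rowSums(terms)
  list(entropy = e, mean = mean(e))
}

#' Assemble a metrics report for a clustering result
#'
#' Computes every metric the available annotations support: ARI when truth
#' labels exist, the batch-KL score when batch labels exist, and label entropy
#' always.
#'
#' @param fit A `gdesce_fit` (pipeline result) or `gdesce_cluster_fit`.
#' @param truth Optional per-cell truth labels (defaults to those carried by
#'   the pipeline result).
#' @param batch Optional per-cell batch labels (same default).
#' @return A list of class `metrics_report`:
#'   `ari`, `batch_kl`, `per_cluster_batch_kl`, `mean_entropy`,
#'   `per_cell_entropy`, `n_cells`, `n_outliers_removed`, `K`, `n_epochs`.
#' @export
metrics_report <- function(fit, truth = NULL, batch = NULL) {
  labels <- fit$labels
  if (is.null(truth) && !is.null(fit$truth)) truth <- fit$truth
  if (is.null(batch) && !is.null(fit$batch)) batch <- fit$batch
  ari <- if (!is.null(truth)) adjusted_rand_index(truth, labels) else NULL
  bk <- if (!is.null(batch)) batch_kl(batch, labels) else NULL
  ent <- label_entropy(target_distribution(fit$soft))
  structure(list(
    ari = ari,
    batch_kl = if (!is.null(bk)) bk$overall else NULL,
    per_cluster_batch_kl = if (!is.null(bk)) bk$per_cluster else NULL,
    mean_entropy = ent$mean,
    per_cell_entropy = ent$entropy,
    n_cells = length(labels),
    n_outliers_removed = sum(labels == -1L),
    K = fit$K,
    n_epochs = fit$n_epochs
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  if (!is.null(x$ari)) cat(sprintf("  ARI            %.4f\n", x$ari))
  if (!is.null(x$batch_kl)) cat(sprintf("  batch KL       %.4f\n", x$batch_kl))
  cat(sprintf("  mean entropy   %.4f\n", x$mean_entropy))
  cat(sprintf("  cells %d (outliers removed %d), K = %d, epochs = %d\n",
              x$n_cells, x$n_outliers_removed, x$K, x$n_epochs))
  invisible(x)
}
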