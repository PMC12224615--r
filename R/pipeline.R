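#' Run the full grid-filtered deep-embedding clustering pipeline
#'
#' End-to-end driver: normalize counts (library-size scaling, log transform,
#' per-gene — optionally per-batch — standardization), select highly variable
#' genes, remove grid-density outliers in a 2-D embedding, pretrain and
#' fine-tune the stacked autoencoder on the retained cells, seed centroids by
#' Louvain on the bottleneck features, and run the iterative self-training
#' optimization.
#'
#' Cells removed by the grid filter are reported with label -1 so every input
#' cell is accounted for in the output.
#'
#' @param m A [count_matrix].
#' @param config A [gdesce_config].
#' @param embedding Optional n x 2 matrix used for the grid filter when
#'   `config$grid_embedding == "external"`; ignored otherwise (the first two
#'   principal components of the standardized HVG matrix are used).
#' @return A list of class `gdesce_fit`: `labels` (per input cell, -1 for
#'   removed outliers), `soft` (retained cells x K), `centroids`, `K`,
#'   `keep_mask`, `init_labels_full` (Louvain seed labels, -1 for removed),
#'   `loss_trace`, `tol_trace`, `entropy_trace`, `n_epochs`, `cell_ids`,
#'   `batch`, `truth`, `hvg_mask`, `embedding2d`, `model`, `config`.
#' @export
gdesce <- function(m, config = gdesce_config(), embedding = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  norm <- normalize_counts(m, by_batch = config$by_batch)
  n_hvg <- min(config$n_hvg, ncol(norm$values))
  hvg <- select_hvg(norm, n_hvg)
  x_all <- norm$values[, hvg, drop = FALSE]

  coords <- if (config$grid_embedding == "external") {
    if (is.null(embedding)) stop("grid_embedding = 'external' needs an embedding")
    as.matrix(embedding)
  } else {
    pca_embed2(x_all)
  }
  keep <- if (config$grid_filter) {
    remove_outliers(coords, config$grid_cells_per_axis, config$density_threshold)
  } else {
    rep(TRUE, nrow(x_all))
  }
  x <- x_all[keep, , drop = FALSE]

  model <- pretrain_layerwise(x, dims = NULL, config = config)
  model <- finetune(model, x, config)
  cfit <- gdesce_cluster(x, model, config)

  labels_full <- rep(-1L, nrow(x_all))
  labels_full[keep] <- cfit$labels
  init_full <- rep(-1L, nrow(x_all))
  init_full[keep] <- cfit$init_labels

  structure(list(labels = labels_full, soft = cfit$soft,
                 centroids = cfit$centroids, K = cfit$K,
                 keep_mask = keep, init_labels_full = init_full,
                 loss_trace = cfit$loss_trace, tol_trace = cfit$tol_trace,
                 entropy_trace = cfit$entropy_trace, n_epochs = cfit$n_epochs,
                 cell_ids = m$cell_ids, batch = m$batch, truth = m$truth,
                 hvg_mask = hvg, embedding2d = coords, model = cfit$model,
                 config = config),
            class = "gdesce_fit")
}

#' @export
print.gdesce_fit <- function(x, ...) {
  cat(sprintf(
    "<gdesce_fit> %d cells (%d removed as outliers), K = %d, %d epoch(s)\n",
    length(x$labels), sum(!x$keep_mask), x$K, x$n_epochs))
  invisible(x)
}

#' Tidy per-cell results of a pipeline fit
#'
#' One row per input cell: id, cluster label (-1 for cells removed by the grid
#' filter), whether the cell was kept, the 2-D embedding used by the grid
#' filter, the assignment probability of the chosen cluster, and any batch or
#' truth annotation.
#'
#' @param x A `gdesce_fit`.
#' @param ... Unused.
#' @return A tibble with columns `cell_id`, `cluster`, `kept`, `x`, `y`,
#'   `prob`, and optionally `batch`, `truth`.
#' @method tidy gdesce_fit
#' @export
tidy.gdesce_fit <- function(x, ...) {
  prob <- rep(NA_real_, length(x$labels))
  prob[x$keep_mask] <- x$soft[cbind(seq_len(nrow(x$soft)),
                                    max.col(x$soft))]
  coord_x <- x$embedding2d[, 1]
  coord_y <- x$embedding2d[, 2]
  out <- tibble::tibble(
    cell_id = x$cell_ids,
    cluster = x$labels,
    kept = x$keep_mask,
    x = coord_x,
    y = coord_y,
    prob = prob
  )
  if (!is.null(x$batch)) out$batch <- x$batch
  if (!is.null(x$truth)) out$truth <- x$truth
  out
}

#' One-row summary of a pipeline fit
#'
#' @param x A `gdesce_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_cells`, `n_outliers_removed`, `K`, `n_epochs`,
#'   `final_loss`, `final_tol`, `mean_entropy`.
#' @export
glance.gdesce_fit <- function(x, ...) {
  tibble::tibble(
    n_cells = length(x$labels),
    n_outliers_removed = sum(!x$keep_mask),
    K = x$K,
    n_epochs = x$n_epochs,
    final_loss = if (length(x$loss_trace)) x$loss_trace[x$n_epochs] else NA_real_,
    final_tol = if (length(x$tol_trace)) x$tol_trace[x$n_epochs] else NA_real_,
    mean_entropy = if (length(x$entropy_trace))
      x$entropy_trace[length(x$entropy_trace)] else NA_real_
  )
}

#' Plot a pipeline fit in its 2-D embedding
#'
#' Scatter of the grid-filter embedding colored by cluster; removed cells are
#' drawn as grey crosses.
#'
#' @param object A `gdesce_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gdesce_fit
#' @export
autoplot.gdesce_fit <- function(object, ...) {
  df <- tidy.gdesce_fit(object)
  df$cluster <- factor(df$cluster)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(data = df[!df$kept, ], colour = "grey60", shape = 4) +
    ggplot2::geom_point(data = df[df$kept, ],
                        ggplot2::aes(colour = .data$cluster), size = 0.8) +
    ggplot2::labs(x = "dim 1", y = "dim 2", colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot per-epoch optimization traces
#'
#' Loss, label-change tolerance and mean label entropy against epoch.
#'
#' @param fit A `gdesce_fit` or `gdesce_cluster_fit`.
#' @return A ggplot object (faceted by trace).
#' @export
plot_traces <- function(fit) {
  ep <- seq_along(fit$loss_trace)
  df <- rbind(
    data.frame(epoch = ep, value = fit$loss_trace, trace = "loss"),
    data.frame(epoch = ep, value = fit$tol_trace, trace = "tolerance"),
    data.frame(epoch = seq_along(fit$entropy_trace),
               value = fit$entropy_trace, trace = "mean entropy")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~trace, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
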