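#' Run configuration for the clustering pipeline
#'
#' Collects every tunable parameter of the pipeline in one validated list.
#' All randomness in a run flows from `seed`: each stochastic stage (weight
#' initialization, minibatch shuffling, Louvain, the synthetic generator)
#' derives its own child seed from it, so a run is reproducible end to end.
#'
#' @param n_hvg Number of highly variable genes to keep (capped at the gene
#'   count of the input).
#' @param grid_cells_per_axis Grid resolution per axis for the density-based
#'   outlier filter; the lattice has `grid_cells_per_axis^2` cells.
#' @param density_threshold Grid occupancy above which a grid cell counts as
#'   dense; points in cells at or below it are outlier candidates.
#' @param grid_embedding Either `"pca2"` (first two principal components of the
#'   standardized HVG matrix) or `"external"` (a user-supplied n x 2 matrix
#'   passed to the pipeline).
#' @param encoder_dims Integer vector of hidden-layer widths ending in the
#'   bottleneck size, excluding the input width. `NULL` picks
#'   `c(64, 32)` for 1000 cells or more and `c(32, 16)` below.
#' @param alpha Degrees of freedom of the Student's-t kernel used for soft
#'   assignment; 1 by default.
#' @param learning_rate SGD step size for autoencoder training and the
#'   clustering phase.
#' @param momentum SGD momentum coefficient (0 disables momentum).
#' @param minibatch_size Rows per SGD minibatch.
#' @param pretrain_epochs Epochs per greedy layer-wise pretraining stage.
#' @param finetune_epochs Epochs of end-to-end reconstruction fine-tuning.
#' @param tol_threshold Stopping threshold on the fraction of cells whose hard
#'   label changed between consecutive epochs; must lie in (0, 1). Default
#'   0.005.
#' @param max_epochs Hard cap on clustering epochs.
#' @param louvain_resolution Resolution of Louvain community detection used to
#'   seed centroids.
#' @param knn_k Neighbourhood size of the kNN graph Louvain runs on.
#' @param by_batch Standardize genes within each batch rather than globally.
#' @param grid_filter Apply the grid-density outlier filter before clustering.
#' @param seed Root integer seed.
#'
#' @return An object of class `gdesce_config` (a named list).
#' @export
gdesce_config <- function(n_hvg = 3000,
                          grid_cells_per_axis = 50,
                          density_threshold = 3,
                          grid_embedding = c("pca2", "external"),
                          encoder_dims = NULL,
                          alpha = 1,
                          learning_rate = 0.01,
                          momentum = 0.9,
                          minibatch_size = 256,
                          pretrain_epochs = 100,
                          finetune_epochs = 100,
                          tol_threshold = 0.005,
                          max_epochs = 100,
                          louvain_resolution = 1.0,
                          knn_k = 15,
                          by_batch = TRUE,
                          grid_filter = TRUE,
                          seed = 0L) {
  grid_embedding <- match.arg(grid_embedding)
  stopifnot(
    n_hvg >= 1, grid_cells_per_axis >= 1, density_threshold >= 0,
    alpha > 0, learning_rate > 0, momentum >= 0, minibatch_size >= 1,
    pretrain_epochs >= 0, finetune_epochs >= 0,
    tol_threshold > 0, tol_threshold < 1,
    max_epochs >= 1, louvain_resolution > 0, knn_k >= 1
  )
  if (!is.null(encoder_dims)) {
    encoder_dims <- as.integer(encoder_dims)
    stopifnot(length(encoder_dims) >= 1, all(encoder_dims >= 1))
  }
  structure(list(
    n_hvg = as.integer(n_hvg),
    grid_cells_per_axis = as.integer(grid_cells_per_axis),
    density_threshold = as.integer(density_threshold),
    grid_embedding = grid_embedding,
    encoder_dims = encoder_dims,
    alpha = alpha,
    learning_rate = learning_rate,
    momentum = momentum,
    minibatch_size = as.integer(minibatch_size),
    pretrain_epochs = as.integer(pretrain_epochs),
    finetune_epochs = as.integer(finetune_epochs),
    tol_threshold = tol_threshold,
    max_epochs = as.integer(max_epochs),
    louvain_resolution = louvain_resolution,
    knn_k = as.integer(knn_k),
    by_batch = isTRUE(by_batch),
    grid_filter = isTRUE(grid_filter),
    seed = as.integer(seed)
  ), class = "gdesce_config")
}

#' @export
print.gdesce_config <- function(x, ...) {
  cat("<gdesce_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(v)) "auto" else paste(v, collapse = ", ")))
  }
  invisible(x)
}
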