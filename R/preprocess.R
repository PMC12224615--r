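#' Normalize a count matrix for clustering
#'
#' Two-step normalization standard for UMI data. First each cell is scaled to
#' a common library size: every count is divided by the cell's total count,
#' multiplied by 10,000 and log-transformed as `log(1 + x)`. Second, every
#' gene column is standardized to mean 0, standard deviation 1 — within each
#' batch separately when `by_batch` is `TRUE` and batch labels are present, so
#' additive batch offsets are absorbed before clustering.
#'
#' Zero-variance gene columns are set to all zeros (with a warning) rather
#' than producing NaNs.
#'
#' @param m A [count_matrix].
#' @param by_batch Standardize within batches when batch labels are present.
#' @return A list of class `normalized_matrix` with elements `values`
#'   (cells x genes), `log_values` (the log-scaled values before
#'   standardization), `gene_means`, `gene_sds` (per standardization group),
#'   and `per_batch` (logical flag).
#' @export
normalize_counts <- function(m, by_batch = TRUE) {
  stopifnot(inherits(m, "count_matrix"))
  x <- m$values
  totals <- rowSums(x)
  if (any(totals == 0))
    stop("cells with zero total count: ",
         paste(head(m$cell_ids[totals == 0], 5), collapse = ", "))
  lognorm <- log1p(x / totals * 1e4)

  use_batch <- by_batch && !is.null(m$batch) && nlevels(m$batch) > 1
  z <- lognorm
  groups <- if (use_batch) split(seq_len(nrow(x)), m$batch) else list(all = seq_len(nrow(x)))
  gene_means <- list()
  gene_sds <- list()
  n_const <- 0L
  for (g in names(groups)) {
    idx <- groups[[g]]
    mu <- colMeans(lognorm[idx, , drop = FALSE])
    sdv <- apply(lognorm[idx, , drop = FALSE], 2, sd)
    const <- sdv == 0 | !is.finite(sdv)
    n_const <- n_const + sum(const)
    sdv[const] <- Inf  # constant column -> all zeros after centering/scaling
    z[idx, ] <- sweep(sweep(lognorm[idx, , drop = FALSE], 2, mu), 2, sdv, "/")
    z[idx, const] <- 0
    gene_means[[g]] <- mu
    gene_sds[[g]] <- sdv
  }
  if (n_const > 0)
    warning(n_const, " zero-variance gene column(s) set to zero")
  structure(list(values = z, log_values = lognorm,
                 gene_means = gene_means, gene_sds = gene_sds,
                 per_batch = use_batch, batch = m$batch,
                 cell_ids = m$cell_ids, gene_ids = m$gene_ids),
            class = "normalized_matrix")
}

#' Select highly variable genes by binned dispersion
#'
#' Dispersion-based selection on the log-normalized scale: per-gene dispersion
#' is variance/mean; genes are placed in 20 equal-frequency bins of mean
#' expression and dispersions are z-scored within each bin, so highly variable
#' genes are chosen relative to genes of similar abundance. Ties are broken by
#' gene order.
#'
#' @param norm A `normalized_matrix` (its `log_values` are used) or a plain
#'   cells x genes matrix of log-normalized values.
#' @param n_top Number of genes to keep; must not exceed the gene count.
#' @param n_bins Number of equal-frequency mean bins.
#' @return Logical per-gene mask with `n_top` `TRUE` entries.
#' @export
select_hvg <- function(norm, n_top, n_bins = 20) {
  x <- if (inherits(norm, "normalized_matrix")) norm$log_values else as.matrix(norm)
  g <- ncol(x)
  if (n_top > g) stop("n_top (", n_top, ") exceeds gene count (", g, ")")
  mu <- colMeans(x)
  v <- apply(x, 2, var)
  disp <- ifelse(mu > 0, v / mu, 0)

  # keep bins populated (>= ~5 genes each) so within-bin z-scores are defined
  n_bins <- max(1, min(n_bins, g %/% 5))
  qs <- unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- if (length(qs) > 2) cut(mu, breaks = qs, include.lowest = TRUE)
  else factor(rep(1L, g))
  zdisp <- disp
  for (b in levels(bins)) {
    idx <- which(bins == b)
    s <- sd(disp[idx])
    if (!is.finite(s) || s == 0) {
      zdisp[idx] <- 0
    } else {
      zdisp[idx] <- (disp[idx] - mean(disp[idx])) / s
    }
  }
  # stable order: rank by z-scored dispersion, ties resolved by gene position
  ord <- order(-zdisp, seq_len(g))
  mask <- logical(g)
  mask[ord[seq_len(n_top)]] <- TRUE
  mask
}

#' Euclidean distance between two 2-D points
#'
#' @param a,b Numeric length-2 vectors (x, y).
#' @return Nonnegative distance `sqrt((x_a - x_b)^2 + (y_a - y_b)^2)`.
#' @export
euclidean_distance <- function(a, b) {
  stopifnot(length(a) == 2, length(b) == 2, all(is.finite(a)), all(is.finite(b)))
  sqrt(sum((a - b)^2))
}

#' First two principal components of a matrix
#'
#' Default 2-D embedding on which the grid-density outlier filter operates.
#'
#' @param x Cells x features numeric matrix (typically standardized HVG
#'   expression).
#' @return n x 2 matrix of PC scores.
#' @export
pca_embed2 <- function(x) {
  x <- as.matrix(x)
  p <- prcomp(x, center = TRUE, scale. = FALSE, rank. = 2)
  coords <- p$x[, seq_len(min(2, ncol(p$x))), drop = FALSE]
  if (ncol(coords) < 2) coords <- cbind(coords, 0)
  colnames(coords) <- c("x", "y")
  coords
}

#' Partition 2-D points into a uniform density grid
#'
#' Lays an axis-aligned `cells_per_axis` x `cells_per_axis` lattice over the
#' bounding box of the points. Grid cells are half-open except along the top
#' edges, so points on the maximal x or y boundary fall in the last cell. A
#' grid cell is dense when it holds strictly more points than
#' `density_threshold`.
#'
#' @param coords n x 2 numeric matrix of point coordinates.
#' @param cells_per_axis Grid resolution per axis.
#' @param density_threshold Occupancy above which a cell is dense.
#' @return A list of class `grid_partition`: `cell_of_point` (linear grid-cell
#'   index per point), `counts`, `dense_mask`, `centers` (p x 2 matrix of grid
#'   cell centers), `origin`, `cell_size`, `cells_per_axis`, `p`.
#' @export
build_grid <- function(coords, cells_per_axis, density_threshold) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 1, ncol(coords) == 2, cells_per_axis >= 1)
  rng_x <- range(coords[, 1])
  rng_y <- range(coords[, 2])
  # degenerate spans (all points on a line/point) collapse to one bin on that axis
  span <- c(max(rng_x[2] - rng_x[1], .Machine$double.eps),
            max(rng_y[2] - rng_y[1], .Machine$double.eps))
  size <- span / cells_per_axis
  ix <- pmin(floor((coords[, 1] - rng_x[1]) / size[1]), cells_per_axis - 1)
  iy <- pmin(floor((coords[, 2] - rng_y[1]) / size[2]), cells_per_axis - 1)
  cell <- as.integer(ix + cells_per_axis * iy + 1)
  p <- cells_per_axis^2
  counts <- tabulate(cell, nbins = p)
  gx <- (seq_len(cells_per_axis) - 0.5) * size[1] + rng_x[1]
  gy <- (seq_len(cells_per_axis) - 0.5) * size[2] + rng_y[1]
  centers <- cbind(x = rep(gx, times = cells_per_axis),
                   y = rep(gy, each = cells_per_axis))
  structure(list(cell_of_point = cell, counts = counts,
                 dense_mask = counts > density_threshold,
                 centers = centers, origin = c(rng_x[1], rng_y[1]),
                 cell_size = size, cells_per_axis = as.integer(cells_per_axis),
                 p = as.integer(p)),
            class = "grid_partition")
}

#' Remove low-density outlier points on a 2-D grid
#'
#' Iterative grid-density filter. A lattice is laid over the bounding box of
#' the input points and its geometry is kept fixed; each pass re-counts the
#' occupancy of the surviving points on that lattice. A point in a sparsely
#' occupied grid cell (occupancy in `(0, density_threshold]`) is flagged when
#' its Euclidean distance to the center of the nearest dense cell exceeds half
#' of one grid cell's diagonal. Flagged points are removed and occupancies
#' re-counted — removals can tip further cells below the density threshold —
#' until a pass removes nothing, so the result is a fixed point of the filter.
#'
#' If no grid cell is ever dense the filter cannot anchor itself; it then
#' keeps all points and warns.
#'
#' @inheritParams build_grid
#' @return Logical keep-mask aligned with the input rows.
#' @export
remove_outliers <- function(coords, cells_per_axis = 50, density_threshold = 3) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(n >= 1, ncol(coords) == 2)
  keep <- rep(TRUE, n)
  g0 <- build_grid(coords, cells_per_axis, density_threshold)
  half_diag <- sqrt(sum(g0$cell_size^2)) / 2
  p <- g0$p
  repeat {
    idx <- which(keep)
    counts <- tabulate(g0$cell_of_point[idx], nbins = p)
    dense <- counts > density_threshold
    if (!any(dense)) {
      if (all(keep)) {
        warning("no dense grid cell found; keeping all points")
        return(keep)
      }
      break
    }
    sparse_pt <- counts[g0$cell_of_point[idx]] <= density_threshold
    if (!any(sparse_pt)) break
    dense_centers <- g0$centers[dense, , drop = FALSE]
    cand <- idx[sparse_pt]
    pc <- coords[cand, , drop = FALSE]
    # distance from each candidate to its nearest dense-cell center
    d2 <- outer(rowSums(pc^2), rowSums(dense_centers^2), "+") -
      2 * pc %*% t(dense_centers)
    nearest <- sqrt(pmax(apply(d2, 1, min), 0))
    flagged <- cand[nearest > half_diag]
    if (length(flagged) == 0) break
    keep[flagged] <- FALSE
    if (!any(keep)) {
      warning("grid filter flagged every point; keeping all points")
      return(rep(TRUE, n))
    }
  }
  keep
}
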