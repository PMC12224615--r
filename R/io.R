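#' Construct a validated single-cell count matrix
#'
#' The package's input container: a cells x genes matrix of nonnegative UMI
#' counts with unique cell and gene identifiers, plus optional per-cell batch
#' and ground-truth labels. Cells are always rows, whatever the on-disk
#' orientation of the source file was.
#'
#' @param values Numeric cells x genes matrix (dense or `Matrix` sparse);
#'   coerced to a dense base matrix.
#' @param cell_ids Character vector of unique cell identifiers, one per row.
#' @param gene_ids Character vector of unique gene identifiers, one per column.
#' @param batch Optional per-cell batch label (factor or character).
#' @param truth Optional per-cell ground-truth label for evaluation.
#'
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(values, cell_ids = rownames(values),
                         gene_ids = colnames(values),
                         batch = NULL, truth = NULL) {
  values <- as.matrix(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values) || length(gene_ids) != ncol(values))
    stop("id lengths must match matrix dimensions")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyNA(values) || any(values < 0))
    stop("count matrix must be nonnegative with no missing values")
  if (!is.null(batch)) {
    if (length(batch) != nrow(values)) stop("batch must have one label per cell")
    batch <- as.factor(batch)
  }
  if (!is.null(truth)) {
    if (length(truth) != nrow(values)) stop("truth must have one label per cell")
    truth <- as.factor(truth)
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 batch = batch, truth = truth),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d cells x %d genes", nrow(x$values), ncol(x$values)))
  if (!is.null(x$batch)) cat(sprintf(", %d batches", nlevels(x$batch)))
  if (!is.null(x$truth)) cat(sprintf(", %d truth labels", nlevels(x$truth)))
  cat("\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Read a single-cell count matrix
#'
#' Supported formats:
#' \describe{
#'   \item{`csv`}{Self-describing dense table: first column `cell_id`, header
#'     row of gene ids; optional reserved columns `batch` and `truth`.}
#'   \item{`mtx`}{MatrixMarket coordinate triplet in the 10x genes x cells
#'     orientation (transposed on read so cells are rows), with sidecar
#'     `barcodes.tsv` (cells) and `features.tsv` or `genes.tsv` (genes) in the
#'     same directory.}
#'   \item{`10x-h5`}{CellRanger v3-style HDF5 with a `matrix/` group holding a
#'     CSC sparse genes x cells matrix; requires the `rhdf5` package.}
#' }
#'
#' @param path File path (for `mtx`, the `.mtx` file).
#' @param format One of `"csv"`, `"mtx"`, `"10x-h5"`. Guessed from the file
#'   extension when missing.
#' @return A [count_matrix] with cells as rows.
#' @export
read_counts <- function(path, format = c("csv", "mtx", "10x-h5")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", h5 = "10x-h5", hdf5 = "10x-h5",
                     csv = "csv", tsv = "csv",
                     stop("cannot guess format from extension: ", path))
  }
  format <- match.arg(format)
  switch(format,
         csv = read_counts_csv(path),
         mtx = read_counts_mtx(path),
         `10x-h5` = read_counts_10x_h5(path))
}

read_counts_csv <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("CSV must have a cell_id column plus gene columns")
  cell_ids <- as.character(df[[1]])
  df <- df[-1]
  batch <- if ("batch" %in% names(df)) df[["batch"]] else NULL
  truth <- if ("truth" %in% names(df)) df[["truth"]] else NULL
  df <- df[setdiff(names(df), c("batch", "truth"))]
  values <- as.matrix(df)
  storage.mode(values) <- "double"
  count_matrix(values, cell_ids, colnames(values), batch = batch, truth = truth)
}

find_sidecar <- function(dir, stems) {
  for (s in stems) {
    p <- file.path(dir, s)
    if (file.exists(p)) return(p)
  }
  NULL
}

read_counts_mtx <- function(path) {
  dir <- dirname(path)
  bc <- find_sidecar(dir, c("barcodes.tsv", "barcodes.txt"))
  ft <- find_sidecar(dir, c("features.tsv", "genes.tsv", "features.txt"))
  if (is.null(bc) || is.null(ft))
    stop("mtx sidecar files (barcodes.tsv and features.tsv/genes.tsv) not found in ", dir)
  m <- Matrix::readMM(path)                      # genes x cells on disk
  barcodes <- readLines(bc)
  feats <- read.delim(ft, header = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(feats[[1]])
  if (nrow(m) != length(gene_ids) || ncol(m) != length(barcodes))
    stop("mtx dimensions do not match sidecar files (expect genes x cells)")
  values <- t(as.matrix(m))                      # cells x genes in memory
  count_matrix(values, barcodes, gene_ids)
}

read_counts_10x_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("reading 10x HDF5 requires the rhdf5 package")
  root <- "matrix"
  data <- rhdf5::h5read(path, file.path(root, "data"))
  indices <- rhdf5::h5read(path, file.path(root, "indices"))
  indptr <- rhdf5::h5read(path, file.path(root, "indptr"))
  shape <- rhdf5::h5read(path, file.path(root, "shape"))   # genes, cells
  barcodes <- as.character(rhdf5::h5read(path, file.path(root, "barcodes")))
  gene_ids <- as.character(rhdf5::h5read(path, file.path(root, "features/id")))
  m <- Matrix::sparseMatrix(i = as.integer(indices) + 1L,
                            p = as.integer(indptr),
                            x = as.numeric(data),
                            dims = as.integer(shape))
  count_matrix(t(as.matrix(m)), barcodes, gene_ids)
}

#' Write a count matrix as a MatrixMarket triplet with sidecars
#'
#' Writes `matrix.mtx` (genes x cells, 10x orientation), `barcodes.tsv`,
#' `features.tsv`, and, when batch or truth labels are present, `labels.csv`
#' with the per-cell annotations.
#'
#' @param m A [count_matrix].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_counts_mtx <- function(m, dir) {
  stopifnot(inherits(m, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(Matrix::Matrix(t(m$values), sparse = TRUE), mtx)
  writeLines(m$cell_ids, file.path(dir, "barcodes.tsv"))
  write.table(data.frame(id = m$gene_ids, name = m$gene_ids),
              file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  paths <- c(mtx, file.path(dir, c("barcodes.tsv", "features.tsv")))
  if (!is.null(m$batch) || !is.null(m$truth)) {
    lab <- data.frame(cell_id = m$cell_ids)
    if (!is.null(m$batch)) lab$batch <- as.character(m$batch)
    if (!is.null(m$truth)) lab$truth <- as.character(m$truth)
    lp <- file.path(dir, "labels.csv")
    write.csv(lab, lp, row.names = FALSE, quote = FALSE)
    paths <- c(paths, lp)
  }
  invisible(paths)
}

#' Write clustering results and metrics to a directory
#'
#' Writes `labels.csv` (cell_id, cluster; removed outliers carry cluster -1),
#' `probabilities.csv` (cell_id plus one column per cluster; NA rows for
#' removed cells), `metrics.json`, and `config.json`. Re-reading `labels.csv`
#' reproduces the label vector exactly.
#'
#' @param result A `gdesce_fit` object (see [gdesce_cluster()]).
#' @param report Optional metrics report from [metrics_report()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, report = NULL, dir) {
  stopifnot(inherits(result, "gdesce_fit"))
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  labels <- data.frame(cell_id = result$cell_ids, cluster = result$labels)
  write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)

  K <- ncol(result$soft)
  probs <- matrix(NA_real_, nrow = length(result$cell_ids), ncol = K,
                  dimnames = list(NULL, paste0("cluster", seq_len(K) - 1L)))
  if (any(result$labels >= 0))
    probs[result$labels >= 0, ] <- result$soft
  probs_df <- data.frame(cell_id = result$cell_ids, probs, check.names = FALSE)
  write.csv(probs_df, file.path(dir, "probabilities.csv"), row.names = FALSE, quote = FALSE)

  if (is.null(report)) report <- list()
  jsonlite::write_json(unclass(report), file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(unclass(result$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file.path(dir, c("labels.csv", "probabilities.csv",
                             "metrics.json", "config.json")))
}
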