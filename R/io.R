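#' Read a spatial dataset from disk
#'
#' Reads the plain-tables layout: a directory containing `expression.mtx`
#' (MatrixMarket sparse counts) or `expression.csv` (dense), `cells.csv`
#' (columns `cell_id`, `x`, `y`\[, `z`\], `slice_id`, plus any per-cell
#' metadata) and `genes.csv` (column `gene`). HDF5-backed single-cell
#' containers are not handled by this build; export such objects to the
#' tables layout first (e.g. with `anndata`/`scanpy` in Python).
#'
#' @param path directory holding the tables.
#' @param format currently `"tables"`.
#' @param unit_scale factor converting stored coordinate units to micrometers.
#' @return a validated [spatial_dataset].
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(path, format = c("tables", "h5ad"), unit_scale = 1) {
  format <- match.arg(format)
  if (format == "h5ad") {
    abort(paste0(
      "HDF5 (.h5ad) containers are not supported by this build; ",
      "export to the tables layout (expression.mtx + cells.csv + genes.csv) ",
      "and read with format = \"tables\""))
  }
  if (!dir.exists(path)) abort(sprintf("directory not found: %s", path))

  mtx <- file.path(path, "expression.mtx")
  csv <- file.path(path, "expression.csv")
  if (file.exists(mtx)) {
    expr <- as(Matrix::readMM(mtx), "CsparseMatrix")
  } else if (file.exists(csv)) {
    expr <- as.matrix(read.csv(csv, header = FALSE))
    dimnames(expr) <- NULL
  } else {
    abort(sprintf("no expression.mtx or expression.csv found in %s", path))
  }

  cells_path <- file.path(path, "cells.csv")
  genes_path <- file.path(path, "genes.csv")
  if (!file.exists(cells_path)) abort(sprintf("cells.csv not found in %s", path))
  if (!file.exists(genes_path)) abort(sprintf("genes.csv not found in %s", path))
  cells <- read.csv(cells_path, stringsAsFactors = FALSE)
  genes <- read.csv(genes_path, stringsAsFactors = FALSE)

  if (!"slice_id" %in% names(cells)) {
    abort("multi-slice key absent: cells table has no `slice_id` column")
  }
  coord_cols <- intersect(c("x", "y", "z"), names(cells))
  if (!all(c("x", "y") %in% coord_cols)) {
    abort("cells table must contain coordinate columns `x` and `y`")
  }
  if (nrow(cells) != nrow(expr)) {
    abort(sprintf(
      "shape mismatch: expression has %d rows but cells.csv has %d",
      nrow(expr), nrow(cells)))
  }
  if (!"gene" %in% names(genes)) abort("genes.csv must have a `gene` column")
  if (nrow(genes) != ncol(expr)) {
    abort(sprintf(
      "shape mismatch: expression has %d columns but genes.csv has %d rows",
      ncol(expr), nrow(genes)))
  }

  meta_cols <- setdiff(names(cells), c("cell_id", "slice_id", coord_cols))
  ds <- spatial_dataset(
    expression = expr,
    coordinates = as.matrix(cells[coord_cols]),
    slice_id = cells$slice_id,
    cell_meta = if (length(meta_cols)) cells[meta_cols] else NULL,
    gene_names = genes$gene,
    cell_ids = if ("cell_id" %in% names(cells)) cells$cell_id else NULL,
    unit_scale = unit_scale)
  rep <- validate_dataset(ds)
  if (!attr(rep, "ok")) {
    abort(paste0("dataset failed validation:\n  ",
                 paste(rep$message[rep$severity == "error"], collapse = "\n  ")))
  }
  ds
}

#' Write a spatial dataset to disk
#'
#' Writes the plain-tables layout read back by [read_dataset()]. Expression
#' goes to `expression.mtx` when sparse (or when `sparse = TRUE`), otherwise
#' to `expression.csv`; coordinates, slice identifiers and all per-cell
#' metadata go to `cells.csv`; feature names to `genes.csv`.
#'
#' @param ds a [spatial_dataset].
#' @param path output directory (created if missing).
#' @param sparse force MatrixMarket output for dense expression matrices.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, sparse = is(ds$expression, "sparseMatrix")) {
  stopifnot(inherits(ds, "spatial_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (sparse) {
    Matrix::writeMM(as(as(ds$expression, "dMatrix"), "CsparseMatrix"),
                    file.path(path, "expression.mtx"))
  } else {
    write.table(as.matrix(ds$expression), file.path(path, "expression.csv"),
                sep = ",", row.names = FALSE, col.names = FALSE)
  }
  cells <- dplyr::bind_cols(
    ds$cells["cell_id"],
    as_tibble(as.data.frame(ds$coordinates)),
    ds$cells[setdiff(names(ds$cells), "cell_id")])
  write.csv(cells, file.path(path, "cells.csv"), row.names = FALSE)
  write.csv(data.frame(gene = ds$genes), file.path(path, "genes.csv"),
            row.names = FALSE)
  invisible(path)
}

#' Write per-cell domain labels as a flat CSV
#'
#' @param result a `domain_result` from [cluster_domains()], [res_search()]
#'   or [identify_domains()].
#' @param ds the `spatial_dataset` the result was computed on.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_domains_csv <- function(result, ds, file) {
  stopifnot(inherits(result, "domain_result"))
  out <- tibble(cell_id = ds$cells$cell_id,
                slice_id = as.character(ds$cells$slice_id),
                domain = as.character(result$labels))
  write.csv(out, file, row.names = FALSE)
  invisible(file)
}
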