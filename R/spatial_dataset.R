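#' Assemble a multi-slice spatial omics dataset
#'
#' The single input container for the whole pipeline: a cells-by-genes
#' expression matrix, per-cell spatial coordinates, and a slice identifier
#' that keeps cells from different tissue sections from ever becoming
#' spatial neighbors. Optional per-cell annotations (prior cell states,
#' ground-truth domains, patient metadata) ride along in a cell table.
#'
#' @param expression numeric matrix (dense or `dgCMatrix`), cells in rows,
#'   genes in columns. Raw counts are expected but not enforced; the pipeline
#'   normalizes internally.
#' @param coordinates numeric matrix with 2 or 3 columns (x, y\[, z\]), one
#'   row per cell. Units are micrometers unless `unit_scale` says otherwise.
#' @param slice_id per-cell slice identifier, length `nrow(expression)`.
#' @param cell_meta optional data frame of additional per-cell columns
#'   (e.g. `cell_state`, `truth_domain`, `patient_id`, `group`).
#' @param gene_names optional character vector of feature names; defaults to
#'   `colnames(expression)` or `gene1..geneG`.
#' @param cell_ids optional character vector of cell identifiers; defaults to
#'   `cell1..cellN`.
#' @param unit_scale multiplicative factor converting stored coordinate units
#'   to micrometers (default 1: coordinates already in um). All radius logic
#'   (ring construction, radius estimation) applies after this conversion.
#'
#' @return A `spatial_dataset`: a list with elements `expression`,
#'   `coordinates`, `cells` (a tibble with `cell_id`, `slice_id` and any
#'   metadata columns), `genes`, and `unit_scale`.
#' @examples
#' expr <- matrix(rpois(50, 2), 10, 5)
#' xy <- cbind(runif(10, 0, 100), runif(10, 0, 100))
#' ds <- spatial_dataset(expr, xy, slice_id = rep(c("s1", "s2"), each = 5))
#' ds
#' @export
spatial_dataset <- function(expression, coordinates, slice_id,
                            cell_meta = NULL, gene_names = NULL,
                            cell_ids = NULL, unit_scale = 1) {
  if (is.data.frame(expression)) expression <- as.matrix(expression)
  if (!(is.matrix(expression) || is(expression, "sparseMatrix"))) {
    abort("`expression` must be a matrix or sparse Matrix (cells x genes)")
  }
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  n <- nrow(expression)
  if (nrow(coordinates) != n) {
    abort(sprintf(
      "shape mismatch: `expression` has %d rows but `coordinates` has %d",
      n, nrow(coordinates)))
  }
  if (!ncol(coordinates) %in% 2:3) {
    abort("`coordinates` must have 2 or 3 columns (x, y[, z])")
  }
  if (length(slice_id) != n) {
    abort(sprintf(
      "shape mismatch: `expression` has %d rows but `slice_id` has length %d",
      n, length(slice_id)))
  }
  check_number(unit_scale, "unit_scale", lower = .Machine$double.eps)

  gene_names <- gene_names %||% colnames(expression) %||%
    paste0("gene", seq_len(ncol(expression)))
  if (length(gene_names) != ncol(expression)) {
    abort("`gene_names` length must equal the number of expression columns")
  }
  cell_ids <- cell_ids %||% rownames(expression) %||% paste0("cell", seq_len(n))
  if (anyDuplicated(cell_ids)) abort("cell identifiers must be unique")

  cells <- tibble(cell_id = as.character(cell_ids),
                  slice_id = as_label_factor(slice_id))
  if (!is.null(cell_meta)) {
    cell_meta <- as_tibble(cell_meta)
    if (nrow(cell_meta) != n) {
      abort(sprintf(
        "shape mismatch: `cell_meta` has %d rows for %d cells", nrow(cell_meta), n))
    }
    cell_meta <- cell_meta[setdiff(names(cell_meta), c("cell_id", "slice_id"))]
    cells <- dplyr::bind_cols(cells, cell_meta)
  }
  colnames(expression) <- gene_names
  rownames(expression) <- cells$cell_id
  colnames(coordinates) <- c("x", "y", "z")[seq_len(ncol(coordinates))]

  structure(
    list(expression = expression, coordinates = coordinates, cells = cells,
         genes = as.character(gene_names), unit_scale = unit_scale),
    class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("<spatial_dataset> %d cells x %d genes, %d slice(s), %dD coordinates\n",
              n_cells(x), length(x$genes), nlevels(x$cells$slice_id),
              ncol(x$coordinates)))
  counts <- table(x$cells$slice_id)
  cat("  slices:", paste(sprintf("%s (%d)", names(counts), counts), collapse = ", "), "\n")
  extra <- setdiff(names(x$cells), c("cell_id", "slice_id"))
  if (length(extra)) cat("  cell metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' Number of cells in a spatial dataset
#' @param ds a `spatial_dataset`.
#' @return integer cell count.
#' @export
n_cells <- function(ds) nrow(ds$expression)

# coordinates converted to micrometers (radius logic always works in um)
coords_um <- function(ds) ds$coordinates * ds$unit_scale

#' Validate a spatial dataset
#'
#' Pure consistency check: reports problems without throwing. Errors (NaN or
#' missing coordinates, array length mismatches) make the dataset unusable;
#' warnings (negative expression entries, empty slice levels, duplicated gene
#' names, duplicated coordinates) flag suspicious but tolerated input.
#'
#' @param ds a `spatial_dataset`.
#' @return A `ringscape_validation`: a tibble with columns `severity`
#'   (`"error"` or `"warning"`), `message`, and `index` (list-column of
#'   offending cell/gene indices), with attribute `ok` that is `TRUE` iff no
#'   error-severity issue exists.
#' @examples
#' expr <- matrix(1, 4, 3)
#' xy <- cbind(c(0, 1, 2, NaN), 0)
#' ds <- spatial_dataset(expr, xy, slice_id = rep("a", 4))
#' rep <- validate_dataset(ds)
#' attr(rep, "ok")
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "spatial_dataset"))
  issues <- list()
  add <- function(severity, message, index = integer()) {
    issues[[length(issues) + 1L]] <<- tibble(
      severity = severity, message = message, index = list(as.integer(index)))
  }

  bad_coord <- which(apply(!is.finite(ds$coordinates), 1L, any))
  if (length(bad_coord)) {
    add("error", sprintf("non-finite coordinates for %d cell(s): %s",
                         length(bad_coord),
                         paste(head(bad_coord, 5L), collapse = ", ")),
        bad_coord)
  }
  neg <- if (is(ds$expression, "sparseMatrix")) {
    any(ds$expression@x < 0)
  } else {
    any(ds$expression < 0)
  }
  if (isTRUE(neg)) {
    add("warning", "expression matrix contains negative entries (counts expected)")
  }
  empty <- levels(ds$cells$slice_id)[tabulate(ds$cells$slice_id,
                                              nlevels(ds$cells$slice_id)) == 0L]
  if (length(empty)) {
    add("warning", sprintf("slice level(s) with zero cells: %s",
                           paste(empty, collapse = ", ")))
  }
  dup <- which(duplicated(ds$genes))
  if (length(dup)) {
    add("warning", sprintf("duplicated gene name(s): %s",
                           paste(unique(ds$genes[dup]), collapse = ", ")), dup)
  }

  report <- if (length(issues)) dplyr::bind_rows(issues) else {
    tibble(severity = character(), message = character(), index = list())
  }
  attr(report, "ok") <- !any(report$severity == "error")
  class(report) <- c("ringscape_validation", class(report))
  report
}

#' @export
print.ringscape_validation <- function(x, ...) {
  ok <- attr(x, "ok")
  cat(sprintf("<validation> ok = %s, %d issue(s)\n", ok, nrow(x)))
  if (nrow(x)) {
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  [%s] %s\n", x$severity[i], x$message[i]))
    }
  }
  invisible(x)
}
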