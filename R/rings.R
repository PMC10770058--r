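# ---- multi-range ring neighborhoods ----------------------------------------

#' Build per-slice multi-range ring neighborhoods
#'
#' Around every index cell, `S` concentric ranges are formed within its own
#' slice; cells from other slices are never neighbors. In `radius` mode,
#' ring `s` of cell `i` is the annulus of same-slice cells `j` with
#' `(s-1)*R <= Dist(i, j) < s*R` (half-open, so a cell exactly on a boundary
#' falls in the outer ring; distances in micrometers after `unit_scale`).
#' In `knn` mode (array-like spot technologies), ring `s` is the set of spots
#' at exact hop distance `s` in the per-slice `nn`-nearest-neighbor graph,
#' symmetrized by union. The index cell itself (distance/hop 0) belongs to
#' ring 1 iff `self_in_first_ring`.
#'
#' Neighborhoods are computed per slice by exact vectorized distance
#' evaluation, so results are identical to a brute-force scan by
#' construction and independent of slice processing order.
#'
#' @param ds a [spatial_dataset].
#' @param mode `"radius"` (single-cell resolution data) or `"knn"`
#'   (array-like spots); see [default_params()] for per-technology defaults.
#' @param R ring width in micrometers (radius mode; default 15).
#' @param nn neighbors per spot (knn mode).
#' @param S number of ranges.
#' @param self_in_first_ring include the index cell in ring 1 (default TRUE,
#'   the literal reading of the half-open interval at distance 0).
#' @return a `ring_index`: `rings[[s]][[i]]` holds the cell indices in ring
#'   `s` of cell `i`, plus the parameter record.
#' @examples
#' ds <- spatial_dataset(matrix(1, 3, 2), cbind(c(0, 10, 25), 0), rep("s1", 3))
#' ri <- build_rings(ds, "radius", R = 15, S = 2)
#' ri$rings[[1]][[1]]  # ring 1 of cell 1: itself and the cell 10 um away
#' @export
build_rings <- function(ds, mode = c("radius", "knn"), R = 15, nn = 6, S = 6,
                        self_in_first_ring = TRUE) {
  stopifnot(inherits(ds, "spatial_dataset"))
  mode <- match.arg(mode)
  S <- check_count(S, "S")
  n <- n_cells(ds)
  xy <- coords_um(ds)
  slice <- ds$cells$slice_id

  rings <- replicate(S, vector("list", n), simplify = FALSE)
  for (sl in levels(slice)) {
    idx <- which(slice == sl)
    if (!length(idx)) next
    ring_of <- if (mode == "radius") {
      check_number(R, "R", lower = .Machine$double.eps)
      rings_radius(xy[idx, , drop = FALSE], R, S)
    } else {
      nn <- check_count(nn, "nn")
      if (length(idx) <= nn) {
        abort(sprintf("slice '%s' has %d spot(s) but knn mode needs more than nn = %d",
                      sl, length(idx), nn))
      }
      rings_hops(xy[idx, , drop = FALSE], nn, S)
    }
    # ring_of: n_sl x n_sl integer matrix of ring numbers (0 = not captured)
    for (s in seq_len(S)) {
      hits <- which(ring_of == s, arr.ind = TRUE)
      per_cell <- split(idx[hits[, 2L]], factor(hits[, 1L], levels = seq_along(idx)))
      for (ii in seq_along(idx)) rings[[s]][[idx[ii]]] <- as.integer(per_cell[[ii]])
    }
  }
  if (!self_in_first_ring) {
    for (i in seq_len(n)) rings[[1L]][[i]] <- setdiff(rings[[1L]][[i]], i)
  }
  structure(list(rings = rings, mode = mode,
                 R = if (mode == "radius") R else NA_real_,
                 nn = if (mode == "knn") nn else NA_integer_,
                 S = S, self_in_first_ring = self_in_first_ring,
                 slice = slice, n = n),
            class = "ring_index")
}

#' @export
print.ring_index <- function(x, ...) {
  size <- if (x$mode == "radius") sprintf("R = %g um", x$R) else sprintf("nn = %d", x$nn)
  cat(sprintf("<ring_index> %d cells, mode = %s, %s, S = %d, self in ring 1: %s\n",
              x$n, x$mode, size, x$S, x$self_in_first_ring))
  invisible(x)
}

# ring membership by half-open annuli, chunked over query cells.
# Returns an n x n integer matrix: entry [i, j] = ring of j around i (0 = none).
rings_radius <- function(xy, R, S, chunk = 512L) {
  n <- nrow(xy)
  out <- matrix(0L, n, n)
  sq <- rowSums(xy^2)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[rows], sq, `+`) - 2 * tcrossprod(xy[rows, , drop = FALSE], xy)
    d <- sqrt(pmax(d2, 0))
    ring <- floor(d / R) + 1
    ring[d >= S * R] <- 0
    out[rows, ] <- as.integer(ring)
  }
  out
}

# hop-shell rings on the union-symmetrized nn-nearest-neighbor graph
rings_hops <- function(xy, nn, S) {
  n <- nrow(xy)
  g <- knn_graph(xy, nn)
  hops <- igraph::distances(g, mode = "all")
  ring <- hops
  ring[hops == 0] <- 1          # self joins ring 1 (stripped later if excluded)
  ring[hops > S] <- 0
  ring[!is.finite(hops)] <- 0
  storage.mode(ring) <- "integer"
  ring
}

#' Count cell states per ring: the multi-range context representation
#'
#' For every cell `i`, counts how many cells of each state `g_c` fall in each
#' of its `S` rings, and concatenates the counts range-major:
#' `M[i, (s-1)*C + c]` is the number of same-slice cells of state `c` in ring
#' `s` of `i`. Rows of this nonnegative integer matrix are the cellular
#' context representations that the domain clustering operates on.
#'
#' @param rings a `ring_index` from [build_rings()].
#' @param states a `cell_states` object over the same cells.
#' @return a `context_representation`: sparse matrix `M` (cells x `S*C`),
#'   `column_map` tibble (`column`, `range`, `state`; 1-based), and the
#'   parameter record inherited from `rings`.
#' @export
compute_representation <- function(rings, states) {
  stopifnot(inherits(rings, "ring_index"), inherits(states, "cell_states"))
  if (length(states$labels) != rings$n) {
    abort(sprintf("ring index covers %d cells but states cover %d",
                  rings$n, length(states$labels)))
  }
  C <- states$C
  if (C < 1L) abort("cell-state alphabet is empty")
  S <- rings$S
  st <- as.integer(states$labels)

  ii <- integer(0); jj <- integer(0)
  for (s in seq_len(S)) {
    members <- rings$rings[[s]]
    len <- lengths(members)
    ii <- c(ii, rep.int(seq_len(rings$n), len))
    jj <- c(jj, (s - 1L) * C + st[unlist(members, use.names = FALSE)])
  }
  M <- sparseMatrix(i = ii, j = jj, x = 1, dims = c(rings$n, S * C))
  column_map <- tibble(
    column = seq_len(S * C),
    range = rep(seq_len(S), each = C),
    state = rep(levels(states$labels), times = S))
  colnames(M) <- paste0(column_map$state, ".r", column_map$range)
  structure(list(M = M, column_map = column_map,
                 states = levels(states$labels),
                 params = list(mode = rings$mode, R = rings$R, nn = rings$nn,
                               S = S, self_in_first_ring = rings$self_in_first_ring)),
            class = "context_representation")
}

#' @export
print.context_representation <- function(x, ...) {
  cat(sprintf("<context_representation> %d cells x %d features (S = %d ranges x C = %d states)\n",
              nrow(x$M), ncol(x$M), x$params$S, length(x$states)))
  invisible(x)
}

#' Decode a representation column into its (cell state, range) pair
#'
#' Inverts the range-major column layout `column = (s-1)*C + c` (1-based).
#'
#' @param column integer column index (1-based, may be a vector).
#' @param column_map the `column_map` tibble of a `context_representation`,
#'   or a `context_representation` itself.
#' @return tibble with `column`, `state`, `range`.
#' @export
decode_feature <- function(column, column_map) {
  if (inherits(column_map, "context_representation")) {
    column_map <- column_map$column_map
  }
  if (any(column < 1L | column > nrow(column_map))) {
    abort(sprintf("column index out of range 1..%d", nrow(column_map)))
  }
  column_map[column, ]
}

# ---- radius diagnostic ------------------------------------------------------

#' Nearest-neighbor distance diagnostic for choosing the ring radius
#'
#' For each cell, records the distance to its nearest same-slice cell
#' (self excluded), collects the per-slice distributions, and recommends the
#' pooled median as ring radius. On the single-cell resolution technologies
#' this distribution concentrates around 15 um, motivating the package
#' default; run this on new data before trusting that default.
#'
#' @param ds a [spatial_dataset] with at least 2 cells per slice.
#' @param slices_to_sample optionally analyze only this many slices
#'   (seed-controlled sample; useful for large multi-slice cohorts).
#' @param seed RNG seed for the slice subsample.
#' @return a `radius_report`: per-slice distance vectors, a `summary` tibble
#'   (`slice`, `n`, `q1`, `median`, `q3`), `pooled_median`, and
#'   `recommended_radius` (= pooled median). Quartiles use the standard
#'   linear-interpolation definition.
#' @export
estimate_radius <- function(ds, slices_to_sample = NULL, seed = 0) {
  stopifnot(inherits(ds, "spatial_dataset"))
  xy <- coords_um(ds)
  slice <- ds$cells$slice_id
  keep <- levels(slice)
  if (!is.null(slices_to_sample) && slices_to_sample < length(keep)) {
    keep <- with_seed(seed, sort(sample(keep, slices_to_sample)))
  }

  dists <- list()
  for (sl in keep) {
    idx <- which(slice == sl)
    if (length(idx) < 2L) {
      abort(sprintf("slice '%s' has %d cell(s); need at least 2 for nearest-neighbor distances",
                    sl, length(idx)))
    }
    nn <- RANN::nn2(xy[idx, , drop = FALSE], k = 2L)
    d1 <- nn$nn.dists[, 2L]
    if (any(d1 == 0)) {
      warn(sprintf("slice '%s' contains coincident coordinates (zero nearest-neighbor distance)", sl))
    }
    dists[[sl]] <- d1
  }
  summary <- dplyr::bind_rows(lapply(keep, function(sl) {
    q <- quantile(dists[[sl]], c(0.25, 0.5, 0.75), names = FALSE)
    tibble(slice = sl, n = length(dists[[sl]]), q1 = q[1], median = q[2], q3 = q[3])
  }))
  pooled <- median(unlist(dists, use.names = FALSE))
  structure(list(distances = dists, summary = summary,
                 pooled_median = pooled, recommended_radius = pooled),
            class = "radius_report")
}

#' @export
print.radius_report <- function(x, ...) {
  cat("<radius_report> per-slice 1-NN distances (um)\n")
  print(x$summary)
  cat(sprintf("pooled median: %.3f -> recommended radius %.3f um\n",
              x$pooled_median, x$recommended_radius))
  invisible(x)
}

#' Conventional neighborhood parameters per spatial technology
#'
#' Array-like spot technologies use lattice-hop rings: 6 neighbors per spot
#' for 10X Visium's hexagonal array, 4 for ST's square array, both with 2
#' ranges. Single-cell resolution technologies use radius rings of 15 um
#' with 6 ranges. Slide-seq beads are array-like in distribution but are
#' conventionally given radius rings (15 um, 4 ranges); treat that choice as
#' a convention, not a measurement, and check [estimate_radius()] on new
#' data.
#'
#' @param technology one of `"visium"`, `"st"`, `"slide_seq"`, `"merfish"`,
#'   `"starmap"`, `"baristaseq"`, `"merscope"`, `"osmfish"`, `"stereo_seq"`,
#'   `"starmap_plus"`.
#' @return list with `mode`, `R` or `nn`, and `S`.
#' @export
default_params <- function(technology) {
  single_cell <- c("merfish", "starmap", "baristaseq", "merscope", "osmfish",
                   "stereo_seq", "starmap_plus")
  if (!is.character(technology) || length(technology) != 1L ||
      !technology %in% c("visium", "st", "slide_seq", single_cell)) {
    abort(paste0("unknown technology; for unlisted platforms choose the mode yourself ",
                 "and use estimate_radius() to pick a ring radius"))
  }
  switch(technology,
         visium = list(mode = "knn", nn = 6L, S = 2L),
         st = list(mode = "knn", nn = 4L, S = 2L),
         slide_seq = list(mode = "radius", R = 15, S = 4L),
         list(mode = "radius", R = 15, S = 6L))
}
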