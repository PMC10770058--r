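# ---- shared numerical steps -------------------------------------------------

# total-count scaling to target_total, then log1p. Zero rows stay zero; the
# caller decides whether that deserves a warning.
normalize_log <- function(X, target_total) {
  X <- as.matrix(X)
  totals <- rowSums(X)
  scale <- ifelse(totals > 0, target_total / totals, 0)
  log1p(X * scale)
}

# centered PCA with a fixed sign convention: each component's
# largest-magnitude loading is made positive, so results are reproducible
# across BLAS/LAPACK builds up to that convention.
pca_project <- function(L, n_components) {
  k <- min(n_components, ncol(L), nrow(L) - 1L)
  if (k < 1L) abort("cannot compute a principal-component projection: need >= 2 rows")
  p <- prcomp(L, center = TRUE, scale. = FALSE, rank. = k)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    v <- p$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2L, flip, `*`)
  dimnames(scores) <- list(rownames(L), paste0("PC", seq_len(ncol(scores))))
  scores
}

# exact k-nearest-neighbor graph, symmetrized by union (undirected, simple)
knn_graph <- function(embedding, n_neighbors) {
  n <- nrow(embedding)
  if (n_neighbors >= n) {
    abort(sprintf("`n_neighbors` (%d) must be smaller than the number of rows (%d)",
                  n_neighbors, n))
  }
  nn <- RANN::nn2(embedding, k = n_neighbors + 1L)
  from <- rep(seq_len(n), n_neighbors)
  to <- as.vector(nn$nn.idx[, -1L, drop = FALSE])
  keep <- from != to  # duplicate points can echo the query back
  g <- igraph::graph_from_edgelist(cbind(from[keep], to[keep]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::simplify(g)
}

# Leiden modularity clustering with size-ordered integer labels
# (1 = largest community; ties broken by the smallest member index)
leiden_labels <- function(graph, resolution, seed) {
  part <- with_seed(seed, igraph::cluster_leiden(
    graph, objective_function = "modularity", resolution = resolution,
    n_iterations = 3L))
  m <- as.integer(igraph::membership(part))
  sizes <- tabulate(m)
  first_member <- vapply(seq_along(sizes), function(k) match(k, m), integer(1))
  ord <- order(-sizes, first_member)
  rank <- integer(length(sizes))
  rank[ord] <- seq_along(ord)
  rank[m]
}

# ---- cell states ------------------------------------------------------------

new_cell_states <- function(labels, provenance, seed = NA_integer_) {
  labels <- as_label_factor(labels)
  structure(list(labels = labels, C = nlevels(labels),
                 provenance = provenance, seed = seed),
            class = "cell_states")
}

#' @export
print.cell_states <- function(x, ...) {
  cat(sprintf("<cell_states> %d cells, %d state(s), provenance = %s\n",
              length(x$labels), x$C, x$provenance))
  invisible(x)
}

#' Normalize, log-transform and PCA-reduce expression
#'
#' Standard scRNA-style preprocessing ahead of cell-state clustering: per-cell
#' total-count scaling to `target_total`, `log(1+x)`, then projection onto the
#' top principal components. Deterministic given identical input; the sign of
#' each component is fixed by making its largest-magnitude loading positive.
#'
#' @param ds a [spatial_dataset]; expression should be nonnegative.
#' @param target_total per-cell total after scaling (default 1e4).
#' @param n_components number of principal components (capped at
#'   `min(n_components, G, N - 1)`).
#' @param seed recorded for provenance; the computation itself is
#'   deterministic.
#' @return numeric matrix, cells x K.
#' @export
preprocess_expression <- function(ds, target_total = 1e4, n_components = 50,
                                  seed = 0) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (ncol(ds$expression) < 2L) abort("too few features: need at least 2 genes")
  check_number(target_total, "target_total", lower = .Machine$double.eps)
  n_components <- check_count(n_components, "n_components")
  L <- normalize_log(ds$expression, target_total)
  pca_project(L, n_components)
}

#' Cluster cells into discrete states
#'
#' Builds an exact k-nearest-neighbor graph in the embedding space and
#' partitions it by Leiden modularity community detection. This is the
#' "cell group" step: the state alphabet whose per-ring composition later
#' forms the context representation. The default resolution of 2 favors
#' fine-grained states; domain identification is robust to over-clustering
#' here.
#'
#' @param embedding cells x K numeric matrix (from [preprocess_expression()]
#'   or any externally computed embedding, e.g. a batch-integrated one).
#' @param resolution Leiden resolution (default 2).
#' @param n_neighbors neighbors for the graph (default 15).
#' @param seed RNG seed for the community detection.
#' @return a `cell_states` object: `labels` (factor `g1`, `g2`, ... ordered
#'   by decreasing cluster size), `C`, `provenance = "computed"`, `seed`.
#' @export
assign_cell_states <- function(embedding, resolution = 2, n_neighbors = 15,
                               seed = 0) {
  embedding <- as.matrix(embedding)
  check_number(resolution, "resolution", lower = .Machine$double.eps)
  n_neighbors <- check_count(n_neighbors, "n_neighbors")
  if (nrow(unique(embedding)) == 1L) {
    # degenerate input: no structure to partition
    return(new_cell_states(factor(rep("g1", nrow(embedding))),
                           provenance = "computed", seed = as.integer(seed)))
  }
  g <- knn_graph(embedding, n_neighbors)
  lab <- leiden_labels(g, resolution, seed)
  new_cell_states(factor(paste0("g", lab), levels = paste0("g", seq_len(max(lab)))),
                  provenance = "computed", seed = as.integer(seed))
}

#' Adopt provided cell-state annotations
#'
#' When reliable cell-type annotation is available as prior knowledge, the
#' expression-clustering step can be bypassed and the annotation used
#' directly as the state alphabet.
#'
#' @param ds a [spatial_dataset].
#' @param labels length-N vector/factor of per-cell states, or the name of a
#'   column in `ds$cells`.
#' @return a `cell_states` object with `provenance = "provided"`.
#' @export
set_cell_states <- function(ds, labels) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (is.character(labels) && length(labels) == 1L && labels %in% names(ds$cells)) {
    labels <- ds$cells[[labels]]
  }
  if (length(labels) != n_cells(ds)) {
    abort(sprintf("`labels` has length %d but the dataset has %d cells",
                  length(labels), n_cells(ds)))
  }
  bad <- which(is.na(labels) | as.character(labels) == "")
  if (length(bad)) {
    abort(sprintf("missing cell-state labels at index: %s",
                  paste(head(bad, 10L), collapse = ", ")))
  }
  new_cell_states(labels, provenance = "provided")
}

#' Randomly corrupt cell-state labels
#'
#' Robustness protocol for noisy cell typing: each cell is independently
#' selected with probability `noise_level` and, if selected, reassigned a
#' label drawn uniformly from the other `C - 1` states. The expected fraction
#' of changed labels therefore equals `noise_level` exactly, so robustness
#' curves indexed by noise level read literally.
#'
#' @param states a `cell_states` object with `C >= 2` when `noise_level > 0`.
#' @param noise_level fraction in \[0, 1\].
#' @param seed RNG seed.
#' @return a new `cell_states` object over the same state alphabet.
#' @export
inject_label_noise <- function(states, noise_level, seed = 0) {
  stopifnot(inherits(states, "cell_states"))
  check_number(noise_level, "noise_level", lower = 0, upper = 1)
  if (noise_level == 0) return(states)
  if (states$C < 2L) abort("label noise needs at least 2 states")
  lev <- levels(states$labels)
  old <- as.integer(states$labels)
  new <- with_seed(seed, {
    sel <- runif(length(old)) < noise_level
    shift <- sample.int(states$C - 1L, sum(sel), replace = TRUE)
    repl <- old
    # adding 1..C-1 modulo C lands uniformly on the other C-1 labels
    repl[sel] <- ((old[sel] - 1L + shift) %% states$C) + 1L
    repl
  })
  new_cell_states(factor(lev[new], levels = lev),
                  provenance = states$provenance, seed = as.integer(seed))
}
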