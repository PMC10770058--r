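# ---- from context representation to spatial domains ------------------------

new_domain_result <- function(labels, resolution_used, embedding, seed,
                              params = list(), umap = NULL, inexact = FALSE) {
  structure(list(labels = labels, resolution_used = resolution_used,
                 embedding = embedding, umap = umap, seed = seed,
                 params = params, inexact = inexact),
            class = "domain_result")
}

#' @export
print.domain_result <- function(x, ...) {
  cat(sprintf("<domain_result> %d cells, %d domain(s), resolution = %.4g%s\n",
              length(x$labels), nlevels(x$labels), x$resolution_used,
              if (isTRUE(x$inexact)) " (inexact target)" else ""))
  print(table(x$labels))
  invisible(x)
}

#' Normalize and reduce the context representation
#'
#' Same numeric recipe as [preprocess_expression()], applied to the ring
#' count matrix: per-cell total scaling, `log(1+x)`, principal components.
#' Cells whose rings captured no neighbors (all-zero rows, possible when the
#' index cell is excluded and isolated) are passed through as zeros with a
#' warning.
#'
#' @param cr a `context_representation` from [compute_representation()].
#' @inheritParams preprocess_expression
#' @return numeric matrix, cells x K, K = `min(n_components, S*C, N - 1)`.
#' @export
embed_representation <- function(cr, target_total = 1e4, n_components = 50,
                                 seed = 0) {
  stopifnot(inherits(cr, "context_representation"))
  zero <- which(rowSums(cr$M) == 0)
  if (length(zero)) {
    warn(sprintf("%d cell(s) have empty multi-range neighborhoods (all-zero rows): %s",
                 length(zero), paste(head(zero, 5L), collapse = ", ")))
  }
  L <- normalize_log(cr$M, target_total)
  pca_project(L, check_count(n_components, "n_components"))
}

#' Cluster the reduced representation into spatial domains
#'
#' Leiden modularity community detection on the exact k-nearest-neighbor
#' graph of the embedding. All slices are clustered jointly, so domain labels
#' are directly comparable across slices. Labels are emitted as `D0`, `D1`,
#' ... in decreasing size order.
#'
#' @param embedding cells x K matrix from [embed_representation()].
#' @param n_neighbors neighbors for the graph (default 15).
#' @param resolution Leiden resolution; the exploratory default is 0.5.
#'   Use [res_search()] when the expected number of domains is known.
#' @param seed RNG seed.
#' @return a `domain_result` (without visualization coordinates; see
#'   [umap_embed()]).
#' @export
cluster_domains <- function(embedding, n_neighbors = 15, resolution = 0.5,
                            seed = 0) {
  embedding <- as.matrix(embedding)
  check_number(resolution, "resolution", lower = .Machine$double.eps)
  g <- knn_graph(embedding, check_count(n_neighbors, "n_neighbors"))
  lab <- leiden_labels(g, resolution, seed)
  labels <- factor(paste0("D", lab - 1L), levels = paste0("D", seq_len(max(lab)) - 1L))
  new_domain_result(labels, resolution, embedding, seed,
                    params = list(n_neighbors = n_neighbors))
}

#' Search the Leiden resolution for a target number of domains
#'
#' When the expected number of regions is known a priori, bisects the
#' resolution (geometrically, since useful resolutions span decades) until
#' the clustering yields exactly `target_k` domains: too few domains raise
#' the lower bound, too many lower the upper bound. The bounds themselves are
#' probed first. If no visited resolution attains `target_k` within
#' `max_iter` iterations, the run with the closest domain count (ties:
#' smaller resolution) is returned with `inexact = TRUE`.
#'
#' @inheritParams cluster_domains
#' @param target_k requested number of domains (`1 <= target_k <= N`).
#' @param max_iter bisection iterations (default 30).
#' @param res_bounds numeric length-2 search interval (default `c(0.01, 10)`).
#' @return a `domain_result`; `resolution_used` is the selected resolution
#'   and `inexact` flags non-attainment.
#' @export
res_search <- function(embedding, target_k, n_neighbors = 15, seed = 0,
                       max_iter = 30, res_bounds = c(0.01, 10)) {
  embedding <- as.matrix(embedding)
  target_k <- check_count(target_k, "target_k")
  if (target_k > nrow(embedding)) {
    abort(sprintf("target_k (%d) exceeds the number of cells (%d)",
                  target_k, nrow(embedding)))
  }
  stopifnot(length(res_bounds) == 2L, res_bounds[1] > 0,
            res_bounds[2] > res_bounds[1])
  g <- knn_graph(embedding, check_count(n_neighbors, "n_neighbors"))

  best <- NULL
  try_res <- function(res) {
    lab <- leiden_labels(g, res, seed)
    k <- max(lab)
    cand <- list(res = res, lab = lab, k = k)
    if (is.null(best) || abs(k - target_k) < abs(best$k - target_k) ||
        (abs(k - target_k) == abs(best$k - target_k) && res < best$res)) {
      best <<- cand
    }
    cand
  }

  lo <- res_bounds[1]; hi <- res_bounds[2]
  for (res in c(lo, hi)) {
    if (try_res(res)$k == target_k) return(finish_search(best, embedding, seed, n_neighbors, FALSE))
  }
  for (iter in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    got <- try_res(mid)
    if (got$k == target_k) {
      return(finish_search(best, embedding, seed, n_neighbors, FALSE))
    } else if (got$k < target_k) {
      lo <- mid
    } else {
      hi <- mid
    }
  }
  finish_search(best, embedding, seed, n_neighbors, TRUE)
}

finish_search <- function(best, embedding, seed, n_neighbors, inexact) {
  labels <- factor(paste0("D", best$lab - 1L),
                   levels = paste0("D", seq_len(best$k) - 1L))
  new_domain_result(labels, best$res, embedding, seed,
                    params = list(n_neighbors = n_neighbors), inexact = inexact)
}

#' 2-D visualization embedding of the representation
#'
#' UMAP on the reduced representation, for plotting only -- clustering always
#' operates on the neighbor graph of the full embedding, never on these
#' coordinates.
#'
#' @param embedding cells x K matrix (N >= 3).
#' @param seed RNG seed (the layout is deterministic given the seed).
#' @param n_neighbors UMAP neighborhood size (default 15, capped at N - 1).
#' @return N x 2 coordinate matrix.
#' @export
umap_embed <- function(embedding, seed = 0, n_neighbors = 15) {
  embedding <- as.matrix(embedding)
  if (nrow(embedding) < 3L) abort("need at least 3 cells for a 2-D embedding")
  k <- min(n_neighbors, nrow(embedding) - 1L)
  coords <- uwot::umap(embedding, n_neighbors = k, seed = as.integer(seed),
                       init = "spca", n_threads = 1, n_sgd_threads = 0,
                       batch = FALSE)
  colnames(coords) <- c("UMAP1", "UMAP2")
  coords
}

#' Run the full multi-slice domain identification pipeline
#'
#' Orchestrates the whole method: cell states (computed from expression or
#' adopted from an annotation), per-slice multi-range rings, the ring-count
#' context representation, normalization + PCA, joint Leiden clustering
#' (fixed resolution or [res_search()] for a target domain count), and
#' optionally the 2-D visualization. Cells from all slices are clustered
#' together, so a domain label means the same tissue context in every slice.
#'
#' @param ds a [spatial_dataset].
#' @param technology optional technology name passed to [default_params()];
#'   overrides `mode`/`R`/`nn`/`S` when given.
#' @param mode,R,nn,S ring parameters, see [build_rings()].
#' @param states one of: `NULL` (cluster expression via
#'   [preprocess_expression()] + [assign_cell_states()]), the name of a
#'   column of `ds$cells` holding a prior annotation, or a ready
#'   `cell_states` object.
#' @param resolution,target_k exactly one may be non-`NULL`: a fixed Leiden
#'   resolution, or a requested domain count for [res_search()]. If both are
#'   `NULL` the exploratory default `resolution = 0.5` is used. As a
#'   shorthand mirroring a signed-`k` convention, a negative `target_k` is
#'   interpreted as `resolution = abs(target_k)`.
#' @param state_resolution Leiden resolution for the cell-state step
#'   (default 2).
#' @param n_neighbors neighbor-graph size for both clustering steps.
#' @param target_total,n_components normalization/PCA settings for both
#'   embedding steps.
#' @param self_in_first_ring see [build_rings()].
#' @param umap also compute the 2-D visualization coordinates.
#' @param seed master RNG seed for every stochastic stage.
#' @param verbose emit a structured per-stage log with timings.
#' @return a `domain_result` with additional fields: `cells` (tibble
#'   `cell_id`, `slice_id`, `domain`), `representation` (the
#'   `context_representation`), and `states` (the `cell_states` used).
#' @examples
#' \donttest{
#' sim <- generate_layered_tissue(tissue_spec(n_slices = 2, cells_per_layer = 150),
#'                                seed = 1)
#' res <- identify_domains(sim$dataset, states = "truth_state", target_k = 5,
#'                         seed = 1, verbose = FALSE)
#' table(res$labels, sim$dataset$cells$truth_domain)
#' }
#' @export
identify_domains <- function(ds, technology = NULL, mode = "radius", R = 15,
                             nn = 6, S = 6, states = NULL, resolution = NULL,
                             target_k = NULL, state_resolution = 2,
                             n_neighbors = 15, target_total = 1e4,
                             n_components = 50, self_in_first_ring = TRUE,
                             umap = FALSE, seed = 0, verbose = TRUE) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (!is.null(technology)) {
    p <- default_params(technology)
    mode <- p$mode; S <- p$S
    if (mode == "radius") R <- p$R else nn <- p$nn
  }
  if (!is.null(resolution) && !is.null(target_k)) {
    abort("supply exactly one of `resolution` and `target_k`")
  }
  if (!is.null(target_k) && target_k < 0) {
    resolution <- abs(target_k); target_k <- NULL
  }
  if (is.null(resolution) && is.null(target_k)) resolution <- 0.5
  t0 <- as.numeric(Sys.time())

  st <- tryCatch({
    if (inherits(states, "cell_states")) {
      states
    } else if (is.character(states)) {
      set_cell_states(ds, states)
    } else {
      emb <- preprocess_expression(ds, target_total, n_components, seed)
      assign_cell_states(emb, resolution = state_resolution,
                         n_neighbors = n_neighbors, seed = seed)
    }
  }, error = function(e) abort(paste0("cell_states: ", conditionMessage(e))))
  stage_log(verbose, "cell_states", "%d state(s), provenance = %s",
            st$C, st$provenance, t0 = t0)

  cr <- tryCatch({
    ri <- build_rings(ds, mode = mode, R = R, nn = nn, S = S,
                      self_in_first_ring = self_in_first_ring)
    compute_representation(ri, st)
  }, error = function(e) abort(paste0("context: ", conditionMessage(e))))
  stage_log(verbose, "context", "representation %d x %d (mode = %s, S = %d)",
            nrow(cr$M), ncol(cr$M), mode, S, t0 = t0)

  result <- tryCatch({
    emb <- embed_representation(cr, target_total, n_components, seed)
    if (!is.null(target_k)) {
      res_search(emb, target_k, n_neighbors = n_neighbors, seed = seed)
    } else {
      cluster_domains(emb, n_neighbors = n_neighbors, resolution = resolution,
                      seed = seed)
    }
  }, error = function(e) abort(paste0("domains: ", conditionMessage(e))))
  stage_log(verbose, "domains", "%d domain(s) at resolution %.4g%s",
            nlevels(result$labels), result$resolution_used,
            if (isTRUE(result$inexact)) " (inexact)" else "", t0 = t0)

  if (umap) {
    result$umap <- tryCatch(
      umap_embed(result$embedding, seed = seed, n_neighbors = n_neighbors),
      error = function(e) abort(paste0("umap: ", conditionMessage(e))))
    stage_log(verbose, "umap", "2-D visualization computed", t0 = t0)
  }

  result$cells <- tibble(cell_id = ds$cells$cell_id,
                         slice_id = as.character(ds$cells$slice_id),
                         domain = as.character(result$labels))
  result$representation <- cr
  result$states <- st
  result$params <- c(result$params,
                     list(mode = mode, R = R, nn = nn, S = S,
                          state_source = st$provenance,
                          state_resolution = state_resolution,
                          resolution = resolution, target_k = target_k,
                          target_total = target_total,
                          n_components = n_components,
                          self_in_first_ring = self_in_first_ring,
                          seed = seed))
  result
}
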