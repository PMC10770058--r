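#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a domain result into one row per cell
#'
#' @param x a `domain_result`.
#' @param ... unused.
#' @return tibble with `cell_id`/`slice_id` (when the result came from
#'   [identify_domains()]), `domain`, and `UMAP1`/`UMAP2` when computed.
#' @method tidy domain_result
#' @export
tidy.domain_result <- function(x, ...) {
  out <- if (!is.null(x$cells)) {
    dplyr::mutate(x$cells, domain = as.character(x$labels))
  } else {
    tibble(cell = seq_along(x$labels), domain = as.character(x$labels))
  }
  if (!is.null(x$umap)) {
    out$UMAP1 <- x$umap[, 1L]
    out$UMAP2 <- x$umap[, 2L]
  }
  out
}

#' One-row summary of a domain result
#'
#' @param x a `domain_result`.
#' @param ... unused.
#' @return tibble with `n_cells`, `n_domains`, `resolution`, `inexact`,
#'   `seed`.
#' @method glance domain_result
#' @export
glance.domain_result <- function(x, ...) {
  tibble(n_cells = length(x$labels), n_domains = nlevels(x$labels),
         resolution = x$resolution_used, inexact = isTRUE(x$inexact),
         seed = x$seed)
}

#' Tidy a radius report into one row per slice
#'
#' @param x a `radius_report`.
#' @param ... unused.
#' @method tidy radius_report
#' @export
tidy.radius_report <- function(x, ...) x$summary

#' One-row summary of a radius report
#'
#' @param x a `radius_report`.
#' @param ... unused.
#' @method glance radius_report
#' @export
glance.radius_report <- function(x, ...) {
  tibble(n_slices = nrow(x$summary), pooled_median = x$pooled_median,
         recommended_radius = x$recommended_radius)
}

#' Tidy a patient embedding into one row per patient
#'
#' @param x a `patient_embedding`.
#' @param ... unused.
#' @method tidy patient_embedding
#' @export
tidy.patient_embedding <- function(x, ...) {
  out <- dplyr::bind_cols(tibble(patient_id = rownames(x$scores)),
                          as_tibble(as.data.frame(x$scores)))
  if (!is.null(x$groups)) out$group <- as.character(x$groups)
  out
}
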