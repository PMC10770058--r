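#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_boxplot geom_hline
#'   facet_wrap labs theme_minimal scale_size_area coord_equal geom_tile
#' @export
ggplot2::autoplot

#' Plot spatial domain maps per slice
#'
#' @param object a `domain_result` from [identify_domains()] (needs the
#'   attached cell table) or any result paired with `ds`.
#' @param ds the [spatial_dataset] providing coordinates (required).
#' @param point_size dot size.
#' @param ... unused.
#' @return a ggplot: one panel per slice, cells colored by domain.
#' @method autoplot domain_result
#' @export
autoplot.domain_result <- function(object, ds, point_size = 0.6, ...) {
  xy <- coords_um(ds)
  df <- tibble(x = xy[, 1L], y = xy[, 2L],
               slice = as.character(ds$cells$slice_id),
               domain = object$labels)
  ggplot(df, aes(x = .data$x, y = .data$y, colour = .data$domain)) +
    geom_point(size = point_size) +
    facet_wrap(~slice) +
    coord_equal() +
    labs(x = "x (um)", y = "y (um)", colour = "domain") +
    theme_minimal()
}

#' Plot the 2-D visualization embedding colored by domain
#'
#' @param result a `domain_result` with `umap` coordinates (run
#'   [identify_domains()] with `umap = TRUE` or [umap_embed()]).
#' @param point_size dot size.
#' @return a ggplot.
#' @export
plot_embedding <- function(result, point_size = 0.6) {
  if (is.null(result$umap)) abort("no 2-D coordinates; compute them with umap_embed()")
  df <- tibble(UMAP1 = result$umap[, 1L], UMAP2 = result$umap[, 2L],
               domain = result$labels)
  ggplot(df, aes(x = .data$UMAP1, y = .data$UMAP2, colour = .data$domain)) +
    geom_point(size = point_size) +
    theme_minimal()
}

#' Boxplot of per-slice nearest-neighbor distances
#'
#' @param object a `radius_report` from [estimate_radius()].
#' @param ... unused.
#' @return a ggplot with the recommended radius marked.
#' @method autoplot radius_report
#' @export
autoplot.radius_report <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(names(object$distances), function(sl) {
    tibble(slice = sl, distance = object$distances[[sl]])
  }))
  ggplot(df, aes(x = .data$slice, y = .data$distance)) +
    geom_boxplot(outlier.size = 0.4) +
    geom_hline(yintercept = object$recommended_radius, linetype = "dashed") +
    labs(y = "1-NN distance (um)",
         title = sprintf("recommended radius: %.1f um", object$recommended_radius)) +
    theme_minimal()
}

#' Dot-plot of domain spatial signatures
#'
#' Rows are (cell state, ring) features of the context representation, one
#' panel column layout per domain: dot size is the fraction of the domain's
#' cells with a nonzero count for the feature, color the mean count.
#'
#' @param object a `signature_table` from [rank_signatures()].
#' @param cr the `context_representation` the signatures were computed on.
#' @param domains the per-cell domain labels used.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot signature_table
#' @export
autoplot.signature_table <- function(object, cr, domains, ...) {
  M <- as.matrix(cr$M)
  domains <- as_label_factor(domains)
  feats <- unique(object$column)
  df <- dplyr::bind_rows(lapply(levels(domains), function(d) {
    in_d <- domains == d
    tibble(domain = d,
           feature = paste0(cr$column_map$state[feats], " r",
                            cr$column_map$range[feats]),
           frac_nonzero = colMeans(M[in_d, feats, drop = FALSE] > 0),
           mean_count = colMeans(M[in_d, feats, drop = FALSE]))
  }))
  ggplot(df, aes(x = .data$domain, y = .data$feature,
                 size = .data$frac_nonzero, colour = .data$mean_count)) +
    geom_point() +
    scale_size_area(max_size = 6) +
    labs(size = "fraction > 0", colour = "mean count") +
    theme_minimal()
}

#' Scatter plot of the patient embedding
#'
#' @param object a `patient_embedding` from [embed_patients()].
#' @param ... unused.
#' @return a ggplot of the first two components, colored by group when
#'   available.
#' @method autoplot patient_embedding
#' @export
autoplot.patient_embedding <- function(object, ...) {
  df <- tidy.patient_embedding(object)
  mapping <- if (!is.null(object$groups)) {
    aes(x = .data$PC1, y = .data$PC2, colour = .data$group)
  } else {
    aes(x = .data$PC1, y = .data$PC2)
  }
  ggplot(df, mapping) + geom_point(size = 2) + theme_minimal()
}
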