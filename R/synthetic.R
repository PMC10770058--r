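# ---- synthetic layered tissues ----------------------------------------------

#' Specify a synthetic layered tissue
#'
#' Describes a multi-slice tissue of ordered horizontal layers (the planted
#' spatial domains), each with its own cell-state composition, and a
#' per-state expression model. The defaults emulate a laminar tissue at
#' single-cell spatial resolution: 3 slices, 5 stacked layers of 400 cells
#' each (2000 cells/slice), layers 408 um thick (the scale of cortical
#' laminae) and 1000 um wide so the median nearest-neighbor spacing is about
#' 15 um, and each layer dominated by its own cell states (70% dominant
#' state, a laminar organization with sharp boundaries).
#'
#' @param n_slices number of tissue sections (default 3).
#' @param n_layers number of stacked layers = planted domains (default 5).
#' @param layer_height layer thickness in um (default 408).
#' @param width slice width in um (default 1000; with the default cell
#'   counts this gives a density whose median 1-NN distance is ~15 um).
#' @param cells_per_layer exact cells per layer per slice (default 400), or
#'   `NULL` to draw Poisson counts from `density`.
#' @param density cells per um^2 when `cells_per_layer = NULL`.
#' @param composition layers x states matrix, rows summing to 1; default a
#'   5 x 6 laminar design with one dominant state per layer.
#' @param state_means states x genes nonnegative mean expression matrix;
#'   default gives each state a 5-gene block at mean 10 over a 0.5 baseline
#'   (30 genes).
#' @param expression_model `"poisson"` or `"nb"` (negative binomial with
#'   `dispersion` = size parameter).
#' @param dispersion NB size parameter (default 2; ignored for Poisson).
#' @param jitter standard deviation of Gaussian coordinate jitter in um
#'   (default 0).
#' @return a `tissue_spec` list, validated.
#' @export
tissue_spec <- function(n_slices = 3, n_layers = 5, layer_height = 408,
                        width = 1000, cells_per_layer = 400, density = NULL,
                        composition = NULL, state_means = NULL,
                        expression_model = c("poisson", "nb"), dispersion = 2,
                        jitter = 0) {
  expression_model <- match.arg(expression_model)
  n_slices <- check_count(n_slices, "n_slices")
  n_layers <- check_count(n_layers, "n_layers")
  check_number(layer_height, "layer_height", lower = .Machine$double.eps)
  check_number(width, "width", lower = .Machine$double.eps)
  if (is.null(cells_per_layer) && is.null(density)) {
    abort("give either `cells_per_layer` or `density`")
  }
  if (!is.null(cells_per_layer)) cells_per_layer <- check_count(cells_per_layer, "cells_per_layer")
  if (!is.null(density)) check_number(density, "density", lower = .Machine$double.eps)

  if (is.null(composition)) {
    composition <- default_composition(n_layers)
  }
  composition <- as.matrix(composition)
  if (nrow(composition) != n_layers) {
    abort(sprintf("composition has %d rows for %d layers", nrow(composition), n_layers))
  }
  if (any(composition < 0) || any(abs(rowSums(composition) - 1) > 1e-8)) {
    abort("composition rows must be nonnegative and sum to 1")
  }
  n_states <- ncol(composition)
  if (is.null(state_means)) state_means <- default_state_means(n_states)
  state_means <- as.matrix(state_means)
  if (nrow(state_means) != n_states) {
    abort(sprintf("state_means has %d rows for %d states", nrow(state_means), n_states))
  }
  if (any(state_means < 0)) abort("state_means must be nonnegative")
  check_number(jitter, "jitter", lower = 0)

  structure(list(n_slices = n_slices, n_layers = n_layers,
                 layer_height = layer_height, width = width,
                 cells_per_layer = cells_per_layer, density = density,
                 composition = composition, state_means = state_means,
                 expression_model = expression_model, dispersion = dispersion,
                 jitter = jitter),
            class = "tissue_spec")
}

# one dominant state per layer (70/10 with a 5% floor); the last layer gets
# two co-dominant states when layers outnumber states
default_composition <- function(n_layers) {
  n_states <- max(4L, min(n_layers + 1L, 6L))
  comp <- matrix(0.05, n_layers, n_states)
  for (l in seq_len(n_layers)) {
    dom <- ((l - 1L) %% n_states) + 1L
    sub <- (dom %% n_states) + 1L
    comp[l, dom] <- comp[l, dom] + 0.65
    comp[l, sub] <- comp[l, sub] + 0.05
  }
  comp / rowSums(comp)
}

# block-marker means: state c is high on its own 5-gene block
default_state_means <- function(n_states, genes_per_state = 5L,
                                high = 10, baseline = 0.5) {
  G <- n_states * genes_per_state
  mu <- matrix(baseline, n_states, G)
  for (c in seq_len(n_states)) {
    mu[c, (c - 1L) * genes_per_state + seq_len(genes_per_state)] <- high
  }
  colnames(mu) <- paste0("gene", seq_len(G))
  mu
}

#' Generate a multi-slice layered tissue
#'
#' Scatters cells uniformly within each layer of each slice, draws each
#' cell's state from its layer's composition row, and draws expression
#' counts from the state's mean vector under the chosen noise model. All
#' randomness flows from `seed`; identical spec + seed reproduce the dataset
#' exactly.
#'
#' @param spec a [tissue_spec()].
#' @param seed RNG seed.
#' @return list with `dataset` (a [spatial_dataset] whose cell table carries
#'   `truth_domain` = `L1..` and `truth_state` = `g1..`), and `truth`
#'   (tibble `cell_id`, `slice_id`, `domain`, `state`).
#' @export
generate_layered_tissue <- function(spec, seed = 0) {
  stopifnot(inherits(spec, "tissue_spec"))
  C <- ncol(spec$composition)
  G <- ncol(spec$state_means)

  with_seed(seed, {
    rows <- list()
    for (sl in seq_len(spec$n_slices)) {
      for (l in seq_len(spec$n_layers)) {
        n_cells <- if (!is.null(spec$cells_per_layer)) {
          spec$cells_per_layer
        } else {
          rpois(1L, spec$density * spec$width * spec$layer_height)
        }
        if (n_cells == 0L) {
          abort(sprintf("layer %d of slice %d has an expected cell count of 0", l, sl))
        }
        x <- runif(n_cells, 0, spec$width)
        y <- runif(n_cells, (l - 1) * spec$layer_height, l * spec$layer_height)
        state <- sample.int(C, n_cells, replace = TRUE, prob = spec$composition[l, ])
        rows[[length(rows) + 1L]] <- tibble(
          slice = paste0("slice", sl), layer = paste0("L", l),
          x = x, y = y, state = state)
      }
    }
    cells <- dplyr::bind_rows(rows)
    if (spec$jitter > 0) {
      cells$x <- cells$x + stats::rnorm(nrow(cells), 0, spec$jitter)
      cells$y <- cells$y + stats::rnorm(nrow(cells), 0, spec$jitter)
    }
    mu <- spec$state_means[cells$state, , drop = FALSE]
    expr <- if (spec$expression_model == "poisson") {
      matrix(rpois(length(mu), as.vector(mu)), nrow(mu), G)
    } else {
      matrix(rnbinom(length(mu), size = spec$dispersion, mu = as.vector(mu)),
             nrow(mu), G)
    }
    colnames(expr) <- colnames(spec$state_means)

    ds <- spatial_dataset(
      expression = expr,
      coordinates = cbind(cells$x, cells$y),
      slice_id = cells$slice,
      cell_meta = tibble(truth_domain = cells$layer,
                         truth_state = paste0("g", cells$state)))
    list(dataset = ds,
         truth = tibble(cell_id = ds$cells$cell_id,
                        slice_id = cells$slice,
                        domain = cells$layer,
                        state = paste0("g", cells$state)))
  })
}

#' Homogeneous planar Poisson point process
#'
#' Draws `Poisson(intensity * area)` points uniformly in a rectangular
#' window. The median nearest-neighbor distance of this process is
#' `sqrt(log(2) / (pi * intensity))` in closed form, which makes it the
#' reference fixture for calibrating [estimate_radius()].
#'
#' @param intensity points per um^2.
#' @param window rectangle `c(xmin, xmax, ymin, ymax)` (default the unit
#'   1000 x 1000 um window).
#' @param seed RNG seed.
#' @return tibble with columns `x`, `y`.
#' @export
generate_poisson_points <- function(intensity, window = c(0, 1000, 0, 1000),
                                    seed = 0) {
  check_number(intensity, "intensity", lower = .Machine$double.eps)
  stopifnot(length(window) == 4L, window[2] > window[1], window[4] > window[3])
  area <- (window[2] - window[1]) * (window[4] - window[3])
  with_seed(seed, {
    n <- rpois(1L, intensity * area)
    tibble(x = runif(n, window[1], window[2]),
           y = runif(n, window[3], window[4]))
  })
}

#' Generate a synthetic patient cohort from group-level label profiles
#'
#' Each group has a mean label-proportion profile; each patient draws their
#' own proportion vector from a Dirichlet centered on that profile
#' (`alpha = concentration * profile`, so larger concentration means
#' patients hug the group mean), then draws cell labels multinomially.
#'
#' @param groups a data frame (or tibble) with columns `group`,
#'   `n_patients`, `profile` (list-column of named numeric proportion
#'   vectors over a shared label vocabulary), and `concentration`
#'   (positive Dirichlet concentration).
#' @param cells_per_patient cells drawn per patient (default 500).
#' @param seed RNG seed.
#' @return list with `cells` (tibble `patient_id`, `group`, `label`) and
#'   `patients` (tibble `patient_id`, `group`).
#' @export
generate_patient_cohort <- function(groups, cells_per_patient = 500, seed = 0) {
  groups <- as_tibble(groups)
  stopifnot(all(c("group", "n_patients", "profile", "concentration") %in% names(groups)))
  if (any(groups$concentration <= 0)) abort("`concentration` must be positive")
  labels <- unique(unlist(lapply(groups$profile, names)))
  if (is.null(labels)) abort("profiles must be named numeric vectors")
  cells_per_patient <- check_count(cells_per_patient, "cells_per_patient")

  with_seed(seed, {
    cells <- list(); patients <- list()
    pid <- 0L
    for (g in seq_len(nrow(groups))) {
      prof <- rep(0, length(labels)); names(prof) <- labels
      prof[names(groups$profile[[g]])] <- groups$profile[[g]]
      prof <- prof / sum(prof)
      for (i in seq_len(groups$n_patients[g])) {
        pid <- pid + 1L
        id <- sprintf("P%03d", pid)
        alpha <- groups$concentration[g] * prof
        draw <- rgamma(length(alpha), shape = alpha)  # shape 0 -> exactly 0
        if (sum(draw) == 0) draw <- prof
        prop <- draw / sum(draw)
        lab <- sample(labels, cells_per_patient, replace = TRUE, prob = prop)
        cells[[pid]] <- tibble(patient_id = id, group = groups$group[g], label = lab)
        patients[[pid]] <- tibble(patient_id = id, group = groups$group[g])
      }
    }
    list(cells = dplyr::bind_rows(cells), patients = dplyr::bind_rows(patients))
  })
}
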