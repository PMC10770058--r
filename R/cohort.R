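# ---- patient-level representations and stratification ----------------------

#' Represent each patient by their label proportions
#'
#' Row `p`, column `l` is the fraction of patient `p`'s cells carrying label
#' `l` (spatial domain, or a cell-type annotation at any granularity). The
#' label vocabulary is global across the cohort, so rows are directly
#' comparable and each row sums to 1.
#'
#' @param cell_labels per-cell labels (e.g. `domain_result$labels`).
#' @param patient_id per-cell patient identifier, same length.
#' @param source label provenance tag: `"domain"`, `"cell_type_fine"`,
#'   `"cell_type_coarse"`, or any string.
#' @return a `cohort_representation`: `proportions` (patients x labels
#'   matrix), `patients`, `labels`, `source`.
#' @export
patient_representation <- function(cell_labels, patient_id, source = "domain") {
  if (length(cell_labels) != length(patient_id)) {
    abort(sprintf("cell_labels length %d but patient_id length %d",
                  length(cell_labels), length(patient_id)))
  }
  lab <- as_label_factor(cell_labels)
  pat <- if (is.factor(patient_id)) patient_id else factor(patient_id, levels = unique(patient_id))
  empty <- levels(pat)[tabulate(pat, nlevels(pat)) == 0L]
  if (length(empty)) {
    warn(sprintf("patient(s) with no cells excluded: %s", paste(empty, collapse = ", ")))
    pat <- droplevels(pat)
  }
  counts <- table(pat, lab)
  prop <- counts / rowSums(counts)
  prop <- matrix(prop, nrow = nrow(counts),
                 dimnames = list(rownames(counts), colnames(counts)))
  structure(list(proportions = prop, patients = rownames(prop),
                 labels = colnames(prop), source = source),
            class = "cohort_representation")
}

#' @export
print.cohort_representation <- function(x, ...) {
  cat(sprintf("<cohort_representation> %d patient(s) x %d label(s), source = %s\n",
              nrow(x$proportions), ncol(x$proportions), x$source))
  invisible(x)
}

#' @method as_tibble cohort_representation
#' @export
as_tibble.cohort_representation <- function(x, ...) {
  dplyr::bind_cols(tibble(patient_id = x$patients),
                   as_tibble(as.data.frame(x$proportions)))
}

#' Unsupervised embedding of a patient cohort
#'
#' Centered PCA of the proportion matrix, mapping each patient into a
#' low-dimensional space. When group labels are supplied, each top component
#' is tested for group separation with two-sided one-vs-rest two-sample
#' t-tests (groups with fewer than 2 patients, or zero-variance components,
#' are skipped with a warning).
#'
#' @param repr a `cohort_representation`.
#' @param groups optional per-patient group labels (aligned with
#'   `repr$patients`).
#' @param n_components components to keep (default 2).
#' @param seed recorded; the projection is deterministic up to the fixed
#'   sign convention.
#' @return a `patient_embedding`: `scores` (patients x components),
#'   `variance` (per-component variance share), `tests` (tibble `component`,
#'   `group`, `statistic`, `p_value`), `groups`.
#' @export
embed_patients <- function(repr, groups = NULL, n_components = 2, seed = 0) {
  stopifnot(inherits(repr, "cohort_representation"))
  X <- repr$proportions
  if (nrow(X) < 3L) abort("need at least 3 patients")
  if (all(apply(X, 2L, function(col) max(col) - min(col)) < 1e-12)) {
    warn("all patients identical: scores are zero and group tests are skipped")
    k <- min(n_components, ncol(X))
    scores <- matrix(0, nrow(X), k,
                     dimnames = list(repr$patients, paste0("PC", seq_len(k))))
    return(structure(list(scores = scores, variance = rep(0, k),
                          tests = empty_tests(), groups = groups),
                     class = "patient_embedding"))
  }
  scores <- pca_project(X, check_count(n_components, "n_components"))
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  var_share <- (p$sdev^2 / sum(p$sdev^2))[seq_len(ncol(scores))]

  tests <- empty_tests()
  if (!is.null(groups)) {
    groups <- as_label_factor(groups)
    if (length(groups) != nrow(X)) {
      abort("`groups` must have one entry per patient")
    }
    sizes <- tabulate(groups, nlevels(groups))
    skip <- sizes < 2L | (length(groups) - sizes) < 2L
    for (g in levels(groups)[skip]) {
      warn(sprintf("group '%s' too small for a one-vs-rest t-test; skipped", g))
    }
    for (j in seq_len(ncol(scores))) {
      for (g in levels(groups)[!skip]) {
        in_g <- groups == g
        if (sd(scores[in_g, j]) == 0 && sd(scores[!in_g, j]) == 0) next
        tt <- t.test(scores[in_g, j], scores[!in_g, j])
        tests <- dplyr::bind_rows(tests, tibble(
          component = colnames(scores)[j], group = g,
          statistic = unname(tt$statistic), p_value = tt$p.value))
      }
    }
  }
  structure(list(scores = scores, variance = var_share, tests = tests,
                 groups = groups),
            class = "patient_embedding")
}

empty_tests <- function() {
  tibble(component = character(), group = character(),
         statistic = numeric(), p_value = numeric())
}

#' @export
print.patient_embedding <- function(x, ...) {
  cat(sprintf("<patient_embedding> %d patient(s), %d component(s)\n",
              nrow(x$scores), ncol(x$scores)))
  if (nrow(x$tests)) print(x$tests)
  invisible(x)
}

#' Cross-validated classification of patient groups
#'
#' Stratified k-fold cross-validation of a pluggable classifier on the
#' proportion representation. When `n_pcs` is given, features are the top
#' principal components fitted on each training fold only and the held-out
#' patients are projected into that fold's space -- the test fold never
#' influences the projection.
#'
#' @param repr a `cohort_representation` (or a plain patients x features
#'   matrix).
#' @param groups per-patient group labels.
#' @param classifier a list with `fit(X, y) -> model` and
#'   `predict(model, X) -> labels`; see [knn_classifier()] and
#'   [svm_classifier()].
#' @param folds folds for stratified cross-validation (default 5).
#' @param repeats independent shuffles of the fold assignment (default 1).
#' @param n_pcs optional number of fold-fitted principal components.
#' @param seed RNG seed for fold assignment (and any stochastic classifier).
#' @return list with `mean_accuracy` and `fold_accuracies` (tibble `rep`,
#'   `fold`, `accuracy`).
#' @export
classify_patients <- function(repr, groups, classifier = knn_classifier(),
                              folds = 5, repeats = 1, n_pcs = NULL, seed = 0) {
  X <- if (inherits(repr, "cohort_representation")) repr$proportions else as.matrix(repr)
  groups <- as_label_factor(groups)
  if (length(groups) != nrow(X)) abort("`groups` must have one entry per patient")
  folds <- check_count(folds, "folds", lower = 2L)
  small <- levels(groups)[tabulate(groups, nlevels(groups)) < folds]
  if (length(small)) {
    abort(sprintf("group(s) smaller than %d folds: %s; use fewer folds",
                  folds, paste(small, collapse = ", ")))
  }
  stopifnot(is.list(classifier), is.function(classifier$fit),
            is.function(classifier$predict))

  rows <- list()
  for (r in seq_len(check_count(repeats, "repeats"))) {
    assign <- with_seed(seed + r - 1L, stratified_folds(groups, folds))
    for (f in seq_len(folds)) {
      test <- assign == f
      Xtr <- X[!test, , drop = FALSE]; Xte <- X[test, , drop = FALSE]
      if (!is.null(n_pcs)) {
        ctr <- colMeans(Xtr)
        p <- prcomp(Xtr, center = TRUE, scale. = FALSE)
        k <- min(n_pcs, ncol(p$rotation))
        rot <- p$rotation[, seq_len(k), drop = FALSE]
        Xte <- sweep(Xte, 2L, ctr) %*% rot
        Xtr <- p$x[, seq_len(k), drop = FALSE]
      }
      model <- with_seed(seed + 1000L * r + f,
                         classifier$fit(Xtr, groups[!test]))
      pred <- with_seed(seed + 1000L * r + f,
                        classifier$predict(model, Xte))
      rows[[length(rows) + 1L]] <- tibble(
        rep = r, fold = f,
        accuracy = mean(as.character(pred) == as.character(groups[test])))
    }
  }
  fold_acc <- dplyr::bind_rows(rows)
  list(mean_accuracy = mean(fold_acc$accuracy), fold_accuracies = fold_acc)
}

# round-robin fold labels within each group, after a seeded shuffle
stratified_folds <- function(groups, folds) {
  assign <- integer(length(groups))
  for (g in levels(groups)) {
    idx <- sample(which(groups == g))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' k-nearest-neighbor classifier contract
#'
#' @param k neighbors (default 5).
#' @return a `fit`/`predict` list for [classify_patients()].
#' @export
knn_classifier <- function(k = 5) {
  if (!requireNamespace("class", quietly = TRUE)) {
    abort("the 'class' package is required for knn_classifier()")
  }
  list(
    fit = function(X, y) list(X = X, y = y, k = min(k, nrow(X))),
    predict = function(model, X) {
      class::knn(model$X, X, model$y, k = model$k)
    })
}

#' Support-vector-machine classifier contract
#'
#' @param ... passed to [e1071::svm()] (e.g. `kernel`, `cost`).
#' @return a `fit`/`predict` list for [classify_patients()].
#' @export
svm_classifier <- function(...) {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    abort("the 'e1071' package is required for svm_classifier()")
  }
  args <- list(...)
  list(
    fit = function(X, y) do.call(e1071::svm, c(list(x = X, y = y), args)),
    predict = function(model, X) predict(model, X))
}
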