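# ---- clustering evaluation metrics ------------------------------------------

# contingency table of two labelings after dropping masked (NA) positions
label_pair <- function(P, T_, mask = NULL) {
  if (length(P) != length(T_)) {
    abort(sprintf("label vectors differ in length: %d vs %d", length(P), length(T_)))
  }
  keep <- !(is.na(P) | is.na(T_))
  if (!is.null(mask)) keep <- keep & !mask
  if (!any(keep)) abort("no cells left to score after masking")
  list(P = as_label_factor(P[keep]), T_ = as_label_factor(T_[keep]))
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information between two labelings
#'
#' `NMI = MI(P, T) / sqrt(H(P) * H(T))` with entropies and mutual information
#' computed from the empirical contingency table in natural log (the log base
#' cancels in the ratio). Invariant to relabeling either side. When one side
#' has zero entropy (a single cluster), the value is 1 if both partitions are
#' identical as set partitions and 0 otherwise.
#'
#' @param P,T predicted and reference labels (any vectors/factors of equal
#'   length). `NA` positions on either side are excluded.
#' @param mask optional logical vector; `TRUE` cells are excluded.
#' @return number in \[0, 1\].
#' @export
nmi <- function(P, T, mask = NULL) {
  lp <- label_pair(P, T, mask)
  tab <- table(lp$P, lp$T_)
  n <- sum(tab)
  pi <- rowSums(tab) / n
  pj <- colSums(tab) / n
  hp <- entropy_nat(pi)
  ht <- entropy_nat(pj)
  if (hp == 0 || ht == 0) {
    same <- nmi_same_partition(lp$P, lp$T_)
    return(if (same) 1 else 0)
  }
  pij <- tab / n
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi, pj)[nz]))
  max(0, min(1, mi / sqrt(hp * ht)))
}

nmi_same_partition <- function(P, T_) {
  identical(as.integer(factor(as.integer(P), levels = unique(as.integer(P)))),
            as.integer(factor(as.integer(T_), levels = unique(as.integer(T_)))))
}

#' Adjusted Rand index between two labelings
#'
#' Pair-counting partition agreement with the expected-index correction:
#' `ARI = (Index - E[Index]) / (Max - E[Index])`. Equals 1 iff the partitions
#' are identical; near 0 for independent labelings; can be negative.
#'
#' @inheritParams nmi
#' @return number in (-1, 1\].
#' @export
ari <- function(P, T, mask = NULL) {
  lp <- label_pair(P, T, mask)
  n <- length(lp$P)
  if (n < 2L) abort("ARI needs at least 2 cells")
  tab <- table(lp$P, lp$T_)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  total <- comb2(n)
  expected <- sum_i * sum_j / total
  maximum <- (sum_i + sum_j) / 2
  if (maximum == expected) return(1)  # both sides single-cluster or all-singletons
  (sum_ij - expected) / (maximum - expected)
}

#' Percentage of abnormal spots (spatial continuity of a labeling)
#'
#' A cell is abnormal when its label differs from at least `threshold` of its
#' `k` nearest same-slice cells (self excluded; distance ties broken by cell
#' index). PAS is the abnormal fraction over all cells; lower means smoother
#' domains. Slices with fewer than `k + 1` cells fall back to
#' `k_eff = n - 1` neighbors with a proportionally rescaled threshold
#' (`ceiling(threshold * k_eff / k)`), with a warning.
#'
#' @param labels per-cell labels.
#' @param coordinates N x D coordinate matrix.
#' @param slice_id per-cell slice identifier (default: one slice).
#' @param k neighbors to inspect (default 10).
#' @param threshold disagreements that make a cell abnormal (default 6).
#' @return number in \[0, 1\].
#' @export
pas <- function(labels, coordinates, slice_id = NULL, k = 10, threshold = 6) {
  coordinates <- as.matrix(coordinates)
  n <- nrow(coordinates)
  if (length(labels) != n) {
    abort(sprintf("labels length %d but %d coordinate rows", length(labels), n))
  }
  slice_id <- if (is.null(slice_id)) factor(rep("slice", n)) else as_label_factor(slice_id)
  k <- check_count(k, "k")
  threshold <- check_count(threshold, "threshold")
  lab <- as.integer(as_label_factor(labels))

  abnormal <- 0L
  for (sl in levels(slice_id)) {
    idx <- which(slice_id == sl)
    n_sl <- length(idx)
    if (n_sl < 2L) next
    k_eff <- min(k, n_sl - 1L)
    thr_eff <- if (k_eff < k) {
      warn(sprintf("slice '%s' has %d cells; using k = %d with threshold %d",
                   sl, n_sl, k_eff, as.integer(ceiling(threshold * k_eff / k))))
      as.integer(ceiling(threshold * k_eff / k))
    } else {
      threshold
    }
    nbr <- knn_by_index(coordinates[idx, , drop = FALSE], k_eff)
    diff_counts <- rowSums(matrix(lab[idx][nbr], nrow = n_sl) != lab[idx])
    abnormal <- abnormal + sum(diff_counts >= thr_eff)
  }
  abnormal / n
}

# exact k nearest neighbors with deterministic tie-breaking by index.
# Returns an n x k matrix of within-slice neighbor indices (self excluded).
knn_by_index <- function(xy, k, chunk = 512L) {
  n <- nrow(xy)
  out <- matrix(0L, n, k)
  sq <- rowSums(xy^2)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[rows], sq, `+`) - 2 * tcrossprod(xy[rows, , drop = FALSE], xy)
    for (r in seq_along(rows)) {
      i <- rows[r]
      d <- d2[r, ]
      d[i] <- Inf  # self excluded
      ord <- order(d, seq_len(n))  # stable: ties resolved by cell index
      out[i, ] <- ord[seq_len(k)]
    }
  }
  out
}

#' Per-slice and joint evaluation table
#'
#' One row per slice with NMI and ARI against the reference labels and the
#' PAS of the prediction, plus a pooled `"joint"` row over all cells. In a
#' joint multi-slice clustering the per-slice rows show whether shared labels
#' hold up within each section.
#'
#' @param pred per-cell predicted labels (or a `domain_result`).
#' @param truth per-cell reference labels (`NA` = unscored).
#' @param ds the [spatial_dataset()] providing coordinates and slice IDs.
#' @param k,threshold PAS parameters.
#' @return tibble with columns `slice`, `n`, `nmi`, `ari`, `pas`.
#' @export
per_slice_metrics <- function(pred, truth, ds, k = 10, threshold = 6) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (inherits(pred, "domain_result")) pred <- pred$labels
  slice <- ds$cells$slice_id
  xy <- coords_um(ds)
  rows <- lapply(levels(slice), function(sl) {
    i <- which(slice == sl)
    tibble(slice = sl, n = length(i),
           nmi = nmi(pred[i], truth[i]),
           ari = ari(pred[i], truth[i]),
           pas = pas(pred[i], xy[i, , drop = FALSE], k = k, threshold = threshold))
  })
  joint_pas <- pas(pred, xy, slice, k = k, threshold = threshold)
  joint <- tibble(slice = "joint", n = length(pred),
                  nmi = nmi(pred, truth), ari = ari(pred, truth),
                  pas = joint_pas)
  dplyr::bind_rows(c(rows, list(joint)))
}
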