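# ---- spatial signatures: what (state, range) features define each domain ---

#' Rank (cell state, range) features that characterize each domain
#'
#' One-vs-rest Wilcoxon rank-sum tests of every representation column for
#' every domain. The score is the signed standardized rank-sum statistic
#' (tie-corrected, continuity-corrected; positive means enriched in the
#' domain), so rankings are invariant to positive rescaling of the counts.
#' P-values come from `stats::wilcox.test`: exact when both groups are small
#' and tie-free, otherwise the normal approximation with continuity
#' correction. Benjamini-Hochberg adjustment is applied across features
#' within each domain.
#'
#' Because each column of the representation is a (cell state, ring) count,
#' a domain's top features read directly as spatial organization: "state g3
#' in ring 2" means the domain is defined by having that state at that
#' distance from its cells.
#'
#' @param cr a `context_representation` (or any numeric matrix whose columns
#'   are features; then `column_map` metadata is omitted).
#' @param domains per-cell domain labels (or a `domain_result`).
#' @param n_top features kept per domain, by descending score (default 5;
#'   `Inf` keeps all).
#' @param adjust `"BH"` (default) or `"none"`.
#' @return a `signature_table` tibble: `domain`, `column`, `state`, `range`,
#'   `statistic` (rank-sum W of domain vs rest), `score`, `p_value`,
#'   `p_adjusted`, `mean_in`, `mean_out`, `rank`.
#' @export
rank_signatures <- function(cr, domains, n_top = 5, adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  if (inherits(domains, "domain_result")) domains <- domains$labels
  if (inherits(cr, "context_representation")) {
    M <- as.matrix(cr$M)
    column_map <- cr$column_map
  } else {
    M <- as.matrix(cr)
    column_map <- tibble(column = seq_len(ncol(M)),
                         range = NA_integer_, state = NA_character_)
  }
  domains <- as_label_factor(domains)
  if (length(domains) != nrow(M)) {
    abort(sprintf("domains length %d but representation has %d rows",
                  length(domains), nrow(M)))
  }
  if (nlevels(domains) < 2L) abort("need at least 2 domains to contrast")

  out <- list()
  for (d in levels(domains)) {
    in_d <- domains == d
    if (sum(in_d) < 2L) {
      warn(sprintf("domain '%s' has fewer than 2 cells; skipped", d))
      next
    }
    stats_d <- vapply(seq_len(ncol(M)), function(j) {
      wilcox_feature(M[in_d, j], M[!in_d, j])
    }, numeric(3))
    p_adj <- if (adjust == "BH") p.adjust(stats_d[3L, ], "BH") else stats_d[3L, ]
    tab <- tibble(domain = d,
                  column = column_map$column,
                  state = column_map$state,
                  range = column_map$range,
                  statistic = stats_d[1L, ],
                  score = stats_d[2L, ],
                  p_value = stats_d[3L, ],
                  p_adjusted = p_adj,
                  mean_in = colMeans(M[in_d, , drop = FALSE]),
                  mean_out = colMeans(M[!in_d, , drop = FALSE]))
    tab <- dplyr::arrange(tab, dplyr::desc(.data$score), .data$column)
    tab$rank <- seq_len(nrow(tab))
    out[[d]] <- head(tab, n_top)
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("signature_table", class(res))
  res
}

# rank-sum statistic W, tie/continuity-corrected signed z, and p-value for
# one feature, domain (x) vs rest (y)
wilcox_feature <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U of x over y
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(c(W = W, score = 0, p = 1))
  cc <- sign(W - mu) * 0.5  # continuity correction toward the null
  z <- (W - mu - cc) / sqrt(sigma2)
  p <- if (!any(duplicated(c(x, y))) && n < 50) {
    wilcox.test(x, y, exact = TRUE)$p.value
  } else {
    min(1, 2 * pnorm(-abs(z)))
  }
  c(W = W, score = z, p = p)
}

#' @export
print.signature_table <- function(x, ...) {
  cat(sprintf("<signature_table> top features for %d domain(s)\n",
              length(unique(x$domain))))
  NextMethod()
}
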