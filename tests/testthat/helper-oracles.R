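# Independent oracles: deliberately naive implementations used only to check
# the package's optimized paths.

# Literal O(N^2) ring-count representation: loop over ordered pairs applying
# the half-open annulus rule within each slice.
oracle_representation <- function(xy, slice, states_int, C, R, S,
                                  self_in_first_ring = TRUE) {
  n <- nrow(xy)
  M <- matrix(0L, n, S * C)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (slice[j] != slice[i]) next
      if (!self_in_first_ring && i == j) next
      d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
      s <- floor(d / R) + 1
      if (d >= S * R) next
      col <- (s - 1) * C + states_int[j]
      M[i, col] <- M[i, col] + 1L
    }
  }
  M
}

# Textbook NMI via the joint-entropy identity MI = H(P) + H(T) - H(P,T)
# (a different algebraic route than the package's direct MI sum).
nmi_textbook <- function(P, T_) {
  tab <- table(P, T_)
  n <- sum(tab)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hp <- H(rowSums(tab) / n)
  ht <- H(colSums(tab) / n)
  hpt <- H(as.vector(tab) / n)
  mi <- hp + ht - hpt
  mi / sqrt(hp * ht)
}

# Exact two-sided rank-sum p-value by enumerating all group assignments of
# the pooled sample (tie-free inputs only).
wilcox_exact_enum <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# small helper datasets -------------------------------------------------------

grid_dataset <- function(nx = 10, ny = 10, spacing = 1) {
  g <- expand.grid(x = seq_len(nx) * spacing, y = seq_len(ny) * spacing)
  spatial_dataset(matrix(1, nrow(g), 2), as.matrix(g),
                  slice_id = rep("s1", nrow(g)))
}

random_dataset <- function(n = 50, g = 5, n_slices = 1, seed = 1,
                           extent = 100) {
  set.seed(seed)
  spatial_dataset(matrix(rpois(n * g, 3), n, g),
                  cbind(runif(n, 0, extent), runif(n, 0, extent)),
                  slice_id = sample(paste0("s", seq_len(n_slices)), n,
                                    replace = TRUE))
}

# k well-separated Gaussian clouds in 2-D (for clustering contracts)
cloud_embedding <- function(k, n_per = 60, sep = 100, seed = 1) {
  set.seed(seed)
  centers <- cbind(sep * seq_len(k), 0)
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(rnorm(n_per, centers[i, 1]), rnorm(n_per, centers[i, 2]))
  }))
  list(x = x, truth = rep(seq_len(k), each = n_per))
}

# compact layered tissue for fast end-to-end tests
small_tissue <- function(seed = 1, n_slices = 2, cells_per_layer = 120) {
  generate_layered_tissue(
    tissue_spec(n_slices = n_slices, n_layers = 3, layer_height = 300,
                width = 450, cells_per_layer = cells_per_layer,
                composition = rbind(c(0.8, 0.1, 0.1),
                                    c(0.1, 0.8, 0.1),
                                    c(0.1, 0.1, 0.8)),
                state_means = ringscape:::default_state_means(3)),
    seed = seed)
}
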