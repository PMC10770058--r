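test_that("representation embedding is symmetric, scale-free and warns on empty rows", {
  ds <- random_dataset(n = 40, g = 3, seed = 21, extent = 40)
  set.seed(21)
  st <- set_cell_states(ds, sample(c("A", "B"), 40, replace = TRUE))
  cr <- compute_representation(build_rings(ds, "radius", R = 15, S = 2), st)

  cr$M[2, ] <- cr$M[1, ]
  cr$M[4, ] <- 3 * cr$M[3, ]
  emb <- embed_representation(cr, n_components = 5)
  expect_equal(emb[1, ], emb[2, ])
  expect_equal(emb[3, ], emb[4, ])
  expect_identical(emb, embed_representation(cr, n_components = 5))

  cr$M[7, ] <- 0
  expect_warning(embed_representation(cr, n_components = 5), "empty multi-range")
})

test_that("domain clustering recovers separable clouds exactly", {
  cl <- cloud_embedding(2, n_per = 80, sep = 200, seed = 31)
  res <- cluster_domains(cl$x, n_neighbors = 10, resolution = 0.05, seed = 1)
  expect_equal(nlevels(res$labels), 2L)
  # clouds = connected components of the kNN graph (independent check)
  comp <- igraph::components(ringscape:::knn_graph(cl$x, 10))$membership
  expect_equal(nmi(res$labels, comp), 1.0)
  expect_equal(nmi(res$labels, cl$truth), 1.0)
  expect_identical(res$labels,
                   cluster_domains(cl$x, n_neighbors = 10, resolution = 0.05, seed = 1)$labels)

  # resolution -> 0+ on a connected cloud collapses to one domain
  one <- cloud_embedding(1, n_per = 100, seed = 32)
  expect_equal(nlevels(cluster_domains(one$x, n_neighbors = 10,
                                       resolution = 1e-4, seed = 1)$labels), 1L)
  expect_error(cluster_domains(cl$x, resolution = 0), "resolution")
})

test_that("resolution search hits attainable targets and flags unattainable ones", {
  for (k in c(1L, 3L)) {
    cl <- cloud_embedding(max(k, 1), n_per = 50, sep = 150, seed = 40 + k)
    res <- res_search(cl$x, target_k = k, n_neighbors = 10, seed = 1)
    expect_equal(nlevels(res$labels), k)
    expect_false(res$inexact)
    if (k > 1) expect_equal(nmi(res$labels, cl$truth), 1.0)
  }

  # k = 1 is unattainable on a disconnected neighbor graph: communities
  # never span components, so the search must flag inexactness
  cl2 <- cloud_embedding(2, n_per = 40, sep = 500, seed = 44)
  res <- res_search(cl2$x, target_k = 1, n_neighbors = 5, seed = 1,
                    max_iter = 8)
  expect_true(res$inexact)
  expect_equal(nlevels(res$labels), 2L)  # closest attainable count

  expect_error(res_search(cl2$x, target_k = 1000), "exceeds")
})

test_that("the 2-D visualization is deterministic and separates far clouds", {
  cl <- cloud_embedding(2, n_per = 40, sep = 500, seed = 51)
  u1 <- umap_embed(cl$x, seed = 7)
  u2 <- umap_embed(cl$x, seed = 7)
  expect_identical(u1, u2)
  expect_true(all(is.finite(u1)))

  a <- u1[cl$truth == 1, , drop = FALSE]
  b <- u1[cl$truth == 2, , drop = FALSE]
  between <- sqrt(sum((colMeans(a) - colMeans(b))^2))
  r95 <- function(m) quantile(sqrt(rowSums(sweep(m, 2, colMeans(m))^2)), 0.95)
  expect_gt(between, r95(a))
  expect_gt(between, r95(b))

  three <- umap_embed(rbind(c(0, 0), c(1, 0), c(0, 1)), seed = 1)
  expect_equal(dim(three), c(3L, 2L))
  expect_true(all(is.finite(three)))
  expect_error(umap_embed(rbind(c(0, 0), c(1, 0)), seed = 1), "at least 3")
})

test_that("the end-to-end pipeline is deterministic and joins slices correctly", {
  sim <- small_tissue(seed = 1)
  ds <- sim$dataset
  r1 <- identify_domains(ds, states = "truth_state", target_k = 3, seed = 1,
                         verbose = FALSE)
  r2 <- identify_domains(ds, states = "truth_state", target_k = 3, seed = 1,
                         verbose = FALSE)
  expect_identical(r1$labels, r2$labels)
  expect_equal(nlevels(r1$labels), 3L)
  expect_gt(nmi(r1$labels, ds$cells$truth_domain), 0.8)

  # joint-analysis contract: a duplicated slice gets identical labels per copy
  ds2 <- spatial_dataset(
    rbind(ds$expression, ds$expression),
    rbind(ds$coordinates, ds$coordinates),
    c(rep("copyA", n_cells(ds)), rep("copyB", n_cells(ds))),
    cell_meta = tibble::tibble(truth_state = rep(ds$cells$truth_state, 2)),
    cell_ids = paste0("cell", seq_len(2 * n_cells(ds))))
  rj <- identify_domains(ds2, states = "truth_state", target_k = 3, seed = 1,
                         verbose = FALSE)
  labA <- rj$labels[seq_len(n_cells(ds))]
  labB <- rj$labels[n_cells(ds) + seq_len(n_cells(ds))]
  expect_equal(nmi(labA, labB), 1.0)
  expect_true(all(as.character(labA) == as.character(labB)))

  expect_error(identify_domains(ds, resolution = 0.5, target_k = 3),
               "exactly one")
  # negative target_k shorthand = fixed resolution
  rn <- identify_domains(ds, states = "truth_state", target_k = -0.5, seed = 1,
                         verbose = FALSE)
  expect_equal(rn$resolution_used, 0.5)

  # tidy/glance accessors
  td <- tidy(r1)
  expect_equal(nrow(td), n_cells(ds))
  expect_true(all(c("cell_id", "slice_id", "domain") %in% names(td)))
  gl <- glance(r1)
  expect_equal(gl$n_domains, 3L)
})

test_that("moderate cell-state label noise costs little recovery accuracy", {
  for (seed in 1:2) {
    sim <- generate_layered_tissue(tissue_spec(), seed = seed)
    st <- set_cell_states(sim$dataset, "truth_state")
    truth <- sim$dataset$cells$truth_domain
    base <- identify_domains(sim$dataset, states = st, target_k = 5,
                             seed = seed, verbose = FALSE)
    noisy <- identify_domains(sim$dataset,
                              states = inject_label_noise(st, 0.2, seed = seed),
                              target_k = 5, seed = seed, verbose = FALSE)
    expect_lt(nmi(base$labels, truth) - nmi(noisy$labels, truth), 0.15)
  }
})
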