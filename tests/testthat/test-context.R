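test_that("the 3-cell worked example pins the half-open boundary rule", {
  ds <- spatial_dataset(matrix(1, 3, 2), cbind(c(0, 10, 25), 0), rep("s1", 3))
  st <- set_cell_states(ds, c("A", "A", "B"))
  ri <- build_rings(ds, "radius", R = 15, S = 2)

  expect_setequal(ri$rings[[1]][[1]], c(1L, 2L))
  expect_setequal(ri$rings[[2]][[1]], 3L)
  expect_setequal(ri$rings[[1]][[3]], 3L)
  expect_setequal(ri$rings[[2]][[3]], c(1L, 2L))

  M <- as.matrix(compute_representation(ri, st)$M)
  # Dist(cell2, cell3) = 15 falls in ring 2 by the half-open rule
  expect_equal(unname(M), rbind(c(2, 0, 0, 1), c(2, 0, 0, 1), c(0, 1, 2, 0)))

  # same coordinates, but cell 3 on another slice: never a neighbor
  ds2 <- spatial_dataset(matrix(1, 3, 2), cbind(c(0, 10, 25), 0),
                         c("s1", "s1", "s2"))
  ri2 <- build_rings(ds2, "radius", R = 15, S = 2)
  expect_setequal(ri2$rings[[1]][[1]], c(1L, 2L))
  expect_length(ri2$rings[[2]][[1]], 0L)

  # single cell: one-hot of its own state in ring 1
  ds3 <- spatial_dataset(matrix(1, 1, 2), cbind(0, 0), "s1")
  M3 <- compute_representation(build_rings(ds3, "radius", R = 15, S = 2),
                               set_cell_states(ds3, "A"))$M
  expect_equal(unname(as.matrix(M3)), rbind(c(1, 0)))
})

test_that("hop-shell rings on a hexagonal lattice match the 6-neighbor intuition", {
  # hex lattice: odd rows offset by 0.5, row spacing sqrt(3)/2
  pts <- do.call(rbind, lapply(0:10, function(r) {
    cbind(0:10 + (r %% 2) * 0.5, r * sqrt(3) / 2)
  }))
  ds <- spatial_dataset(matrix(1, nrow(pts), 2), pts, rep("s1", nrow(pts)))
  ri <- build_rings(ds, "knn", nn = 6, S = 2)
  center <- which.min((pts[, 1] - 5.25)^2 + (pts[, 2] - 4.33)^2)
  expect_length(ri$rings[[1]][[center]], 7L)   # self + 6 lattice neighbors
  expect_length(ri$rings[[2]][[center]], 12L)  # second hex shell

  tiny <- spatial_dataset(matrix(1, 3, 2), cbind(0:2, 0), rep("s1", 3))
  expect_error(build_rings(tiny, "knn", nn = 6, S = 2), "slice 's1'")
})

test_that("representation equals the literal pairwise-loop oracle", {
  for (case in 1:8) {
    set.seed(100 + case)
    n <- sample(30:120, 1)
    n_slices <- sample(1:3, 1)
    C <- sample(2:6, 1)
    S <- sample(1:6, 1)
    R <- runif(1, 8, 25)
    self_in <- case %% 2 == 0
    ds <- random_dataset(n = n, g = 3, n_slices = n_slices, seed = 200 + case,
                         extent = 60)
    set.seed(300 + case)
    st <- set_cell_states(ds, sample(paste0("g", seq_len(C)), n, replace = TRUE))

    cr <- compute_representation(
      build_rings(ds, "radius", R = R, S = S, self_in_first_ring = self_in), st)
    oracle <- oracle_representation(ds$coordinates, as.integer(ds$cells$slice_id),
                                    as.integer(st$labels), C, R, S, self_in)
    expect_identical(unname(as.matrix(cr$M)), oracle + 0)
  }
})

test_that("slices are isolated and row sums behave as counts", {
  ds <- random_dataset(n = 80, g = 3, n_slices = 2, seed = 9, extent = 50)
  set.seed(9)
  st <- set_cell_states(ds, sample(c("A", "B", "C"), 80, replace = TRUE))
  M1 <- as.matrix(compute_representation(build_rings(ds, "radius", R = 15, S = 3), st)$M)

  # translating slice 2 leaves slice-1 rows of M unchanged
  shifted <- ds
  move <- ds$cells$slice_id == levels(ds$cells$slice_id)[2]
  shifted$coordinates[move, ] <- shifted$coordinates[move, ] + 1e4
  M2 <- as.matrix(compute_representation(build_rings(shifted, "radius", R = 15, S = 3), st)$M)
  expect_equal(M1[!move, ], M2[!move, ])

  # row conservation: total counts = same-slice cells within S*R (self included)
  xy <- ds$coordinates
  for (i in c(1, 25, 60)) {
    same <- which(ds$cells$slice_id == ds$cells$slice_id[i])
    d <- sqrt(colSums((t(xy[same, , drop = FALSE]) - xy[i, ])^2))
    expect_equal(sum(M1[i, ]), sum(d < 3 * 15))
  }

  # enlarging S never decreases a row sum
  M_s1 <- as.matrix(compute_representation(build_rings(ds, "radius", R = 15, S = 1), st)$M)
  expect_true(all(rowSums(M1) >= rowSums(M_s1)))

  # S = 1 with a huge radius reduces to the within-slice state histogram
  M_all <- unname(as.matrix(compute_representation(build_rings(ds, "radius", R = 1e6, S = 1), st)$M))
  for (sl in levels(ds$cells$slice_id)) {
    idx <- which(ds$cells$slice_id == sl)
    hist <- as.vector(table(st$labels[idx]))
    expect_equal(M_all[idx, , drop = FALSE],
                 matrix(hist, length(idx), length(hist), byrow = TRUE))
  }
})

test_that("radius estimation recovers grid spacing and the Poisson closed form", {
  gg <- expand.grid(x = seq(0, 60, 15), y = seq(0, 60, 15))
  ds <- spatial_dataset(matrix(1, 25, 2), as.matrix(gg), rep("s1", 25))
  rep <- estimate_radius(ds)
  expect_equal(rep$summary$q1, 15)
  expect_equal(rep$summary$median, 15)
  expect_equal(rep$summary$q3, 15)
  expect_equal(rep$recommended_radius, 15)

  # homogeneous Poisson: median 1-NN distance = sqrt(ln 2 / (pi * lambda))
  pts <- generate_poisson_points(0.01, c(0, 1000, 0, 1000), seed = 4)
  dsp <- spatial_dataset(matrix(1, nrow(pts), 2), as.matrix(pts),
                         rep("s1", nrow(pts)))
  est <- estimate_radius(dsp)$pooled_median
  expect_lt(abs(est - sqrt(log(2) / (pi * 0.01))) / sqrt(log(2) / (pi * 0.01)), 0.05)

  dup <- spatial_dataset(matrix(1, 2, 2), rbind(c(1, 1), c(1, 1)), rep("s", 2))
  expect_warning(estimate_radius(dup), "coincident")

  # unit scale converts before any radius logic
  mm <- spatial_dataset(matrix(1, 25, 2), as.matrix(gg) / 1000, rep("s1", 25),
                        unit_scale = 1000)
  expect_equal(estimate_radius(mm)$recommended_radius, 15)
})

test_that("technology conventions match the published parameter table", {
  expect_equal(default_params("visium"), list(mode = "knn", nn = 6L, S = 2L))
  expect_equal(default_params("st"), list(mode = "knn", nn = 4L, S = 2L))
  expect_equal(default_params("merfish"), list(mode = "radius", R = 15, S = 6L))
  expect_equal(default_params("starmap_plus"), list(mode = "radius", R = 15, S = 6L))
  expect_equal(default_params("slide_seq"), list(mode = "radius", R = 15, S = 4L))
  expect_error(default_params("cytof"), "estimate_radius")
})

test_that("feature decoding inverts the range-major column layout", {
  ds <- random_dataset(n = 20, g = 3, seed = 2)
  set.seed(2)
  st <- set_cell_states(ds, factor(sample(c("A", "B", "C"), 20, replace = TRUE),
                                   levels = c("A", "B", "C")))
  cr <- compute_representation(build_rings(ds, "radius", R = 15, S = 4), st)

  for (col in seq_len(nrow(cr$column_map))) {
    dec <- decode_feature(col, cr)
    s <- (col - 1) %/% 3 + 1
    c_idx <- (col - 1) %% 3 + 1
    expect_equal(dec$range, s)
    expect_equal(dec$state, c("A", "B", "C")[c_idx])
  }
  expect_equal(decode_feature(1, cr)$range, 1)          # first column: state 1, ring 1
  expect_equal(decode_feature(3 + 1, cr)$state, "A")    # column C+1: state 1, ring 2
  expect_equal(decode_feature(3 + 1, cr)$range, 2)
  expect_error(decode_feature(13, cr), "out of range")
})
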