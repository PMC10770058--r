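test_that("NMI identities, invariances and the independent 2x2 example hold", {
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1.0)
  expect_equal(nmi(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1.0)   # label permutation
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0.0)   # uniform 2x2 table
  expect_error(nmi(c(0, 1), c(0, 1, 1)), "length")

  # zero-entropy conventions
  expect_equal(nmi(rep("a", 5), rep("b", 5)), 1.0)  # identical as partitions
  expect_equal(nmi(rep("a", 5), c(1, 1, 2, 2, 2)), 0.0)

  # NA positions are masked out
  expect_equal(nmi(c(0, 0, 1, 1, 0), c(1, 1, 0, 0, NA)), 1.0)

  # symmetry and relabeling invariance on random pairs
  set.seed(77)
  for (i in 1:20) {
    P <- sample(0:3, 60, replace = TRUE)
    T_ <- sample(0:2, 60, replace = TRUE)
    expect_equal(nmi(P, T_), nmi(T_, P), tolerance = 1e-14)
    expect_equal(nmi(P, T_), nmi(paste0("x", P), rev(as.character(rev(T_)))),
                 tolerance = 1e-14)
    expect_gte(nmi(P, T_), 0); expect_lte(nmi(P, T_), 1)
  }
})

test_that("NMI matches an independent textbook implementation to 1e-12", {
  set.seed(123)
  for (i in 1:100) {
    n <- sample(20:80, 1)
    P <- sample(seq_len(sample(2:6, 1)), n, replace = TRUE)
    T_ <- sample(seq_len(sample(2:6, 1)), n, replace = TRUE)
    if (length(unique(P)) < 2 || length(unique(T_)) < 2) next
    expect_equal(nmi(P, T_), nmi_textbook(P, T_), tolerance = 1e-12)
  }
})

test_that("NMI and ARI agree with reference library values", {
  # frozen values from scikit-learn (geometric-mean NMI, adjusted_rand_score)
  P1 <- c(0,3,2,1,1,3,0,2,0,0,2,3,2,3,2,3,2,0,3,1,2,1,0,3,3,2,1,3,2,1,1,0,0,2,3,0,3,3,1,2)
  T1 <- c(0,2,2,1,0,2,1,2,2,2,2,0,1,1,1,0,1,0,2,2,2,2,1,2,1,0,2,1,0,1,2,0,1,0,2,1,0,0,1,2)
  expect_equal(nmi(P1, T1), 0.02990642523288233, tolerance = 1e-12)
  expect_equal(ari(P1, T1), -0.0377776881828811, tolerance = 1e-12)
  P2 <- c(3,1,0,3,2,2,0,1,3,3,1,3,3,1,3,1,0,2,2,0,3,0,3,0,3,3,3,2,1,2,1,3,2,1,2,2,0,0,0,0)
  T2 <- c(1,2,1,1,2,1,0,2,1,1,1,1,0,1,2,0,1,0,1,1,2,0,0,1,2,2,0,0,2,0,2,0,2,0,1,1,0,1,1,2)
  expect_equal(nmi(P2, T2), 0.04405910731488575, tolerance = 1e-12)
  expect_equal(ari(P2, T2), -0.022533792695502035, tolerance = 1e-12)
})

test_that("ARI matches its pair-counting definition and mclust on random pairs", {
  expect_equal(ari(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1.0)
  # a = 0, sum C(a_i,2) = 2, sum C(b_j,2) = 2, C(4,2) = 6 -> (0 - 4/6)/(2 - 4/6)
  expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  expect_equal(ari(c("a", "a", "b", "b"), c("b", "b", "a", "a")), 1.0)

  skip_if_not_installed("mclust")
  set.seed(99)
  for (i in 1:25) {
    P <- sample(1:4, 50, replace = TRUE)
    T_ <- sample(1:3, 50, replace = TRUE)
    expect_equal(ari(P, T_), mclust::adjustedRandIndex(P, T_), tolerance = 1e-12)
  }
})

test_that("PAS matches direct enumeration on grids and respects geometry", {
  g <- as.matrix(expand.grid(x = 1:10, y = 1:10))
  expect_equal(pas(rep("A", 100), g), 0.0)
  expect_equal(pas(as.character(1:100), g), 1.0)

  lab <- rep("A", 100)
  lab[which(g[, 1] == 5 & g[, 2] == 5)] <- "B"
  expect_equal(pas(lab, g), 0.01)

  # rigid motion invariance per slice
  theta <- 0.7
  rot <- g %*% rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta))) + 42
  expect_equal(pas(lab, rot), pas(lab, g))

  # two slices: PAS computed within slices only
  two <- rbind(g, g + 1e6)
  lab2 <- c(lab, rep("A", 100))
  expect_equal(pas(lab2, two, rep(c("s1", "s2"), each = 100)), 0.005)

  # small-slice fallback rescales k and threshold with a warning
  sm <- cbind(seq_len(8), 0)
  expect_warning(v <- pas(rep(c("A", "B"), 4), sm, k = 10, threshold = 6),
                 "using k = 7")
  expect_gte(v, 0); expect_lte(v, 1)
})

test_that("the per-slice table reports each slice plus a joint row", {
  sim <- small_tissue(seed = 3)
  ds <- sim$dataset
  truth <- ds$cells$truth_domain

  tab <- per_slice_metrics(truth, truth, ds)
  expect_equal(nrow(tab), nlevels(ds$cells$slice_id) + 1L)
  expect_true(all(tab$nmi == 1) && all(tab$ari == 1))
  expect_equal(tab$slice[nrow(tab)], "joint")

  # prediction correct on slice 1, shuffled on slice 2
  pred <- as.character(truth)
  s2 <- ds$cells$slice_id == "slice2"
  set.seed(8)
  pred[s2] <- sample(pred[s2])
  tab2 <- per_slice_metrics(pred, truth, ds)
  expect_equal(tab2$nmi[tab2$slice == "slice1"], 1.0)
  expect_lt(tab2$nmi[tab2$slice == "slice2"], 0.2)

  # single-slice dataset: slice row equals the joint row
  one <- small_tissue(seed = 4, n_slices = 1)
  tab3 <- per_slice_metrics(one$dataset$cells$truth_domain,
                            one$dataset$cells$truth_domain, one$dataset)
  expect_equal(nrow(tab3), 2L)
  expect_equal(tab3$nmi[1], tab3$nmi[2])
  expect_equal(tab3$pas[1], tab3$pas[2])
})
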