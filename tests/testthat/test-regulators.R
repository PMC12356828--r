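test_that("qc_filter_cells applies the strict 'fewer than' exclusion", {
  counts <- rbind(
    c(rep(1, 599), rep(0, 601)),             # 599 UMIs over 599 genes: out
    c(rep(1, 300), rep(2, 250), rep(0, 650)),# 800 UMIs, 550 genes: in
    rep(0, 1200))                            # all-zero: out
  # boundary cell: exactly 800 UMIs over exactly 500 genes is retained
  exact <- c(rep(1, 200), rep(2, 300), rep(0, 700))
  counts <- rbind(counts, exact)
  rownames(counts) <- paste0("c", 1:4)
  kept <- qc_filter_cells(counts)
  expect_setequal(kept, c("c2", "c4"))
  # a 799-UMI cell with plenty of genes is excluded (strict threshold)
  c799 <- matrix(c(rep(1, 799), rep(0, 401)), nrow = 1,
                 dimnames = list("x", NULL))
  expect_length(qc_filter_cells(c799), 0)
  expect_warning(qc_filter_cells(matrix(0, 0, 5)), "empty")
})

test_that("cluster z-scores match an independent Welch oracle", {
  set.seed(42)
  n <- 50
  x <- rnorm(n) + 2; y <- rnorm(n)
  am <- activity_matrix(rbind(c(x, y)), rep(c("AD", "control"), each = n),
                        rep(1, 2 * n))
  z <- cluster_zscores(am)
  or <- oracle_welch(x, y)
  expect_gt(z[1, 1], 0)
  expect_lt(2 * pnorm(-abs(z[1, 1])), 0.001)
  # the z is the normal quantile of the Welch tail probability
  expect_equal(unname(z[1, 1]),
               qnorm(pt(or$t, or$df, lower.tail = FALSE), lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("cluster z handles identical groups, zero variance, small clusters", {
  v <- c(1, 2, 3, 1, 2, 3)
  am <- activity_matrix(rbind(v), rep(c("AD", "control"), each = 3),
                        rep(1, 6))
  expect_equal(unname(cluster_zscores(am)[1, 1]), 0)
  # zero variance, unequal means: clamped
  am2 <- activity_matrix(rbind(c(5, 5, 0, 0)),
                         rep(c("AD", "control"), each = 2), rep(1, 4))
  expect_equal(unname(cluster_zscores(am2)[1, 1]), 38)
  # a cluster with one control sample is dropped with a warning
  am3 <- activity_matrix(rbind(rnorm(8)), rep(c("AD", "control"), each = 4),
                         c(1, 1, 2, 2, 1, 1, 1, 2))
  expect_warning(z3 <- cluster_zscores(am3), "dropping")
  expect_equal(colnames(z3), "1")
})

test_that("stouffer_combine matches its closed form and is scale-invariant", {
  expect_equal(stouffer_combine(rep(1, 4)), 2)
  expect_equal(stouffer_combine(-2.3), -2.3)
  expect_equal(stouffer_combine(c(2, -1), c(3, 1)), 5 / sqrt(10))
  expect_equal(round(stouffer_combine(c(2, -1), c(3, 1)), 4), 1.5811)
  # weights w and c*w give identical Z
  set.seed(1)
  z <- rnorm(6); w <- runif(6, 0.5, 2)
  expect_equal(stouffer_combine(z, w), stouffer_combine(z, 7 * w))
  expect_error(stouffer_combine(numeric()), ">= 1")
  expect_error(stouffer_combine(1:2, c(1, -1)), "> 0")
})

test_that("bh_adjust equals brute-force step-up exhaustively up to length 8", {
  grid <- c(0.01, 0.3, 0.8)
  for (len in 1:8) {
    vecs <- as.matrix(expand.grid(rep(list(grid), len)))
    for (r in seq_len(nrow(vecs))) {
      p <- unname(vecs[r, ])
      expect_identical(bh_adjust(p), oracle_bh(p))
    }
  }
  # random vectors too, and the spec worked examples
  set.seed(3)
  for (i in 1:50) {
    p <- runif(sample(1:8, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  expect_equal(bh_adjust(rep(0.01, 5)), rep(0.01, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("call_ders flags a planted regulator and applies the |Z| gate", {
  spec <- activity_sim_spec(n_regulators = 30, n_metacells_per_group = 40,
                            planted_up = 5, effect_size = 2, noise_sd = 0.5,
                            seed = 21)
  ders <- call_ders(generate_activity_matrix(spec))
  expect_true(ders$significant[5])
  expect_equal(ders$direction[5], "up")
  expect_false(any(ders$significant[-5]))
  # gate logic: tiny q but |Z| below the association threshold
  fake <- activity_matrix(
    matrix(rnorm(4 * 40, sd = 1), nrow = 4,
           dimnames = list(paste0("R", 1:4), NULL)),
    rep(c("AD", "control"), each = 20), rep(1, 40))
  out <- call_ders(fake, min_abs_association = 50)
  expect_false(any(out$significant))   # |Z| = 50 gate fails regardless of q
})

test_that("BH q-values respect the step-up contract within call_ders", {
  spec <- activity_sim_spec(n_regulators = 100, n_metacells_per_group = 20,
                            planted_up = 1:3, effect_size = 1.5, seed = 8)
  ders <- call_ders(generate_activity_matrix(spec))
  expect_true(all(ders$q_value >= ders$p_value - 1e-12))
  expect_true(all(ders$q_value <= 1))
  expect_equal(ders$q_value, bh_adjust(ders$p_value))
})

test_that("intersect_ders maps members to exact set combinations", {
  res <- intersect_ders(list(A = c("x", "y"), B = c("y", "z")))
  memb <- res$membership
  expect_equal(memb$region[memb$id == "y"], "A&B")
  expect_equal(memb$region[memb$id == "x"], "A")
  expect_equal(memb$region[memb$id == "z"], "B")
  # three identical sets: everything in the triple intersection
  res3 <- intersect_ders(list(a = c("p", "q"), b = c("p", "q"),
                              c = c("p", "q")))
  expect_true(all(res3$membership$region == "a&b&c"))
  # disjoint sets: empty intersection
  resd <- intersect_ders(list(A = "m", B = "n"))
  expect_false(any(resd$membership$region == "A&B"))
  expect_error(intersect_ders(list(A = "x")), ">= 2")
})
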