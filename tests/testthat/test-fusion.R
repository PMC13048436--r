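test_that("fusion is the plain elementwise sum", {
  set.seed(14)
  Z1 <- matrix(runif(25), 5, 5); Z2 <- matrix(runif(25), 5, 5)
  expect_equal(fuse_representations(list(Z1)), Z1)
  ref <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) ref[i, j] <- Z1[i, j] + Z2[i, j]
  expect_equal(fuse_representations(list(Z1, Z2)), ref)
  # two row-stochastic matrices sum to row sums of exactly 2
  S1 <- Z1 / rowSums(Z1); S2 <- Z2 / rowSums(Z2)
  expect_equal(rowSums(fuse_representations(list(S1, S2))), rep(2, 5))
  expect_error(fuse_representations(list(Z1, matrix(0, 4, 4))), "shape")
})

test_that("information-retention ratio follows its formula and clips", {
  expect_equal(compute_tau(200, c(85, 0.001, 1)), 85 + 1 / 1.2)
  expect_equal(compute_tau(50, c(90, 0, 0.1)), 100)   # 90 + 10, clipped
  taus <- vapply(c(50, 100, 500, 2000), compute_tau, numeric(1),
                 eps = c(85, 0.001, 1))
  expect_true(all(diff(taus) < 0))                    # decreasing in n
  expect_error(compute_tau(10, c(85, 0, 0)), "positive")
})

test_that("column-wise truncation keeps the smallest tau-mass prefix", {
  Z <- matrix(c(0.5, 0.3, 0.2), 3, 1)
  expect_equal(simplify_affinity(cbind(Z), 70), matrix(c(0.5, 0.3, 0), 3, 1))
  expect_equal(simplify_affinity(cbind(Z), 100), cbind(Z))  # full retention
  one <- matrix(c(0, 0.4, 0), 3, 1)
  expect_equal(simplify_affinity(one, 5), one)    # single nonzero stays
  # ties broken toward the lower row index
  tied <- matrix(c(0.4, 0.4, 0.2), 3, 1)
  expect_equal(simplify_affinity(tied, 50), matrix(c(0.4, 0.4, 0), 3, 1))
  expect_error(simplify_affinity(matrix(-1, 1, 1), 50), "nonnegative")
  expect_error(simplify_affinity(matrix(1, 1, 1), 0), "tau")
})

test_that("truncation retains at least tau% column mass, minimally", {
  set.seed(15)
  for (rep in 1:10) {
    Z <- matrix(runif(64), 8, 8)
    tau <- runif(1, 30, 95)
    Zt <- simplify_affinity(Z, tau)
    expect_true(all(Zt <= Z + 1e-15))               # never increases entries
    for (j in 1:8) {
      kept <- Zt[, j]
      expect_gte(sum(kept), tau / 100 * sum(Z[, j]) - 1e-12)
      smallest <- min(kept[kept > 0])
      expect_lt(sum(kept) - smallest, tau / 100 * sum(Z[, j]))  # minimality
    }
  }
})

test_that("angle similarity separates orthogonal blocks and saturates on rank one", {
  # rank-1 input with no zero rows: all rows of M collinear -> all-ones W
  u <- c(1, 2, 3, 4); v <- c(4, 3, 2, 1)
  W1 <- angle_similarity(outer(u, v))$W
  expect_equal(W1, matrix(1, 4, 4), tolerance = 1e-10)

  # two orthogonal blocks: zero similarity across, unit diagonal
  B <- matrix(0, 6, 6)
  B[1:3, 1:3] <- matrix(runif(9, 0.5, 1), 3)
  B[4:6, 4:6] <- matrix(runif(9, 0.5, 1), 3)
  res <- angle_similarity(B)
  expect_equal(res$W[1:3, 4:6], matrix(0, 3, 3), tolerance = 1e-10)
  expect_equal(diag(res$W), rep(1, 6))
  expect_equal(res$W, t(res$W), tolerance = 1e-10)
  expect_true(all(res$W >= 0 & res$W <= 1 + 1e-12))

  # zero rows get zero similarity everywhere, including the diagonal
  Bz <- B; Bz[2, ] <- 0; Bz[, 2] <- 0
  Wz <- angle_similarity(Bz)$W
  expect_equal(Wz[2, ], rep(0, 6))
  expect_error(angle_similarity(matrix(0, 3, 3)), "degenerate")
})

test_that("eigengap counts well-separated blocks and ignores cell order", {
  lab <- rep(1:3, times = c(5, 7, 8))
  W <- 1 * outer(lab, lab, "==")
  expect_equal(eigengap_k(W, 8), 3L)
  expect_equal(eigengap_k(matrix(1, 10, 10), 5), 1L)  # single clique
  set.seed(16)
  perm <- sample(20)
  expect_equal(eigengap_k(W[perm, perm], 8), 3L)
  expect_error(eigengap_k(W, 20), "k_max")
})

test_that("spectral clustering recovers planted blocks and handles edge cases", {
  lab <- rep(1:2, times = c(6, 9))
  W <- 1 * outer(lab, lab, "==")
  cl <- spectral_cluster(W, 2, seed = 1)
  expect_equal(clustering_acc(lab, cl$labels), 1)
  expect_equal(length(unique(cl$labels)), 2L)

  expect_equal(spectral_cluster(W, 1, seed = 1)$labels, rep(1L, 15))
  # K = n on a diagonal-dominant similarity: singletons
  Wd <- diag(6) + matrix(1e-4, 6, 6)
  expect_equal(sort(spectral_cluster(Wd, 6, seed = 2)$labels), 1:6)
  expect_error(spectral_cluster(W, 20, seed = 1), "K")

  # permuting cells permutes labels consistently
  set.seed(17)
  perm <- sample(15)
  clp <- spectral_cluster(W[perm, perm], 2, seed = 1)
  expect_equal(clustering_acc(lab[perm], clp$labels), 1)
})
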