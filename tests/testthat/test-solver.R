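ns <- asNamespace("scmoclust")

test_that("orthogonal-Procrustes factor updates attain the trace maximum", {
  n <- 4
  expect_equal(ns$update_LR(diag(n), diag(n), diag(n), diag(n))$L, diag(n))

  # 2x2: sweep rotations and reflections on a fine grid
  set.seed(9)
  for (rep in 1:20) {
    G <- matrix(rnorm(4), 2, 2)
    L <- ns$procrustes(G)
    expect_equal(crossprod(L), diag(2), tolerance = 1e-10)
    grid_best <- -Inf
    for (th in seq(0, 2 * pi, length.out = 2000)) {
      Rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      Ref <- Rot %*% diag(c(1, -1))
      grid_best <- max(grid_best, sum(diag(t(Rot) %*% G)), sum(diag(t(Ref) %*% G)))
    }
    expect_gte(sum(diag(t(L) %*% G)) + 1e-5, grid_best)
  }

  # returned factors are orthonormal to high precision on random updates
  set.seed(10)
  Zt <- matrix(rnorm(25), 5, 5); C <- matrix(rnorm(25), 5, 5)
  lr <- ns$update_LR(Zt, C, diag(5), diag(5))
  expect_equal(crossprod(lr$L), diag(5), tolerance = 1e-10)
  expect_equal(crossprod(lr$R), diag(5), tolerance = 1e-10)
})

test_that("view-core update solves its quadratic exactly", {
  set.seed(11)
  for (rep in 1:20) {
    n <- 5
    qrL <- qr.Q(qr(matrix(rnorm(n * n), n)))
    qrR <- qr.Q(qr(matrix(rnorm(n * n), n)))
    Zt <- matrix(rnorm(n * n), n); Cstar <- matrix(rnorm(n * n), n)
    w <- runif(1, 0.1, 5); mu <- runif(1, 0.01, 10)
    C_hat <- ns$update_C_view(Zt, qrL, qrR, Cstar, w, mu)
    obj <- function(cvec) {
      C <- matrix(cvec, n, n)
      mu / 2 * sum((Zt - qrL %*% C %*% t(qrR))^2) + w * sum((C - Cstar)^2)
    }
    C_num <- matrix(optim_oracle(as.numeric(Cstar), obj), n, n)
    expect_equal(C_hat, C_num, tolerance = 1e-5)
  }
  # limits: consensus term off; penalty term off
  Zt <- matrix(rnorm(16), 4); Cstar <- matrix(rnorm(16), 4)
  expect_equal(ns$update_C_view(Zt, diag(4), diag(4), Cstar, 1e-14, 2), Zt,
               tolerance = 1e-10)
  expect_equal(ns$update_C_view(Zt, diag(4), diag(4), Cstar, 1, 1e-14), Cstar,
               tolerance = 1e-10)
})

test_that("consensus update minimises nuclear norm plus weighted residuals", {
  # near-identity shrink when one view dominates
  res <- ns$update_consensus(list(diag(c(5, 5))), 1000)
  expect_equal(res$Cstar, diag(c(5 - 1 / 2000, 5 - 1 / 2000)), tolerance = 1e-12)

  # identical views: weighted mean minus a per-singular-value shrink of 1/(2S)
  set.seed(12)
  C1 <- matrix(rnorm(16, sd = 4), 4, 4)
  res2 <- ns$update_consensus(list(C1, C1), c(2, 3))
  expect_equal(res2$Cstar, svt_oracle(C1, 1 / 10), tolerance = 1e-10)

  # random two-view instances vs the Moreau-identity oracle and a numeric check
  for (rep in 1:20) {
    Cs <- list(matrix(rnorm(25), 5, 5), matrix(rnorm(25), 5, 5))
    w <- runif(2, 0.2, 3)
    res <- ns$update_consensus(Cs, w)
    Cbar <- (w[1] * Cs[[1]] + w[2] * Cs[[2]]) / sum(w)
    expect_equal(res$Cstar, svt_oracle(Cbar, 1 / (2 * sum(w))), tolerance = 1e-8)
    full_obj <- function(C) sum(svd(C)$d) +
      w[1] * sum((Cs[[1]] - C)^2) + w[2] * sum((Cs[[2]] - C)^2)
    # the closed form beats random perturbations of itself
    base <- full_obj(res$Cstar)
    for (k in 1:5)
      expect_lte(base, full_obj(res$Cstar + matrix(rnorm(25, sd = 0.05), 5)) + 1e-12)
  }
})

test_that("adaptive view weights follow the inverse-residual rule", {
  C1 <- diag(2); Cstar <- diag(2)
  expect_equal(ns$update_weights(list(C1), Cstar), 1 / (2 * 1e-8))
  Cs <- list(Cstar + diag(c(1, 0)) * 1, Cstar + matrix(c(2, 0, 0, 0), 2))
  expect_equal(ns$update_weights(Cs, Cstar), c(0.5, 0.25))
  # strictly decreasing in the residual
  r <- seq(0.5, 4, by = 0.5)
  w <- vapply(r, function(s) ns$update_weights(list(Cstar + diag(2) * s / sqrt(2)),
                                               Cstar), numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("unconstrained representation update solves its normal equations", {
  set.seed(13)
  n <- 6; m <- 8
  X <- matrix(rnorm(m * n), m, n)
  pre <- list(X = X, XtX = crossprod(X), chol = chol(crossprod(X) + diag(n)))
  LCRt <- matrix(rnorm(n * n), n, n)
  Q <- abs(matrix(rnorm(n * n), n, n))
  Y2 <- matrix(rnorm(n * n, sd = 0.2), n, n)
  E <- matrix(rnorm(m * n, sd = 0.1), m, n)
  Y1 <- matrix(rnorm(m * n, sd = 0.1), m, n)
  mu <- 2; lambda1 <- 0.7
  XtF <- crossprod(X, E - Y1 / mu)
  Z_hat <- ns$update_Z(pre, XtF, LCRt, Y2, Q, lambda1, mu, project = FALSE)
  obj <- function(z) {
    Z <- matrix(z, n, n)
    mu / 2 * sum((X - X %*% Z - E + Y1 / mu)^2) +
      mu / 2 * sum((Z - LCRt + Y2 / mu)^2) + lambda1 * sum(Q * Z)
  }
  Z_num <- matrix(optim_oracle(as.numeric(LCRt), obj), n, n)
  expect_equal(Z_hat, Z_num, tolerance = 1e-5)

  # lambda1 = 0 drops the penalty: solution matches a least-squares oracle
  Z0 <- ns$update_Z(pre, XtF * 0, LCRt, Y2 * 0, Q, 0, 1, project = FALSE)
  Z_ls <- solve(crossprod(X) + diag(n), crossprod(X) + LCRt)
  expect_equal(Z0, Z_ls, tolerance = 1e-8)
  # projected output always satisfies the three representation constraints
  Zp <- ns$update_Z(pre, XtF, LCRt, Y2, Q, lambda1, mu)
  expect_true(all(diag(Zp) == 0))
  expect_true(all(Zp >= 0))
  expect_equal(rowSums(Zp), rep(1, n), tolerance = 1e-12)
})

test_that("the full solve keeps every invariant at every iteration", {
  ds <- tiny_dataset(n = 60, seed = 21)
  cfg <- solver_config(max_iter = 50, tolerance = 1e-12, seed = 21)
  st <- solve_multiomics(ds, cfg)
  tr <- st$trace
  expect_equal(nrow(tr), 50)
  expect_true(all(tr$z_constraint_err < 1e-12))     # simplex + diag to machine precision
  expect_true(all(tr$lr_orth_err < 1e-8))
  expect_true(all(tr$w_min > 0))
  expect_true(all(diff(tr$mu) >= 0))                # mu nondecreasing, capped
  expect_true(all(tr$mu <= cfg$mu_max))
  expect_true(all(tr[, c("nuclear", "penalty", "consensus", "noise")] >= 0))
  expect_equal(tr$total, tr$nuclear + tr$penalty + tr$consensus + tr$noise)
})

test_that("identical configurations give bitwise-identical runs", {
  ds <- tiny_dataset(n = 40, dims = c(30, 45), seed = 4)
  cfg <- solver_config(max_iter = 15, seed = 4)
  s1 <- solve_multiomics(ds, cfg)
  s2 <- solve_multiomics(ds, cfg)
  expect_identical(s1$trace, s2$trace)
  expect_identical(s1$Z, s2$Z)
})

test_that("single-view, penalty-free solve satisfies the self-representation constraint", {
  ds0 <- tiny_dataset(n = 40, dims = c(35), seed = 5)
  ds <- assemble_dataset(ds0$views[1], labels = ds0$labels)
  st <- solve_multiomics(ds, solver_config(lambda1 = 0, max_iter = 200,
                                           tolerance = 1e-7, seed = 5))
  X <- ds$views[[1]]
  resid <- X - X %*% st$Z[[1]] - st$E[[1]]
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("degenerate inputs are rejected", {
  ds <- tiny_dataset(n = 20, dims = c(10, 15), seed = 6)
  expect_error(solve_multiomics(ds, solver_config(knn_k = 25)), "knn_k")
  tiny <- assemble_dataset(list(matrix(rnorm(4), 2, 2)))
  expect_error(solve_multiomics(tiny), "at least 3 cells")
})
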