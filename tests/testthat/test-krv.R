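test_that("krv statistic matches the brute-force trace oracle", {
  K <- rand_psd(6, seed = 10)
  L <- rand_psd(6, seed = 11)
  expect_equal(krv_statistic(krv_kernel(K), krv_kernel(L)),
               krv_bruteforce(K, L), tolerance = 1e-12)
  expect_equal(krv_statistic(krv_kernel(K), krv_kernel(K)), 1)
  # orthogonal centered rank-1 factors give exactly zero
  u <- c(1, -1, 0, 0); v <- c(0, 0, 1, -1)
  expect_equal(krv_statistic(krv_kernel(outer(u, u)), krv_kernel(outer(v, v))),
               0, tolerance = 1e-12)
  # in [0, 1] for psd kernels
  for (seed in 1:5) {
    s <- krv_statistic(krv_kernel(rand_psd(9, seed)),
                       krv_kernel(rand_psd(9, seed + 100)))
    expect_gte(s, 0); expect_lte(s, 1)
  }
  expect_error(krv_statistic(krv_kernel(matrix(1, 4, 4)),
                             krv_kernel(rand_psd(4, 1))), "degenerate")
})

test_that("kernel adjustment projects out the covariate space", {
  n <- 20
  set.seed(12)
  K <- rand_psd(n, seed = 12)
  x <- rnorm(n)
  X <- covariate_design(cbind(x))
  # intercept-only adjustment is plain centering
  K0 <- adjust_kernel(krv_kernel(K), covariate_design(n = n))
  expect_equal(unclass(K0), unclass(center_kernel(krv_kernel(K))),
               tolerance = 1e-12, ignore_attr = TRUE)
  # a kernel built from a covariate column is annihilated
  Kx <- adjust_kernel(krv_kernel(outer(x, x)), X)
  expect_lt(max(abs(unclass(Kx))), 1e-10)
  # idempotence
  K1 <- adjust_kernel(krv_kernel(K), X)
  expect_equal(unclass(adjust_kernel(K1, X)), unclass(K1), tolerance = 1e-10,
               ignore_attr = TRUE)
  # equivalence with residualizing every kernel PC and reconstructing
  kp <- kernel_pca(krv_kernel(K))
  S <- kp$scores
  Xm <- X$X
  resid_scores <- S - Xm %*% solve(crossprod(Xm), crossprod(Xm, S))
  expect_equal(unclass(K1), tcrossprod(resid_scores), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(adjust_kernel(krv_kernel(K),
                             covariate_design(cbind(x, 2 * x))),
               "rank")
})

test_that("adjusted krv on linear kernels equals the residual-based approach", {
  n <- 25
  set.seed(13)
  Z1 <- matrix(rnorm(n * 4), n, 4)
  Z2 <- matrix(rnorm(n * 6), n, 6)
  Xc <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  X <- covariate_design(Xc)
  a <- adjusted_krv(linear_kernel(Z1), linear_kernel(Z2), X)
  Xm <- X$X
  Pp <- diag(n) - Xm %*% solve(crossprod(Xm), t(Xm))
  R1 <- Pp %*% Z1
  R2 <- Pp %*% Z2
  b <- krv_statistic(linear_kernel(R1), linear_kernel(R2))
  expect_equal(a, b, tolerance = 1e-10)
  # intercept-only reduces to the unadjusted statistic
  expect_equal(adjusted_krv(linear_kernel(Z1), linear_kernel(Z2),
                            covariate_design(n = n)),
               krv_statistic(linear_kernel(Z1), linear_kernel(Z2)),
               tolerance = 1e-12)
  # statistic invariant to simultaneous sample permutation
  p <- sample(n)
  expect_equal(adjusted_krv(linear_kernel(Z1[p, ]), linear_kernel(Z2[p, ]),
                            covariate_design(Xc[p, , drop = FALSE])),
               a, tolerance = 1e-10)
})

test_that("analytic permutation moments match exhaustive enumeration", {
  n <- 7
  P <- all_perms(n)
  for (seed in c(20, 21)) {
    set.seed(seed)
    H <- diag(n) - 1 / n
    M1 <- matrix(rnorm(n * n), n); A <- H %*% (M1 + t(M1)) %*% H
    M2 <- matrix(rnorm(n * n), n); W <- H %*% (M2 + t(M2)) %*% H
    vals <- apply(P, 1, function(p) sum(A * W[p, p]))
    mom <- krvgwas:::krv_perm_moments(krvgwas:::krv_invariants(A),
                                      krvgwas:::krv_invariants(W))
    expect_equal(mom[["mean"]], mean(vals), tolerance = 1e-10)
    expect_equal(mom[["variance"]], mean(vals^2) - mean(vals)^2,
                 tolerance = 1e-10)
    m3 <- mean((vals - mean(vals))^3)
    expect_equal(mom[["skewness"]], m3 / (mean(vals^2) - mean(vals)^2)^1.5,
                 tolerance = 1e-8)
  }
})

test_that("analytic null mean matches the empirical permutation mean", {
  n <- 25
  set.seed(30)
  K <- rand_psd(n, seed = 30, rank = 5)
  L <- rand_psd(n, seed = 31, rank = 8)
  Kc <- unclass(center_kernel(krv_kernel(K)))
  Lc <- unclass(center_kernel(krv_kernel(L)))
  A <- Kc / sqrt(sum(Kc^2)); W <- Lc / sqrt(sum(Lc^2))
  mom <- krvgwas:::krv_perm_moments(krvgwas:::krv_invariants(A),
                                    krvgwas:::krv_invariants(W))
  B <- 1e5
  vals <- replicate(B, { p <- sample.int(n); sum(A * W[p, p]) })
  mc_se <- sd(vals) / sqrt(B)
  expect_lt(abs(mom[["mean"]] - mean(vals)), 3 * mc_se)
})

test_that("permutation p-values are deterministic and maximal-statistic exact", {
  K <- krv_kernel(rand_psd(15, seed = 40, rank = 4))
  p1 <- permutation_pvalue(K, K, B = 200, seed = 5)
  expect_equal(p1, 1 / 201)
  expect_equal(permutation_pvalue(K, K, B = 200, seed = 5), p1)
  expect_error(permutation_pvalue(K, K, B = 10), "at least 100")
})

test_that("analytic p-values are calibrated under an unconfounded null", {
  n <- 40
  set.seed(50)
  pvals <- replicate(2000, {
    K <- tcrossprod(matrix(rnorm(n * 3), n, 3))
    L <- tcrossprod(matrix(rnorm(n * 5), n, 5))
    krv_test(krv_kernel(K), krv_kernel(L))$p_value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 1e-3)
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("kernel pca reconstructs the centered kernel", {
  set.seed(61)
  z <- rnorm(12)
  # rank-1 case: PC1 proportional to centered data
  kpz <- kernel_pca(linear_kernel(cbind(z)))
  cc <- z - mean(z)
  expect_equal(abs(cor(kpz$scores[, 1], cc)), 1, tolerance = 1e-10)
  K <- krv_kernel(rand_psd(10, seed = 60, rank = 6))
  kp <- kernel_pca(K)
  expect_equal(tcrossprod(kp$scores), unclass(center_kernel(K)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sum(kp$var_explained), 1, tolerance = 1e-12)
  expect_true(all(diff(kp$eigenvalues) <= 1e-12))
})
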