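test_that("spd_sqrt returns the unique SPD square root", {
  expect_equal(spd_sqrt(diag(3)), diag(3))
  expect_equal(spd_sqrt(diag(c(4, 9))), diag(c(2, 3)))
  set.seed(11)
  for (n in 2:4) {
    S <- rand_spd(n)
    R <- spd_sqrt(S)
    expect_equal(R, t(R), tolerance = 1e-12)
    expect_lt(max(abs(R %*% R - S)), 1e-10 * max(1, max(abs(S))))
  }
  expect_error(spd_sqrt(matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("Gaussian Wasserstein distance matches closed forms and is symmetric", {
  I2 <- diag(2)
  expect_equal(wasserstein_gaussian(c(0, 0), I2, c(0, 0), I2), 0)
  # 1-D: sqrt((mu1-mu2)^2 + (sd1-sd2)^2)
  expect_equal(wasserstein_gaussian(0, matrix(4), 3, matrix(1)), sqrt(10))
  # equal means, commuting diagonal covariances
  expect_equal(
    wasserstein_gaussian(c(0, 0), diag(c(4, 1)), c(0, 0), diag(c(1, 4))),
    sqrt(2))
  set.seed(21)
  for (i in 1:10) {
    S1 <- rand_spd(3); S2 <- rand_spd(3)
    m1 <- rnorm(3); m2 <- rnorm(3)
    expect_equal(wasserstein_gaussian(m1, S1, m2, S2),
                 wasserstein_gaussian(m2, S2, m1, S1), tolerance = 1e-10)
  }
})

test_that("sylvester_gamma solves S G + G S = Y, including asymmetric Y", {
  Y <- rand_sym(3)
  expect_equal(sylvester_gamma(diag(3), Y), Y / 2)
  # entrywise division by lambda_i + lambda_j in the eigenbasis
  expect_equal(sylvester_gamma(diag(c(1, 3)), matrix(c(2, 4, 4, 6), 2)),
               matrix(1, 2, 2))
  set.seed(31)
  for (i in 1:10) {
    S <- rand_spd(3)
    Y <- matrix(rnorm(9), 3)          # asymmetric, as the curvature commutator
    G <- sylvester_gamma(S, Y)
    expect_lt(max(abs(S %*% G + G %*% S - Y)), 1e-10 * max(1, max(abs(Y))))
  }
  Ysym <- rand_sym(3)
  G <- sylvester_gamma(rand_spd(3), Ysym)
  expect_equal(G, t(G), tolerance = 1e-10)
})

test_that("the metric is symmetric, positive, and consistent with the distance", {
  set.seed(41)
  X <- rand_sym(3); Y <- rand_sym(3)
  expect_equal(metric_gw(diag(3), X, Y), sum(diag(X %*% Y)) / 4)
  for (i in 1:10) {
    S <- rand_spd(3)
    X <- rand_sym(3); Y <- rand_sym(3)
    expect_equal(metric_gw(S, X, Y), metric_gw(S, Y, X), tolerance = 1e-10)
    expect_gt(metric_gw(S, X, X), 0)
  }
  # second-order expansion of the squared distance recovers g(X, X)
  for (i in 1:5) {
    S <- rand_spd(3, cond_max = 100)
    X <- rand_sym(3)
    f <- function(t) {
      wasserstein_gaussian(rep(0, 3), S, rep(0, 3), S + t * X)^2 / t^2
    }
    richardson <- 2 * f(5e-4) - f(1e-3)
    g <- metric_gw(S, X, X)
    expect_equal(richardson, g, tolerance = 1e-3)
  }
})

test_that("the curvature tensor vanishes on parallel pairs and is orthogonally invariant", {
  set.seed(51)
  S <- rand_spd(3)
  X <- rand_sym(3)
  expect_equal(curvature_tensor(S, X, X), 0, tolerance = 1e-10)
  expect_equal(curvature_tensor(S, X, 2.7 * X), 0, tolerance = 1e-9)
  Y <- rand_sym(3)
  O <- rand_orthogonal(3)
  expect_equal(curvature_tensor(O %*% S %*% t(O), O %*% X %*% t(O), O %*% Y %*% t(O)),
               curvature_tensor(S, X, Y), tolerance = 1e-8)
})

test_that("sectional values of generic orthonormal pairs are positive and bounded", {
  set.seed(61)
  for (i in 1:10) {
    S <- rand_spd(3, cond_max = 100)
    X <- rand_sym(3)
    X <- X / sqrt(metric_gw(S, X, X))
    Y0 <- rand_sym(3)
    Y <- Y0 - metric_gw(S, Y0, X) * X
    Y <- Y / sqrt(metric_gw(S, Y, Y))
    K <- curvature_tensor(S, X, Y)
    lam <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    expect_gt(K, 0)
    expect_lt(K, 3 / lam[2])
  }
})

test_that("scalar curvature obeys the scale law and orthogonal invariance", {
  set.seed(71)
  S <- rand_spd(3)
  rho <- scalar_curvature(S)
  for (c in c(0.5, 2, 10)) {
    expect_equal(scalar_curvature(c * S), rho / c, tolerance = 1e-10)
  }
  O <- rand_orthogonal(3)
  expect_equal(scalar_curvature(O %*% S %*% t(O)), rho, tolerance = 1e-8)
  expect_gt(rho, 0)
})

test_that("closed-form scalar curvature agrees with the basis-summation oracle", {
  # frozen oracle values at the identity (computed by the double sum)
  expect_equal(scalar_curvature_oracle(diag(2)), 3, tolerance = 1e-8)
  expect_equal(scalar_curvature(diag(2)), 3, tolerance = 1e-8)
  expect_equal(scalar_curvature(diag(3)), 11.25, tolerance = 1e-8)
  expect_equal(scalar_curvature(diag(c(1, 2, 5))),
               scalar_curvature_oracle(diag(c(1, 2, 5))), tolerance = 1e-6)
  set.seed(81)
  for (n in 2:3) {
    for (i in 1:5) {
      S <- rand_spd(n)
      rho <- scalar_curvature(S)
      expect_equal(scalar_curvature_oracle(S), rho, tolerance = 1e-6)
    }
  }
})

test_that("the oracle is invariant under re-mixing of the starting basis", {
  set.seed(91)
  S <- rand_spd(2)
  base <- list(matrix(c(1, 0, 0, 0), 2), matrix(c(0, 0, 0, 1), 2),
               matrix(c(0, 1, 1, 0), 2))
  M <- matrix(rnorm(9), 3)
  while (abs(det(M)) < 0.1) M <- matrix(rnorm(9), 3)
  mixed <- lapply(1:3, function(i) {
    Reduce(`+`, Map(`*`, M[i, ], base))
  })
  expect_equal(scalar_curvature_oracle(S, basis = mixed),
               scalar_curvature_oracle(S), tolerance = 1e-8)
})

test_that("the second-smallest-eigenvalue bound holds and is tight in order", {
  expect_equal(curvature_upper_bound(diag(3)), 18)
  expect_equal(curvature_upper_bound(diag(c(0.09, 0.09, 1))), 200)
  set.seed(101)
  ratios <- replicate(100, {
    S <- rand_spd(3)
    scalar_curvature(S) / curvature_upper_bound(S)
  })
  expect_true(all(ratios > 0 & ratios < 1))
  expect_gt(max(ratios), 0.1)   # the bound is of the right order, not loose by magnitudes
})
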