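# Shrinkage covariance estimators: intensities, spectra, ridge precision.

test_that("sample covariance has divisor N-1, unit diagonal and the expected rank deficiency", {
  set.seed(101)
  # perfectly correlated pair: rank 1, eigenvalues (2, 0)
  x <- rnorm(20)
  S <- sample_covariance(autoscale(cbind(x, 2 * x + 5)))
  expect_equal(unname(S$matrix), matrix(c(1, 1, 1, 1), 2), tolerance = 1e-12)
  expect_equal(S$eigenvalues, c(2, 0), tolerance = 1e-10)
  expect_identical(S$intensity, 0)

  # auto-scaling forces a unit diagonal
  z <- autoscale(matrix(rnorm(15 * 8), 15))
  expect_equal(unname(diag(sample_covariance(z)$matrix)), rep(1, 8),
               tolerance = 1e-12)

  # P >= N: at least P - N + 1 zero eigenvalues
  z <- autoscale(matrix(rnorm(100 * 200), 100))
  ev <- sample_covariance(z)$eigenvalues
  expect_gte(sum(ev <= 1e-10), 200 - 100 + 1)

  expect_error(sample_covariance(matrix(1, 1, 3)), "N >= 2")
})

test_that("intensity estimators match independent transcriptions of their source formulas", {
  set.seed(202)
  for (dims in list(c(25, 250), c(12, 40), c(60, 20), c(50, 250), c(8, 100),
                    c(30, 30), c(45, 90), c(10, 10), c(100, 150), c(24, 6))) {
    X <- autoscale(draw_blocked(dims[1], dims[2], rho = 0.6, block = 5L))
    expect_equal(lw_intensity(X), oracle_lw_intensity(X), tolerance = 1e-10)
    expect_equal(oas_intensity(X), oracle_oas_intensity(X), tolerance = 1e-10)
    expect_equal(lt_intensity(X), oracle_lt_intensity(X), tolerance = 1e-8)
  }
})

test_that("Ledoit-Wolf intensity is near 0 when the sample covariance is trustworthy", {
  set.seed(303)
  x <- rnorm(4000)
  X <- autoscale(cbind(x, x + rnorm(4000, sd = 1e-3)))
  expect_lt(lw_intensity(X), 0.01)
})

test_that("Ledoit-Wolf intensity minimises the expected Frobenius loss (Monte-Carlo check)", {
  set.seed(404)
  p <- 5
  Sigma <- make_block_cov(p, 5L, 0.6)
  R <- chol(Sigma)
  grid <- seq(0, 1, by = 0.05)
  loss <- numeric(length(grid))
  lam_hat <- numeric(200)
  for (r in 1:200) {
    X <- matrix(rnorm(30 * p), 30) %*% R
    S <- cov(X)
    lam_hat[r] <- lw_intensity(X)
    for (g in seq_along(grid)) {
      loss[g] <- loss[g] + sum(((1 - grid[g]) * S + grid[g] * diag(p) - Sigma)^2)
    }
  }
  expect_lt(abs(grid[which.min(loss)] - mean(lam_hat)), 0.15)
})

test_that("degenerate spectra trigger the full-shrinkage branch", {
  # sample covariance exactly the identity: d2 = 0 for LW, OAS denominator 0
  H <- qr.Q(qr(cbind(1, matrix(rnorm(6 * 3), 6))))[, 2:4]
  X <- sqrt(5) * H # centered columns, cov(X) = I exactly
  expect_equal(unname(cov(X)), diag(3), tolerance = 1e-12)
  expect_warning(lw1 <- lw_intensity(X), "degenerate")
  expect_identical(lw1, 1)
  expect_warning(oas1 <- oas_intensity(X), "spherical")
  expect_identical(oas1, 1)
  # the nonparametric estimator works from fourth-moment trace estimates;
  # on this data they degenerate and full shrinkage is returned
  expect_identical(suppressWarnings(lt_intensity(X)), 1)
  set.seed(7)
  Z <- matrix(rnorm(40 * 120), 40) # Sigma = I: target equals the truth
  expect_identical(lt_intensity(autoscale(Z)), 1)
})

test_that("intensities decrease with the sample size and live in (0, 1)", {
  set.seed(505)
  p <- 100L
  Sigma <- make_block_cov(p, 25L, 0.8)
  R <- chol(Sigma)
  means <- sapply(c(25, 50, 100, 200), function(n) {
    est <- replicate(20, {
      X <- autoscale(matrix(rnorm(n * p), n) %*% R)
      c(lw_intensity(X), oas_intensity(X), lt_intensity(X))
    })
    rowMeans(est)
  })
  for (i in 1:3) {
    expect_true(all(diff(means[i, ]) <= 0))
    expect_true(all(means[i, ] > 0 & means[i, ] < 1))
  }
})

test_that("linear shrinkage maps the spectrum affinely and preserves/creates positive definiteness", {
  S <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(shrink_covariance(S, 0)$matrix, S)
  expect_equal(unname(shrink_covariance(S, 1)$matrix), diag(2))
  expect_equal(shrink_covariance(S, 0.5)$eigenvalues, c(1.5, 0.5),
               tolerance = 1e-10)
  expect_error(shrink_covariance(S, 1.2), "intensity")

  set.seed(606)
  for (r in 1:50) {
    n <- sample(5:40, 1)
    p <- sample(c(3, 10, 60, 150), 1)
    lam <- runif(1, 0.01, 1)
    X <- autoscale(matrix(rnorm(n * p), n))
    sh <- shrink_covariance(sample_covariance(X), lam)
    expect_gt(min(sh$eigenvalues), 0)
    # affine spectrum identity, against a from-scratch eigendecomposition
    ev <- eigen(sh$matrix, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sort(ev, decreasing = TRUE),
                 (1 - lam) * sample_covariance(X)$eigenvalues + lam,
                 tolerance = 1e-10)
  }
})

test_that("shrunken spectra are strictly less dispersed than sample spectra on identity-truth data", {
  set.seed(707)
  for (dims in list(c(800, 200), c(200, 200), c(100, 200))) {
    for (r in 1:20) {
      X <- autoscale(matrix(rnorm(dims[1] * dims[2]), dims[1]))
      S <- sample_covariance(X)
      spread <- max(S$eigenvalues) - min(S$eigenvalues)
      for (fn in c(lw_intensity, oas_intensity, lt_intensity)) {
        lam <- fn(X)
        sh <- shrink_covariance(S, lam)
        expect_lt(max(sh$eigenvalues) - min(sh$eigenvalues), spread)
      }
    }
  }
})

test_that("ridge precision follows the printed formula and is PD even for singular input", {
  # scalar case s = 4, delta = 1: ((1 + 0.25 * 9)^0.5 + 1.5)^-1
  pr <- vw_ridge_precision(matrix(4, 1, 1), 1)
  expect_equal(drop(pr$matrix), 1 / (sqrt(3.25) + 1.5), tolerance = 1e-12)
  expect_equal(drop(pr$matrix), 0.3028, tolerance = 1e-3)

  # S = I, delta = 1 forces the identity precision
  expect_equal(unname(vw_ridge_precision(diag(3), 1)$matrix), diag(3),
               tolerance = 1e-12)

  # rank-deficient S: finite positive spectrum matching the scalar formula
  set.seed(808)
  X <- autoscale(matrix(rnorm(10 * 25), 10))
  S <- sample_covariance(X)
  pr <- vw_ridge_precision(S, 0.1)
  ev <- eigen(pr$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_equal(sort(ev, decreasing = TRUE),
               oracle_vw_precision_eigenvalues(S$matrix, 0.1),
               tolerance = 1e-8)
  expect_error(vw_ridge_precision(S, 0), "positive")
})

test_that("ridge penalty selection maximises leave-one-out likelihood with ties to larger delta", {
  expect_identical(select_vw_delta(matrix(rnorm(20), 10), grid = 0.7), 0.7)
  expect_error(select_vw_delta(matrix(rnorm(20), 10), grid = c(1, -1)), "positive")

  set.seed(909)
  X <- autoscale(matrix(rnorm(25 * 8), 25)) # identity truth
  grid <- c(0.01, 1, 100)
  sel <- select_vw_delta(X, grid)
  # exhaustive evaluation of the three candidates
  ll <- sapply(grid, function(d) {
    tot <- 0
    for (i in 1:25) {
      Xi <- X[-i, , drop = FALSE]
      prec <- vw_ridge_precision(cov(Xi), d)$matrix
      z <- X[i, ] - colMeans(Xi)
      tot <- tot + 0.5 * (determinant(prec)$modulus - drop(t(z) %*% prec %*% z))
    }
    tot
  })
  expect_identical(sel, grid[which.max(ll)])

  # bit-for-bit reproducible under a fixed seed
  set.seed(11)
  X <- draw_blocked(25, 100, block = 25L)
  s1 <- select_vw_delta(X, c(0.05, 0.5, 5))
  s2 <- select_vw_delta(X, c(0.05, 0.5, 5))
  expect_identical(s1, s2)
})

test_that("the nonlinear estimator name is reserved but unimplemented", {
  expect_error(shrink_intensity(matrix(rnorm(40), 10), "nl_lw"), "not implemented")
})
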