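# Independent oracle implementations: literal, loop-based transcriptions of
# the source formulas, deliberately coded differently from the package
# internals (explicit P x P matrices, solve() instead of factorized
# quadratic forms, elementwise sums instead of Gram-matrix identities).

oracle_lw_intensity <- function(X) {
  n <- nrow(X)
  p <- ncol(X)
  C <- sweep(X, 2, colMeans(X))
  S <- crossprod(C) / (n - 1)
  m <- sum(diag(S)) / p
  d2 <- sum((S - m * diag(p))^2) / p
  b2sum <- 0
  for (k in seq_len(n)) {
    b2sum <- b2sum + sum((tcrossprod(C[k, ]) - S)^2)
  }
  b2 <- min(d2, b2sum / (n^2 * p))
  min(1, max(0, b2 / d2))
}

oracle_oas_intensity <- function(X) {
  n <- nrow(X)
  p <- ncol(X)
  S <- cov(X)
  tr <- sum(diag(S))
  tr2 <- sum(S * S)
  num <- (1 - 2 / p) * tr2 + tr^2
  den <- (n + 1 - 2 / p) * (tr2 - tr^2 / p)
  if (den <= 0) 1 else min(1, num / den)
}

oracle_lt_intensity <- function(X) {
  n <- nrow(X)
  p <- ncol(X)
  C <- sweep(X, 2, colMeans(X))
  S <- crossprod(C) / (n - 1)
  y1 <- sum(diag(S))
  q <- 0
  for (k in seq_len(n)) q <- q + sum(C[k, ]^2)^2
  q <- q / (n - 1)
  y2 <- (n - 1) / (n * (n - 2) * (n - 3)) *
    ((n - 1) * (n - 2) * sum(S^2) + y1^2 - n * q)
  min(1, max(0, (y1^2 + y2) / (n * y2 + y1^2 + (n - 1) * (p - 2 * y1))))
}

# scalar evaluation of the ridge-precision formula on each eigenvalue
oracle_vw_precision_eigenvalues <- function(S, delta) {
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  sort(1 / (sqrt(delta + 0.25 * (lam - delta)^2) + 0.5 * (lam - delta)),
       decreasing = TRUE)
}

oracle_md2 <- function(y, x_train, intensity) {
  mu <- colMeans(x_train)
  sds <- apply(x_train, 2, sd)
  z <- (y - mu) / sds
  Z <- sweep(sweep(x_train, 2, mu), 2, sds, "/")
  Sig <- (1 - intensity) * cov(Z) + intensity * diag(ncol(x_train))
  drop(t(z) %*% solve(Sig) %*% z)
}

# reference data with a blocked correlation; returns the raw matrix
draw_blocked <- function(n, p, rho = 0.8, block = 10L) {
  R <- chol(make_block_cov(p, block, rho))
  matrix(rnorm(n * p), n) %*% R
}
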