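# Linear eigenvalue-shrinkage estimators of the reference-class covariance
# matrix.  All intensity estimators shrink toward the identity target, the
# natural choice for auto-scaled data (unit variances, correlations pulled
# toward zero).  `intensity` is always the weight placed on the TARGET:
# 0 = pure sample covariance, 1 = pure identity.

#' Summary statistics of a centered data matrix
#'
#' Computes tr(S), tr(S^2), per-row quadratic forms and fourth-power norms
#' needed by the shrinkage-intensity estimators, where S is the sample
#' covariance with divisor n - 1.  When P > n everything is computed from the
#' n x n Gram matrix of the centered rows, so the P x P covariance is never
#' formed; this is what makes leave-one-out refitting affordable for
#' metabolomics-sized P.
#'
#' @param x numeric matrix, observations in rows.
#' @param center logical; center columns at their means first (default TRUE).
#' @return list with n, p, trS, trS2, xnorm2 (squared row norms of the
#'   centered rows), xSx (row-wise quadratic forms x' S x), and q
#'   (sum(xnorm2^2) / (n - 1), the fourth-moment statistic used by the
#'   nonparametric Steinian intensity).
#' @keywords internal
scatter_stats <- function(x, center = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L) stop("at least 2 observations are required")
  C <- if (center) sweep(x, 2L, colMeans(x), "-") else x
  m <- n - 1
  if (p > n) {
    G <- tcrossprod(C)
    dG <- diag(G)
    trS <- sum(dG) / m
    trS2 <- sum(G * G) / m^2
    xnorm2 <- dG
    xSx <- colSums(G * G) / m # G symmetric: ||G[, k]||^2 / m = x_k' S x_k
  } else {
    S <- crossprod(C) / m
    trS <- sum(diag(S))
    trS2 <- sum(S * S)
    xnorm2 <- rowSums(C * C)
    xSx <- rowSums((C %*% S) * C)
  }
  list(n = n, p = p, trS = trS, trS2 = trS2,
       xnorm2 = xnorm2, xSx = xSx, q = sum(xnorm2^2) / m)
}

# Clipping events are frequent and benign when the target is close to the
# truth (the raw optimum overshoots 1), so they are only reported when
# options(escm.verbose = TRUE).
.clip01 <- function(x, label) {
  if (x < 0 || x > 1) {
    if (isTRUE(getOption("escm.verbose", FALSE))) {
      message(sprintf("%s intensity %.4g clipped to [0, 1]", label, x))
    }
    x <- min(1, max(0, x))
  }
  x
}

#' Sample covariance estimate
#'
#' The usual unbiased sample covariance (divisor N - 1) wrapped as a
#' `cov_estimate` object carrying its spectrum and a shrinkage intensity of
#' zero.  For auto-scaled data the diagonal is exactly 1.  When P >= N the
#' matrix is rank deficient: at least P - N + 1 eigenvalues are zero, which
#' is precisely why the plain Mahalanobis distance breaks down for
#' untargeted metabolomics tables.
#'
#' @param x numeric matrix of (auto-scaled) observations, samples in rows.
#' @return object of class `cov_estimate`: list with `matrix`, `intensity`
#'   (0), `estimator_name` ("sample") and `eigenvalues` (nonincreasing).
#' @export
#' @examples
#' z <- autoscale(matrix(rnorm(40), 10, 4))
#' S <- sample_covariance(z)
#' range(diag(S$matrix)) # unit diagonal
sample_covariance <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("sample covariance requires N >= 2 observations")
  S <- stats::cov(x)
  new_cov_estimate(S, intensity = 0, estimator_name = "sample")
}

new_cov_estimate <- function(S, intensity, estimator_name,
                             eigenvalues = NULL) {
  if (is.null(eigenvalues)) {
    eigenvalues <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  }
  structure(
    list(matrix = S, intensity = intensity,
         estimator_name = estimator_name,
         eigenvalues = sort(eigenvalues, decreasing = TRUE)),
    class = "cov_estimate")
}

#' @export
print.cov_estimate <- function(x, ...) {
  p <- ncol(x$matrix)
  cat(sprintf("Covariance estimate (%s), P = %d\n", x$estimator_name, p))
  cat(sprintf("  shrinkage intensity (weight on identity target): %.4f\n",
              x$intensity))
  cat(sprintf("  eigenvalue range: [%.4g, %.4g]\n",
              min(x$eigenvalues), max(x$eigenvalues)))
  invisible(x)
}

#' Ledoit-Wolf analytic shrinkage intensity
#'
#' Analytic optimal weight on the identity target for the linear shrinkage
#' estimator (1 - intensity) * S + intensity * I, following the original
#' well-conditioned-estimator construction: with m = tr(S)/P,
#' d2 = ||S - mI||_F^2 / P and
#' b2 = min(d2, sum_k ||x_k x_k' - S||_F^2 / (N^2 P)), the intensity is
#' b2 / d2, clipped to \[0, 1\].  For auto-scaled data m = 1 so the target
#' is exactly the identity.
#'
#' @param x auto-scaled numeric matrix (samples in rows), N >= 2.
#' @return shrinkage intensity in \[0, 1\].
#' @export
lw_intensity <- function(x) {
  st <- scatter_stats(x)
  .lw_from_stats(st)
}

.lw_from_stats <- function(st) {
  mbar <- st$trS / st$p
  d2 <- (st$trS2 - 2 * mbar * st$trS + mbar^2 * st$p) / st$p
  if (d2 <= .Machine$double.eps * st$p) {
    warning("sample covariance already equals the target (degenerate spectrum); intensity = 1")
    return(1)
  }
  b2sum <- sum(st$xnorm2^2 - 2 * st$xSx) + st$n * st$trS2
  b2 <- min(d2, b2sum / (st$n^2 * st$p))
  .clip01(b2 / d2, "Ledoit-Wolf")
}

#' Oracle-approximating (OAS) shrinkage intensity
#'
#' Closed-form intensity derived under multivariate normality,
#' rho = min(1, \[(1 - 2/P) tr(S^2) + tr(S)^2\] /
#' \[(N + 1 - 2/P)(tr(S^2) - tr(S)^2 / P)\]).  When S is exactly spherical
#' the denominator vanishes and full shrinkage (1) is returned with a
#' warning.
#'
#' @inheritParams lw_intensity
#' @return shrinkage intensity in \[0, 1\].
#' @export
oas_intensity <- function(x) {
  st <- scatter_stats(x)
  .oas_from_stats(st)
}

.oas_from_stats <- function(st) {
  num <- (1 - 2 / st$p) * st$trS2 + st$trS^2
  den <- (st$n + 1 - 2 / st$p) * (st$trS2 - st$trS^2 / st$p)
  if (den <= 1e-12 * num) {
    warning("sample covariance is spherical; OAS intensity = 1")
    return(1)
  }
  min(1, num / den)
}

#' Nonparametric Steinian (Touloumis) shrinkage intensity
#'
#' Nonparametric optimal weight on the identity target, built from unbiased
#' U-statistic estimators of tr(Sigma) and tr(Sigma^2):
#' Y1 = tr(S), and
#' Y2 = (N-1) / (N (N-2) (N-3)) \[(N-1)(N-2) tr(S^2) + tr(S)^2 - N Q\]
#' with Q = sum_i ((x_i - xbar)'(x_i - xbar))^2 / (N - 1).  The intensity is
#' (Y1^2 + Y2) / (N Y2 + Y1^2 + (N-1)(P - 2 Y1)), clipped to \[0, 1\].
#' Being moment-based rather than likelihood-based, it is robust to
#' departures from normality and is the default estimator used by
#' [escm()].
#'
#' @param x auto-scaled numeric matrix (samples in rows); the unbiased trace
#'   estimators require N >= 4.
#' @return shrinkage intensity in \[0, 1\].
#' @export
lt_intensity <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 4L) stop("the nonparametric intensity requires N >= 4 observations")
  st <- scatter_stats(x)
  .lt_from_stats(st)
}

.lt_from_stats <- function(st) {
  n <- st$n
  if (n < 4L) stop("the nonparametric intensity requires N >= 4 observations")
  y1 <- st$trS
  y2 <- (n - 1) / (n * (n - 2) * (n - 3)) *
    ((n - 1) * (n - 2) * st$trS2 + st$trS^2 - n * st$q)
  num <- y1^2 + y2
  den <- n * y2 + y1^2 + (n - 1) * (st$p - 2 * y1)
  if (den <= 0) {
    warning("degenerate trace estimates; intensity = 1")
    return(1)
  }
  .clip01(num / den, "nonparametric Steinian")
}

#' Shrinkage intensity by estimator name
#'
#' @param x auto-scaled numeric matrix, samples in rows.
#' @param method one of `"lt"` (nonparametric Steinian, default), `"oas"`
#'   (oracle approximating), `"lw"` (Ledoit-Wolf analytic).  The nonlinear
#'   spectral-density estimator (`"nl_lw"`) is recognised but not
#'   implemented: it is computationally infeasible inside the leave-one-out
#'   limit calibration and linear shrinkage captures most of the gain when
#'   P/N is large.
#' @return shrinkage intensity in \[0, 1\].
#' @export
shrink_intensity <- function(x, method = c("lt", "oas", "lw", "nl_lw")) {
  method <- match.arg(method)
  switch(method,
    lt = lt_intensity(x),
    oas = oas_intensity(x),
    lw = lw_intensity(x),
    nl_lw = stop("nonlinear spectral-density shrinkage is not implemented"))
}

#' Linear shrinkage of a covariance estimate toward a target
#'
#' Returns (1 - intensity) * S + intensity * T.  The spectrum transforms
#' affinely: eig(result) = (1 - intensity) * eig(S) + intensity * eig(T), so
#' the result is positive definite for any intensity > 0 even when S is
#' singular.
#'
#' @param S a `cov_estimate` (or plain symmetric matrix).
#' @param intensity weight on the target, in \[0, 1\].
#' @param target `"identity"` or a numeric vector giving a diagonal target.
#' @return a `cov_estimate`.
#' @export
shrink_covariance <- function(S, intensity, target = "identity") {
  if (!is.numeric(intensity) || length(intensity) != 1L ||
      intensity < 0 || intensity > 1) {
    stop("intensity must be a single number in [0, 1]")
  }
  est <- if (inherits(S, "cov_estimate")) S else sample_covariance_from_matrix(S)
  tdiag <- if (identical(target, "identity")) {
    rep(1, ncol(est$matrix))
  } else if (is.numeric(target) && is.vector(target)) {
    if (length(target) != ncol(est$matrix)) stop("diagonal target has wrong length")
    target
  } else {
    stop("target must be \"identity\" or a numeric diagonal")
  }
  M <- (1 - intensity) * est$matrix
  diag(M) <- diag(M) + intensity * tdiag
  ev <- if (identical(target, "identity")) {
    (1 - intensity) * est$eigenvalues + intensity
  } else NULL
  out <- new_cov_estimate(M, intensity = intensity,
                          estimator_name = paste0("shrunk_", est$estimator_name),
                          eigenvalues = ev)
  out
}

# wrap a bare symmetric matrix (not necessarily from data)
sample_covariance_from_matrix <- function(S) {
  S <- as.matrix(S)
  if (!isSymmetric(S, tol = 1e-8)) stop("covariance matrix must be symmetric")
  new_cov_estimate(S, intensity = 0, estimator_name = "sample")
}

#' Ridge (van Wieringen) precision estimate
#'
#' Direct ridge estimator of the inverse covariance,
#' \[ (delta I + 0.25 (S - delta T)^2)^{1/2} + 0.5 (S - delta T) \]^{-1}
#' with identity target T, equivalent to a nonlinear shrinkage of the sample
#' eigenvalues.  Computed by symmetric eigendecomposition (eigenvalues
#' floored at 0 before the square root), so the result is symmetric positive
#' definite for any delta > 0 even when S is singular.
#'
#' @param S a `cov_estimate` or symmetric matrix.
#' @param delta ridge penalty, > 0.
#' @return object of class `precision_estimate` with a dense `matrix`,
#'   `source = "vw_ridge"` and `ridge_delta`.
#' @export
vw_ridge_precision <- function(S, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) {
    stop("delta must be a single positive number")
  }
  est <- if (inherits(S, "cov_estimate")) S else sample_covariance_from_matrix(S)
  e <- eigen(est$matrix, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  d <- lam - delta
  prec_ev <- 1 / (sqrt(delta + 0.25 * d^2) + 0.5 * d)
  M <- e$vectors %*% (prec_ev * t(e$vectors))
  M <- (M + t(M)) / 2
  structure(list(type = "dense", matrix = M, source = "vw_ridge",
                 ridge_delta = delta, eigenvalues = sort(prec_ev, decreasing = TRUE)),
            class = "precision_estimate")
}

#' Select the ridge penalty by leave-one-out likelihood
#'
#' Evaluates each candidate delta by the sum over observations of the
#' Gaussian log-likelihood of the held-out row under the ridge precision
#' estimated from the remaining rows, and returns the maximiser (ties broken
#' toward the larger, i.e. more regularised, delta).
#'
#' @param x auto-scaled numeric matrix, samples in rows (N >= 3).
#' @param grid numeric vector of candidate penalties, all > 0.
#' @return the selected delta.
#' @export
select_vw_delta <- function(x, grid) {
  if (length(grid) == 0L) stop("grid must be nonempty")
  if (any(grid <= 0)) stop("grid values must be positive")
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("leave-one-out selection requires N >= 3")
  ll <- numeric(length(grid))
  for (i in seq_len(n)) {
    xi <- x[-i, , drop = FALSE]
    S <- stats::cov(xi)
    mu <- colMeans(xi)
    z <- x[i, ] - mu
    e <- eigen(S, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    w <- drop(crossprod(e$vectors, z))
    for (g in seq_along(grid)) {
      d <- lam - grid[g]
      pe <- 1 / (sqrt(grid[g] + 0.25 * d^2) + 0.5 * d)
      ll[g] <- ll[g] + 0.5 * (sum(log(pe)) - sum(pe * w^2))
    }
  }
  # ties toward larger delta
  best <- max(ll)
  max(grid[ll >= best - 1e-9 * abs(best)])
}
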