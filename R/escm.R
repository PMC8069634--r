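# The eigenvalue-shrinkage one-class model (ES-CM): auto-scaling, shrunken
# Mahalanobis distance, and a critical limit from a scaled chi-square
# distribution moment-matched to leave-one-out cross-validated distances.

#' Fit an auto-scaler
#'
#' Per-variable means and standard deviations (divisor N - 1) of the
#' training table.  All data entering the one-class model -- training rows
#' and new observations alike -- is standardised with these training
#' parameters, so the model is invariant to the units of each variable.
#'
#' @param x numeric matrix, samples in rows; no missing values.
#' @return object of class `escm_scaler` with `means` and `sds`.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("at least 2 observations are required to fit a scaler")
  if (anyNA(x)) stop("missing values are not allowed; impute non-detects first")
  mu <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  bad <- which(sds < 1e-12)
  if (length(bad)) {
    nm <- colnames(x)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("constant column(s) cannot be auto-scaled: ",
         paste(utils::head(nm, 10L), collapse = ", "))
  }
  structure(list(means = mu, sds = sds), class = "escm_scaler")
}

#' Apply an auto-scaler
#'
#' @param scaler an `escm_scaler` from [fit_scaler()].
#' @param x numeric matrix (or vector of length P) to standardise.
#' @return matrix of the same shape with zero-mean unit-variance columns
#'   relative to the training data.
#' @export
apply_scaler <- function(scaler, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != length(scaler$means)) {
    stop(sprintf("expected %d variables, got %d", length(scaler$means), ncol(x)))
  }
  sweep(sweep(x, 2L, scaler$means, "-"), 2L, scaler$sds, "/")
}

#' Auto-scale a matrix
#'
#' Convenience wrapper: fit a scaler on `x` and apply it to `x`.
#' @inheritParams fit_scaler
#' @return the auto-scaled matrix (attribute `"scaler"` holds the fitted
#'   scaler).
#' @export
autoscale <- function(x) {
  sc <- fit_scaler(x)
  z <- apply_scaler(sc, x)
  attr(z, "scaler") <- sc
  z
}

# --- precision representations ------------------------------------------

# A shrunken covariance (1 - lambda) S + lambda I with S = C'C / m admits a
# Woodbury inverse through the n x n Gram matrix of the centered rows C, so
# Mahalanobis distances cost O(nP) per observation and the P x P precision
# never needs to be formed.  `new_precision_lowrank` stores that implicit
# factorisation; `new_precision_dense` stores an explicit matrix.

new_precision_dense <- function(M, source = "inverted_covariance") {
  structure(list(type = "dense", matrix = (M + t(M)) / 2, source = source),
            class = "precision_estimate")
}

new_precision_lowrank <- function(C, lambda, divisor) {
  n <- nrow(C)
  if (lambda <= 1e-12) {
    stop("shrinkage intensity is (numerically) zero with P >= N: covariance not invertible")
  }
  G <- tcrossprod(C)
  K <- diag(lambda, n) + ((1 - lambda) / divisor) * G
  structure(list(type = "lowrank", C = C, lambda = lambda, divisor = divisor,
                 chol = chol(K), source = "inverted_covariance"),
            class = "precision_estimate")
}

# quadratic forms z' P z for rows of Z (already auto-scaled)
.prec_quadform <- function(prec, Z) {
  if (is.vector(Z)) Z <- matrix(Z, nrow = 1L)
  if (prec$type == "dense") {
    rowSums((Z %*% prec$matrix) * Z)
  } else {
    w <- ((1 - prec$lambda) / prec$divisor)
    CZ <- tcrossprod(prec$C, Z) # n x m
    u <- backsolve(prec$chol, CZ, transpose = TRUE)
    (rowSums(Z * Z) - w * colSums(u * u)) / prec$lambda
  }
}

#' Materialise a precision estimate as a matrix
#' @param prec a `precision_estimate`.
#' @return dense P x P symmetric positive-definite matrix.
#' @export
as_precision_matrix <- function(prec) {
  if (prec$type == "dense") return(prec$matrix)
  p <- ncol(prec$C)
  w <- (1 - prec$lambda) / prec$divisor
  B <- backsolve(prec$chol, prec$C, transpose = TRUE)
  M <- (diag(p) - w * crossprod(B)) / prec$lambda
  (M + t(M)) / 2
}

# precision of (1 - lambda) S + lambda I from scaled data Z (centered at the
# scaler mean, i.e. already mean zero for the training set)
.shrunk_precision <- function(C, lambda, divisor) {
  n <- nrow(C)
  p <- ncol(C)
  if (p > n) return(new_precision_lowrank(C, lambda, divisor))
  S <- crossprod(C) / divisor
  M <- (1 - lambda) * S
  diag(M) <- diag(M) + lambda
  new_precision_dense(chol2inv(chol(M)))
}

#' Squared Mahalanobis distance of new observations
#'
#' MD^2(y) = z' Sigma^{-1} z where z is y auto-scaled with the training
#' scaler.  When the precision is held as a low-rank (Woodbury)
#' factorisation the distance is computed by a triangular solve, never by
#' explicit inversion.
#'
#' @param y numeric vector of length P or an M x P matrix.
#' @param scaler an `escm_scaler`.
#' @param precision a `precision_estimate`.
#' @return numeric vector of squared distances (always >= 0).
#' @export
md_squared <- function(y, scaler, precision) {
  Z <- apply_scaler(scaler, y)
  pmax(.prec_quadform(precision, Z), 0)
}

#' Classical F-based Mahalanobis critical limit (N > P only)
#'
#' Prediction-form Hotelling limit for the squared Mahalanobis distance of a
#' new observation under multivariate normality with the sample mean and
#' covariance estimated from N references:
#' P (N - 1)(N + 1) / (N (N - P)) * F_(1 - alpha)(P, N - P).
#' Only defined for N > P; high-dimensional tables need the shrinkage model
#' ([escm()]) instead.
#'
#' @param n number of reference observations.
#' @param p number of variables.
#' @param alpha significance level in (0, 1).
#' @return the critical value for MD^2.
#' @export
classical_md_limit <- function(n, p, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n <= p) {
    stop("the classical F-based limit requires N > P; use escm() for high-dimensional data")
  }
  p * (n - 1) * (n + 1) / (n * (n - p)) * stats::qf(1 - alpha, p, n - p)
}

#' Leave-one-out cross-validated shrunken Mahalanobis distances
#'
#' For each reference observation: the mean and the shrinkage covariance
#' (with its intensity) are re-estimated from the other N - 1 rows, and the
#' squared Mahalanobis distance of the held-out row about that fold's mean
#' is computed against the fold's precision.  The auto-scaling itself is fit
#' once on the full reference set and held fixed across folds (only the
#' model -- mean and covariance -- is re-estimated, mirroring the
#' limit-calibration algorithm); `refit_scaler = TRUE` additionally
#' re-standardises within each fold, which makes the held-out row fully
#' out-of-sample and yields a slightly more conservative limit.
#'
#' @param x raw reference matrix, samples in rows (N >= 5).
#' @param estimator `"lt"`, `"oas"` or `"lw"`.
#' @param refit_scaler logical; re-fit the auto-scaler inside each fold.
#' @return numeric vector of length N, in row order.
#' @export
loo_cv_md2 <- function(x, estimator = c("lt", "oas", "lw"),
                       refit_scaler = FALSE) {
  estimator <- match.arg(estimator)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 5L) stop("leave-one-out calibration requires N >= 5 references")
  if (anyNA(x)) stop("missing values are not allowed")
  sc <- fit_scaler(x)
  Z <- apply_scaler(sc, x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (refit_scaler) {
      sci <- fit_scaler(x[-i, , drop = FALSE])
      Zi <- apply_scaler(sci, x[-i, , drop = FALSE])
      zi <- apply_scaler(sci, x[i, ])
    } else {
      Zi <- Z[-i, , drop = FALSE]
      fold_mean <- colMeans(Zi)
      zi <- matrix(Z[i, ] - fold_mean, nrow = 1L)
      Zi <- sweep(Zi, 2L, fold_mean, "-")
    }
    Ci <- Zi # centered at the fold mean
    st <- scatter_stats(Ci, center = FALSE)
    lam <- switch(estimator,
                  lt = .lt_from_stats(st),
                  oas = .oas_from_stats(st),
                  lw = .lw_from_stats(st))
    prec <- .shrunk_precision(Ci, lam, divisor = n - 2)
    out[i] <- max(.prec_quadform(prec, zi), 0)
  }
  out
}

#' Scaled chi-square critical limit from cross-validated distances
#'
#' Approximates the null distribution of the shrunken MD^2 by a scaled
#' chi-square law g1 * chisq(g2) fitted to the leave-one-out distances.  The
#' default mode matches the first two moments exactly: with m = mean and
#' s2 = sample variance of the CV distances, g1 = s2 / (2 m) and
#' g2 = 2 m^2 / s2, so that g1 * g2 = m and 2 * g1^2 * g2 = s2.  Mode
#' `"paper_printed"` uses g1 = s2 / m (a published variant whose implied
#' mean is 2 m); it is provided for replication only and yields a far more
#' conservative limit.
#'
#' @param cv_md2 numeric vector of cross-validated squared distances
#'   (length >= 3, nonconstant).
#' @param alpha significance level in (0, 1).
#' @param mode `"moment_matched"` (default) or `"paper_printed"`.
#' @return list with `g1`, `g2` and `md2_crit = g1 * qchisq(1 - alpha, g2)`.
#' @export
scaled_chi2_limit <- function(cv_md2, alpha = 0.05,
                              mode = c("moment_matched", "paper_printed")) {
  mode <- match.arg(mode)
  if (length(cv_md2) < 3L) stop("need at least 3 cross-validated distances")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  m <- mean(cv_md2)
  s2 <- stats::var(cv_md2)
  if (!is.finite(s2) || s2 <= 0) {
    stop("cross-validated distances have zero variance (duplicated references?)")
  }
  g1 <- if (mode == "moment_matched") s2 / (2 * m) else s2 / m
  g2 <- 2 * m^2 / s2
  list(g1 = g1, g2 = g2, md2_crit = g1 * stats::qchisq(1 - alpha, g2))
}

#' Bootstrap critical limit from cross-validated distances
#'
#' Nonparametric alternative to the scaled chi-square limit: the mean over B
#' bootstrap resamples of the empirical (1 - alpha) quantile (type-7
#' interpolation) of the cross-validated distances.
#'
#' @inheritParams scaled_chi2_limit
#' @param B number of bootstrap resamples (>= 100 recommended; >= 1 allowed).
#' @param seed optional integer seed for reproducibility.
#' @return the critical value for MD^2.
#' @export
bootstrap_limit <- function(cv_md2, alpha = 0.05, B = 2000L, seed = NULL) {
  if (length(cv_md2) < 5L) stop("need at least 5 cross-validated distances")
  if (B < 1L) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(cv_md2)
  q <- numeric(B)
  for (b in seq_len(B)) {
    q[b] <- stats::quantile(cv_md2[sample.int(n, n, replace = TRUE)],
                            probs = 1 - alpha, type = 7, names = FALSE)
  }
  mean(q)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Exact two-sided interval for a binomial proportion via beta quantiles;
#' used as the acceptance band around the nominal type-I error level when
#' evaluating a one-class model on a finite number of test observations.
#'
#' @param x number of successes (0 <= x <= n).
#' @param n number of trials (>= 1).
#' @param conf confidence level (default 0.95).
#' @return numeric vector `c(lo, hi)`; `lo = 0` when `x = 0` and `hi = 1`
#'   when `x = n`.
#' @export
#' @examples
#' round(clopper_pearson(6, 120), 3) # 0.019 0.106
clopper_pearson <- function(x, n, conf = 0.95) {
  if (n < 1L || x < 0 || x > n) stop("need 0 <= x <= n with n >= 1")
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lo = lo, hi = hi)
}

# --- the fitted model ----------------------------------------------------

#' Fit an eigenvalue-shrinkage one-class model
#'
#' Trains a one-class classifier on a table of reference samples.  The data
#' is auto-scaled, the reference covariance is estimated by linear
#' eigenvalue-shrinkage toward the identity (intensity chosen by the
#' selected estimator), and the critical limit for the squared Mahalanobis
#' distance is calibrated on leave-one-out cross-validated distances through
#' a moment-matched scaled chi-square distribution.  New observations whose
#' shrunken MD^2 exceeds the limit are flagged as outliers by
#' [predict.escm()].
#'
#' @param x raw reference matrix (samples in rows, N >= 5) or a
#'   [metabolite_table()].
#' @param alpha significance level for the critical limit (default 0.05).
#' @param estimator shrinkage-intensity estimator: `"lt"` (nonparametric
#'   Steinian, the default -- fastest with type-I error closest to nominal in
#'   the simulation study), `"oas"`, or `"lw"`.
#' @param limit_mode `"moment_matched"` (default), `"paper_printed"`, or
#'   `"bootstrap"` (see [scaled_chi2_limit()] and [bootstrap_limit()]).
#' @param refit_scaler re-fit the auto-scaler inside each cross-validation
#'   fold (default FALSE: the scaler is fit once on all references).
#' @param boot_B bootstrap resamples when `limit_mode = "bootstrap"`.
#' @return object of class `escm`: list with `scaler`, `intensity`,
#'   `estimator`, `precision` (a `precision_estimate`), `cv_md2`, `g1`,
#'   `g2`, `md2_crit`, `alpha`, `limit_mode`, `n`, `p`.
#' @seealso [predict.escm()], [summary.escm()], [simulate.escm()],
#'   [write_escm_json()]
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(30 * 60), 30, 60) # 30 references, 60 variables
#' fit <- escm(x)
#' fit
#' pred <- predict(fit, matrix(rnorm(5 * 60), 5, 60))
#' pred
escm <- function(x, alpha = 0.05, estimator = c("lt", "oas", "lw"),
                 limit_mode = c("moment_matched", "paper_printed", "bootstrap"),
                 refit_scaler = FALSE, boot_B = 2000L) {
  estimator <- match.arg(estimator)
  limit_mode <- match.arg(limit_mode)
  if (inherits(x, "metabolite_table")) x <- as.matrix(x)
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 5L) stop("fitting requires N >= 5 references")
  if (anyNA(x)) stop("missing values are not allowed; impute non-detects first")

  sc <- fit_scaler(x)
  Z <- apply_scaler(sc, x)
  st <- scatter_stats(Z, center = FALSE) # training columns have mean 0 exactly
  lam <- switch(estimator,
                lt = .lt_from_stats(st),
                oas = .oas_from_stats(st),
                lw = .lw_from_stats(st))
  prec <- .shrunk_precision(Z, lam, divisor = n - 1)
  cv <- loo_cv_md2(x, estimator = estimator, refit_scaler = refit_scaler)

  if (limit_mode == "bootstrap") {
    lim <- list(g1 = NA_real_, g2 = NA_real_,
                md2_crit = bootstrap_limit(cv, alpha = alpha, B = boot_B))
  } else {
    lim <- scaled_chi2_limit(cv, alpha = alpha, mode = limit_mode)
  }
  structure(
    list(scaler = sc, intensity = lam, estimator = estimator,
         precision = prec, cv_md2 = cv,
         g1 = lim$g1, g2 = lim$g2, md2_crit = lim$md2_crit,
         alpha = alpha, limit_mode = limit_mode, n = n, p = p,
         variable_names = colnames(x)),
    class = "escm")
}

#' Classify new observations with a fitted one-class model
#'
#' Applies the training auto-scaler to the new rows, computes their shrunken
#' squared Mahalanobis distances, and flags those strictly above the
#' critical limit (equality classifies as inside the class).
#'
#' @param object a fitted `escm` model.
#' @param newdata M x P matrix (or [metabolite_table()]) with the training
#'   variables, in order; if both carry column names they must match.
#' @param ids optional sample identifiers (defaults to rownames or an index).
#' @param ... unused.
#' @return an `escm_classification`: data frame with columns `sample_id`,
#'   `md2`, `md2_crit`, `outlier`.
#' @export
predict.escm <- function(object, newdata, ids = NULL, ...) {
  if (inherits(newdata, "metabolite_table")) {
    if (is.null(ids)) ids <- newdata$sample_ids
    newdata <- as.matrix(newdata)
  }
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) {
    stop(sprintf("model was trained on %d variables; newdata has %d",
                 object$p, ncol(newdata)))
  }
  if (!is.null(object$variable_names) && !is.null(colnames(newdata)) &&
      !identical(object$variable_names, colnames(newdata))) {
    stop("variable names of newdata do not match the training variables")
  }
  if (is.null(ids)) {
    ids <- rownames(newdata)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(newdata)))
  }
  d2 <- md_squared(newdata, object$scaler, object$precision)
  out <- data.frame(sample_id = ids, md2 = d2,
                    md2_crit = object$md2_crit,
                    outlier = d2 > object$md2_crit,
                    stringsAsFactors = FALSE)
  class(out) <- c("escm_classification", "data.frame")
  out
}

#' @export
print.escm <- function(x, ...) {
  cat("Eigenvalue-shrinkage one-class model (ES-CM)\n")
  cat(sprintf("  references: N = %d, variables: P = %d\n", x$n, x$p))
  cat(sprintf("  intensity (%s, weight on identity target): %.4f\n",
              toupper(x$estimator), x$intensity))
  cat(sprintf("  critical limit (alpha = %g, %s): MD^2 = %.4f\n",
              x$alpha, x$limit_mode, x$md2_crit))
  invisible(x)
}

#' @export
summary.escm <- function(object, ...) {
  flagged <- sum(object$cv_md2 > object$md2_crit)
  out <- list(n = object$n, p = object$p, estimator = object$estimator,
              intensity = object$intensity, alpha = object$alpha,
              limit_mode = object$limit_mode,
              g1 = object$g1, g2 = object$g2, md2_crit = object$md2_crit,
              cv_mean = mean(object$cv_md2), cv_var = stats::var(object$cv_md2),
              cv_flagged = flagged,
              cv_band = clopper_pearson(round(object$alpha * object$n), object$n))
  class(out) <- "summary.escm"
  out
}

#' @export
print.summary.escm <- function(x, ...) {
  cat("Eigenvalue-shrinkage one-class model (ES-CM)\n")
  cat(sprintf("  references: N = %d, variables: P = %d\n", x$n, x$p))
  cat(sprintf("  shrinkage estimator: %s, intensity = %.4f\n",
              toupper(x$estimator), x$intensity))
  cat(sprintf("  cross-validated MD^2: mean = %.3f, variance = %.3f\n",
              x$cv_mean, x$cv_var))
  if (x$limit_mode != "bootstrap") {
    cat(sprintf("  scaled chi-square limit: g1 = %.4f, g2 = %.2f\n", x$g1, x$g2))
  }
  cat(sprintf("  critical limit (alpha = %g): MD^2 = %.4f\n", x$alpha, x$md2_crit))
  cat(sprintf("  references flagged in cross-validation: %d of %d (%.1f%%)\n",
              x$cv_flagged, x$n, 100 * x$cv_flagged / x$n))
  cat(sprintf("  Clopper-Pearson band at nominal level: %.1f%% - %.1f%%\n",
              100 * x$cv_band[1], 100 * x$cv_band[2]))
  invisible(x)
}

#' Distance plot of a fitted one-class model
#'
#' Index plot of the cross-validated reference distances with the critical
#' limit as a horizontal line; optionally overlays the distances of new
#' observations.
#'
#' @param x a fitted `escm` model.
#' @param newdata optional matrix of new observations to overlay.
#' @param ... passed to [graphics::plot()].
#' @export
plot.escm <- function(x, newdata = NULL, ...) {
  d <- x$cv_md2
  col <- rep("grey30", length(d))
  pch <- rep(1L, length(d))
  if (!is.null(newdata)) {
    dn <- md_squared(as.matrix(newdata), x$scaler, x$precision)
    d <- c(d, dn)
    col <- c(col, rep("firebrick", length(dn)))
    pch <- c(pch, rep(17L, length(dn)))
  }
  graphics::plot(seq_along(d), d, col = col, pch = pch,
                 xlab = "sample index", ylab = expression(MD^2),
                 main = "ES-CM distances", ...)
  graphics::abline(h = x$md2_crit, lty = 2)
  invisible(x)
}

#' Simulate from the fitted reference-class distribution
#'
#' Draws observations from the multivariate normal with the training means
#' and the shrunken covariance estimate, on the raw (unscaled) variable
#' scale.  Useful for parametric-bootstrap checks of the critical limit.
#'
#' @param object a fitted `escm` model.
#' @param nsim number of observations to draw.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return nsim x P numeric matrix.
#' @export
simulate.escm <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$p
  prec <- object$precision
  if (prec$type == "lowrank") {
    # Sigma = lambda I + w C'C with w = (1 - lambda) / divisor
    w <- (1 - prec$lambda) / prec$divisor
    E1 <- matrix(stats::rnorm(nsim * p), nsim, p)
    E2 <- matrix(stats::rnorm(nsim * nrow(prec$C)), nsim, nrow(prec$C))
    Z <- sqrt(prec$lambda) * E1 + sqrt(w) * (E2 %*% prec$C)
  } else {
    Sig <- chol2inv(chol(prec$matrix))
    Z <- matrix(stats::rnorm(nsim * p), nsim, p) %*% chol((Sig + t(Sig)) / 2)
  }
  sweep(sweep(Z, 2L, object$scaler$sds, "*"), 2L, object$scaler$means, "+")
}

#' Residuals of a fitted one-class model
#'
#' Returns the leave-one-out squared Mahalanobis distances of the reference
#' samples, the quantities on which the critical limit is calibrated.
#'
#' @param object a fitted `escm` model.
#' @param ... unused.
#' @return numeric vector of length N.
#' @export
residuals.escm <- function(object, ...) object$cv_md2

#' @export
print.escm_classification <- function(x, ...) {
  cat(sprintf("One-class classification: %d of %d flagged as outliers (MD^2 > %.3f)\n",
              sum(x$outlier), nrow(x), x$md2_crit[1]))
  print.data.frame(x, ...)
  invisible(x)
}
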