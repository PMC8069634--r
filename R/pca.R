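# PCA-based one-class baseline (SIMCA): Hotelling's T2 inside the principal
# component subspace, the Q residual statistic orthogonal to it, and their
# combination, with training-set-calibrated critical limits.

#' Fit a PCA one-class (SIMCA) baseline model
#'
#' PCA of the auto-scaled reference table via SVD.  The number of retained
#' components A is the smallest number explaining at least `var_target` of
#' the sample variance (capped at N - 2 so the F-based T2 limit is defined).
#' Per-reference training T2 and Q statistics are computed from the model
#' fitted on all references (no cross-validation, the common SIMCA
#' practice).  Limits: T2 from the prediction-form Hotelling bound
#' A (N^2 - 1) / (N (N - A)) * F(1 - alpha; A, N - A); Q and the combined
#' statistic from moment-matched scaled chi-square fits to their training
#' values.
#'
#' @param x raw reference matrix (samples in rows, N >= 5) or a
#'   [metabolite_table()].
#' @param alpha significance level (default 0.05).
#' @param var_target minimum cumulative explained variance fraction in
#'   (0, 1\] (default 0.80).
#' @return object of class `simca`: scaler, `loadings` (P x A, orthonormal
#'   columns), `component_variances` (score variances, nonincreasing),
#'   `n_components`, training `t2`/`q`/`combined`, and `t2_crit`, `q_crit`,
#'   `combined_crit`.
#' @export
simca <- function(x, alpha = 0.05, var_target = 0.80) {
  if (inherits(x, "metabolite_table")) x <- as.matrix(x)
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 5L) stop("fitting requires N >= 5 references")
  if (var_target <= 0 || var_target > 1) stop("var_target must be in (0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")

  sc <- fit_scaler(x)
  Z <- apply_scaler(sc, x)
  sv <- svd(Z)
  ev <- sv$d^2 / (n - 1) # score variances
  keep <- ev > max(ev) * 1e-12
  ev <- ev[keep]
  expl <- cumsum(ev) / sum(ev)
  A <- which(expl >= var_target)[1]
  if (is.na(A)) A <- length(ev)
  A <- min(A, n - 2L, p)
  loadings <- sv$v[, seq_len(A), drop = FALSE]
  lambda <- ev[seq_len(A)]

  scores <- Z %*% loadings
  t2 <- rowSums(sweep(scores^2, 2L, lambda, "/"))
  resid <- Z - tcrossprod(scores, loadings) # Z - scores %*% t(loadings)
  q <- rowSums(resid^2)

  t2_crit <- A * (n^2 - 1) / (n * (n - A)) * stats::qf(1 - alpha, A, n - A)
  q_crit <- .training_chi2_crit(q, alpha)
  combined <- t2 / t2_crit + if (q_crit > 0) q / q_crit else 0
  combined_crit <- .training_chi2_crit(combined, alpha)

  structure(
    list(scaler = sc, loadings = loadings, component_variances = lambda,
         n_components = A, explained = expl[A],
         t2 = t2, q = q, combined = combined,
         t2_crit = t2_crit, q_crit = q_crit, combined_crit = combined_crit,
         alpha = alpha, var_target = var_target, n = n, p = p,
         variable_names = colnames(x)),
    class = "simca")
}

# moment-matched scaled chi-square quantile of training statistics; exactly
# low-rank data can give identically zero residuals, in which case the limit
# degenerates to 0 (any positive residual is then an outlier) with a warning
.training_chi2_crit <- function(v, alpha) {
  m <- mean(v)
  s2 <- stats::var(v)
  if (!is.finite(s2) || s2 <= 0 || m <= 0) {
    if (any(v > 0)) warning("degenerate training statistics; limit set to their maximum")
    return(max(v, 0))
  }
  g1 <- s2 / (2 * m)
  g2 <- 2 * m^2 / s2
  g1 * stats::qchisq(1 - alpha, g2)
}

# scores/statistics of new (raw) observations
.simca_eval <- function(model, y) {
  Z <- apply_scaler(model$scaler, y)
  scores <- Z %*% model$loadings
  t2 <- rowSums(sweep(scores^2, 2L, model$component_variances, "/"))
  resid <- Z - scores %*% t(model$loadings)
  q <- rowSums(resid^2)
  combined <- t2 / model$t2_crit +
    if (model$q_crit > 0) q / model$q_crit else ifelse(q > 0, Inf, 0)
  list(t2 = t2, q = q, combined = combined)
}

#' SIMCA distance statistics of new observations
#'
#' Hotelling's T2 (within the retained component subspace, scores scaled by
#' their training variances), the Q residual statistic (squared distance
#' orthogonal to the subspace), and the combined statistic
#' T2 / T2_crit + Q / Q_crit, for each row of `y`.
#'
#' @param model a fitted `simca` model.
#' @param y numeric vector (length P) or M x P matrix of raw observations.
#' @return data frame with columns `t2`, `q`, `combined`.
#' @export
simca_stats <- function(model, y) {
  as.data.frame(.simca_eval(model, y))
}

#' @rdname simca_stats
#' @export
t2_stat <- function(model, y) .simca_eval(model, y)$t2

#' @rdname simca_stats
#' @export
q_stat <- function(model, y) .simca_eval(model, y)$q

#' @rdname simca_stats
#' @export
combined_stat <- function(model, y) .simca_eval(model, y)$combined

#' Classify new observations with a SIMCA model
#'
#' Flags observations whose chosen statistic strictly exceeds its critical
#' limit (equality classifies as inside the class).
#'
#' @param object a fitted `simca` model.
#' @param newdata M x P matrix (or [metabolite_table()]).
#' @param criterion `"T2"`, `"Q"`, or `"T2_plus_Q"` (the combined statistic).
#' @param ids optional sample identifiers.
#' @param ... unused.
#' @return data frame of class `escm_classification` with columns
#'   `sample_id`, `stat`, `crit`, `outlier` plus the raw `t2` and `q`.
#' @export
predict.simca <- function(object, newdata, criterion = c("T2", "Q", "T2_plus_Q"),
                          ids = NULL, ...) {
  criterion <- match.arg(criterion)
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
  if (is.null(ids)) {
    ids <- rownames(newdata)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(newdata)))
  }
  st <- .simca_eval(object, newdata)
  stat <- switch(criterion, T2 = st$t2, Q = st$q, T2_plus_Q = st$combined)
  crit <- switch(criterion, T2 = object$t2_crit, Q = object$q_crit,
                 T2_plus_Q = object$combined_crit)
  out <- data.frame(sample_id = ids, stat = stat, crit = crit,
                    outlier = stat > crit, t2 = st$t2, q = st$q,
                    stringsAsFactors = FALSE)
  attr(out, "criterion") <- criterion
  class(out) <- c("escm_classification", "data.frame")
  out
}

#' @export
print.simca <- function(x, ...) {
  cat("PCA one-class (SIMCA) baseline model\n")
  cat(sprintf("  references: N = %d, variables: P = %d\n", x$n, x$p))
  cat(sprintf("  components: A = %d (%.1f%% of variance, target %.0f%%)\n",
              x$n_components, 100 * x$explained, 100 * x$var_target))
  cat(sprintf("  limits (alpha = %g): T2 = %.3f, Q = %.3f, combined = %.3f\n",
              x$alpha, x$t2_crit, x$q_crit, x$combined_crit))
  invisible(x)
}

#' @export
summary.simca <- function(object, ...) {
  cat("PCA one-class (SIMCA) baseline model\n")
  cat(sprintf("  N = %d, P = %d, A = %d components (>= %.0f%% variance)\n",
              object$n, object$p, object$n_components, 100 * object$var_target))
  cat(sprintf("  score variances: %s\n",
              paste(signif(utils::head(object$component_variances, 5), 3),
                    collapse = ", ")))
  cat(sprintf("  training flag rates: T2 %.1f%%, Q %.1f%%, T2+Q %.1f%%\n",
              100 * mean(object$t2 > object$t2_crit),
              100 * mean(object$q > object$q_crit),
              100 * mean(object$combined > object$combined_crit)))
  invisible(object)
}

#' Distance-distance plot of a SIMCA model
#'
#' Training T2 against Q with both critical limits; optionally overlays new
#' observations.
#'
#' @param x a fitted `simca` model.
#' @param newdata optional matrix of new observations.
#' @param ... passed to [graphics::plot()].
#' @export
plot.simca <- function(x, newdata = NULL, ...) {
  t2 <- x$t2; q <- x$q
  col <- rep("grey30", length(t2)); pch <- rep(1L, length(t2))
  if (!is.null(newdata)) {
    st <- .simca_eval(x, as.matrix(newdata))
    t2 <- c(t2, st$t2); q <- c(q, st$q)
    col <- c(col, rep("firebrick", length(st$t2)))
    pch <- c(pch, rep(17L, length(st$t2)))
  }
  graphics::plot(t2, q, col = col, pch = pch,
                 xlab = expression(T^2), ylab = "Q",
                 main = "SIMCA distance-distance plot", ...)
  graphics::abline(v = x$t2_crit, lty = 2)
  graphics::abline(h = x$q_crit, lty = 2)
  invisible(x)
}
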