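# Metabolite abundance tables and the preprocessing chain: non-detect
# filtering, half-minimum imputation, log transform.  Non-detects (peak
# intensities below the instrument reporting threshold) are encoded as 0 and
# are distinct from missing cells, which are rejected at read time.

#' Construct a metabolite table
#'
#' @param values N x P matrix of nonnegative abundances (0 = non-detect).
#' @param sample_ids character vector of length N (defaults to rownames or
#'   an index).
#' @param variable_names unique character vector of length P (defaults to
#'   colnames or `V1..VP`).
#' @param group_labels optional length-N vector of group labels (e.g.
#'   reference / cisgenic / starch).
#' @return object of class `metabolite_table`.
#' @export
metabolite_table <- function(values, sample_ids = NULL, variable_names = NULL,
                             group_labels = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing values are not allowed; non-detects must be encoded as 0")
  if (any(values < 0)) stop("abundances must be nonnegative")
  n <- nrow(values); p <- ncol(values)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  }
  if (is.null(variable_names)) {
    variable_names <- colnames(values)
    if (is.null(variable_names)) variable_names <- paste0("V", seq_len(p))
  }
  if (length(sample_ids) != n) stop("sample_ids length does not match rows")
  if (length(variable_names) != p) stop("variable_names length does not match columns")
  if (anyDuplicated(variable_names)) stop("variable names must be unique")
  if (!is.null(group_labels) && length(group_labels) != n) {
    stop("group_labels length does not match rows")
  }
  dimnames(values) <- list(sample_ids, variable_names)
  structure(list(values = values, sample_ids = as.character(sample_ids),
                 variable_names = as.character(variable_names),
                 group_labels = group_labels,
                 imputed = FALSE, logged = FALSE),
            class = "metabolite_table")
}

#' @export
as.matrix.metabolite_table <- function(x, ...) x$values

#' @export
dim.metabolite_table <- function(x) dim(x$values)

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("Metabolite table: %d samples x %d variables\n",
              nrow(x$values), ncol(x$values)))
  zf <- mean(x$values == 0)
  cat(sprintf("  non-detects (zeros): %.1f%% of entries\n", 100 * zf))
  if (!is.null(x$group_labels)) {
    cat("  groups: ")
    print(table(x$group_labels))
  }
  invisible(x)
}

#' Read a metabolite table from a delimited file
#'
#' Expects a header line and a leading identifier column; remaining cells
#' must be numeric.  Empty or NA cells are rejected -- a non-detect must be
#' written as 0, which is a measurement ("below threshold"), not a missing
#' value.
#'
#' @param path file path.
#' @param format `"csv"` or `"tsv"`.
#' @param orientation `"samples_in_rows"` (default) or `"samples_in_cols"`
#'   (the file is transposed after reading).
#' @param group_col optional name or index of a column (after orientation)
#'   holding group labels.
#' @return a [metabolite_table()].
#' @export
read_metabolite_table <- function(path, format = c("csv", "tsv"),
                                  orientation = c("samples_in_rows",
                                                  "samples_in_cols"),
                                  group_col = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (orientation == "samples_in_cols") {
    df <- as.data.frame(t(as.matrix(df)), check.names = FALSE,
                        stringsAsFactors = FALSE)
  }
  groups <- NULL
  if (!is.null(group_col)) {
    groups <- as.character(df[[group_col]])
    if (is.null(groups)) stop("group column not found: ", group_col)
    if (is.character(group_col)) {
      df[[group_col]] <- NULL
    } else {
      df <- df[, -group_col, drop = FALSE]
    }
  }
  M <- suppressWarnings(vapply(df, function(col) as.numeric(as.character(col)),
                               numeric(nrow(df))))
  if (!is.matrix(M)) M <- matrix(M, nrow = nrow(df), dimnames = list(rownames(df), names(df)))
  rownames(M) <- rownames(df)
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop(sprintf("missing or non-numeric cell at sample '%s', variable '%s'; non-detects must be encoded as 0",
                 rownames(M)[bad[1]], colnames(M)[bad[2]]))
  }
  metabolite_table(M, sample_ids = rownames(M), variable_names = colnames(M),
                   group_labels = groups)
}

#' Write a metabolite table to a delimited file
#'
#' @param x a [metabolite_table()].
#' @param path output file path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_metabolite_table <- function(x, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  df <- data.frame(sample_id = x$sample_ids, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter variables by non-detect fraction
#'
#' Drops variables whose fraction of zeros (non-detects) is strictly greater
#' than `max_zero_frac` ("more than 40%" by default); a variable at exactly
#' the threshold is retained.  Must run before imputation.
#'
#' @param x a [metabolite_table()].
#' @param max_zero_frac maximum tolerated zero fraction in \[0, 1\].
#' @return the filtered table (original variable order preserved).
#' @export
filter_nondetect <- function(x, max_zero_frac = 0.40) {
  stopifnot(inherits(x, "metabolite_table"))
  if (max_zero_frac < 0 || max_zero_frac > 1) stop("max_zero_frac must be in [0, 1]")
  if (isTRUE(x$imputed)) {
    stop("non-detect filtering must precede imputation (zeros are gone after imputing)")
  }
  zf <- colMeans(x$values == 0)
  keep <- zf <= max_zero_frac
  dropped <- x$variable_names[!keep]
  if (length(dropped)) {
    message(sprintf("dropping %d of %d variables with > %.0f%% non-detects",
                    length(dropped), length(keep), 100 * max_zero_frac))
  }
  out <- x
  out$values <- x$values[, keep, drop = FALSE]
  out$variable_names <- x$variable_names[keep]
  out
}

#' Impute non-detects by half the minimum value
#'
#' Replaces each 0 by half the minimum positive value of its own variable
#' (default) or of the whole table (`scope = "global"`).  A variable that is
#' entirely zero cannot be imputed and raises an error -- filter such
#' variables out first.
#'
#' @param x a [metabolite_table()].
#' @param scope `"variable"` (default) or `"global"`.
#' @return the imputed table (all values > 0).
#' @export
impute_halfmin <- function(x, scope = c("variable", "global")) {
  scope <- match.arg(scope)
  stopifnot(inherits(x, "metabolite_table"))
  v <- x$values
  if (scope == "global") {
    pos <- v[v > 0]
    if (!length(pos)) stop("table contains no positive values to impute from")
    v[v == 0] <- min(pos) / 2
  } else {
    for (j in seq_len(ncol(v))) {
      zi <- v[, j] == 0
      if (!any(zi)) next
      pos <- v[!zi, j]
      if (!length(pos)) {
        stop("variable '", x$variable_names[j],
             "' is entirely non-detect and cannot be imputed; filter it out first")
      }
      v[zi, j] <- min(pos) / 2
    }
  }
  out <- x
  out$values <- v
  out$imputed <- TRUE
  out
}

#' Log-transform a metabolite table
#'
#' Elementwise log of the (imputed) abundances.  All values must be strictly
#' positive beforehand (after adding `offset`, if any).
#'
#' @param x a [metabolite_table()].
#' @param base logarithm base (default e).
#' @param offset nonnegative constant added before the log (default 0).
#' @return the transformed table.
#' @export
log_transform <- function(x, base = exp(1), offset = 0) {
  stopifnot(inherits(x, "metabolite_table"))
  v <- x$values + offset
  if (any(v <= 0)) {
    stop("log transform requires strictly positive values; impute non-detects first")
  }
  out <- x
  out$values <- log(v, base = base)
  out$logged <- TRUE
  out
}

#' Run the full preprocessing chain
#'
#' filter (non-detects) -> impute (half-minimum) -> log -> auto-scale, in
#' that fixed order.  Returns the auto-scaled matrix ready for [escm()] or
#' [simca()], with the scaler attached as an attribute.
#'
#' @param x a [metabolite_table()].
#' @param max_zero_frac passed to [filter_nondetect()].
#' @param impute_scope passed to [impute_halfmin()].
#' @param log_base passed to [log_transform()].
#' @return auto-scaled numeric matrix with attributes `"scaler"` and
#'   `"table"` (the preprocessed table before scaling).
#' @export
preprocess <- function(x, max_zero_frac = 0.40, impute_scope = "variable",
                       log_base = exp(1)) {
  t1 <- filter_nondetect(x, max_zero_frac)
  t2 <- impute_halfmin(t1, scope = impute_scope)
  t3 <- log_transform(t2, base = log_base)
  z <- autoscale(t3$values)
  attr(z, "table") <- t3
  z
}

#' Generate a synthetic reference/test fixture
#'
#' Emulates an untargeted LC-MS abundance table: log-scale profiles are
#' drawn from a multivariate normal with a blocked correlation structure and
#' per-variable baselines, exponentiated to positive abundances, and a
#' random fraction of entries is masked to 0 (non-detects).  The test group
#' can carry a mean shift on the log scale (see [shifted_mean()]).
#'
#' @param n_ref number of reference samples.
#' @param n_test number of test samples.
#' @param p number of variables.
#' @param cov_structure covariance structure (see [sim_config()]).
#' @param zero_frac fraction of entries masked to 0, in \[0, 0.5\].
#' @param shift_scenario,gamma abnormality of the test group (log scale).
#' @param seed integer seed.
#' @return list with components `reference` and `test`, both
#'   [metabolite_table()]s, plus `sigma` (the generating correlation matrix)
#'   and `baseline` (per-variable log-abundance baselines).
#' @export
make_fixture <- function(n_ref = 41L, n_test = 21L, p = 200L,
                         cov_structure = "block_random", zero_frac = 0.1,
                         shift_scenario = "none", gamma = 0, seed = 1L) {
  if (zero_frac < 0 || zero_frac > 0.5) stop("zero_frac must be in [0, 0.5]")
  set.seed(seed)
  Sigma <- switch(cov_structure,
                  block_fixed = make_block_cov(p),
                  block_random = make_random_block_cov(p),
                  surrogate_real = make_surrogate_real_cov(p),
                  stop("unknown cov_structure"))
  R <- chol(Sigma)
  baseline <- stats::runif(p, 6, 10) # log-abundance baselines
  Xlog <- sweep(.rmvn(n_ref, R), 2L, baseline, "+")
  mu <- shifted_mean(shift_scenario, gamma, Sigma)
  Ylog <- sweep(.rmvn(n_test, R, mu = mu), 2L, baseline, "+")
  X <- exp(Xlog)
  Y <- exp(Ylog)
  if (zero_frac > 0) {
    X[matrix(stats::runif(length(X)) < zero_frac, nrow(X))] <- 0
    Y[matrix(stats::runif(length(Y)) < zero_frac, nrow(Y))] <- 0
  }
  ref <- metabolite_table(X, sample_ids = paste0("ref", seq_len(n_ref)),
                          variable_names = paste0("M", seq_len(p)),
                          group_labels = rep("reference", n_ref))
  tst <- metabolite_table(Y, sample_ids = paste0("test", seq_len(n_test)),
                          variable_names = paste0("M", seq_len(p)),
                          group_labels = rep("test", n_test))
  list(reference = ref, test = tst, sigma = Sigma, baseline = baseline)
}
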