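# JSON serialization of fitted models and CSV export of classifications.

#' Serialize a fitted ES-CM model to JSON
#'
#' Writes everything needed to classify new observations: the scaler, the
#' shrinkage intensity and estimator, the precision (dense matrix, or the
#' low-rank Woodbury components when P is large), the cross-validated
#' distances and the critical limit.
#'
#' @param model a fitted `escm` model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_escm_json <- function(model, path) {
  stopifnot(inherits(model, "escm"))
  prec <- model$precision
  prec_out <- if (prec$type == "dense") {
    list(type = "dense", matrix = prec$matrix)
  } else {
    list(type = "lowrank", lambda = prec$lambda, divisor = prec$divisor,
         C = prec$C)
  }
  obj <- list(
    class = "escm",
    package_version = as.character(utils::packageVersion("escm")),
    scaler = list(means = unname(model$scaler$means),
                  sds = unname(model$scaler$sds)),
    estimator = model$estimator,
    intensity = model$intensity,
    precision = prec_out,
    cv_md2 = model$cv_md2,
    g1 = model$g1, g2 = model$g2, md2_crit = model$md2_crit,
    alpha = model$alpha, limit_mode = model$limit_mode,
    n = model$n, p = model$p,
    variable_names = model$variable_names)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Restore an ES-CM model from JSON
#'
#' @param path path to a file written by [write_escm_json()].
#' @return a fitted `escm` model.
#' @export
read_escm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$class, "escm")) stop("not a serialized escm model")
  sc <- structure(list(means = obj$scaler$means, sds = obj$scaler$sds),
                  class = "escm_scaler")
  prec <- if (identical(obj$precision$type, "dense")) {
    new_precision_dense(as.matrix(obj$precision$matrix))
  } else {
    new_precision_lowrank(as.matrix(obj$precision$C), obj$precision$lambda,
                          obj$precision$divisor)
  }
  vn <- obj$variable_names
  if (length(vn) == 0L) vn <- NULL
  structure(
    list(scaler = sc, intensity = obj$intensity, estimator = obj$estimator,
         precision = prec, cv_md2 = obj$cv_md2,
         g1 = ifelse(is.null(obj$g1), NA_real_, obj$g1),
         g2 = ifelse(is.null(obj$g2), NA_real_, obj$g2),
         md2_crit = obj$md2_crit, alpha = obj$alpha,
         limit_mode = obj$limit_mode, n = obj$n, p = obj$p,
         variable_names = vn),
    class = "escm")
}

#' Write a classification result to CSV
#'
#' @param result an `escm_classification` from [predict.escm()] or
#'   [predict.simca()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}
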