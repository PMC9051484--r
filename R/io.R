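#' Read and write twin tables
#'
#' The package's two normative CSV dialects:
#' * long: `family_id,twin,zygosity,wave,age,birth_year,scanner,ethnicity,phenotype`
#'   (one assessment per row; covariate columns optional);
#' * wide: `family_id,zygosity,t1_a,...,tT_a,t1_b,...,tT_b`
#'   (one pair per row; empty field = missing).
#'
#' @param path File path.
#' @param x Table to write.
#' @return The tibble (readers) or `path` invisibly (writers).
#' @name twin_io
NULL

#' @rdname twin_io
#' @export
read_twin_long <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
}

#' @rdname twin_io
#' @export
write_twin_long <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(path)
}

#' @rdname twin_io
#' @export
read_twin_wide <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"),
                         col_types = readr::cols(
                           family_id = readr::col_character(),
                           zygosity = readr::col_character(),
                           .default = readr::col_double()))
  n_intervals(out) # validates shape
  out
}

#' @rdname twin_io
#' @export
write_twin_wide <- function(x, path) {
  readr::write_csv(x[, c("family_id", "zygosity", wide_value_cols(n_intervals(x)))],
                   path, na = "")
  invisible(path)
}

#' Serialize a fit to JSON
#'
#' @param fit A `twin_fit`.
#' @param path Optional path; if `NULL` the JSON string is returned.
#' @return JSON string or `path` invisibly.
#' @export
fit_to_json <- function(fit, path = NULL) {
  obj <- list(
    model = fit$model$name,
    estimates = as.list(fit$estimates),
    minus2ll = fit$minus2ll,
    npar = fit$npar,
    AIC = fit$minus2ll + 2 * fit$npar,
    converged = fit$converged,
    n_pairs = fit$n_pairs,
    n_obs = fit$n_obs
  )
  if (is.null(path)) return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
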