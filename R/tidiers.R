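#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a twin-model fit
#'
#' @param x A `twin_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`, `free`.
#' @export
tidy.twin_fit <- function(x, ...) {
  tibble(term = names(x$estimates),
         estimate = unname(x$estimates),
         free = x$model$params$free)
}

#' One-row summary of a twin-model fit
#'
#' @param x A `twin_fit`.
#' @param ... Unused.
#' @return Tibble with `model`, `minus2ll`, `npar`, `AIC`, `converged`,
#'   `n_pairs`, `n_obs`.
#' @export
glance.twin_fit <- function(x, ...) {
  tibble(model = x$model$name, minus2ll = x$minus2ll, npar = x$npar,
         AIC = x$minus2ll + 2 * x$npar, converged = x$converged,
         n_pairs = x$n_pairs, n_obs = x$n_obs)
}

#' @export
tidy.twin_comparison <- function(x, ...) x$table

#' @export
glance.twin_comparison <- function(x, ...) {
  sel <- x$fits[[x$selected]]
  tibble(selected = x$selected, minus2ll = sel$minus2ll, npar = sel$npar,
         AIC = sel$minus2ll + 2 * sel$npar, n_models = nrow(x$table))
}
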