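#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_errorbar
#'   geom_hline labs facet_wrap theme_minimal scale_fill_brewer
#' @export
ggplot2::autoplot

#' Plot a standardized variance decomposition
#'
#' Stacked bars of the standardized A / C / E shares per interval variable.
#'
#' @param object A [standardize()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.variance_decomposition <- function(object, ...) {
  dat <- object %>%
    select("variable", dplyr::starts_with("std_")) %>%
    select(!dplyr::ends_with("lower") & !dplyr::ends_with("upper")) %>%
    tidyr::pivot_longer(-"variable", names_to = "component",
                        names_prefix = "std_", values_to = "share")
  ggplot(dat, aes(x = factor(.data$variable), y = .data$share,
                  fill = .data$component)) +
    geom_col() +
    scale_fill_brewer(palette = "Set2") +
    labs(x = "interval variable", y = "standardized variance share",
         fill = NULL, title = attr(object, "model_name")) +
    theme_minimal()
}

#' Plot a model comparison
#'
#' AIC of every fitted model, colored by pipeline stage, with the selected
#' model highlighted.
#'
#' @param object A `twin_comparison` from [model_selection_pipeline()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.twin_comparison <- function(object, ...) {
  tab <- object$table
  ggplot(tab, aes(x = stats::reorder(.data$model, .data$AIC), y = .data$AIC,
                  color = .data$stage, shape = .data$selected)) +
    geom_point(size = 3) +
    labs(x = NULL, y = "AIC", color = "stage", shape = "selected") +
    theme_minimal() +
    ggplot2::coord_flip()
}

#' Plot twin-pair correlations by zygosity
#'
#' Point estimates with 95% CIs for each interval variable, MZ vs DZ —
#' the visual version of the classic twin-correlation table. MZ
#' correlations roughly double the DZ ones indicate additive genetic
#' influences.
#'
#' @param tbl Output of [twin_correlation_table()].
#' @return A ggplot.
#' @export
plot_twin_correlations <- function(tbl) {
  ggplot(tbl, aes(x = factor(.data$variable), y = .data$estimate,
                  color = .data$zygosity)) +
    geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    geom_errorbar(aes(ymin = .data$lower95, ymax = .data$upper95),
                  width = 0.2, position = ggplot2::position_dodge(width = 0.4)) +
    geom_hline(yintercept = 0, linetype = 3) +
    labs(x = "interval variable", y = "twin-pair correlation") +
    theme_minimal()
}
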