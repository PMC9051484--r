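#' Standardized variance decomposition from a fit
#'
#' Divides each interval variable's implied A, C and E variances by its
#' implied total, giving standardized components that sum to 1. For factor
#' models (common/independent pathway) the split of each component into
#' common-factor and variable-specific residual parts is reported as well.
#'
#' Optional 95% CIs are computed by profile likelihood ([profile_ci()] with
#' the penalty method); this refits the model many times, so it is off by
#' default.
#'
#' @param fit A converged `twin_fit`.
#' @param conf.int Compute profile-likelihood CIs for the standardized
#'   totals (slow).
#' @param level Confidence level.
#' @return A tibble of class `variance_decomposition`: one row per
#'   variable with `std_A`, `std_C`, `std_E` (components absent from the
#'   model are 0), plus `common_A`/`residual_A` etc. (standardized) where
#'   the model distinguishes them, and CI columns when requested.
#' @export
standardize <- function(fit, conf.int = FALSE, level = 0.95) {
  if (!fit$converged) warn("standardizing a non-converged fit")
  model <- fit$model
  mo <- model_moments(model, fit$estimates)
  Tn <- model$T
  tot <- diag(mo$SA) + diag(mo$SC) + diag(mo$SE)
  if (any(tot <= 0)) abort("zero implied total variance")
  out <- tibble(
    variable = seq_len(Tn),
    std_A = diag(mo$SA) / tot,
    std_C = diag(mo$SC) / tot,
    std_E = diag(mo$SE) / tot
  )
  # common vs residual split where per-variable residual paths exist
  for (cm in c("a", "c", "e")) {
    nm <- paste0("res_", cm, seq_len(Tn))
    if (all(nm %in% model$params$name)) {
      res_var <- vapply(nm, function(x) fit$estimates[[x]]^2, 0)
      CM <- toupper(cm)
      total_cm <- diag(mo[[paste0("S", CM)]])
      out[[paste0("residual_", CM)]] <- res_var / tot
      out[[paste0("common_", CM)]] <- (total_cm - res_var) / tot
    }
  }
  if (conf.int) {
    for (cm in intersect(c("A", "C", "E"), model$components)) {
      lo <- hi <- numeric(Tn)
      for (j in seq_len(Tn)) {
        gj <- local({
          j0 <- j; cm0 <- cm
          function(p) {
            m <- model$moments(as.list(p))
            if (is.null(m)) return(NA_real_)
            (diag(m[[paste0("S", cm0)]]) / (diag(m$SA) + diag(m$SC) + diag(m$SE)))[j0]
          }
        })
        ci <- profile_ci(fit, gj, level = level)
        lo[j] <- max(ci$lower, 0); hi[j] <- min(ci$upper, 1)
      }
      out[[paste0("std_", cm, "_lower")]] <- lo
      out[[paste0("std_", cm, "_upper")]] <- hi
    }
  }
  class(out) <- c("variance_decomposition", class(out))
  attr(out, "model_name") <- model$name
  out
}

#' Genetic and environmental correlation matrices
#'
#' From a multivariate fit, the component correlation between variables i
#' and j is the implied component covariance scaled by the component
#' standard deviations: \eqn{rG_{ij} = \Sigma_{A,ij} /
#' \sqrt{\Sigma_{A,ii}\Sigma_{A,jj}}}, and analogously for C and E. A high
#' rG with a lower rE is the classic signature of stable genetic
#' influences combined with occasion-specific environments.
#'
#' @param fit A converged multivariate `twin_fit`.
#' @return List of class `component_correlations` with matrices `rG`, `rC`
#'   (if modeled), `rE`. Cells involving a zero component variance are
#'   `NA`.
#' @export
component_correlations <- function(fit) {
  model <- fit$model
  if (model$T < 2) abort("component correlations require a multivariate fit")
  if (!fit$converged) warn("using a non-converged fit")
  mo <- model_moments(model, fit$estimates)
  scale_mat <- function(S) {
    d <- diag(S)
    M <- S / sqrt(outer(d, d))
    M[outer(d, d) <= 0] <- NA_real_
    diag(M) <- ifelse(d > 0, 1, NA_real_)
    M
  }
  out <- list(rG = scale_mat(mo$SA), rE = scale_mat(mo$SE))
  if ("C" %in% model$components) out$rC <- scale_mat(mo$SC)
  structure(out, class = "component_correlations", model_name = model$name)
}

#' @export
print.component_correlations <- function(x, digits = 2, ...) {
  cat("Component correlations (", attr(x, "model_name"), ")\n", sep = "")
  for (nm in names(x)) {
    cat(nm, ":\n", sep = "")
    print(round(x[[nm]], digits))
  }
  invisible(x)
}
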