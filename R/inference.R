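#' Likelihood ratio test between nested twin-model fits
#'
#' The test statistic is the difference in -2 log-likelihood between the
#' constrained (nested) and the more general (parent) model, referred to a
#' central chi-square with df equal to the difference in free-parameter
#' counts. For variance components fixed at a boundary (e.g. dropping C)
#' the central reference is conservative-to-anticonservative depending on
#' direction (the chi-bar-square issue); the central reference matches
#' common practice in the twin-modeling literature and is the default.
#'
#' With `boundary = TRUE` the p-value uses the 50:50 chi-bar-square
#' mixture of chi-square(df) and chi-square(df-1) appropriate when a
#' single variance component is tested at its zero boundary; the central
#' reference stays the default so decisions remain comparable with
#' conventional practice.
#'
#' @param parent Fit of the more general model (a `twin_fit`).
#' @param nested Fit of the constrained model on the same data.
#' @param boundary Use the chi-bar-square mixture reference.
#' @return One-row tibble with `chi2`, `df`, `p`.
#' @export
lrt <- function(parent, nested, boundary = FALSE) {
  if (nested$npar > parent$npar)
    abort("nested model has more free parameters than parent")
  if (nested$n_pairs != parent$n_pairs || nested$n_obs != parent$n_obs)
    abort("fits are not on the same data")
  chi2 <- nested$minus2ll - parent$minus2ll
  tol <- 1e-4 * max(1, abs(parent$minus2ll))
  if (chi2 < -tol)
    abort("nested fit has lower -2lnL than parent beyond tolerance; refit needed (more starts?)")
  chi2 <- max(chi2, 0)
  df <- parent$npar - nested$npar
  p <- if (df == 0) {
    if (chi2 <= tol) 1 else 0
  } else if (boundary) {
    lower_mass <- if (df == 1) as.numeric(chi2 <= 0) else
      pchisq(chi2, df - 1, lower.tail = FALSE)
    0.5 * lower_mass + 0.5 * pchisq(chi2, df, lower.tail = FALSE)
  } else {
    pchisq(chi2, df, lower.tail = FALSE)
  }
  tibble(chi2 = chi2, df = as.integer(df), p = p)
}

#' @export
AIC.twin_fit <- function(object, ..., k = 2) {
  object$minus2ll + k * object$npar
}

# ---- profile-likelihood confidence intervals ---------------------------

# refit with one parameter fixed, warm-started at the MLE
profile_fix_param <- function(fit, pname) {
  function(q) {
    m2 <- fix_parameters(fit$model, pname, q)
    f <- suppressWarnings(fit_twin_model_stats(
      fit$stats, m2, n_starts = 1, start = fit$estimates,
      control = list(iter.max = 400)))
    f$minus2ll
  }
}

# univariate standardized-component profile by substitution:
# target component h of total v; remaining mass split by w when 3 components
profile_uni_std <- function(fit, comp) {
  model <- fit$model
  comps <- model$components
  others <- setdiff(comps, comp)
  est <- fit$estimates
  letters_ <- setNames(c("a", "c", "e"), c("A", "C", "E"))
  v_hat <- sum(vapply(comps, function(cm) est[[letters_[cm]]]^2, 0))
  mu_hat <- est[["mu1"]]
  function(q) {
    build <- function(th) {
      v <- th[1]; mu <- th[length(th)]
      p <- c(mu1 = mu)
      rest <- (1 - q) * v
      if (length(others) == 2) {
        w <- th[2]
        p[letters_[others[1]]] <- sqrt(max(rest * w, 0))
        p[letters_[others[2]]] <- sqrt(max(rest * (1 - w), 0))
      } else {
        p[letters_[others[1]]] <- sqrt(max(rest, 0))
      }
      p[letters_[comp]] <- sqrt(max(q * v, 0))
      p[model$params$name]
    }
    obj <- function(th) fiml_m2ll_stats(model, build(th), fit$stats)
    th0 <- if (length(others) == 2) {
      w0 <- est[[letters_[others[1]]]]^2 /
        max(est[[letters_[others[1]]]]^2 + est[[letters_[others[2]]]]^2, 1e-12)
      c(v_hat, min(max(w0, 0.01), 0.99), mu_hat)
    } else c(v_hat, mu_hat)
    lower <- if (length(others) == 2) c(1e-10, 0, -Inf) else c(1e-10, -Inf)
    upper <- if (length(others) == 2) c(Inf, 1, Inf) else c(Inf, Inf)
    nlminb(th0, obj, lower = lower, upper = upper)$objective
  }
}

# penalty-method profile for an arbitrary smooth scalar function of the
# full parameter vector
profile_penalty <- function(fit, g, weight = 1e6) {
  model <- fit$model
  free <- model$params$free
  function(q) {
    obj <- function(th) {
      p <- ifelse(free, NA_real_, model$params$value)
      p[free] <- th
      names(p) <- model$params$name
      fiml_m2ll_stats(model, p, fit$stats) + weight * (g(p) - q)^2
    }
    nlminb(fit$estimates[free], obj,
           lower = model$params$lower[free],
           upper = model$params$upper[free],
           control = list(iter.max = 500))$objective
  }
}

#' Profile-likelihood confidence interval
#'
#' Finds the bounds at which the profiled -2 log-likelihood (re-optimizing
#' all other parameters) rises by the chi-square(1) critical value above
#' its minimum — 3.841 at the default 95% level. For standardized
#' quantities the bounds are clipped to `[0, 1]` and flagged when the
#' likelihood never reaches the critical rise before the boundary.
#'
#' Supported quantities:
#' * a free parameter name (profiled by fixing it);
#' * `"std_A"`, `"std_C"`, `"std_E"` for univariate fits (profiled by an
#'   exact reparameterization in total variance and standardized shares);
#' * `"factor_a_share"` for common pathway fits (the squared factor A path,
#'   i.e. the standardized genetic share of the latent factor);
#' * a function of the full named parameter vector (profiled by a penalty
#'   method).
#'
#' @param fit A converged `twin_fit`.
#' @param quantity See above.
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `quantity`, `estimate`, `lower`, `upper`,
#'   `level`, `lower_boundary`, `upper_boundary`.
#' @export
profile_ci <- function(fit, quantity, level = 0.95) {
  if (!fit$converged) warn("profiling a non-converged fit")
  model <- fit$model
  est <- fit$estimates
  crit <- qchisq(level, 1)
  target <- fit$minus2ll + crit

  is_std <- FALSE
  if (is.function(quantity)) {
    g <- quantity
    q_hat <- g(est)
    pm <- profile_penalty(fit, g)
    rng <- c(-Inf, Inf)
    label <- "function"
  } else if (quantity %in% c("std_A", "std_C", "std_E") && model$T == 1) {
    comp <- sub("std_", "", quantity)
    if (!comp %in% model$components)
      abort(paste0("component ", comp, " not in model"))
    letters_ <- setNames(c("a", "c", "e"), c("A", "C", "E"))
    tot <- sum(vapply(model$components, function(cm) est[[letters_[cm]]]^2, 0))
    q_hat <- est[[letters_[comp]]]^2 / tot
    pm <- profile_uni_std(fit, comp)
    rng <- c(0, 1)
    is_std <- TRUE
    label <- quantity
  } else if (identical(quantity, "factor_a_share")) {
    if (!"fac_a1" %in% model$params$name)
      abort("factor_a_share requires a common pathway model with an A factor path")
    q_hat <- est[["fac_a1"]]^2
    pfix <- profile_fix_param(fit, "fac_a1")
    pm <- function(q) pfix(sqrt(q))
    rng <- c(0, 1)
    is_std <- TRUE
    label <- quantity
  } else {
    idx <- match(quantity, model$params$name)
    if (is.na(idx) || !model$params$free[idx])
      abort(paste0("unknown or fixed parameter: ", quantity))
    q_hat <- est[[quantity]]
    pm <- profile_fix_param(fit, quantity)
    rng <- c(model$params$lower[idx], model$params$upper[idx])
    label <- quantity
  }

  f <- function(q) pm(q) - target
  search_bound <- function(dir) {
    # dir = -1 lower, +1 upper
    bound <- if (dir < 0) rng[1] else rng[2]
    if (is.finite(bound)) {
      fb <- f(bound)
      if (fb < 0) return(list(value = bound, boundary = TRUE))
      r <- uniroot(f, sort(c(q_hat, bound)),
                   tol = 1e-5 * max(1, abs(q_hat)))
      return(list(value = r$root, boundary = FALSE))
    }
    step <- max(abs(q_hat), 0.5)
    q <- q_hat
    for (i in 1:40) {
      q2 <- q + dir * step
      if (f(q2) > 0)
        return(list(value = uniroot(f, sort(c(q, q2)),
                                    tol = 1e-5 * max(1, abs(q_hat)))$root,
                    boundary = FALSE))
      q <- q2
      step <- step * 1.6
    }
    list(value = dir * Inf, boundary = TRUE)
  }
  lo <- search_bound(-1)
  hi <- search_bound(+1)
  lower <- lo$value; upper <- hi$value
  if (is_std) { lower <- max(lower, 0); upper <- min(upper, 1) }
  tibble(quantity = label, estimate = q_hat, lower = lower, upper = upper,
         level = level, lower_boundary = lo$boundary, upper_boundary = hi$boundary)
}
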