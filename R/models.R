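#' @title Twin model objects
#' @description
#' A `twin_model` is a declarative description of a biometrical genetic
#' model: a parameter table (names, bounds, start values, free/fixed status)
#' plus a map from a parameter vector to the model-implied means and the
#' within-person additive genetic (A), shared environmental (C) and
#' non-shared environmental (E) covariance blocks. The twin-pair covariance
#' for a zygosity group is assembled from those blocks by
#' [pair_covariance()]: cross-twin A covariance is weighted 1.0 for MZ and
#' 0.5 for DZ pairs, C is shared with weight 1 in both groups, and E is
#' uncorrelated across twins.
#'
#' All models use a path (square-root / Cholesky / loading) parameterization
#' so that every implied component matrix is positive semi-definite by
#' construction; reported variances are squares of paths, and path signs are
#' not identified (estimates are sign-normalized).
#' @name twin_model
NULL

param_row <- function(name, lower = -Inf, upper = Inf, start = 0) {
  tibble(name = name, free = TRUE, value = NA_real_,
         lower = lower, upper = upper, start = start)
}

mean_params <- function(Tn) {
  param_row(paste0("mu", seq_len(Tn)), -Inf, Inf, 0)
}

parse_components <- function(components) {
  if (length(components) == 1 && nchar(components) > 1)
    components <- strsplit(components, "")[[1]]
  components <- unique(toupper(components))
  bad <- setdiff(components, c("A", "C", "E"))
  if (length(bad)) abort(paste0("unknown variance components: ", paste(bad, collapse = ", ")))
  if (!"E" %in% components)
    abort("the E (non-shared environment) component is required for identification")
  intersect(c("A", "C", "E"), components) # canonical order
}

new_twin_model <- function(name, Tn, components, params, moments) {
  structure(list(name = name, T = Tn, components = components,
                 params = params, moments = moments),
            class = "twin_model")
}

#' @export
print.twin_model <- function(x, ...) {
  cat("<twin_model> ", x$name, "  (T = ", x$T, ", components: ",
      paste(x$components, collapse = ""), ")\n", sep = "")
  cat("  free parameters: ", sum(x$params$free), " of ", nrow(x$params), "\n", sep = "")
  invisible(x)
}

#' Univariate ACE-family model
#'
#' One phenotype, variance decomposed into any subset of A, C, E that
#' includes E. Paths `a`, `c`, `e` give variances \eqn{a^2, c^2, e^2}.
#'
#' @param components Subset of `"A"`, `"C"`, `"E"` (string like `"AE"` or a
#'   character vector); must include `"E"`.
#' @return A [twin_model].
#' @examples
#' univariate_model("ACE")
#' @export
univariate_model <- function(components = "ACE") {
  comps <- parse_components(components)
  params <- bind_rows(
    if ("A" %in% comps) param_row("a", 0, Inf, 0.7),
    if ("C" %in% comps) param_row("c", 0, Inf, 0.4),
    param_row("e", 0, Inf, 0.7),
    mean_params(1)
  )
  moments <- function(p) {
    z <- matrix(0, 1, 1)
    list(mean = p[["mu1"]],
         SA = if ("A" %in% comps) matrix(p[["a"]]^2) else z,
         SC = if ("C" %in% comps) matrix(p[["c"]]^2) else z,
         SE = matrix(p[["e"]]^2))
  }
  new_twin_model(paste0("uni-", tolower(paste(comps, collapse = ""))),
                 1L, comps, params, moments)
}

chol_names <- function(letter, Tn) {
  out <- character(0)
  for (i in seq_len(Tn)) for (j in seq_len(i))
    out <- c(out, paste0(letter, i, j))
  out
}

#' Correlated-factors (Cholesky) multivariate model
#'
#' The atheoretical reference model: per included component, a full
#' lower-triangular path matrix gives free variances and covariances among
#' the T interval variables. Every other multivariate model in the package
#' is a constrained special case, so this model fits at least as well
#' (in -2lnL) as any of them on the same data.
#'
#' @param T Number of interval variables (>= 2).
#' @inheritParams univariate_model
#' @return A [twin_model].
#' @export
correlated_factors_model <- function(T = 4, components = "ACE") {
  stopifnot(T >= 2)
  comps <- parse_components(components)
  pr <- list()
  for (cm in comps) {
    letter <- tolower(cm)
    for (i in seq_len(T)) for (j in seq_len(i)) {
      nm <- paste0(letter, i, j)
      if (i == j) pr[[nm]] <- param_row(nm, 0, Inf, if (cm == "C") 0.3 else 0.6)
      else pr[[nm]] <- param_row(nm, -Inf, Inf, 0.2)
    }
  }
  params <- bind_rows(bind_rows(pr), mean_params(T))
  build_L <- function(p, letter) {
    L <- matrix(0, T, T)
    for (i in seq_len(T)) for (j in seq_len(i))
      L[i, j] <- p[[paste0(letter, i, j)]]
    L
  }
  moments <- function(p) {
    z <- matrix(0, T, T)
    comp_mat <- function(cm) {
      if (!cm %in% comps) return(z)
      L <- build_L(p, tolower(cm))
      tcrossprod(L)
    }
    list(mean = unname(vapply(seq_len(T), function(j) p[[paste0("mu", j)]], 0)),
         SA = comp_mat("A"), SC = comp_mat("C"), SE = comp_mat("E"))
  }
  new_twin_model(paste0("cf-", tolower(paste(comps, collapse = ""))),
                 as.integer(T), comps, params, moments)
}

#' Autoregressive (simplex) multivariate model
#'
#' Separate latent chains per included component: the latent true score at
#' occasion t is \eqn{\beta_t} times the true score at t-1 plus an
#' occasion-specific innovation. The observed variable is the sum of the
#' latent chain values plus an occasion-specific residual, which is
#' non-shared environmental (absorbing measurement error). This model
#' expresses the hypothesis that influences accumulate and are transmitted
#' occasion to occasion rather than acting through a single stable factor.
#'
#' Parameters per chain x (x = a, c, e): innovations `x_innov1..T`
#' (path scale) and transmission coefficients `x_beta2..T`; plus the
#' occasion residual path(s).
#'
#' A simplex with freely varying occasion residual variances is locally
#' unidentified: the innovation and residual variances of the first and
#' last occasions only enter the likelihood through their sums, so two
#' parameter directions are redundant (the moment-map Jacobian loses rank
#' 2) and likelihood-ratio df against the correlated-factors reference are
#' overstated. The default therefore constrains the residual variance
#' equal across occasions (single path `res_e`), the standard remedy for
#' simplex measurement models; `equal_residuals = FALSE` gives the free
#' per-occasion variant (`res_e1..T`) for sensitivity analyses.
#'
#' @param equal_residuals Constrain occasion residual variances equal
#'   (default, identified) or leave one per occasion.
#' @inheritParams correlated_factors_model
#' @return A [twin_model].
#' @export
autoregression_model <- function(T = 4, components = "AE",
                                 equal_residuals = TRUE) {
  stopifnot(T >= 2)
  comps <- parse_components(components)
  pr <- list()
  for (cm in comps) {
    letter <- tolower(cm)
    pr[[paste0(letter, "_innov")]] <-
      param_row(paste0(letter, "_innov", seq_len(T)), 0, Inf, 0.6)
    pr[[paste0(letter, "_beta")]] <-
      param_row(paste0(letter, "_beta", 2:T), -3, 3, 0.5)
  }
  pr[["res"]] <- if (equal_residuals) param_row("res_e", 0, Inf, 0.4)
                 else param_row(paste0("res_e", seq_len(T)), 0, Inf, 0.4)
  params <- bind_rows(bind_rows(pr), mean_params(T))
  chain_cov <- function(p, letter) {
    B <- matrix(0, T, T)
    for (t in 2:T) B[t, t - 1] <- p[[paste0(letter, "_beta", t)]]
    M <- solve(diag(T) - B)
    iv <- vapply(seq_len(T), function(t) p[[paste0(letter, "_innov", t)]]^2, 0)
    M %*% diag(iv, T) %*% t(M)
  }
  moments <- function(p) {
    z <- matrix(0, T, T)
    SA <- if ("A" %in% comps) chain_cov(p, "a") else z
    SC <- if ("C" %in% comps) chain_cov(p, "c") else z
    res <- if (equal_residuals) rep(p[["res_e"]]^2, T)
           else vapply(seq_len(T), function(t) p[[paste0("res_e", t)]]^2, 0)
    SE <- chain_cov(p, "e") + diag(res, T)
    list(mean = unname(vapply(seq_len(T), function(j) p[[paste0("mu", j)]], 0)),
         SA = SA, SC = SC, SE = SE)
  }
  new_twin_model(paste0("ar-", tolower(paste(comps, collapse = ""))),
                 as.integer(T), comps, params, moments)
}

#' Common pathway multivariate model
#'
#' One or two latent phenotypic factors, each with total variance fixed to 1
#' and decomposed into included components (factor paths `fac_a<m>`,
#' `fac_c<m>`; the factor E path is derived as
#' \eqn{\sqrt{1 - fac\_a^2 - fac\_c^2}}, so the squared factor paths are
#' directly the standardized factor decomposition). Loadings `load<m>_<j>`
#' carry the factor(s) to the observed variables; per-variable residuals
#' (`res_a<j>`, `res_c<j>`, `res_e<j>` as included) absorb
#' occasion-specific influences. Expresses the hypothesis of a single stable
#' latent phenotype behind all occasions.
#'
#' For identification the second factor does not load on the first variable
#' and the first loading of each factor is non-negative. One factor requires
#' T >= 3.
#'
#' @param n_factors 1 or 2 latent factors.
#' @inheritParams correlated_factors_model
#' @return A [twin_model].
#' @export
common_pathway_model <- function(T = 4, n_factors = 1, components = "AE") {
  stopifnot(T >= 3, n_factors %in% 1:2)
  comps <- parse_components(components)
  pr <- list()
  for (m in seq_len(n_factors)) {
    if ("A" %in% comps) pr[[paste0("fac_a", m)]] <- param_row(paste0("fac_a", m), 0, 1, 0.8)
    if ("C" %in% comps) pr[[paste0("fac_c", m)]] <- param_row(paste0("fac_c", m), 0, 1, 0.3)
    jj <- if (m == 1) seq_len(T) else 2:T
    for (j in jj) {
      nm <- paste0("load", m, "_", j)
      pr[[nm]] <- param_row(nm, if (j == jj[1]) 0 else -Inf, Inf, 0.7)
    }
  }
  for (cm in comps) {
    letter <- tolower(cm)
    pr[[paste0("res_", letter)]] <-
      param_row(paste0("res_", letter, seq_len(T)), 0, Inf, 0.4)
  }
  params <- bind_rows(bind_rows(pr), mean_params(T))
  moments <- function(p) {
    z <- matrix(0, T, T)
    SA <- z; SC <- z; SE <- z
    for (m in seq_len(n_factors)) {
      fa2 <- if ("A" %in% comps) p[[paste0("fac_a", m)]]^2 else 0
      fc2 <- if ("C" %in% comps) p[[paste0("fac_c", m)]]^2 else 0
      fe2 <- 1 - fa2 - fc2
      if (fe2 < 0) return(NULL) # inadmissible: factor variance exceeds 1
      lam <- numeric(T)
      jj <- if (m == 1) seq_len(T) else 2:T
      for (j in jj) lam[j] <- p[[paste0("load", m, "_", j)]]
      LL <- tcrossprod(lam)
      SA <- SA + fa2 * LL; SC <- SC + fc2 * LL; SE <- SE + fe2 * LL
    }
    rd <- function(letter) diag(vapply(seq_len(T), function(j)
      p[[paste0("res_", letter, j)]]^2, 0), T)
    if ("A" %in% comps) SA <- SA + rd("a")
    if ("C" %in% comps) SC <- SC + rd("c")
    SE <- SE + rd("e")
    list(mean = unname(vapply(seq_len(T), function(j) p[[paste0("mu", j)]], 0)),
         SA = SA, SC = SC, SE = SE)
  }
  new_twin_model(paste0("cp", n_factors, "-", tolower(paste(comps, collapse = ""))),
                 as.integer(T), comps, params, moments)
}

#' Independent pathway multivariate model
#'
#' Per included component, one common factor loads directly on the observed
#' variables (loadings `lam_a<j>`, `lam_c<j>`, `lam_e<j>`) with per-variable
#' residuals (`res_a<j>`, ...). Unlike the common pathway model, the genetic
#' and environmental common factors are distinct latent variables, so their
#' loading patterns may differ freely.
#'
#' @inheritParams correlated_factors_model
#' @return A [twin_model].
#' @export
independent_pathway_model <- function(T = 4, components = "AE") {
  stopifnot(T >= 3)
  comps <- parse_components(components)
  pr <- list()
  for (cm in comps) {
    letter <- tolower(cm)
    for (j in seq_len(T)) {
      nm <- paste0("lam_", letter, j)
      pr[[nm]] <- param_row(nm, if (j == 1) 0 else -Inf, Inf, 0.6)
    }
    pr[[paste0("res_", letter)]] <-
      param_row(paste0("res_", letter, seq_len(T)), 0, Inf, 0.4)
  }
  params <- bind_rows(bind_rows(pr), mean_params(T))
  moments <- function(p) {
    z <- matrix(0, T, T)
    comp_mat <- function(letter) {
      lam <- vapply(seq_len(T), function(j) p[[paste0("lam_", letter, j)]], 0)
      res <- vapply(seq_len(T), function(j) p[[paste0("res_", letter, j)]]^2, 0)
      tcrossprod(lam) + diag(res, T)
    }
    list(mean = unname(vapply(seq_len(T), function(j) p[[paste0("mu", j)]], 0)),
         SA = if ("A" %in% comps) comp_mat("a") else z,
         SC = if ("C" %in% comps) comp_mat("c") else z,
         SE = comp_mat("e"))
  }
  new_twin_model(paste0("ip-", tolower(paste(comps, collapse = ""))),
                 as.integer(T), comps, params, moments)
}

#' Fix parameters of a twin model
#'
#' Returns a copy of the model with the named parameters fixed (default to
#' zero), e.g. to drop a residual genetic path or test a constrained
#' submodel by likelihood ratio.
#'
#' @param model A [twin_model].
#' @param names Parameter names to fix.
#' @param value Value(s) at which to fix them.
#' @return A [twin_model] with those parameters no longer free.
#' @export
fix_parameters <- function(model, names, value = 0) {
  idx <- match(names, model$params$name)
  if (anyNA(idx)) abort(paste0("unknown parameters: ",
                               paste(names[is.na(idx)], collapse = ", ")))
  model$params$free[idx] <- FALSE
  model$params$value[idx] <- rep_len(value, length(idx))
  model$name <- paste0(model$name, "*")
  model
}

#' Build a model by short name
#'
#' Convenience registry mapping short identifiers (`"uni"`, `"cf"`, `"ar"`,
#' `"cp1"`, `"cp2"`, `"ip"`) to constructors.
#'
#' @param name Short model identifier.
#' @param T Number of interval variables.
#' @param components Variance components, e.g. `"ACE"` or `"AE"`.
#' @return A [twin_model].
#' @export
twin_model_by_name <- function(name, T = 4, components = "ACE") {
  switch(name,
    "uni" = univariate_model(components),
    "cf"  = correlated_factors_model(T, components),
    "ar"  = autoregression_model(T, components),
    "cp1" = common_pathway_model(T, 1, components),
    "cp2" = common_pathway_model(T, 2, components),
    "ip"  = independent_pathway_model(T, components),
    abort(paste0("unknown model name: ", name))
  )
}

# expand a free-parameter vector into the full named parameter vector
full_params <- function(model, free) {
  p <- ifelse(model$params$free, NA_real_, model$params$value)
  names(p) <- model$params$name
  p[model$params$free] <- free
  p
}

#' Model-implied twin-pair covariance matrix
#'
#' Assembles the 2T x 2T covariance matrix of a twin pair's stacked
#' phenotype vector for a zygosity group: within-person block
#' \eqn{\Sigma_W = \Sigma_A + \Sigma_C + \Sigma_E} and cross-twin block
#' \eqn{\Sigma_X = r_A \Sigma_A + \Sigma_C}, where the additive genetic
#' cross-twin weight \eqn{r_A} is 1.0 for MZ and 0.5 for DZ pairs, shared
#' environment is fully correlated within pairs in both groups, and
#' non-shared environment is uncorrelated across twins.
#'
#' @param model A [twin_model].
#' @param params Full named parameter vector (defaults to model start values).
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A symmetric 2T x 2T matrix.
#' @export
pair_covariance <- function(model, params = NULL, zygosity = c("MZ", "DZ")) {
  zygosity <- toupper(zygosity[1])
  if (!zygosity %in% c("MZ", "DZ")) abort(paste0("unknown zygosity code: ", zygosity))
  mo <- model_moments(model, params)
  rA <- if (zygosity == "MZ") 1.0 else 0.5
  W <- mo$SA + mo$SC + mo$SE
  X <- rA * mo$SA + mo$SC
  rbind(cbind(W, X), cbind(t(X), W))
}

model_moments <- function(model, params = NULL) {
  if (is.null(params)) {
    params <- ifelse(model$params$free, model$params$start, model$params$value)
    names(params) <- model$params$name
  }
  mo <- model$moments(as.list(params))
  if (is.null(mo)) abort("inadmissible parameter point: implied component variances are negative")
  mo
}

#' Model-implied means and per-zygosity pair covariances
#'
#' @inheritParams pair_covariance
#' @return List with `mean` (length-2T stacked mean vector), `Sigma_MZ`,
#'   `Sigma_DZ`, and the component blocks `SA`, `SC`, `SE`.
#' @export
implied_moments <- function(model, params = NULL) {
  mo <- model_moments(model, params)
  W <- mo$SA + mo$SC + mo$SE
  list(mean = rep(mo$mean, 2),
       Sigma_MZ = rbind(cbind(W, mo$SA + mo$SC), cbind(mo$SA + mo$SC, W)),
       Sigma_DZ = rbind(cbind(W, 0.5 * mo$SA + mo$SC), cbind(0.5 * mo$SA + mo$SC, W)),
       SA = mo$SA, SC = mo$SC, SE = mo$SE)
}
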