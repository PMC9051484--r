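#' @title Raw-data FIML for twin-pair models
#' @description
#' The likelihood engine treats each twin pair as one observation of a
#' 2T-variate normal vector whose mean and covariance are implied by a
#' [twin_model] (zygosity-specific covariance). Missing entries are handled
#' by full-information maximum likelihood: each pair contributes the normal
#' density of its observed sub-vector, i.e. rows/columns of missing entries
#' are deleted from the implied moments for that pair — no pair is ever
#' discarded for being incomplete.
#'
#' Internally, pairs are grouped by (zygosity, missingness pattern) and the
#' likelihood is evaluated from each group's sufficient statistics (count,
#' mean, scatter), which makes the cost of one evaluation independent of the
#' number of pairs.
#' @name fiml
NULL

BIG_OBJ <- 1e10

# group pairs by zygosity x missingness pattern; store sufficient statistics
prep_pair_stats <- function(wide, Tn = n_intervals(wide)) {
  cols <- wide_value_cols(Tn)
  Y <- as.matrix(as.data.frame(wide[, cols]))
  storage.mode(Y) <- "double"
  zyg <- toupper(as.character(wide$zygosity))
  bad <- setdiff(unique(zyg), c("MZ", "DZ"))
  if (length(bad)) abort(paste0("unknown zygosity code: ", paste(bad, collapse = ", ")))
  obs <- !is.na(Y)
  empty <- rowSums(obs) == 0
  if (any(empty)) {
    warn(paste0(sum(empty), " pair(s) with no observed entries dropped"))
    Y <- Y[!empty, , drop = FALSE]; obs <- obs[!empty, , drop = FALSE]
    zyg <- zyg[!empty]
  }
  if (nrow(Y) == 0) abort("no usable pairs")
  key <- paste0(zyg, ":", apply(obs, 1, function(r) paste0(as.integer(r), collapse = "")))
  groups <- lapply(split(seq_len(nrow(Y)), key), function(rows) {
    o <- which(obs[rows[1], ])
    Yg <- Y[rows, o, drop = FALSE]
    m <- colMeans(Yg)
    S <- crossprod(sweep(Yg, 2, m))
    list(zyg = zyg[rows[1]], o = o, n = length(rows), m = m, S = S)
  })
  # per-variable pooled moments for start values
  vm <- vv <- numeric(Tn)
  for (j in seq_len(Tn)) {
    v <- c(Y[, j], Y[, Tn + j])
    v <- v[!is.na(v)]
    vm[j] <- if (length(v)) mean(v) else 0
    vv[j] <- if (length(v) > 1) var(v) else 1
  }
  list(groups = groups, Tn = Tn, n_pairs = nrow(Y), n_obs = sum(obs),
       var_means = vm, var_vars = vv,
       n_mz = sum(zyg == "MZ"), n_dz = sum(zyg == "DZ"))
}

# -2 log-likelihood from sufficient statistics at a full parameter vector
fiml_m2ll_stats <- function(model, params, stats) {
  mo <- model$moments(as.list(params))
  if (is.null(mo)) return(BIG_OBJ)
  W <- mo$SA + mo$SC + mo$SE
  mean2 <- rep(mo$mean, 2)
  Sig <- list(
    MZ = rbind(cbind(W, mo$SA + mo$SC), cbind(mo$SA + mo$SC, W)),
    DZ = rbind(cbind(W, 0.5 * mo$SA + mo$SC), cbind(0.5 * mo$SA + mo$SC, W))
  )
  tot <- 0
  for (g in stats$groups) {
    So <- Sig[[g$zyg]][g$o, g$o, drop = FALSE]
    ch <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(ch)) return(BIG_OBJ)
    inv <- chol2inv(ch)
    d <- g$m - mean2[g$o]
    tot <- tot + g$n * length(g$o) * log(2 * pi) +
      g$n * 2 * sum(log(diag(ch))) +
      sum(inv * g$S) +
      g$n * drop(crossprod(d, inv %*% d))
  }
  tot
}

#' Evaluate the FIML -2 log-likelihood
#'
#' Sums, over twin pairs, minus twice the log multivariate-normal density of
#' each pair's observed phenotype sub-vector under the model-implied mean
#' and zygosity-specific pair covariance.
#'
#' @param data Wide twin table (`family_id`, `zygosity`, `t1_a`, ...).
#' @param model A [twin_model].
#' @param params Full named parameter vector; defaults to the model's start
#'   values.
#' @return The -2 log-likelihood (scalar). Parameter points whose implied
#'   observed submatrix is not positive definite return a large finite
#'   penalty value so optimizers can recover.
#' @export
fiml_loglik <- function(data, model, params = NULL) {
  stats <- prep_pair_stats(data, model$T)
  if (is.null(params)) {
    params <- ifelse(model$params$free, model$params$start, model$params$value)
    names(params) <- model$params$name
  }
  fiml_m2ll_stats(model, params[model$params$name], stats)
}

scaled_starts <- function(model, stats) {
  st <- model$params$start
  nm <- model$params$name
  s <- sqrt(mean(stats$var_vars))
  is_mu <- grepl("^mu", nm)
  is_beta <- grepl("_beta", nm)
  is_fac <- grepl("^fac_", nm)
  st[!is_mu & !is_beta & !is_fac] <- st[!is_mu & !is_beta & !is_fac] * s
  mu_idx <- match(paste0("mu", seq_len(model$T)), nm)
  if (model$T == 1) st[mu_idx] <- stats$var_means
  else st[mu_idx] <- stats$var_means
  st
}

jitter_start <- function(st, model, scale) {
  nm <- model$params$name
  is_mu <- grepl("^mu", nm)
  is_beta <- grepl("_beta", nm)
  is_fac <- grepl("^fac_", nm)
  pos <- !is_mu & !is_beta & !is_fac
  st[pos] <- st[pos] * exp(rnorm(sum(pos), 0, 0.25))
  st[is_beta] <- st[is_beta] + rnorm(sum(is_beta), 0, 0.3)
  st[is_fac] <- pmin(0.98, pmax(0.02, st[is_fac] + rnorm(sum(is_fac), 0, 0.15)))
  st[is_mu] <- st[is_mu] + rnorm(sum(is_mu), 0, 0.1 * scale)
  pmin(pmax(st, model$params$lower), model$params$upper)
}

#' Fit a twin model by full-information maximum likelihood
#'
#' Minimizes the raw-data -2 log-likelihood with a bounded quasi-Newton
#' optimizer (`nlminb`) from several jittered start points and returns the
#' best solution. Multimodal likelihood surfaces (simplex and
#' common-pathway models can have local optima) are the reason for the
#' multi-start default.
#'
#' @param data Wide twin table.
#' @param model A [twin_model].
#' @param n_starts Number of optimizer starts (first start is deterministic,
#'   the rest are seeded jitters). Default 10.
#' @param seed Seed for the start-point jitter (and nothing else).
#' @param start Optional full named vector of custom start values.
#' @param control Control list passed to [stats::nlminb()].
#' @return A `twin_fit` object: estimates, `minus2ll`, free-parameter count,
#'   convergence flag, per-start diagnostics, and the sufficient statistics
#'   needed for profiling and refits. Supports [tidy()], [glance()],
#'   [stats::logLik()], [stats::AIC()].
#' @examples
#' mod <- univariate_model("AE")
#' wide <- simulate_wide(mod, c(a = 0.8, e = 0.6, mu1 = 0), 200, 200, seed = 1)
#' fit <- fit_twin_model(wide, mod, n_starts = 2)
#' glance(fit)
#' @export
fit_twin_model <- function(data, model, n_starts = 10, seed = 1,
                           start = NULL, control = list()) {
  stats <- prep_pair_stats(data, model$T)
  fit_twin_model_stats(stats, model, n_starts = n_starts, seed = seed,
                       start = start, control = control)
}

fit_twin_model_stats <- function(stats, model, n_starts = 10, seed = 1,
                                 start = NULL, control = list()) {
  free <- model$params$free
  if (!any(free)) abort("model has no free parameters")
  lower <- model$params$lower[free]
  upper <- model$params$upper[free]
  base <- if (is.null(start)) scaled_starts(model, stats)
          else unname(start[model$params$name])
  scale <- sqrt(mean(stats$var_vars))
  ctrl <- modifyList(list(iter.max = 800, eval.max = 4000, rel.tol = 1e-8),
                     control)

  obj <- function(th) {
    p <- ifelse(free, NA_real_, model$params$value)
    p[free] <- th
    names(p) <- model$params$name
    fiml_m2ll_stats(model, p, stats)
  }

  starts <- list(pmin(pmax(base, model$params$lower), model$params$upper))
  if (n_starts > 1) {
    jit <- with_seed(seed, lapply(seq_len(n_starts - 1), function(i)
      jitter_start(base, model, scale)))
    starts <- c(starts, jit)
  }

  runs <- lapply(seq_along(starts), function(i) {
    st <- starts[[i]][free]
    r <- tryCatch(
      nlminb(st, obj, lower = lower, upper = upper, control = ctrl),
      error = function(e) list(objective = Inf, convergence = 1L,
                               message = conditionMessage(e), par = st))
    list(i = i, par = r$par, objective = r$objective,
         convergence = r$convergence, message = r$message %||% "")
  })
  objs <- vapply(runs, function(r) r$objective, 0)
  if (all(!is.finite(objs)))
    abort(paste0("all optimizer starts failed:\n",
                 paste(vapply(runs, function(r) paste0("  start ", r$i, ": ", r$message),
                              ""), collapse = "\n")))
  best <- runs[[which.min(objs)]]
  converged <- best$convergence == 0 && best$objective < BIG_OBJ / 2
  if (!converged)
    warn(paste0("optimizer did not report convergence for model ", model$name,
                " (", best$message, ")"))
  est <- ifelse(free, NA_real_, model$params$value)
  est[free] <- best$par
  names(est) <- model$params$name

  structure(list(
    model = model,
    estimates = est,
    minus2ll = best$objective,
    npar = sum(free),
    converged = converged,
    n_pairs = stats$n_pairs,
    n_obs = stats$n_obs,
    starts = tibble(
      start = vapply(runs, function(r) r$i, 0L),
      objective = objs,
      convergence = vapply(runs, function(r) as.integer(r$convergence), 0L)
    ),
    stats = stats,
    options = list(n_starts = n_starts, seed = seed, control = ctrl)
  ), class = "twin_fit")
}

#' @export
print.twin_fit <- function(x, ...) {
  cat("<twin_fit> ", x$model$name, "\n", sep = "")
  cat("  -2lnL = ", format(x$minus2ll, digits = 10),
      "  free params = ", x$npar,
      "  AIC = ", format(x$minus2ll + 2 * x$npar, digits = 10), "\n", sep = "")
  cat("  pairs = ", x$n_pairs, " (", x$stats$n_mz, " MZ, ", x$stats$n_dz,
      " DZ), observations = ", x$n_obs, "\n", sep = "")
  if (!x$converged) cat("  WARNING: not converged\n")
  invisible(x)
}

#' @export
logLik.twin_fit <- function(object, ...) {
  structure(-object$minus2ll / 2, df = object$npar, nobs = object$n_pairs,
            class = "logLik")
}
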