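cor_estimate <- function(estimate, lower, upper, n, method, ...) {
  tibble(estimate = estimate, lower95 = lower, upper95 = upper,
         n = as.integer(n), method = method, ...)
}

#' Cross-interval phenotypic correlations
#'
#' Correlations between the T interval variables across individuals (both
#' members of each pair stacked as individuals), using pairwise-complete
#' observations. CIs are Fisher-z at 95%.
#'
#' @param wide Wide twin table.
#' @param method `"pearson"` (default).
#' @return A tibble with one row per variable pair (`var1`, `var2`,
#'   `estimate`, `lower95`, `upper95`, `n`); convert to a matrix with
#'   [correlation_matrix()].
#' @export
cross_interval_correlations <- function(wide, method = "pearson") {
  method <- match.arg(method, "pearson")
  Tn <- n_intervals(wide)
  X <- individuals_matrix(wide, Tn)
  out <- list()
  for (i in seq_len(Tn)) for (j in seq_len(Tn)) {
    if (j > i) next
    ok <- complete.cases(X[, c(i, j)])
    n <- sum(ok)
    if (i == j) {
      out[[length(out) + 1]] <- cor_estimate(1, 1, 1, n, method,
                                             var1 = i, var2 = j)
      next
    }
    if (n < 3) {
      out[[length(out) + 1]] <- cor_estimate(NA_real_, NA_real_, NA_real_, n,
                                             method, var1 = i, var2 = j)
      next
    }
    r <- cor(X[ok, i], X[ok, j])
    z <- atanh(r); se <- 1 / sqrt(n - 3)
    out[[length(out) + 1]] <- cor_estimate(
      r, tanh(z - 1.96 * se), tanh(z + 1.96 * se), n, method,
      var1 = i, var2 = j)
  }
  bind_rows(out) %>% select("var1", "var2", dplyr::everything())
}

# stack both twins as individuals: n*2 rows x T columns
individuals_matrix <- function(wide, Tn = n_intervals(wide)) {
  A <- as.matrix(as.data.frame(wide[, paste0("t", seq_len(Tn), "_a")]))
  B <- as.matrix(as.data.frame(wide[, paste0("t", seq_len(Tn), "_b")]))
  X <- rbind(A, B)
  colnames(X) <- paste0("t", seq_len(Tn))
  X
}

#' Convert a correlation tibble to a matrix
#'
#' @param tbl Output of [cross_interval_correlations()].
#' @param value Column to spread (default `"estimate"`).
#' @return A symmetric matrix.
#' @export
correlation_matrix <- function(tbl, value = "estimate") {
  Tn <- max(tbl$var1, tbl$var2)
  M <- diag(1, Tn)
  for (k in seq_len(nrow(tbl))) {
    M[tbl$var1[k], tbl$var2[k]] <- tbl[[value]][k]
    M[tbl$var2[k], tbl$var1[k]] <- tbl[[value]][k]
  }
  M
}

# -2lnL of exchangeable bivariate normal pairs (equal mean/variance across
# twin order) at (mu, v, r)
pair_binorm_m2ll <- function(x1, x2, mu, v, r) {
  if (v <= 0 || abs(r) >= 1) return(BIG_OBJ)
  det <- v^2 * (1 - r^2)
  q <- ((x1 - mu)^2 - 2 * r * (x1 - mu) * (x2 - mu) + (x2 - mu)^2) / (v * (1 - r^2))
  sum(2 * log(2 * pi) + log(det) + q)
}

#' Twin-pair correlation for one interval variable
#'
#' Maximum-likelihood correlation across twin pairs of one zygosity under a
#' bivariate normal with mean and variance constrained equal across twin
#' order (the double-entry / intraclass convention, which makes the
#' estimate invariant to within-pair relabeling). The 95% CI is
#' profile-likelihood based, hence possibly asymmetric.
#'
#' @param wide Wide twin table.
#' @param variable Interval variable index (1..T).
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return One-row tibble (`variable`, `zygosity`, `estimate`, `lower95`,
#'   `upper95`, `n` complete pairs, `method`).
#' @export
twin_pair_correlation <- function(wide, variable, zygosity) {
  zygosity <- toupper(zygosity)
  rows <- toupper(wide$zygosity) == zygosity
  x1 <- wide[[paste0("t", variable, "_a")]][rows]
  x2 <- wide[[paste0("t", variable, "_b")]][rows]
  ok <- !is.na(x1) & !is.na(x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  n <- length(x1)
  if (n < 3) abort(paste0("fewer than 3 complete ", zygosity,
                          " pairs for variable ", variable))
  prof <- function(r) { # minimize over mu, v at fixed r
    mu <- mean(c(x1, x2))
    # closed-form v at fixed r, mu: d/dv of -2lnL = 0
    s11 <- mean((x1 - mu)^2 + (x2 - mu)^2) / 2
    s12 <- mean((x1 - mu) * (x2 - mu))
    v <- (s11 - r * s12) / (1 - r^2)
    pair_binorm_m2ll(x1, x2, mu, v, r)
  }
  opt <- optimize(prof, c(-0.999, 0.999))
  r_hat <- opt$minimum
  m2_min <- opt$objective
  crit <- qchisq(0.95, 1)
  f <- function(r) prof(r) - m2_min - crit
  lo <- if (f(-0.999) < 0) -1 else uniroot(f, c(-0.999, r_hat))$root
  hi <- if (f(0.999) < 0) 1 else uniroot(f, c(r_hat, 0.999))$root
  cor_estimate(r_hat, lo, hi, n, "ml-bivariate",
               variable = variable, zygosity = zygosity) %>%
    select("variable", "zygosity", dplyr::everything())
}

#' Twin-pair correlation table by zygosity
#'
#' Computes [twin_pair_correlation()] for every interval variable and both
#' zygosity groups — the machine-readable analog of the familiar
#' "corrMZ / corrDZ with 95% CIs" table of twin studies.
#'
#' @param wide Wide twin table.
#' @return Tibble with one row per variable x zygosity.
#' @export
twin_correlation_table <- function(wide) {
  Tn <- n_intervals(wide)
  grid <- expand.grid(variable = seq_len(Tn), zygosity = c("MZ", "DZ"),
                      stringsAsFactors = FALSE)
  purrr::pmap(grid, function(variable, zygosity)
    twin_pair_correlation(wide, variable, zygosity)) %>% bind_rows()
}

#' Polyserial correlation
#'
#' Maximum-likelihood estimate of the correlation of the latent bivariate
#' normal assumed to underlie a continuous variable and an ordinal variable
#' with K categories. The continuous margin's mean/SD and the thresholds
#' are estimated from the margins (two-step); the correlation maximizes the
#' joint likelihood given those margins, and its 95% CI is
#' profile-likelihood based. Unlike a Pearson correlation on category
#' codes, the estimate is not attenuated by the coarse ordinalization.
#'
#' @param continuous Numeric vector.
#' @param ordinal Ordinal vector (factor, integer or character; ordered by
#'   sorted unique values if not a factor).
#' @return One-row tibble (`estimate`, `lower95`, `upper95`, `n`, `method`,
#'   `k` categories used).
#' @export
polyserial_correlation <- function(continuous, ordinal) {
  ok <- !is.na(continuous) & !is.na(ordinal)
  x <- continuous[ok]
  y <- ordinal[ok]
  if (!is.factor(y)) y <- factor(y)
  counts <- table(y)
  if (any(counts == 0)) {
    warn("empty ordinal categories dropped")
    y <- droplevels(y)
    counts <- table(y)
  }
  K <- nlevels(y)
  if (K < 2) abort("ordinal variable must have at least 2 non-empty categories")
  if (sd(x) == 0) abort("continuous variable is degenerate (zero variance)")
  n <- length(x)
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2)) # ML scale
  tau <- qnorm(cumsum(counts)[-K] / n)
  z <- (x - mu) / s
  ky <- as.integer(y)
  taul <- c(-Inf, tau)[ky]
  tauu <- c(tau, Inf)[ky]
  negll <- function(rho) {
    sr <- sqrt(1 - rho^2)
    p <- pnorm((tauu - rho * z) / sr) - pnorm((taul - rho * z) / sr)
    if (any(p <= 0)) return(BIG_OBJ)
    -(sum(dnorm(x, mu, s, log = TRUE)) + sum(log(p)))
  }
  opt <- optimize(negll, c(-0.999, 0.999))
  rho_hat <- opt$minimum
  crit <- qchisq(0.95, 1) / 2
  f <- function(r) negll(r) - opt$objective - crit
  lo <- if (f(-0.999) < 0) -1 else uniroot(f, c(-0.999, rho_hat))$root
  hi <- if (f(0.999) < 0) 1 else uniroot(f, c(rho_hat, 0.999))$root
  cor_estimate(rho_hat, lo, hi, n, "polyserial", k = K)
}
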