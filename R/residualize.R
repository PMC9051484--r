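#' Residualize interval phenotypes for covariates
#'
#' Replaces each interval variable by its residual from an ordinary
#' least-squares regression (intercept included) on the requested covariate
#' terms, fitted across all individuals (both twins pooled) with non-missing
#' values for that interval. This mirrors the common practice of adjusting
#' twin phenotypes for scanner/site, assessment age, ethnicity and birth-year
#' (cohort) effects before variance-component modeling. Missing cells stay
#' missing.
#'
#' @param wide Wide twin table (from [age_anchor()] or [simulate_wide()]).
#' @param covariates Per-observation covariate table with columns
#'   `family_id`, `twin`, `interval` plus covariate columns; defaults to the
#'   table attached by [age_anchor()].
#' @param terms Character vector of covariate terms, any of `"scanner"`,
#'   `"age"` (age at assessment, centered within interval), `"ethnicity"`,
#'   `"cohort"` (birth year). `character(0)` demeans each variable.
#' @return The wide tibble with phenotype columns replaced by residuals.
#'   Attributes of `wide` are preserved.
#' @export
residualize <- function(wide,
                        covariates = anchor_covariates(wide),
                        terms = c("scanner", "age", "ethnicity", "cohort")) {
  if (length(terms) > 0)
    terms <- match.arg(terms, c("scanner", "age", "ethnicity", "cohort"),
                       several.ok = TRUE)
  Tn <- n_intervals(wide)
  labels <- interval_labels_of(wide)
  out <- wide

  col_map <- c(scanner = "scanner", age = "age", ethnicity = "ethnicity",
               cohort = "birth_year")

  for (j in seq_len(Tn)) {
    # stack both twins as individuals for this interval variable
    cols <- paste0("t", j, c("_a", "_b"))
    vals <- c(wide[[cols[1]]], wide[[cols[2]]])
    ids <- tibble(
      family_id = rep(wide$family_id, 2),
      twin = rep(1:2, each = nrow(wide)),
      value = vals
    )
    obs <- which(!is.na(ids$value))
    if (length(obs) == 0) next
    dat <- ids[obs, ]
    if (length(terms) > 0) {
      cv <- covariates %>%
        filter(.data$interval == labels[j]) %>%
        select("family_id", "twin", dplyr::any_of(unname(col_map[terms])))
      dat <- left_join(dat, cv, by = c("family_id", "twin"))
      need <- unname(col_map[terms])
      lost <- setdiff(need, names(dat))
      if (length(lost))
        abort(paste0("covariate columns missing for terms: ",
                     paste(names(col_map)[col_map %in% lost], collapse = ", ")))
      if (anyNA(dat[need]))
        abort(paste0("missing covariate values for observed phenotypes in interval ",
                     labels[j]))
      if ("age" %in% terms) dat$age <- dat$age - mean(dat$age)
      if ("ethnicity" %in% terms) dat$ethnicity <- factor(dat$ethnicity)
      form <- stats::as.formula(paste("value ~", paste(need, collapse = " + ")))
    } else {
      form <- value ~ 1
    }
    mm <- model.matrix(form, data = dat)
    # covariates constant within an interval (e.g. scanner in an interval
    # reachable from a single wave) are absorbed by the intercept: drop them
    if (ncol(mm) > 1) {
      const <- c(FALSE, apply(mm[, -1, drop = FALSE], 2,
                              function(x) max(x) - min(x) == 0))
      mm <- mm[, !const, drop = FALSE]
    }
    qr_mm <- qr(mm)
    if (qr_mm$rank < ncol(mm)) {
      bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
      abort(paste0("rank-deficient covariate design in interval ", labels[j],
                   "; collinear terms: ", paste(bad, collapse = ", ")))
    }
    res <- stats::lm.fit(mm, dat$value)$residuals
    full <- ids$value
    full[obs] <- res
    out[[cols[1]]] <- full[seq_len(nrow(wide))]
    out[[cols[2]]] <- full[nrow(wide) + seq_len(nrow(wide))]
  }
  for (a in c("report", "covariates")) attr(out, a) <- attr(wide, a)
  out
}

# number of interval variables encoded in a wide table's t<j>_a columns
n_intervals <- function(wide) {
  cols <- grep("^t[0-9]+_a$", names(wide), value = TRUE)
  if (length(cols) == 0) abort("not a wide twin table: no t<j>_a columns")
  length(cols)
}

interval_labels_of <- function(wide) {
  labs <- attr(wide, "interval_labels")
  if (!is.null(labs)) return(labs)
  rep <- attr(wide, "covariates")
  if (!is.null(rep) && nrow(rep) > 0 && "interval" %in% names(rep)) {
    sch <- age_interval_scheme()
    if (all(unique(rep$interval) %in% sch$label) && n_intervals(wide) == nrow(sch))
      return(sch$label)
    return(sort(unique(rep$interval)))
  }
  age_interval_scheme()$label[seq_len(n_intervals(wide))]
}
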