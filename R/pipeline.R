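#' Model-selection pipeline for longitudinal twin data
#'
#' Reproduces the standard decision sequence for competing multivariate
#' genetic models:
#' 1. fit the correlated-factors (Cholesky) reference model and the
#'    candidate structured models (autoregressive simplex, 1- and 2-factor
#'    common pathway, independent pathway), all with the same components;
#' 2. test each candidate against the reference by likelihood ratio;
#'    candidates that deteriorate significantly are eliminated; among the
#'    survivors, a candidate nested inside another survivor whose extra
#'    parameters do not significantly improve the likelihood displaces the
#'    more complex one (parsimony by nested LRT), and the remaining models
#'    are ranked by AIC (ties go to fewer parameters); if every candidate
#'    deteriorates, keep the reference;
#' 3. within the winner, drop whole components (ACE -> AE / CE / E),
#'    keeping the most parsimonious variant whose likelihood-ratio test
#'    against the winner is non-significant, again tie-broken by AIC;
#' 4. optionally (factor models) drop per-variable residual genetic paths
#'    stepwise, largest p first, while the cumulative drop stays
#'    non-significant.
#'
#' Non-converged candidates are excluded with a warning, never silently
#' selected.
#'
#' @param data Wide twin table (anchored and residualized).
#' @param components Components for the stage-1 candidates (`"ACE"` or
#'   `"AE"`).
#' @param candidates Character vector of stage-1 candidate classes.
#' @param n_starts Optimizer starts per fit.
#' @param seed Seed for optimizer start jitter.
#' @param alpha LRT significance level for "deteriorates".
#' @param refine Run stages 3-4.
#' @param drop_residuals Run stage 4 (per-variable residual-A drops).
#' @return An object of class `twin_comparison`: `table` (one row per
#'   fitted model with `minus2ll`, `npar`, `AIC`, `chi2`, `df`, `p` vs its
#'   comparison parent, `stage`, `selected`), `fits`, `selected`,
#'   `selected_fit`, plus the selected model's [standardize()] and
#'   [component_correlations()] results.
#' @export
model_selection_pipeline <- function(data,
                                     components = "ACE",
                                     candidates = c("ar", "cp1", "cp2", "ip"),
                                     n_starts = 4,
                                     seed = 1,
                                     alpha = 0.05,
                                     refine = TRUE,
                                     drop_residuals = TRUE) {
  Tn <- n_intervals(data)
  stats <- prep_pair_stats(data, Tn)
  comps <- parse_components(components)
  comp_str <- paste(comps, collapse = "")
  fit1 <- function(m, sd_off) suppressWarnings(
    fit_twin_model_stats(stats, m, n_starts = n_starts, seed = seed + sd_off))

  fits <- list()
  rows <- list()
  cf <- fit1(correlated_factors_model(Tn, comp_str), 0)
  fits[[cf$model$name]] <- cf
  rows[[1]] <- tibble(model = cf$model$name, stage = "reference",
                      minus2ll = cf$minus2ll, npar = cf$npar,
                      AIC = AIC(cf), chi2 = NA_real_, df = NA_integer_,
                      p = NA_real_, converged = cf$converged)
  for (i in seq_along(candidates)) {
    m <- twin_model_by_name(candidates[i], Tn, comp_str)
    f <- fit1(m, i)
    fits[[f$model$name]] <- f
    tst <- if (f$converged && cf$converged) lrt(cf, f) else
      tibble(chi2 = NA_real_, df = NA_integer_, p = NA_real_)
    rows[[length(rows) + 1]] <- tibble(
      model = f$model$name, stage = "candidate",
      minus2ll = f$minus2ll, npar = f$npar, AIC = AIC(f),
      chi2 = tst$chi2, df = tst$df, p = tst$p, converged = f$converged)
  }
  tab <- bind_rows(rows)

  cand <- filter(tab, .data$stage == "candidate")
  if (any(!cand$converged))
    warn(paste0("excluded non-converged candidates: ",
                paste(cand$model[!cand$converged], collapse = ", ")))
  cand <- filter(cand, .data$converged)
  ok <- filter(cand, .data$p > alpha)
  # parsimony filter among survivors: when one surviving candidate is
  # nested in another and the LRT between them is non-significant, the
  # more complex one adds nothing and leaves the race (the cp1 < {cp2, ip}
  # nestings are structural: proportional independent-pathway loadings
  # reproduce a common pathway exactly)
  nestings <- list(cp1 = c("cp2", "ip"))
  if (nrow(ok) > 1) {
    classes <- vapply(ok$model, function(nm) strsplit(nm, "-")[[1]][1], "")
    drop <- rep(FALSE, nrow(ok))
    for (i in seq_len(nrow(ok))) for (j in seq_len(nrow(ok))) {
      if (i == j || drop[i]) next
      if (classes[j] %in% (nestings[[classes[i]]] %||% character(0))) {
        pj <- tryCatch(lrt(fits[[ok$model[j]]], fits[[ok$model[i]]])$p,
                       error = function(e) 1)
        if (pj > alpha) drop[j] <- TRUE
      }
    }
    ok <- ok[!drop, ]
  }
  winner_name <- if (nrow(ok) > 0) {
    ok <- arrange(ok, .data$AIC, .data$npar)
    ok$model[1]
  } else if (nrow(cand) > 0 && cf$converged) {
    cf$model$name
  } else if (nrow(cand) > 0) {
    arrange(cand, .data$AIC, .data$npar)$model[1]
  } else {
    cf$model$name
  }
  winner <- fits[[winner_name]]
  winner_class <- strsplit(winner_name, "-")[[1]][1]

  # stage 3: whole-component drops within the winner class
  if (refine && winner_class != "cf" && length(comps) > 1) {
    subsets <- list()
    if (setequal(comps, c("A", "C", "E"))) subsets <- list("AE", "CE", "E")
    else if (setequal(comps, c("A", "E"))) subsets <- list("E")
    else if (setequal(comps, c("C", "E"))) subsets <- list("E")
    cand_rows <- list()
    for (k in seq_along(subsets)) {
      m <- twin_model_by_name(winner_class, Tn, subsets[[k]])
      f <- fit1(m, 100 + k)
      fits[[f$model$name]] <- f
      tst <- if (f$converged) lrt(winner, f) else
        tibble(chi2 = NA_real_, df = NA_integer_, p = NA_real_)
      cand_rows[[k]] <- tibble(
        model = f$model$name, stage = "components",
        minus2ll = f$minus2ll, npar = f$npar, AIC = AIC(f),
        chi2 = tst$chi2, df = tst$df, p = tst$p, converged = f$converged)
    }
    crows <- bind_rows(cand_rows)
    tab <- bind_rows(tab, crows)
    keep <- filter(crows, .data$converged, .data$p > alpha)
    pool <- bind_rows(
      tibble(model = winner_name, AIC = AIC(winner), npar = winner$npar),
      select(keep, "model", "AIC", "npar"))
    pool <- arrange(pool, .data$AIC, .data$npar)
    winner_name <- pool$model[1]
    winner <- fits[[winner_name]]
  }

  # stage 4: stepwise per-variable residual-A drops (factor models)
  if (refine && drop_residuals &&
      all(paste0("res_a", seq_len(Tn)) %in% winner$model$params$name) &&
      "A" %in% winner$model$components) {
    current <- winner
    dropped <- character(0)
    repeat {
      remaining <- setdiff(paste0("res_a", seq_len(Tn)), dropped)
      remaining <- remaining[vapply(remaining, function(nm)
        current$model$params$free[match(nm, current$model$params$name)], TRUE)]
      if (!length(remaining)) break
      trials <- lapply(remaining, function(nm) {
        m <- fix_parameters(current$model, nm, 0)
        m$name <- paste0(winner_name, " -", nm)
        f <- fit1(m, 200 + match(nm, remaining))
        list(nm = nm, fit = f, tst = if (f$converged) lrt(current, f) else
          tibble(chi2 = NA_real_, df = NA_integer_, p = NA_real_))
      })
      ps <- vapply(trials, function(t) t$tst$p %||% NA_real_, 0)
      for (t in trials) {
        tab <- bind_rows(tab, tibble(
          model = t$fit$model$name, stage = "residuals",
          minus2ll = t$fit$minus2ll, npar = t$fit$npar, AIC = AIC(t$fit),
          chi2 = t$tst$chi2, df = t$tst$df, p = t$tst$p,
          converged = t$fit$converged))
      }
      best_i <- which.max(ps)
      if (!length(best_i) || is.na(ps[best_i]) || ps[best_i] <= alpha) break
      current <- trials[[best_i]]$fit
      dropped <- c(dropped, trials[[best_i]]$nm)
      fits[[current$model$name]] <- current
      winner_name <- current$model$name
    }
    winner <- current
  }

  tab$selected <- tab$model == winner_name
  decomposition <- tryCatch(standardize(winner), error = function(e) NULL)
  correlations <- if (winner$model$T > 1)
    tryCatch(component_correlations(winner), error = function(e) NULL) else NULL

  structure(list(table = tab, fits = fits, selected = winner_name,
                 selected_fit = winner, decomposition = decomposition,
                 correlations = correlations,
                 options = list(components = comp_str, alpha = alpha,
                                n_starts = n_starts, seed = seed)),
            class = "twin_comparison")
}

#' @export
print.twin_comparison <- function(x, ...) {
  cat("Twin model comparison (selected: ", x$selected, ")\n\n", sep = "")
  print(as.data.frame(x$table), digits = 5)
  invisible(x)
}

fnv1a_hash <- function(obj) {
  bytes <- charToRaw(jsonlite::toJSON(obj, auto_unbox = TRUE, force = TRUE,
                                      digits = 10))
  h <- 2166136261
  for (b in as.integer(bytes)) {
    # xor only touches the low byte; bitwXor() cannot take values >= 2^31
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply split in 16-bit halves to stay exact in doubles
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  # h is a double (may exceed .Machine$integer.max); format in 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full twin-analysis pipeline from a config
#'
#' Executes simulate (optional) -> anchor -> residualize -> correlate ->
#' model comparison, writing every table (CSV), fit and report (JSON) and a
#' run log to the output directory. Every artifact is regenerable from the
#' config and seed alone; the config hash and seed are recorded in the
#' manifest and log.
#'
#' @param config A list, or path to a YAML/JSON config file. Recognized
#'   fields: `seed`; `out_dir`; `input` (path to a long CSV) or `simulate`
#'   (list with `model` = list(name, T, components, params), plus any
#'   [cohort_config()] fields); `covariates` (character vector of
#'   residualization terms); `components`; `n_starts`; `refine`.
#' @return Invisibly, a list with the key in-memory results (`long`,
#'   `wide`, `residualized`, `twin_correlations`, `comparison`) and the
#'   manifest of written files.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% "twinpath-run"
  if (!is.null(config$input) && !file.exists(config$input))
    abort(paste0("input file does not exist: ", config$input))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- fnv1a_hash(config[setdiff(names(config), "out_dir")])
  log_lines <- c(
    paste0("twinpath ", as.character(utils::packageVersion("twinpath"))),
    paste0("R ", R.version.string),
    paste0("seed: ", seed),
    paste0("config hash: ", cfg_hash),
    paste0("started: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  )
  written <- character(0)
  emit <- function(x, name, writer) {
    p <- file.path(out_dir, name)
    writer(x, p)
    written <<- c(written, name)
    p
  }

  # stage: data
  if (!is.null(config$input)) {
    long <- read_twin_long(config$input)
  } else {
    sim <- config$simulate %||% list()
    mspec <- sim$model %||% list(name = "cp1", T = 4, components = "AE")
    model <- twin_model_by_name(mspec$name %||% "cp1",
                                T = mspec$T %||% 4,
                                components = mspec$components %||% "AE")
    params <- if (!is.null(mspec$params)) unlist(mspec$params) else NULL
    cc_args <- sim[setdiff(names(sim), "model")]
    cc_args$seed <- seed
    cc <- do.call(cohort_config, cc_args)
    long <- simulate_cohort(cc, model, params)
    emit(long, "long.csv", write_twin_long)
    log_lines <- c(log_lines, paste0("simulated cohort under ", model$name,
                                     ": ", nrow(long), " records"))
  }

  # stage: preprocess
  wide <- age_anchor(long)
  rep <- anchor_report(wide)
  emit(wide, "wide.csv", write_twin_wide)
  emit(rep, "anchor_report.json", function(x, p)
    jsonlite::write_json(c(unclass(x), list(config_hash = cfg_hash)), p,
                         auto_unbox = TRUE))
  terms <- config$covariates %||% c("scanner", "age", "ethnicity", "cohort")
  resid <- residualize(wide, terms = terms)
  emit(resid, "residualized.csv", write_twin_wide)
  log_lines <- c(log_lines, paste0("anchored ", rep$n_pairs, " pairs; dropped ",
                                   rep$dropped_duplicates, " duplicate(s), ",
                                   rep$dropped_out_of_range, " out-of-range"))

  # stage: correlations
  twin_cors <- twin_correlation_table(resid)
  emit(twin_cors, "twin_correlations.csv", function(x, p) readr::write_csv(x, p))
  pheno_cors <- cross_interval_correlations(resid)
  emit(pheno_cors, "phenotypic_correlations.csv", function(x, p) readr::write_csv(x, p))

  # stage: model comparison
  cmp <- withCallingHandlers(
    model_selection_pipeline(resid,
                             components = config$components %||% "ACE",
                             n_starts = config$n_starts %||% 4,
                             seed = seed,
                             refine = config$refine %||% TRUE),
    warning = function(w) {
      log_lines <<- c(log_lines, paste0("warning: ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  emit(cmp$table, "comparison.csv", function(x, p) readr::write_csv(x, p))
  emit(cmp$selected_fit, "selected_fit.json", function(x, p) fit_to_json(x, p))
  if (!is.null(cmp$decomposition))
    emit(cmp$decomposition, "variance_decomposition.csv",
         function(x, p) readr::write_csv(x, p))
  if (!is.null(cmp$correlations)) {
    for (nm in names(cmp$correlations)) {
      emit(as.data.frame(cmp$correlations[[nm]]), paste0(nm, ".csv"),
           function(x, p) readr::write_csv(x, p))
    }
  }
  log_lines <- c(log_lines, paste0("selected model: ", cmp$selected))

  manifest <- list(config_hash = cfg_hash, seed = seed, files = written)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  writeLines(c(log_lines, paste0("finished: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
             file.path(out_dir, "run.log"))
  invisible(list(long = long, wide = wide, residualized = resid,
                 twin_correlations = twin_cors, phenotypic_correlations = pheno_cors,
                 comparison = cmp, manifest = manifest))
}
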