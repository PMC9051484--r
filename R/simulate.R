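#' Configure a synthetic twin cohort
#'
#' Describes the assessment schedule and nuisance structure of a
#' longitudinal twin cohort: three waves roughly 5.5-6 years apart with
#' overlapping age ranges (defaults mirror a mid-to-late-life male twin
#' registry assessed at mean ages 56.1, 61.8 and 67.5 with SD 2.6),
#' per-wave participation (attrition), scanner change after wave 1,
#' ethnicity composition, and a birth-year (cohort) gradient. The generator
#' produces exactly the irregular, covariate-contaminated long-format data
#' that [age_anchor()] and [residualize()] are designed to undo.
#'
#' @param n_mz_pairs,n_dz_pairs Complete MZ / DZ pair counts.
#' @param n_incomplete_pairs Pairs with one twin entirely absent (split
#'   evenly between zygosities).
#' @param waves Tibble with columns `mean`, `sd`, `min`, `max` (years), one
#'   row per assessment wave.
#' @param participation Per-wave participation probability in `[0, 1]`.
#'   Attrition is independent across twins and waves.
#' @param scanner_shift Phenotype shift for assessments on the later
#'   scanner (waves 2+), in phenotype units.
#' @param cohort_slope Phenotype change per birth year, units/year.
#' @param ethnicity_probs Named probabilities of ethnicity categories
#'   (shared within a pair).
#' @param ethnicity_shifts Named phenotype shifts per category.
#' @param birth_year_range Integer range of birth years.
#' @param seed Integer seed making the cohort reproducible.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_mz_pairs = 150,
                          n_dz_pairs = 150,
                          n_incomplete_pairs = 30,
                          waves = tibble(
                            mean = c(56.1, 61.8, 67.5),
                            sd = c(2.6, 2.6, 2.6),
                            min = c(51.1, 56.0, 61.4),
                            max = c(60.2, 65.9, 71.7)),
                          participation = c(1, 0.8, 0.65),
                          scanner_shift = 0.5,
                          cohort_slope = 0.05,
                          ethnicity_probs = c(nhw = 0.883, afam = 0.053,
                                              hisp = 0.034, other = 0.030),
                          ethnicity_shifts = c(nhw = 0, afam = 0.3,
                                               hisp = 0.2, other = 0.1),
                          birth_year_range = c(1943L, 1955L),
                          seed = 1L) {
  waves <- as_tibble(waves)
  if (nrow(waves) == 0) abort("at least one assessment wave is required")
  if (any(c(n_mz_pairs, n_dz_pairs, n_incomplete_pairs) < 0))
    abort("pair counts must be non-negative")
  if (length(participation) != nrow(waves))
    abort("participation must have one probability per wave")
  if (any(participation < 0 | participation > 1))
    abort("participation probabilities must lie in [0, 1]")
  if (!setequal(names(ethnicity_probs), names(ethnicity_shifts)))
    abort("ethnicity_probs and ethnicity_shifts must share names")
  structure(list(
    n_mz_pairs = as.integer(n_mz_pairs), n_dz_pairs = as.integer(n_dz_pairs),
    n_incomplete_pairs = as.integer(n_incomplete_pairs),
    waves = waves, participation = participation,
    scanner_shift = scanner_shift, cohort_slope = cohort_slope,
    ethnicity_probs = ethnicity_probs / sum(ethnicity_probs),
    ethnicity_shifts = ethnicity_shifts,
    birth_year_range = as.integer(birth_year_range), seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Simulate wide twin-pair data from a model
#'
#' Draws each pair's stacked 2T phenotype vector from the multivariate
#' normal implied by the model for its zygosity. This is the "clean" data
#' the FIML engine expects; [simulate_cohort()] wraps it in the messy
#' longitudinal schedule.
#'
#' @param model A [twin_model].
#' @param params Full named generating parameter vector (path scale);
#'   defaults to the model's start values.
#' @param n_mz,n_dz Number of MZ / DZ pairs.
#' @param seed Integer seed.
#' @return A wide tibble (`family_id`, `zygosity`, `t1_a`, ...).
#' @examples
#' simulate_wide(univariate_model("AE"), c(a = 0.8, e = 0.6, mu1 = 0),
#'               n_mz = 5, n_dz = 5, seed = 1)
#' @export
simulate_wide <- function(model, params = NULL, n_mz = 100, n_dz = 100, seed = 1) {
  im <- implied_moments(model, params)
  Tn <- model$T
  for (z in c("MZ", "DZ")) {
    S <- im[[paste0("Sigma_", z)]]
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      abort(paste0("implied pair covariance for the ", z,
                   " group is not positive semi-definite"))
  }
  draw <- function(n, S) {
    if (n == 0) return(matrix(0, 0, 2 * Tn))
    if (max(abs(S)) == 0) return(matrix(rep(im$mean, each = n), n, 2 * Tn))
    MASS::mvrnorm(n, mu = im$mean, Sigma = S, tol = 1e-7)
  }
  with_seed(seed, {
    Ymz <- draw(n_mz, im$Sigma_MZ)
    Ydz <- draw(n_dz, im$Sigma_DZ)
    Y <- rbind(Ymz, Ydz)
    if (n_mz + n_dz == 1) Y <- matrix(Y, 1)
    out <- tibble(
      family_id = sprintf("F%05d", seq_len(n_mz + n_dz)),
      zygosity = rep(c("MZ", "DZ"), c(n_mz, n_dz))
    )
    cols <- wide_value_cols(Tn)
    for (k in seq_along(cols)) out[[cols[k]]] <- Y[, k]
    out
  })
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' Simulate a longitudinal twin cohort
#'
#' Generates long-format assessment records under a generating genetic
#' model plus the cohort's nuisance structure. Latent interval-level twin
#' values are drawn via [simulate_wide()]; each subject's phenotype at a
#' wave is the latent value of the age interval containing that wave's age,
#' plus scanner, cohort (birth-year) and ethnicity effects. Twins in a pair
#' share birth year, ethnicity and assessment age; participation is
#' independent per subject and wave; incomplete pairs lack one twin
#' entirely. Two waves of one subject falling in the same interval produce
#' duplicate interval measurements, exercising the first-observation rule
#' in [age_anchor()].
#'
#' @param config A [cohort_config()].
#' @param model A [twin_model] (its `T` must cover the interval scheme).
#' @param params Generating parameter values (default: model start values).
#' @param scheme The [age_interval_scheme()] used to map ages to latent
#'   interval values.
#' @return A long tibble with columns `family_id`, `twin`, `zygosity`,
#'   `wave`, `age`, `birth_year`, `scanner`, `ethnicity`, `phenotype`.
#'   The latent wide table is attached as attribute `latent`.
#' @export
simulate_cohort <- function(config, model, params = NULL,
                            scheme = age_interval_scheme()) {
  stopifnot(inherits(config, "cohort_config"))
  if (model$T != nrow(scheme))
    abort("model T must equal the number of intervals in the scheme")
  n_inc_mz <- config$n_incomplete_pairs %/% 2
  n_inc_dz <- config$n_incomplete_pairs - n_inc_mz
  n_mz <- config$n_mz_pairs + n_inc_mz
  n_dz <- config$n_dz_pairs + n_inc_dz
  latent <- simulate_wide(model, params, n_mz, n_dz, seed = config$seed)

  with_seed(config$seed + 1L, {
    n_fam <- n_mz + n_dz
    # incomplete pairs: last families of each zygosity lose twin 2
    inc <- c(rep(FALSE, config$n_mz_pairs), rep(TRUE, n_inc_mz),
             rep(FALSE, config$n_dz_pairs), rep(TRUE, n_inc_dz))
    birth_year <- sample(seq(config$birth_year_range[1], config$birth_year_range[2]),
                         n_fam, replace = TRUE)
    eth <- sample(names(config$ethnicity_probs), n_fam, replace = TRUE,
                  prob = config$ethnicity_probs)
    by_center <- mean(config$birth_year_range)

    recs <- list()
    for (w in seq_len(nrow(config$waves))) {
      wv <- config$waves[w, ]
      age_w <- rtruncnorm1(n_fam, wv$mean, wv$sd, wv$min, wv$max)
      scanner <- if (w == 1) 0L else 1L
      for (tw in 1:2) {
        present <- runif(n_fam) < config$participation[w]
        present[inc & tw == 2] <- FALSE
        if (!any(present)) next
        fams <- which(present)
        iv <- assign_interval(age_w[fams], scheme)
        keep <- !is.na(iv)
        fams <- fams[keep]; iv <- iv[keep]
        if (!length(fams)) next
        col <- paste0("t", match(iv, scheme$label), "_", c("a", "b")[tw])
        lat <- vapply(seq_along(fams), function(k) latent[[col[k]]][fams[k]], 0)
        recs[[length(recs) + 1]] <- tibble(
          family_id = latent$family_id[fams],
          twin = tw,
          zygosity = latent$zygosity[fams],
          wave = w,
          age = age_w[fams],
          birth_year = birth_year[fams],
          scanner = scanner,
          ethnicity = eth[fams],
          phenotype = lat + config$scanner_shift * scanner +
            config$cohort_slope * (birth_year[fams] - by_center) +
            unname(config$ethnicity_shifts[eth[fams]])
        )
      }
    }
    long <- bind_rows(recs) %>% arrange(.data$family_id, .data$twin, .data$wave)
    attr(long, "latent") <- latent
    long
  })
}
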