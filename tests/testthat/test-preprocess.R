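toy_long <- function() {
  # family A: twin 1 assessed at 54, 59, 65 (three intervals);
  #           twin 2 assessed at 61.5 and 64.9 (same interval twice)
  # family B: one twin only, one wave
  tibble::tibble(
    family_id = c("A", "A", "A", "A", "A", "B"),
    twin = c(1, 1, 1, 2, 2, 1),
    zygosity = c("MZ", "MZ", "MZ", "MZ", "MZ", "DZ"),
    wave = c(1, 2, 3, 2, 3, 1),
    age = c(54, 59, 65, 61.5, 64.9, 57.2),
    phenotype = c(1, 2, 3, 10, 11, 5)
  )
}

test_that("PBAD is chronological age minus predicted brain age", {
  expect_equal(derive_pbad(pba = 65, age = 60), -5) # brain-age older
  expect_equal(derive_pbad(pba = 60, age = 60), 0)
  expect_equal(derive_pbad(pba = 55.5, age = 60.2), 4.7)
  expect_error(derive_pbad(NA, 60), "finite")
})

test_that("interval assignment uses completed years", {
  expect_equal(assign_interval(55.9), "51-55")
  expect_equal(assign_interval(56.0), "56-60")
  expect_equal(assign_interval(71.7), "66-72")
  expect_true(is.na(assign_interval(50.9)))
  expect_true(is.na(assign_interval(73.1)))
  expect_error(age_interval_scheme(data.frame(label = c("x", "y"),
                                              min = c(51, 54), max = c(55, 60))),
               "non-overlapping")
})

test_that("age anchoring assigns intervals, keeps first observations, tallies", {
  w <- age_anchor(toy_long())
  rep <- anchor_report(w)
  expect_equal(nrow(w), 2)
  a <- w[w$family_id == "A", ]
  expect_equal(unlist(a[, c("t1_a", "t2_a", "t3_a")]), c(t1_a = 1, t2_a = 2, t3_a = 3))
  expect_true(is.na(a$t4_a))
  # twin 2: both waves in 61-65; earliest wave (value 10) kept
  expect_equal(a$t3_b, 10)
  expect_equal(rep$dropped_duplicates, 1L)
  expect_equal(unname(rep$subjects_by_n_intervals),
               c(2L, 0L, 1L, 0L)) # B-twin + A-twin2 at one; A-twin1 at three
  # duplicate subject/wave is a data-integrity error
  bad <- toy_long(); bad$wave[2] <- 1
  expect_error(age_anchor(bad), "duplicate")
})

test_that("anchoring drops out-of-range records and handles empty input", {
  lg <- toy_long()
  lg$age[6] <- 49.5
  w <- age_anchor(lg)
  expect_equal(anchor_report(w)$dropped_out_of_range, 1L)
  expect_equal(nrow(w), 1) # family B vanishes entirely
  w0 <- age_anchor(toy_long()[0, ])
  expect_equal(nrow(w0), 0)
  expect_equal(anchor_report(w0)$dropped_duplicates, 0L)
})

test_that("age anchoring is idempotent on already-anchored data", {
  w <- age_anchor(toy_long())
  sch <- age_interval_scheme()
  # rebuild a long table whose ages sit at interval midpoints, one wave per interval
  rows <- list()
  for (j in 1:4) for (tw in 1:2) {
    v <- w[[paste0("t", j, c("_a", "_b")[tw])]]
    keep <- !is.na(v)
    if (!any(keep)) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      family_id = w$family_id[keep], twin = tw, zygosity = w$zygosity[keep],
      wave = j, age = (sch$min[j] + sch$max[j]) / 2, phenotype = v[keep])
  }
  relong <- dplyr::bind_rows(rows)
  w2 <- age_anchor(relong)
  cols <- c("family_id", "zygosity", paste0("t", 1:4, "_a"), paste0("t", 1:4, "_b"))
  expect_equal(as.data.frame(w2[order(w2$family_id), cols]),
               as.data.frame(w[order(w$family_id), cols]),
               ignore_attr = TRUE)
  expect_equal(anchor_report(w2)$dropped_duplicates, 0L)
})

test_that("residualization removes injected covariate effects to numerical precision", {
  gen <- common_pathway_model(4, 1, "AE")
  cc <- cohort_config(n_mz_pairs = 150, n_dz_pairs = 150, n_incomplete_pairs = 0,
                      participation = c(1, 1, 1),
                      scanner_shift = 1.2, cohort_slope = 0.15,
                      ethnicity_shifts = c(nhw = 0, afam = 0.8, hisp = 0.5, other = 0.3),
                      seed = 42)
  long <- simulate_cohort(cc, gen, cp1_gen_params())
  w <- age_anchor(long)
  r <- residualize(w, terms = c("scanner", "age", "ethnicity", "cohort"))
  cv <- anchor_covariates(w)
  # per interval, regressing residuals back on the covariates gives 0 slopes
  for (j in 1:4) {
    vals <- c(r[[paste0("t", j, "_a")]], r[[paste0("t", j, "_b")]])
    ids <- tibble::tibble(family_id = rep(r$family_id, 2),
                          twin = rep(1:2, each = nrow(r)), value = vals)
    dat <- dplyr::inner_join(ids[!is.na(ids$value), ],
                             cv[cv$interval == age_interval_scheme()$label[j], ],
                             by = c("family_id", "twin"))
    fit <- stats::lm(value ~ scanner + age + factor(ethnicity) + birth_year, data = dat)
    slopes <- coef(fit)[-1]
    slopes <- slopes[!is.na(slopes)]
    expect_lt(max(abs(slopes)), 1e-8)
  }
})

test_that("residualize degenerate cases: demeaning, constants, collinearity", {
  m <- univariate_model("AE")
  w <- simulate_wide(m, ae_gen_params(), 20, 20, seed = 2)
  r <- residualize(w, covariates = tibble::tibble(), terms = character(0))
  v <- c(w$t1_a, w$t1_b)
  expect_equal(c(r$t1_a, r$t1_b), v - mean(v), tolerance = 1e-12)
  # constant phenotype: residuals all zero
  wc <- w; wc$t1_a <- 2; wc$t1_b <- 2
  rc <- residualize(wc, covariates = tibble::tibble(), terms = character(0))
  expect_lt(max(abs(c(rc$t1_a, rc$t1_b))), 1e-12)
  # genuinely collinear (non-constant) terms error, naming the culprit
  by <- rep(c(1948, 1950, 1952), length.out = nrow(w) * 2)
  cv <- tibble::tibble(family_id = rep(w$family_id, 2),
                       twin = rep(1:2, each = nrow(w)),
                       interval = "51-55",
                       age = 2005 - by, scanner = 1, ethnicity = "nhw",
                       birth_year = by)
  expect_error(residualize(w, covariates = cv, terms = c("age", "cohort")),
               "collinear")
})

test_that("twin-pair correlation structure survives residualization without covariate effects", {
  gen <- univariate_model("AE")
  cc <- cohort_config(n_mz_pairs = 400, n_dz_pairs = 400, n_incomplete_pairs = 0,
                      waves = tibble::tibble(mean = 53, sd = 1, min = 51.1, max = 55.4),
                      participation = 1,
                      scanner_shift = 0, cohort_slope = 0,
                      ethnicity_shifts = c(nhw = 0, afam = 0, hisp = 0, other = 0),
                      seed = 7)
  long <- simulate_cohort(cc, gen, ae_gen_params(),
                          scheme = age_interval_scheme(
                            data.frame(label = "51-55", min = 51, max = 55)))
  w <- age_anchor(long, age_interval_scheme(data.frame(label = "51-55", min = 51, max = 55)))
  r <- residualize(w, terms = c("scanner", "age", "ethnicity", "cohort"))
  before <- twin_pair_correlation(w, 1, "MZ")$estimate
  after <- twin_pair_correlation(r, 1, "MZ")$estimate
  expect_lt(abs(before - after), 0.05)
})
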