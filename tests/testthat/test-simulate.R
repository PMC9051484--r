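test_that("simulated twin correlations match implied moments", {
  m <- univariate_model("AE")
  w <- simulate_wide(m, ae_gen_params(), 10000, 10000, seed = 1)
  rmz <- cor(w$t1_a[w$zygosity == "MZ"], w$t1_b[w$zygosity == "MZ"])
  rdz <- cor(w$t1_a[w$zygosity == "DZ"], w$t1_b[w$zygosity == "DZ"])
  # implied: a^2/(a^2+e^2) = 0.64 for MZ, half for DZ
  expect_equal(rmz, 0.64, tolerance = 0.03)
  expect_equal(rdz, 0.32, tolerance = 0.05)
  # A-only cross-twin covariance doubles from DZ to MZ
  cmz <- cov(w$t1_a[w$zygosity == "MZ"], w$t1_b[w$zygosity == "MZ"])
  cdz <- cov(w$t1_a[w$zygosity == "DZ"], w$t1_b[w$zygosity == "DZ"])
  expect_equal(cmz / cdz, 2, tolerance = 0.15)
})

test_that("empirical moments converge to implied moments", {
  m <- common_pathway_model(4, 1, "AE")
  p <- cp1_gen_params()
  w <- simulate_wide(m, p, 20000, 0, seed = 3)
  mo <- implied_moments(m, p)
  Y <- as.matrix(as.data.frame(w[, -(1:2)]))
  expect_lt(max(abs(cov(Y) - mo$Sigma_MZ)), 0.05)
  expect_lt(max(abs(colMeans(Y) - mo$mean)), 0.03)
})

test_that("degenerate and deterministic simulation", {
  m <- univariate_model("E")
  w <- simulate_wide(m, c(e = 0, mu1 = 1.5), 5, 5, seed = 1)
  expect_true(all(unlist(w[, c("t1_a", "t1_b")]) == 1.5))
  m2 <- univariate_model("AE")
  w1 <- simulate_wide(m2, ae_gen_params(), 50, 50, seed = 99)
  w2 <- simulate_wide(m2, ae_gen_params(), 50, 50, seed = 99)
  expect_identical(w1, w2)
  cc <- cohort_config(n_mz_pairs = 20, n_dz_pairs = 20, seed = 5)
  g <- common_pathway_model(4, 1, "AE")
  l1 <- simulate_cohort(cc, g, cp1_gen_params())
  l2 <- simulate_cohort(cc, g, cp1_gen_params())
  expect_identical(as.data.frame(l1), as.data.frame(l2))
})

test_that("non-PSD implied covariance errors name the zygosity group", {
  m <- correlated_factors_model(2, "AE")
  # negative DZ cross-twin eigenvalue cannot arise from the path build, so
  # force one via a handcrafted model
  bad <- m
  bad$moments <- function(p) list(mean = c(0, 0),
                                  SA = matrix(c(1, 2, 2, 1), 2),
                                  SC = matrix(0, 2, 2),
                                  SE = diag(0.01, 2))
  expect_error(simulate_wide(bad, NULL, 5, 5), "MZ|DZ")
})

test_that("cohort schedule: ages bin into the four intervals, wave gaps ~5.5y", {
  cc <- cohort_config(n_mz_pairs = 200, n_dz_pairs = 200, seed = 11)
  g <- common_pathway_model(4, 1, "AE")
  long <- simulate_cohort(cc, g, cp1_gen_params())
  iv <- assign_interval(long$age)
  expect_true(all(!is.na(iv)))
  expect_true(all(iv %in% age_interval_scheme()$label))
  m_by_wave <- tapply(long$age, long$wave, mean)
  expect_equal(as.vector(m_by_wave), c(56.1, 61.8, 67.5), tolerance = 0.3)
  # scanner switches after wave 1
  expect_true(all(long$scanner[long$wave == 1] == 0))
  expect_true(all(long$scanner[long$wave > 1] == 1))
  # twins share age, birth year and ethnicity at each wave
  pairs <- tidyr::pivot_wider(long[, c("family_id", "twin", "wave", "age")],
                              names_from = "twin", values_from = "age")
  both <- !is.na(pairs$`1`) & !is.na(pairs$`2`)
  expect_equal(pairs$`1`[both], pairs$`2`[both])
  # with only 3 waves nobody can cover 4 intervals
  w <- age_anchor(long)
  expect_equal(unname(anchor_report(w)$subjects_by_n_intervals["n4"]), 0L)
})

test_that("participation and incomplete pairs shape the record count", {
  cc0 <- cohort_config(n_mz_pairs = 50, n_dz_pairs = 50, n_incomplete_pairs = 10,
                       participation = c(1, 0, 0), seed = 3)
  g <- common_pathway_model(4, 1, "AE")
  long <- simulate_cohort(cc0, g, cp1_gen_params())
  cnt <- dplyr::count(long, long$family_id, long$twin)
  expect_true(all(cnt$n == 1)) # exactly one record per present subject
  # 10 incomplete pairs: twin 2 missing entirely in those families
  n_twin2 <- length(unique(long$family_id[long$twin == 2]))
  expect_equal(n_twin2, 100)
  expect_equal(length(unique(long$family_id)), 110)
  expect_error(cohort_config(participation = c(1, 2, 1)), "\\[0, 1\\]")
  expect_error(cohort_config(waves = tibble::tibble()), "wave")
})

test_that("anchoring the clean cohort recovers the latent wide table", {
  cc <- cohort_config(n_mz_pairs = 120, n_dz_pairs = 120, n_incomplete_pairs = 0,
                      participation = c(1, 1, 1), scanner_shift = 0,
                      cohort_slope = 0,
                      ethnicity_shifts = c(nhw = 0, afam = 0, hisp = 0, other = 0),
                      seed = 21)
  g <- common_pathway_model(4, 1, "AE")
  long <- simulate_cohort(cc, g, cp1_gen_params())
  latent <- attr(long, "latent")
  w <- age_anchor(long)
  w <- w[match(latent$family_id, w$family_id), ]
  for (cl in paste0("t", 1:4, c("_a"))) {
    obs <- !is.na(w[[cl]])
    expect_true(any(obs))
    expect_equal(w[[cl]][obs], latent[[cl]][match(w$family_id, latent$family_id)][obs],
                 tolerance = 1e-12)
  }
})

test_that("wide/long CSV round trips preserve values and missingness", {
  m <- correlated_factors_model(3, "AE")
  set.seed(8)
  w <- simulate_wide(m, random_params(m), 10, 10, seed = 8)
  w$t2_a[3] <- NA
  f <- tempfile(fileext = ".csv")
  write_twin_wide(w, f)
  w2 <- read_twin_wide(f)
  expect_equal(as.data.frame(w2), as.data.frame(w[, names(w2)]), tolerance = 1e-12)
  cc <- cohort_config(n_mz_pairs = 5, n_dz_pairs = 5, seed = 2)
  long <- simulate_cohort(cc, common_pathway_model(4, 1, "AE"), cp1_gen_params())
  f2 <- tempfile(fileext = ".csv")
  write_twin_long(long, f2)
  l2 <- read_twin_long(f2)
  expect_equal(as.data.frame(l2), as.data.frame(long), tolerance = 1e-10,
               ignore_attr = TRUE)
})
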