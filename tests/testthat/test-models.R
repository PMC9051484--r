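test_that("free-parameter counts match model structure", {
  expect_equal(sum(univariate_model("ACE")$params$free), 4)   # a, c, e, mu
  expect_equal(sum(univariate_model("AE")$params$free), 3)
  expect_equal(sum(correlated_factors_model(4, "AE")$params$free), 2 * 10 + 4)
  expect_equal(sum(autoregression_model(4, "AE")$params$free), 4 + 3 + 4 + 3 + 1 + 4)
  expect_equal(sum(autoregression_model(4, "AE", equal_residuals = FALSE)$params$free),
               4 + 3 + 4 + 3 + 4 + 4)
  expect_equal(sum(common_pathway_model(4, 1, "AE")$params$free), 1 + 4 + 8 + 4)
  expect_equal(sum(independent_pathway_model(4, "AE")$params$free), 8 + 8 + 4)
  # AE is nested in ACE with one fewer free parameter
  expect_equal(sum(univariate_model("ACE")$params$free) -
               sum(univariate_model("AE")$params$free), 1)
  # 2-factor CP nests the 1-factor model (extra factor + T-1 loadings)
  expect_gt(sum(common_pathway_model(4, 2, "AE")$params$free),
            sum(common_pathway_model(4, 1, "AE")$params$free))
})

test_that("models without E are rejected, unknown zygosity errors", {
  expect_error(univariate_model("AC"), "E")
  expect_error(common_pathway_model(4, 1, "A"), "E")
  expect_error(pair_covariance(univariate_model("AE"), zygosity = "XZ"),
               "zygosity")
})

test_that("cross-twin structural constants: rA = 0.5 (DZ), rC = 1, rE = 0", {
  m <- univariate_model("AE")
  p <- c(a = 0.8, e = 0.6, mu1 = 0)
  mz <- pair_covariance(m, p, "MZ")
  dz <- pair_covariance(m, p, "DZ")
  expect_equal(dz[1, 2] / mz[1, 2], 0.5)
  # any nonzero additive path gives the same ratio
  p2 <- c(a = 0.31, e = 1.2, mu1 = 3)
  expect_equal(pair_covariance(m, p2, "DZ")[1, 2] /
               pair_covariance(m, p2, "MZ")[1, 2], 0.5)
  # C-only (plus floor E): MZ and DZ pair covariances identical
  mce <- univariate_model("CE")
  pce <- c(c = 0.7, e = 0.5, mu1 = 0)
  expect_equal(pair_covariance(mce, pce, "MZ"), pair_covariance(mce, pce, "DZ"))
  # E-only: cross-twin block is zero
  me <- univariate_model("E")
  pe <- c(e = 0.9, mu1 = 0)
  expect_equal(pair_covariance(me, pe, "MZ")[1, 2], 0)
  expect_equal(pair_covariance(me, pe, "DZ")[1, 2], 0)
  # ACE with a > 0 implies rMZ > rDZ
  mace <- univariate_model("ACE")
  pace <- c(a = 0.5, c = 0.4, e = 0.6, mu1 = 0)
  smz <- pair_covariance(mace, pace, "MZ")
  sdz <- pair_covariance(mace, pace, "DZ")
  expect_gt(smz[1, 2] / smz[1, 1], sdz[1, 2] / sdz[1, 1])
})

test_that("implied pair covariances equal the path-enumeration oracle", {
  set.seed(42)
  cases <- list(
    list(build = function() univariate_model("ACE"),
         ram = function(p, zyg) ram_univariate(p, c("A", "C", "E"), zyg)),
    list(build = function() correlated_factors_model(3, "AE"),
         ram = function(p, zyg) ram_cf(p, 3, c("A", "E"), zyg)),
    list(build = function() correlated_factors_model(4, "ACE"),
         ram = function(p, zyg) ram_cf(p, 4, c("A", "C", "E"), zyg)),
    list(build = function() autoregression_model(3, "AE"),
         ram = function(p, zyg) ram_ar(p, 3, c("A", "E"), zyg)),
    list(build = function() autoregression_model(4, "ACE"),
         ram = function(p, zyg) ram_ar(p, 4, c("A", "C", "E"), zyg)),
    list(build = function() common_pathway_model(4, 1, "AE"),
         ram = function(p, zyg) ram_cp(p, 4, 1, c("A", "E"), zyg)),
    list(build = function() common_pathway_model(4, 2, "ACE"),
         ram = function(p, zyg) ram_cp(p, 4, 2, c("A", "C", "E"), zyg)),
    list(build = function() independent_pathway_model(4, "AE"),
         ram = function(p, zyg) ram_ip(p, 4, c("A", "E"), zyg)),
    list(build = function() independent_pathway_model(3, "ACE"),
         ram = function(p, zyg) ram_ip(p, 3, c("A", "C", "E"), zyg))
  )
  for (cs in cases) {
    model <- cs$build()
    for (rep in 1:3) {
      p <- random_params(model)
      for (zyg in c("MZ", "DZ")) {
        got <- pair_covariance(model, p, zyg)
        want <- oracle_pair_cov(cs$ram(as.list(p), zyg))
        expect_equal(got, unname(want), tolerance = 1e-10,
                     label = paste(model$name, zyg))
      }
    }
  }
})

test_that("autoregression limiting cases", {
  m <- autoregression_model(3, "AE")
  p <- c(a_innov1 = 0.7, a_innov2 = 0.5, a_innov3 = 0.5,
         a_beta2 = 0, a_beta3 = 0,
         e_innov1 = 0.6, e_innov2 = 0.4, e_innov3 = 0.4,
         e_beta2 = 0, e_beta3 = 0,
         res_e = 0.3,
         mu1 = 0, mu2 = 0, mu3 = 0)
  W <- pair_covariance(m, p, "MZ")[1:3, 1:3]
  expect_equal(W[upper.tri(W)], rep(0, 3)) # severed chain: no cross-interval cov
  # perfect transmission: beta = 1, innovations only at t = 1, no residuals
  p2 <- p
  p2[c("a_innov2", "a_innov3", "e_innov2", "e_innov3")] <- 0
  p2[c("a_beta2", "a_beta3", "e_beta2", "e_beta3")] <- 1
  p2["res_e"] <- 0
  W2 <- pair_covariance(m, p2, "MZ")[1:3, 1:3]
  expect_equal(stats::cov2cor(W2), matrix(1, 3, 3))
})

test_that("common pathway limiting cases and factor-share algebra", {
  m <- common_pathway_model(4, 1, "AE")
  p <- cp1_gen_params()
  # zero genetic residuals: all genetic correlations are 1
  p0 <- p; p0[paste0("res_a", 1:4)] <- 0
  mo <- implied_moments(m, p0)
  rg <- stats::cov2cor(mo$SA)
  expect_equal(rg, matrix(1, 4, 4), tolerance = 1e-12)
  # equal loadings, no residuals: compound-symmetric implied covariance
  pc <- p; pc[paste0("res_a", 1:4)] <- 0; pc[paste0("res_e", 1:4)] <- 0
  W <- pair_covariance(m, pc, "MZ")[1:4, 1:4]
  expect_equal(length(unique(round(W[upper.tri(W)], 12))), 1)
  expect_equal(length(unique(round(diag(W), 12))), 1)
  # per-variable total A = loading^2 * factor-A + residual A
  mo2 <- implied_moments(m, p)
  expect_equal(diag(mo2$SA),
               p[paste0("load1_", 1:4)]^2 * p[["fac_a1"]]^2 +
                 p[paste0("res_a", 1:4)]^2,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("independent pathway reduces to common pathway under proportional loadings", {
  ip <- independent_pathway_model(4, "AE")
  fa <- 0.86; fe <- sqrt(1 - fa^2); lam <- c(0.8, 0.7, 0.9, 0.6)
  pip <- c(setNames(fa * lam, paste0("lam_a", 1:4)),
           setNames(fe * lam, paste0("lam_e", 1:4)),
           setNames(rep(0.3, 4), paste0("res_a", 1:4)),
           setNames(rep(0.45, 4), paste0("res_e", 1:4)),
           mu1 = 0, mu2 = 0, mu3 = 0, mu4 = 0)
  cp <- common_pathway_model(4, 1, "AE")
  pcp <- c(fac_a1 = fa, setNames(lam, paste0("load1_", 1:4)),
           setNames(rep(0.3, 4), paste0("res_a", 1:4)),
           setNames(rep(0.45, 4), paste0("res_e", 1:4)),
           mu1 = 0, mu2 = 0, mu3 = 0, mu4 = 0)
  for (zyg in c("MZ", "DZ"))
    expect_equal(pair_covariance(ip, pip, zyg), pair_covariance(cp, pcp, zyg),
                 tolerance = 1e-12)
  # lam_e all zero: E covariance is diagonal
  pe0 <- pip; pe0[paste0("lam_e", 1:4)] <- 0
  moE <- implied_moments(ip, pe0)$SE
  expect_equal(moE, diag(diag(moE)), tolerance = 1e-14)
})

test_that("component correlations follow the implied-moment algebra", {
  # diagonal-only Cholesky: independent variables, rG = identity
  m <- correlated_factors_model(3, "AE")
  p <- numeric(nrow(m$params)); names(p) <- m$params$name
  p[paste0("a", 1:3, 1:3)] <- 0.8
  p[paste0("e", 1:3, 1:3)] <- 0.6
  mo <- implied_moments(m, p)
  expect_equal(stats::cov2cor(mo$SA), diag(3))
  expect_equal(mo$SA[1, 2], 0)
})

test_that("fix_parameters freezes values and rejects unknown names", {
  m <- univariate_model("ACE")
  m2 <- fix_parameters(m, "c", 0)
  expect_equal(sum(m2$params$free), sum(m$params$free) - 1)
  expect_equal(m2$params$value[m2$params$name == "c"], 0)
  expect_error(fix_parameters(m, "nope"), "unknown")
})
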