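# Shared generating parameter vectors and small builders.

cp1_gen_params <- function() {
  c(fac_a1 = 0.86, load1_1 = 0.8, load1_2 = 0.8, load1_3 = 0.8, load1_4 = 0.8,
    res_a1 = 0.3, res_a2 = 0.3, res_a3 = 0.3, res_a4 = 0.3,
    res_e1 = 0.45, res_e2 = 0.45, res_e3 = 0.45, res_e4 = 0.45,
    mu1 = 0, mu2 = 0, mu3 = 0, mu4 = 0)
}

ar_gen_params <- function() {
  c(a_innov1 = 0.8, a_innov2 = 0.4, a_innov3 = 0.4, a_innov4 = 0.4,
    a_beta2 = 0.9, a_beta3 = 0.9, a_beta4 = 0.9,
    e_innov1 = 0.6, e_innov2 = 0.45, e_innov3 = 0.45, e_innov4 = 0.45,
    e_beta2 = 0.5, e_beta3 = 0.5, e_beta4 = 0.5,
    res_e = 0.35,
    mu1 = 0, mu2 = 0, mu3 = 0, mu4 = 0)
}

ae_gen_params <- function() c(a = 0.8, e = 0.6, mu1 = 0)

# random admissible parameter vector for a model (seeded by caller)
random_params <- function(model) {
  p <- numeric(nrow(model$params))
  names(p) <- model$params$name
  for (i in seq_len(nrow(model$params))) {
    nm <- model$params$name[i]
    lo <- model$params$lower[i]
    if (grepl("^mu", nm)) p[i] <- rnorm(1, 0, 0.5)
    else if (grepl("_beta", nm)) p[i] <- runif(1, -0.9, 0.9)
    else if (grepl("^fac_", nm)) p[i] <- runif(1, 0.2, 0.65)
    else if (lo == 0) p[i] <- runif(1, 0.2, 0.9)
    else p[i] <- runif(1, -0.6, 0.9)
  }
  p
}
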