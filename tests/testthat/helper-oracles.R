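# Independent oracles used across tests.
#
# (1) fiml_naive(): per-pair multivariate normal density computed directly
#     with solve()/det() — no sufficient statistics, no pattern grouping.
# (2) A path-enumeration oracle: models are written down as explicit
#     structural graphs (directed edges from exogenous latents to observed
#     variables); covariances are obtained by brute-force enumeration of
#     directed paths (Wright's tracing rules for linear systems), not by
#     the package's component-block algebra.

fiml_naive <- function(wide, model, params) {
  Tn <- model$T
  cols <- c(paste0("t", 1:Tn, "_a"), paste0("t", 1:Tn, "_b"))
  Y <- as.matrix(as.data.frame(wide[, cols]))
  mo <- model$moments(as.list(params[model$params$name]))
  mean2 <- rep(mo$mean, 2)
  W <- mo$SA + mo$SC + mo$SE
  Sig <- list(MZ = rbind(cbind(W, mo$SA + mo$SC), cbind(mo$SA + mo$SC, W)),
              DZ = rbind(cbind(W, 0.5 * mo$SA + mo$SC), cbind(0.5 * mo$SA + mo$SC, W)))
  tot <- 0
  for (i in seq_len(nrow(Y))) {
    o <- which(!is.na(Y[i, ]))
    if (!length(o)) next
    S <- Sig[[toupper(wide$zygosity[i])]][o, o, drop = FALSE]
    d <- Y[i, o] - mean2[o]
    tot <- tot - 2 * (-0.5 * length(o) * log(2 * pi) -
                      0.5 * determinant(S, logarithm = TRUE)$modulus -
                      0.5 * drop(t(d) %*% solve(S) %*% d))
  }
  as.numeric(tot)
}

# --- structural-graph oracle -------------------------------------------

# graph: list(exog = names, S = exog covariance, edges = data.frame(from,
# to, w), observed = names). total effect of exogenous on observed by
# recursive enumeration of directed paths.
path_total_effect <- function(g, from, to) {
  if (from == to) return(1)
  out <- g$edges[g$edges$from == from, , drop = FALSE]
  if (nrow(out) == 0) return(0)
  s <- 0
  for (k in seq_len(nrow(out)))
    s <- s + out$w[k] * path_total_effect(g, out$to[k], to)
  s
}

oracle_pair_cov <- function(g) {
  nE <- length(g$exog); nO <- length(g$observed)
  Tt <- matrix(0, nE, nO, dimnames = list(g$exog, g$observed))
  for (e in g$exog) for (o in g$observed)
    Tt[e, o] <- path_total_effect(g, e, o)
  t(Tt) %*% g$S %*% Tt
}

edge <- function(from, to, w) data.frame(from = from, to = to, w = w)

# cross-twin exogenous covariance by component kind
exog_block <- function(names1, names2, rA, kind) {
  # kind: "A" (cross rA), "C" (cross 1), "E"/"U" (cross 0)
  r <- switch(kind, A = rA, C = 1, 0)
  list(r = r)
}

# assemble S for exogenous variables given per-exog kind labels; exogenous
# come in twin1/twin2 copies with within-twin identity covariance
build_exog_S <- function(kinds, rA) {
  # kinds: named character vector, names like "A_f.1" (suffix .1/.2 twin)
  n <- length(kinds)
  nm <- names(kinds)
  S <- diag(1, n); dimnames(S) <- list(nm, nm)
  base <- sub("\\.[12]$", "", nm)
  twin <- sub("^.*\\.", "", nm)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (base[i] == base[j] && twin[i] != twin[j]) {
      S[i, j] <- switch(kinds[i], A = rA, C = 1, 0)
    }
  }
  S
}

ram_univariate <- function(p, comps, zyg) {
  rA <- if (zyg == "MZ") 1 else 0.5
  kinds <- c()
  edges <- NULL
  for (tw in 1:2) {
    obs <- paste0("P.", tw)
    if ("A" %in% comps) {
      kinds[paste0("LA.", tw)] <- "A"
      edges <- rbind(edges, edge(paste0("LA.", tw), obs, p[["a"]]))
    }
    if ("C" %in% comps) {
      kinds[paste0("LC.", tw)] <- "C"
      edges <- rbind(edges, edge(paste0("LC.", tw), obs, p[["c"]]))
    }
    kinds[paste0("LE.", tw)] <- "E"
    edges <- rbind(edges, edge(paste0("LE.", tw), obs, p[["e"]]))
  }
  list(exog = names(kinds), S = build_exog_S(kinds, rA), edges = edges,
       observed = paste0("P.", 1:2))
}

ram_cf <- function(p, Tn, comps, zyg) {
  rA <- if (zyg == "MZ") 1 else 0.5
  kinds <- c(); edges <- NULL
  for (tw in 1:2) {
    for (cm in comps) {
      letter <- tolower(cm)
      for (j in seq_len(Tn)) {
        lat <- paste0("L", cm, j, ".", tw)
        kinds[lat] <- cm
        for (i in j:Tn)
          edges <- rbind(edges, edge(lat, paste0("P", i, ".", tw),
                                     p[[paste0(letter, i, j)]]))
      }
    }
  }
  list(exog = names(kinds), S = build_exog_S(kinds, rA), edges = edges,
       observed = paste0("P", rep(1:Tn, 2), ".", rep(1:2, each = Tn)))
}

ram_ar <- function(p, Tn, comps, zyg) {
  rA <- if (zyg == "MZ") 1 else 0.5
  kinds <- c(); edges <- NULL
  for (tw in 1:2) {
    for (cm in comps) {
      letter <- tolower(cm)
      for (t in seq_len(Tn)) {
        z <- paste0("Z", cm, t, ".", tw)    # innovation
        x <- paste0("X", cm, t, ".", tw)    # latent true score
        kinds[z] <- cm
        edges <- rbind(edges, edge(z, x, p[[paste0(letter, "_innov", t)]]))
        if (t > 1)
          edges <- rbind(edges, edge(paste0("X", cm, t - 1, ".", tw), x,
                                     p[[paste0(letter, "_beta", t)]]))
        edges <- rbind(edges, edge(x, paste0("P", t, ".", tw), 1))
      }
    }
    for (t in seq_len(Tn)) {
      u <- paste0("U", t, ".", tw)
      kinds[u] <- "E"
      rw <- if (!is.null(p[["res_e"]])) p[["res_e"]] else p[[paste0("res_e", t)]]
      edges <- rbind(edges, edge(u, paste0("P", t, ".", tw), rw))
    }
  }
  list(exog = names(kinds), S = build_exog_S(kinds, rA), edges = edges,
       observed = paste0("P", rep(1:Tn, 2), ".", rep(1:2, each = Tn)))
}

ram_cp <- function(p, Tn, n_factors, comps, zyg) {
  rA <- if (zyg == "MZ") 1 else 0.5
  kinds <- c(); edges <- NULL
  for (tw in 1:2) {
    for (m in seq_len(n_factors)) {
      fa <- if ("A" %in% comps) p[[paste0("fac_a", m)]] else 0
      fc <- if ("C" %in% comps) p[[paste0("fac_c", m)]] else 0
      fe <- sqrt(1 - fa^2 - fc^2)
      fac <- paste0("F", m, ".", tw)
      if ("A" %in% comps) {
        kinds[paste0("FA", m, ".", tw)] <- "A"
        edges <- rbind(edges, edge(paste0("FA", m, ".", tw), fac, fa))
      }
      if ("C" %in% comps) {
        kinds[paste0("FC", m, ".", tw)] <- "C"
        edges <- rbind(edges, edge(paste0("FC", m, ".", tw), fac, fc))
      }
      kinds[paste0("FE", m, ".", tw)] <- "E"
      edges <- rbind(edges, edge(paste0("FE", m, ".", tw), fac, fe))
      jj <- if (m == 1) seq_len(Tn) else 2:Tn
      for (j in jj)
        edges <- rbind(edges, edge(fac, paste0("P", j, ".", tw),
                                   p[[paste0("load", m, "_", j)]]))
    }
    for (cm in comps) {
      letter <- tolower(cm)
      for (j in seq_len(Tn)) {
        r <- paste0("R", cm, j, ".", tw)
        kinds[r] <- cm
        edges <- rbind(edges, edge(r, paste0("P", j, ".", tw),
                                   p[[paste0("res_", letter, j)]]))
      }
    }
  }
  list(exog = names(kinds), S = build_exog_S(kinds, rA), edges = edges,
       observed = paste0("P", rep(1:Tn, 2), ".", rep(1:2, each = Tn)))
}

ram_ip <- function(p, Tn, comps, zyg) {
  rA <- if (zyg == "MZ") 1 else 0.5
  kinds <- c(); edges <- NULL
  for (tw in 1:2) {
    for (cm in comps) {
      letter <- tolower(cm)
      fac <- paste0("G", cm, ".", tw)
      kinds[fac] <- cm
      for (j in seq_len(Tn))
        edges <- rbind(edges, edge(fac, paste0("P", j, ".", tw),
                                   p[[paste0("lam_", letter, j)]]))
      for (j in seq_len(Tn)) {
        r <- paste0("R", cm, j, ".", tw)
        kinds[r] <- cm
        edges <- rbind(edges, edge(r, paste0("P", j, ".", tw),
                                   p[[paste0("res_", letter, j)]]))
      }
    }
  }
  list(exog = names(kinds), S = build_exog_S(kinds, rA), edges = edges,
       observed = paste0("P", rep(1:Tn, 2), ".", rep(1:2, each = Tn)))
}
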