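# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's transfer-matrix / run-scanning code paths.

# Grand-canonical partition function and occupancies by exhaustive summation
# over all 3^M occupancy states (periodic closure).
enum_ensemble <- function(s, gamma, params) {
  M <- length(s)
  states <- as.matrix(expand.grid(rep(list(0:2), M)))
  E <- apply(states, 1, function(sig) {
    e <- sum(binding_free_energy(s, sig, params))
    for (i in seq_len(M)) {
      j <- if (i == M) 1L else i + 1L
      e <- e + interaction_free_energy(sig[i], sig[j], gamma[i], params)
    }
    e
  })
  shift <- min(E)
  w <- exp(-(E - shift))
  log_xi <- log(sum(w)) - shift
  occ <- colSums(states * w) / sum(w)
  list(log_xi = log_xi, Phi = -log_xi, occupancy = unname(occ))
}

# Exact marginal over short-linker indicator patterns: P(gamma) is
# proportional to Xi(gamma) * A^(#short) * B^(#long), where A and B are the
# geometric masses of the two linker-length branches.
enum_gamma_marginal <- function(s, params, link) {
  M <- length(s)
  gammas <- as.matrix(expand.grid(rep(list(0:1), M)))
  z <- link$z
  lc <- link$l_c
  A <- z * (1 - z^lc) / (1 - z)
  B <- z^(lc + 1) / (1 - z)
  logw <- apply(gammas, 1, function(g) {
    enum_ensemble(s, as.integer(g), params)$log_xi +
      sum(g) * log(A) + (M - sum(g)) * log(B)
  })
  w <- exp(logw - max(logw))
  list(gammas = gammas, p = w / sum(w))
}

# Brute-force cluster scanner: checks every window of consecutive
# nucleosomes for the defining property directly.
scan_clusters <- function(lens, l_c, min_size) {
  n_nuc <- length(lens) + 1L
  short <- lens <= l_c
  out <- list()
  i <- 1L
  while (i <= n_nuc) {
    j <- i
    while (j < n_nuc && short[j]) j <- j + 1L
    if (j - i + 1L >= min_size) {
      out[[length(out) + 1L]] <- i:j
    }
    i <- j + 1L
  }
  out
}

# Independent evaluation of the virtual-bond quadratic form, written against
# the model definition rather than sharing code with elastic_energy().
reference_bond_energy <- function(pos_a, tri_a, pos_b, tri_b, l_bp, geom,
                                  lp = 50, lt = 100, L1 = 0.332,
                                  tau = 2 * pi / 10.5, stretch_scale = 90) {
  Qa <- matrix(tri_a, 3, 3, byrow = TRUE)
  Qb <- matrix(tri_b, 3, 3, byrow = TRUE)
  p_out <- pos_a + as.numeric(Qa %*% geom$translation)
  F_out <- Qa %*% geom$rotation
  r <- pos_b - p_out
  L <- l_bp * L1
  rn <- sqrt(sum(r^2))
  u <- r / rn
  ang <- function(v, w) {
    acos(max(-1, min(1, sum(v * w) / sqrt(sum(v^2) * sum(w^2)))))
  }
  th1 <- ang(F_out[, 3], u)
  th2 <- ang(u, Qb[, 3])
  Mr <- t(F_out) %*% Qb
  tw <- atan2(Mr[2, 1] - Mr[1, 2], Mr[1, 1] + Mr[2, 2])
  dev <- tw - tau * l_bp
  dev <- atan2(sin(dev), cos(dev))
  ks <- stretch_scale * lp^2 / L^4
  unname(lp / (2 * L) * (th1^2 + th2^2) + lt / (2 * L) * dev^2 +
           ks / 2 * (rn - L)^2)
}

random_binding_params <- function() {
  binding_params(eps_m = runif(1, -3, 0), J_int = runif(1, -5, 0),
                 mu_hp1 = runif(1, -11, -5), l_c = 15)
}
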