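#' Thermodynamic constants of the HP1 binding model
#'
#' All energies are in units of kBT (beta = 1 internally). The chemical
#' potential relates to the free HP1 concentration via mu = log\[HP1\]_free,
#' but the concentration itself never enters any computation.
#'
#' @param eps_m energetic preference of HP1 for a marked tail (kBT).
#' @param J_int HP1--HP1 oligomerization energy (kBT); applied both between
#'   the two HP1s on a doubly occupied nucleosome and between HP1s bound to
#'   adjacent nucleosomes joined by a short linker.
#' @param mu_hp1 HP1 chemical potential (kBT).
#' @param l_c linker-length cutoff (bp) below which bound HP1s on adjacent
#'   nucleosomes can interact.
#' @return object of class `binding_params`.
#' @export
binding_params <- function(eps_m = -1.5, J_int = -3.92, mu_hp1 = -9.7,
                           l_c = 15) {
  stop_if_not_scalar(eps_m, "eps_m")
  stop_if_not_scalar(J_int, "J_int")
  stop_if_not_scalar(mu_hp1, "mu_hp1")
  stop_if_not_scalar(l_c, "l_c")
  if (l_c < 1) stop("'l_c' must be at least 1 bp")
  structure(list(eps_m = eps_m, J_int = J_int, mu_hp1 = mu_hp1,
                 l_c = as.integer(l_c)),
            class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  cat(sprintf(
    "HP1 binding parameters: eps_m = %g kBT, J_int = %g kBT, mu = %g kBT, l_c = %d bp\n",
    x$eps_m, x$J_int, x$mu_hp1, x$l_c))
  invisible(x)
}

check_state <- function(x, name, max) {
  if (any(is.na(x)) || any(x != as.integer(x)) || any(x < 0 | x > max)) {
    stop(sprintf("'%s' must contain integers in {0..%d}", name, max))
  }
  as.integer(x)
}

#' Single-nucleosome HP1 binding free energy
#'
#' The five-branch free energy (kBT) of a nucleosome with `s` marked tails and
#' `sigma` bound HP1s: 0 for sigma = 0; -mu - log 2 for (1, s = 0);
#' -mu - log(1 + exp(-eps_m)) for (1, s = 1); -mu + eps_m - log 2 for
#' (1, s = 2); and -2 mu + s eps_m + J_int for sigma = 2, where the J_int term
#' accounts for the interaction of the two HP1s sharing the nucleosome.
#'
#' @param s marked-tail count(s) in \{0, 1, 2\} (vectorized).
#' @param sigma bound-HP1 count(s) in \{0, 1, 2\} (vectorized).
#' @param params a [binding_params()] object.
#' @return free energy in kBT (vectorized).
#' @export
binding_free_energy <- function(s, sigma, params = binding_params()) {
  s <- check_state(s, "s", 2L)
  sigma <- check_state(sigma, "sigma", 2L)
  n <- max(length(s), length(sigma))
  s <- rep_len(s, n)
  sigma <- rep_len(sigma, n)
  mu <- params$mu_hp1
  eps <- params$eps_m
  out <- numeric(n)
  i1 <- sigma == 1L
  out[i1 & s == 0L] <- -mu - log(2)
  out[i1 & s == 1L] <- -mu - log(1 + exp(-eps))
  out[i1 & s == 2L] <- -mu + eps - log(2)
  i2 <- sigma == 2L
  out[i2] <- -2 * mu + s[i2] * eps + params$J_int
  out
}

#' Inter-nucleosome HP1--HP1 interaction free energy
#'
#' @param sigma_i,sigma_ip1 bound-HP1 counts on adjacent nucleosomes.
#' @param gamma_i 1 if the connecting linker is within the cutoff, else 0.
#' @param params a [binding_params()] object.
#' @return `J_int * gamma_i * sigma_i * sigma_ip1` in kBT (vectorized).
#' @export
interaction_free_energy <- function(sigma_i, sigma_ip1, gamma_i,
                                    params = binding_params()) {
  sigma_i <- check_state(sigma_i, "sigma_i", 2L)
  sigma_ip1 <- check_state(sigma_ip1, "sigma_ip1", 2L)
  gamma_i <- check_state(gamma_i, "gamma_i", 1L)
  params$J_int * gamma_i * sigma_i * sigma_ip1
}

#' Transfer matrix of one nucleosome bond
#'
#' Entry (sigma_i, sigma_ip1) is
#' exp(-phi_bind(sigma_i)/2 - phi_bind(sigma_ip1)/2 - phi_int(sigma_i,
#' sigma_ip1)); splitting each site's binding free energy over its two bonds
#' makes the trace of the matrix product equal the grand-canonical partition
#' function under periodic closure.
#'
#' @param s_i,s_ip1 marked-tail counts of the bonded nucleosomes.
#' @param gamma_i short-linker indicator of the bond.
#' @param params a [binding_params()] object.
#' @return a 3x3 matrix with strictly positive entries, dimnames "0".."2".
#' @export
transfer_matrix <- function(s_i, s_ip1, gamma_i, params = binding_params()) {
  s_i <- check_state(s_i, "s_i", 2L)
  s_ip1 <- check_state(s_ip1, "s_ip1", 2L)
  gamma_i <- check_state(gamma_i, "gamma_i", 1L)
  sig <- 0:2
  half_i <- binding_free_energy(s_i, sig, params) / 2
  half_j <- binding_free_energy(s_ip1, sig, params) / 2
  Tm <- outer(sig, sig, function(a, b) {
    exp(-half_i[a + 1] - half_j[b + 1] -
          params$J_int * gamma_i * a * b)
  })
  dimnames(Tm) <- list(sigma_i = 0:2, sigma_ip1 = 0:2)
  Tm
}

#' Grand-canonical evaluation of HP1 binding on a nucleosome array
#'
#' Computes the log partition function log(Xi), total binding free energy
#' Phi = -log(Xi) (kBT), and per-site mean occupancies by the transfer-matrix
#' method with periodic closure (sigma_\{M+1\} = sigma_1). The running matrix
#' products are rescaled to unit max-norm after every multiplication, so
#' under/overflow cannot occur at any array length; occupancies use cached
#' prefix/suffix products, giving all M sites in O(M) matrix multiplies.
#'
#' @param pattern an `epigenetic_pattern` or integer vector of mark counts.
#' @param gamma integer vector of short-linker indicators, one per nucleosome
#'   (`gamma[M]` closes the ring, coupling nucleosome M to nucleosome 1).
#' @param params a [binding_params()] object.
#' @return object of class `binding_summary`: list with `log_xi`, `Phi`, and
#'   `occupancy` (each value in \[0, 2\]).
#' @export
evaluate_ensemble <- function(pattern, gamma, params = binding_params()) {
  pattern <- as_epigenetic_pattern(pattern)
  gamma <- check_state(gamma, "gamma", 1L)
  if (length(gamma) != pattern$M) {
    stop("'gamma' must have one indicator per nucleosome")
  }
  res <- .tm_evaluate_cpp(pattern$s, gamma, params$eps_m, params$J_int,
                          params$mu_hp1)
  structure(list(log_xi = res$log_xi, Phi = -res$log_xi,
                 occupancy = res$occupancy),
            class = "binding_summary")
}

#' @export
print.binding_summary <- function(x, ...) {
  cat(sprintf(
    "HP1 binding summary: Phi = %.4f kBT over %d nucleosomes, mean <sigma> = %.4f\n",
    x$Phi, length(x$occupancy), mean(x$occupancy)))
  invisible(x)
}

#' Free-energy change of enabling one linker interaction
#'
#' Returns Phi(gamma_i = 1) - Phi(gamma_i = 0) with all other indicators
#' frozen. With J_int < 0 this is always <= 0: permitting an interaction can
#' only lower the free energy.
#'
#' @param i linker index (1-based; linker `i` joins nucleosomes `i` and
#'   `i + 1`, with linker M closing the ring).
#' @param pattern an `epigenetic_pattern` or integer mark-count vector.
#' @param gamma current indicator vector (entry `i` is ignored).
#' @param params a [binding_params()] object.
#' @return scalar free-energy difference in kBT.
#' @export
delta_free_energy <- function(i, pattern, gamma, params = binding_params()) {
  pattern <- as_epigenetic_pattern(pattern)
  gamma <- check_state(gamma, "gamma", 1L)
  if (length(gamma) != pattern$M) {
    stop("'gamma' must have one indicator per nucleosome")
  }
  stop_if_not_scalar(i, "i")
  if (i < 1 || i > pattern$M) stop("linker index out of range")
  .delta_phi_cpp(as.integer(i), pattern$s, gamma, params$eps_m, params$J_int,
                 params$mu_hp1)
}

#' Write an occupancy profile as two-column CSV
#'
#' @param summary a `binding_summary`.
#' @param path output CSV path (columns `nucleosome`, `occupancy`).
#' @export
write_occupancy <- function(summary, path) {
  stopifnot(inherits(summary, "binding_summary"))
  write.csv(data.frame(nucleosome = seq_along(summary$occupancy),
                       occupancy = summary$occupancy),
            path, row.names = FALSE)
  invisible(path)
}
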