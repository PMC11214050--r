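#' Linker-length distribution parameters
#'
#' In the absence of HP1 interactions, linker lengths follow a geometric
#' (discretized exponential) law P(l) ~ exp(-lambda l) on l = 1, 2, ... with
#' lambda = -log(1 - 1/l0), which fixes the mean at `l0`. `lambda` and
#' `z = exp(-lambda)` are derived quantities and never set independently.
#'
#' @param l0 mean linker length in bp (> 1); the default approximates the
#'   typical genome-wide linker length in eukaryotic cells.
#' @param l_c cutoff (bp) separating the interaction-enabled short-linker
#'   branch from the tail; shared with [binding_params()].
#' @return object of class `linker_params` with fields `l0`, `lambda`, `z`,
#'   `l_c`.
#' @export
linker_params <- function(l0 = 45, l_c = 15) {
  stop_if_not_scalar(l0, "l0")
  if (l0 <= 1) stop("'l0' must exceed 1 bp")
  stop_if_not_scalar(l_c, "l_c")
  if (l_c < 1) stop("'l_c' must be at least 1 bp")
  lambda <- -log(1 - 1 / l0)
  structure(list(l0 = l0, lambda = lambda, z = exp(-lambda),
                 l_c = as.integer(l_c)),
            class = "linker_params")
}

#' @export
print.linker_params <- function(x, ...) {
  cat(sprintf("Linker parameters: l0 = %g bp, lambda = %.6f, l_c = %d bp\n",
              x$l0, x$lambda, x$l_c))
  invisible(x)
}

#' Interaction-modulated linker-length distribution
#'
#' For a free-energy difference `delta_phi` between the interacting
#' (l <= l_c) and non-interacting (l > l_c) branches, the distribution is
#' P(l) = exp(-delta_phi) z^l / N for l <= l_c and z^l / N otherwise, with
#' the closed-form normalization
#' N = z/(1-z) \[(1 - z^l_c) exp(-delta_phi) + z^l_c\].
#'
#' @param delta_phi free-energy difference in kBT (finite).
#' @param link_params a [linker_params()] object.
#' @return object of class `linker_distribution` with the branch mass
#'   `p_short` = P(l <= l_c) and normalization `N`.
#' @export
linker_distribution <- function(delta_phi, link_params = linker_params()) {
  stop_if_not_scalar(delta_phi, "delta_phi")
  z <- link_params$z
  lc <- link_params$l_c
  w <- exp(-delta_phi)
  short_geom <- 1 - z^lc
  N <- z / (1 - z) * (short_geom * w + z^lc)
  p_short <- w * short_geom / (w * short_geom + z^lc)
  structure(list(delta_phi = delta_phi, w = w, z = z, l_c = lc, N = N,
                 p_short = p_short, link_params = link_params),
            class = "linker_distribution")
}

#' @export
print.linker_distribution <- function(x, ...) {
  cat(sprintf(
    "Linker distribution: delta_phi = %g kBT, P(l <= %d) = %.4f\n",
    x$delta_phi, x$l_c, x$p_short))
  invisible(x)
}

#' Probability mass function of a linker distribution
#'
#' @param l integer linker lengths (bp, >= 1).
#' @param dist a [linker_distribution()] object.
#' @return P(l), vectorized.
#' @export
dlinker <- function(l, dist) {
  stopifnot(inherits(dist, "linker_distribution"))
  out <- ifelse(l >= 1 & l == floor(l),
                ifelse(l <= dist$l_c, dist$w, 1) * dist$z^l / dist$N,
                0)
  as.numeric(out)
}

#' Draw linker lengths by exact inverse-CDF sampling
#'
#' Picks the branch (l <= l_c versus l > l_c) by its total mass, then the
#' length by inverse CDF of the truncated or shifted geometric law; no
#' rejection and no truncation of the infinite tail.
#'
#' @param dist a [linker_distribution()] object.
#' @param n number of draws.
#' @param seed optional RNG seed.
#' @return integer vector of linker lengths (bp, all >= 1).
#' @export
sample_linker <- function(dist, n = 1, seed = NULL) {
  stopifnot(inherits(dist, "linker_distribution"))
  with_seed(seed, {
    z <- dist$z
    lc <- dist$l_c
    short_geom <- 1 - z^lc
    take_short <- runif(n) < dist$p_short
    l <- integer(n)
    ns <- sum(take_short)
    if (ns > 0) {
      v <- runif(ns)
      ls <- ceiling(log(1 - v * short_geom) / log(z))
      l[take_short] <- pmin(pmax(ls, 1), lc)
    }
    if (ns < n) {
      v <- runif(n - ns)
      k <- pmax(ceiling(log(1 - v) / log(z)), 1)
      l[!take_short] <- lc + k
    }
    as.integer(l)
  })
}

#' Heat-bath Monte Carlo sampling of linker lengths
#'
#' Runs `n_sweeps` sweeps of `M` single-linker updates each. Every update
#' computes the free-energy difference between the chosen linker's
#' interacting and non-interacting branches with all other indicators frozen
#' (via the transfer-matrix method) and redraws the linker length exactly
#' from its conditional distribution. Because each update is an exact
#' conditional (heat-bath) draw, both scan orders leave the target
#' distribution invariant: `"random"` picks a uniformly random linker per
#' update (and satisfies detailed balance), while `"systematic"`, the
#' default, visits linkers in order, which lets per-sweep suffix caches and
#' an incrementally updated prefix product reduce the cost from O(M) to
#' amortized O(1) matrix products per update.
#'
#' @param pattern an `epigenetic_pattern` or integer mark-count vector.
#' @param binding a [binding_params()] object.
#' @param link a [linker_params()] object (its `l_c` must agree with
#'   `binding$l_c`).
#' @param n_sweeps number of sweeps (`M` single-linker updates per sweep).
#' @param seed optional RNG seed.
#' @param init optional initial `linker_state`; by default lengths are drawn
#'   i.i.d. from the interaction-free geometric law.
#' @param record_gamma keep a per-sweep record of the indicator vector
#'   (useful for convergence diagnostics on small arrays).
#' @param scan update schedule: `"systematic"` (in-order, cached, fast) or
#'   `"random"` (uniformly random linker per update).
#' @return object of class `linker_state`: `lengths` (bp), `gamma`
#'   (indicators, maintained consistent with `lengths`), `sweep_count`,
#'   `trace` (short-linker fraction after each sweep), `seed`, and optionally
#'   `gamma_record`.
#' @export
run_sampler <- function(pattern, binding = binding_params(),
                        link = linker_params(l_c = binding$l_c),
                        n_sweeps = 150, seed = NULL, init = NULL,
                        record_gamma = FALSE,
                        scan = c("systematic", "random")) {
  scan <- match.arg(scan)
  pattern <- as_epigenetic_pattern(pattern)
  if (link$l_c != binding$l_c) {
    stop("'link$l_c' and 'binding$l_c' must agree")
  }
  stop_if_not_scalar(n_sweeps, "n_sweeps", positive = TRUE)
  with_seed(seed, {
    if (is.null(init)) {
      len0 <- sample_linker(linker_distribution(0, link), pattern$M)
    } else {
      stopifnot(inherits(init, "linker_state"))
      if (length(init$lengths) != pattern$M) {
        stop("'init' has the wrong number of linkers")
      }
      len0 <- init$lengths
    }
    res <- .linker_sweep_cpp(pattern$s, len0, binding$eps_m, binding$J_int,
                             binding$mu_hp1, binding$l_c, link$z,
                             as.integer(n_sweeps), record_gamma,
                             scan == "random")
    out <- structure(
      list(lengths = res$lengths, gamma = res$gamma,
           sweep_count = as.integer(n_sweeps) +
             if (is.null(init)) 0L else init$sweep_count,
           trace = res$trace, seed = seed),
      class = "linker_state"
    )
    if (record_gamma) out$gamma_record <- res$gamma_record
    out
  })
}

#' @export
print.linker_state <- function(x, ...) {
  cat(sprintf(
    "Linker state: %d linkers, %d sweeps, short-linker fraction %.4f\n",
    length(x$lengths), x$sweep_count, mean(x$gamma)))
  invisible(x)
}

#' Sliding-window convergence check for the linker sampler
#'
#' Declares convergence when the means of the short-linker fraction over two
#' consecutive windows of `window` sweeps differ by less than `tol`.
#'
#' @param trace per-sweep short-linker fractions (from a `linker_state`).
#' @param window window width in sweeps.
#' @param tol absolute tolerance on the window-mean difference.
#' @param burn_in sweeps discarded before checking.
#' @return logical.
#' @export
sampler_converged <- function(trace, window = 10, tol = 0.005, burn_in = 50) {
  n <- length(trace)
  if (n < burn_in + 2 * window) return(FALSE)
  w2 <- mean(trace[(n - window + 1):n])
  w1 <- mean(trace[(n - 2 * window + 1):(n - window)])
  abs(w2 - w1) < tol
}

#' Write a linker state as CSV
#'
#' @param state a `linker_state`.
#' @param path output CSV path (columns `index`, `l`, `gamma`, and `s` when a
#'   pattern is supplied).
#' @param pattern optional `epigenetic_pattern` to include mark counts.
#' @export
write_linker_state <- function(state, path, pattern = NULL) {
  stopifnot(inherits(state, "linker_state"))
  df <- data.frame(index = seq_along(state$lengths), l = state$lengths,
                   gamma = state$gamma)
  if (!is.null(pattern)) df$s <- as_epigenetic_pattern(pattern)$s
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
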