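#' Generate a synthetic H3K9me3 mark pattern
#'
#' Draws a 1D nucleosome array whose per-nucleosome mark count \eqn{s_i \in
#' \{0,1,2\}} is the number of H3K9me3-modified histone tails. Each of the two
#' tails carries an independent stationary two-state Markov chain along the
#' array, with transition probabilities solved from the target marked fraction
#' and the correlation length, so the per-tail marked indicator has stationary
#' mean `rho_target` and autocovariance decaying exactly as
#' \eqn{\exp(-\Delta/\kappa)} in nucleosome separation \eqn{\Delta}.
#'
#' @param M number of nucleosomes (at least 2; arrays shorter than 200
#'   nucleosomes trigger a warning unless `check_size = FALSE`, since short
#'   arrays show finite-size effects in the periodic binding model).
#' @param rho_target target fraction of histone tails marked, in \[0, 1\].
#' @param corr_length_nuc correlation decay length in nucleosomes (> 0).
#' @param seed optional RNG seed for reproducibility.
#' @param check_size warn when `M < 200`.
#' @return an object of class `epigenetic_pattern`: a list with elements `s`
#'   (integer vector of mark counts), `M`, `rho_target`, `corr_length_nuc`,
#'   and `seed`.
#' @examples
#' p <- generate_marks(500, rho_target = 0.1, corr_length_nuc = 10, seed = 1)
#' mean(p$s) / 2 # realized marked-tail fraction
#' @export
generate_marks <- function(M, rho_target, corr_length_nuc, seed = NULL,
                           check_size = TRUE) {
  stop_if_not_scalar(M, "M")
  if (M < 2) stop("'M' must be at least 2")
  stop_if_not_scalar(rho_target, "rho_target")
  if (rho_target < 0 || rho_target > 1) {
    stop("'rho_target' must lie in [0, 1]")
  }
  stop_if_not_scalar(corr_length_nuc, "corr_length_nuc", positive = TRUE)
  if (check_size && M < 200) {
    warning("arrays shorter than 200 nucleosomes are prone to finite-size ",
            "effects; pass check_size = FALSE to silence")
  }
  M <- as.integer(M)

  with_seed(seed, {
    e <- exp(-1 / corr_length_nuc) # lag-1 autocorrelation of each tail chain
    a <- rho_target * (1 - e)       # P(unmarked -> marked)
    b <- (1 - rho_target) * (1 - e) # P(marked -> unmarked)
    s <- integer(M)
    for (tail in 1:2) {
      x <- integer(M)
      x[1] <- rbinom(1L, 1L, rho_target)
      if (M > 1L) {
        u <- runif(M - 1L)
        for (i in 2:M) {
          x[i] <- if (x[i - 1L] == 1L) as.integer(u[i - 1L] >= b)
                  else as.integer(u[i - 1L] < a)
        }
      }
      s <- s + x
    }
    structure(
      list(s = s, M = M, rho_target = rho_target,
           corr_length_nuc = corr_length_nuc, seed = seed),
      class = "epigenetic_pattern"
    )
  })
}

#' Coerce mark counts to an epigenetic_pattern
#'
#' @param x an `epigenetic_pattern` or an integer vector with values in
#'   \{0, 1, 2\}.
#' @return an `epigenetic_pattern`.
#' @export
as_epigenetic_pattern <- function(x) {
  if (inherits(x, "epigenetic_pattern")) return(x)
  s <- as.integer(x)
  if (any(is.na(s)) || any(s < 0L | s > 2L)) {
    stop("mark counts must be integers in {0, 1, 2}")
  }
  structure(
    list(s = s, M = length(s), rho_target = NA_real_,
         corr_length_nuc = NA_real_, seed = NULL),
    class = "epigenetic_pattern"
  )
}

#' @export
print.epigenetic_pattern <- function(x, ...) {
  cat(sprintf(
    "H3K9me3 pattern: %d nucleosomes, marked-tail fraction %.4f (target %s)\n",
    x$M, sum(x$s) / (2 * x$M),
    if (is.na(x$rho_target)) "unknown" else sprintf("%.4f", x$rho_target)))
  invisible(x)
}

#' Normalized autocovariance of the per-nucleosome mark count
#'
#' Computes the autocorrelation of the mark-count sequence at lags
#' `0..max_lag`, normalizing each lag's autocovariance by the number of
#' available pairs so that exactly periodic toy sequences give exact values.
#' A constant (zero-variance) pattern is degenerate: the function warns and
#' returns all zeros.
#'
#' @param pattern an `epigenetic_pattern` or integer vector of mark counts.
#' @param max_lag largest lag, strictly less than the array length.
#' @return numeric vector of length `max_lag + 1` (lag 0 first).
#' @export
mark_autocorrelation <- function(pattern, max_lag) {
  s <- if (inherits(pattern, "epigenetic_pattern")) pattern$s else
    as.numeric(pattern)
  M <- length(s)
  stop_if_not_scalar(max_lag, "max_lag")
  if (max_lag >= M) stop("'max_lag' must be smaller than the array length")
  d <- s - mean(s)
  v <- mean(d^2)
  if (v == 0) {
    warning("constant mark pattern: autocorrelation undefined, returning 0")
    return(numeric(max_lag + 1))
  }
  vapply(0:max_lag, function(k) {
    if (k == 0) return(1)
    mean(d[1:(M - k)] * d[(k + 1):M]) / v
  }, numeric(1))
}

#' Estimate the correlation decay length of a mark pattern
#'
#' Fits a line to the log-autocorrelation over lags `1..max_lag` and returns
#' `-1/slope` together with the R-squared of the fit. The fit is weighted by
#' the squared autocorrelation (the delta-method variance of a
#' log-transformed correlation estimate grows as its inverse square, so
#' unweighted fits are dominated by the noisiest long lags); lags with
#' autocorrelation below 0.05 are dropped for the same reason.
#'
#' @param pattern an `epigenetic_pattern` or integer vector.
#' @param max_lag largest lag used in the fit (default three times the
#'   pattern's nominal correlation length, or 30).
#' @return list with `corr_length` (nucleosomes) and `r_squared`.
#' @export
fit_mark_correlation <- function(pattern, max_lag = NULL) {
  if (is.null(max_lag)) {
    cl <- if (inherits(pattern, "epigenetic_pattern") &&
              is.finite(pattern$corr_length_nuc)) pattern$corr_length_nuc
          else 10
    max_lag <- max(3L, as.integer(round(3 * cl)))
  }
  ac <- mark_autocorrelation(pattern, max_lag)
  lag <- seq_len(max_lag)
  y <- ac[-1]
  keep <- y > 0.05
  if (sum(keep) < 3) stop("too few positive autocorrelation values to fit")
  fit <- stats::lm(log(y[keep]) ~ lag[keep], weights = y[keep]^2)
  list(corr_length = -1 / unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared)
}

#' Write / read mark patterns as single-column CSV
#'
#' The CSV holds one integer mark count per row (column `s`); a YAML sidecar
#' (`<path>.yaml`) records `M`, `rho_target`, `corr_length_nuc`, and `seed`.
#'
#' @param pattern an `epigenetic_pattern`.
#' @param path output CSV path.
#' @return `write_pattern` returns `path` invisibly; `read_pattern` returns an
#'   `epigenetic_pattern`.
#' @export
write_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "epigenetic_pattern"))
  write.csv(data.frame(s = pattern$s), path, row.names = FALSE)
  meta <- list(M = pattern$M, rho_target = pattern$rho_target,
               corr_length_nuc = pattern$corr_length_nuc,
               seed = if (is.null(pattern$seed)) NA else pattern$seed)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  s <- read.csv(path)$s
  out <- as_epigenetic_pattern(s)
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    out$rho_target <- if (is.null(meta$rho_target) || is.na(meta$rho_target))
      NA_real_ else meta$rho_target
    out$corr_length_nuc <- if (is.null(meta$corr_length_nuc) ||
                               is.na(meta$corr_length_nuc)) NA_real_
      else meta$corr_length_nuc
    out$seed <- if (is.null(meta$seed) || is.na(meta$seed)) NULL else meta$seed
  }
  out
}
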