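#' Mechanical constants of bare DNA
#'
#' @param lp bend persistence length (nm).
#' @param lt twist persistence length (nm).
#' @param L1 contour length per base pair (nm).
#' @param tau natural twist (rad per bp); the default gives 10.5 bp per
#'   helical turn.
#' @return object of class `dna_mechanics`.
#' @export
dna_mechanics <- function(lp = 50, lt = 100, L1 = 0.332, tau = 2 * pi / 10.5) {
  stop_if_not_scalar(lp, "lp", positive = TRUE)
  stop_if_not_scalar(lt, "lt", positive = TRUE)
  stop_if_not_scalar(L1, "L1", positive = TRUE)
  stop_if_not_scalar(tau, "tau", positive = TRUE)
  structure(list(lp = lp, lt = lt, L1 = L1, tau = tau),
            class = "dna_mechanics")
}

#' @export
print.dna_mechanics <- function(x, ...) {
  cat(sprintf(
    "DNA mechanics: lp = %g nm, lt = %g nm, L1 = %g nm/bp, %.2f bp/turn\n",
    x$lp, x$lt, x$L1, 2 * pi / x$tau))
  invisible(x)
}

# orthonormal frame on the superhelical wrapping path at winding angle phi;
# columns: toward-axis normal, co-normal, tangent
superhelix_frame <- function(phi, radius, rise_per_rad, handed) {
  e3 <- c(-radius * sin(phi), handed * radius * cos(phi), rise_per_rad)
  e3 <- e3 / sqrt(sum(e3^2))
  e1 <- c(-cos(phi), -handed * sin(phi), 0)
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  cbind(e1, e2, e3)
}

#' Nucleosome wrapping geometry and the entry/exit kink
#'
#' Models the 147 bp of nucleosomal DNA as a superhelical wrap of
#' `turns` turns around a cylinder of radius `radius` with rise `pitch` per
#' turn (left-handed). The rigid-body transform mapping the DNA frame
#' entering the nucleosome to the frame exiting it -- the "kink" the
#' nucleosome inserts into the fiber -- is derived from the entry and exit
#' frames of that path. The exact crystallographic entry/exit angles are not
#' reproduced; the wrap is a documented geometric approximation and all its
#' parameters are configurable.
#'
#' @param wrap_bp base pairs wrapped per nucleosome.
#' @param radius superhelix radius in nm.
#' @param turns number of superhelical turns (0 gives the degenerate no-kink
#'   control: identity rotation and a straight advance of `wrap_bp * L1`).
#' @param pitch superhelical rise per turn (nm).
#' @param L1 contour length per bp (nm), used only for the zero-turn control.
#' @return object of class `nucleosome_geometry` with the entry/exit
#'   transform (`rotation` 3x3 with det +1, `translation` length-3, both in
#'   the entry frame) and the superhelix-center offset `center_local`.
#' @export
nucleosome_geometry <- function(wrap_bp = 147, radius = 4.19, turns = 1.7,
                                pitch = 2.39, L1 = 0.332) {
  stop_if_not_scalar(wrap_bp, "wrap_bp", positive = TRUE)
  stop_if_not_scalar(radius, "radius", positive = TRUE)
  stop_if_not_scalar(turns, "turns")
  if (turns < 0) stop("'turns' must be non-negative")
  stop_if_not_scalar(pitch, "pitch")
  if (pitch < 0) stop("'pitch' must be non-negative")

  if (turns == 0) {
    rotation <- diag(3)
    translation <- c(0, 0, wrap_bp * L1)
    center_local <- c(0, 0, wrap_bp * L1 / 2)
  } else {
    handed <- -1 # left-handed wrap
    phi1 <- 2 * pi * turns
    rise <- pitch / (2 * pi)
    E0 <- superhelix_frame(0, radius, rise, handed)
    E1 <- superhelix_frame(phi1, radius, rise, handed)
    p0 <- c(radius, 0, 0)
    p1 <- c(radius * cos(phi1), handed * radius * sin(phi1), rise * phi1)
    rotation <- t(E0) %*% E1
    dimnames(rotation) <- NULL
    translation <- as.numeric(t(E0) %*% (p1 - p0))
    center_local <- as.numeric(t(E0) %*% (c(0, 0, rise * phi1 / 2) - p0))
  }
  structure(list(wrap_bp = as.integer(wrap_bp), radius = radius,
                 turns = turns, pitch = pitch,
                 rotation = rotation, translation = translation,
                 center_local = center_local),
            class = "nucleosome_geometry")
}

#' Default nucleosome entry/exit kink
#'
#' @param ... arguments passed to [nucleosome_geometry()].
#' @return a `nucleosome_geometry`.
#' @export
default_kink <- function(...) nucleosome_geometry(...)

#' @export
print.nucleosome_geometry <- function(x, ...) {
  cat(sprintf(
    "Nucleosome geometry: %d bp wrap, R = %g nm, %g turns, pitch %g nm\n",
    x$wrap_bp, x$radius, x$turns, x$pitch))
  invisible(x)
}

#' Sample per-bp bend/twist angles of the twistable wormlike chain
#'
#' Draws independent per-bp deformations from the Boltzmann weight of the
#' discretized elastic energy: the bend magnitude has density proportional to
#' exp(kappa cos(theta)) on the sphere with kappa = lp/L1 (so the mean cosine
#' is the Langevin-type coth(kappa) - 1/kappa), the bend azimuth is uniform,
#' and the twist is Gaussian with mean tau (rad per bp) and variance L1/lt.
#'
#' @param n number of bp steps to sample.
#' @param mech a [dna_mechanics()] object.
#' @param seed optional RNG seed.
#' @return an `n` x 3 matrix with columns `bend`, `azimuth`, `twist` (rad).
#' @export
sample_bp_angles <- function(n, mech = dna_mechanics(), seed = NULL) {
  stop_if_not_scalar(n, "n", positive = TRUE)
  with_seed(seed, .sample_bp_angles_cpp(as.integer(n), mech$lp, mech$lt,
                                        mech$L1, mech$tau))
}

#' Sample a single bp rigid-frame increment
#'
#' @param mech a [dna_mechanics()] object.
#' @param seed optional RNG seed.
#' @return list with `rotation` (3x3, det +1), `translation` (`L1` along the
#'   rotated tangent, in the parent frame), and `angles`.
#' @export
sample_bp_step <- function(mech = dna_mechanics(), seed = NULL) {
  ang <- sample_bp_angles(1, mech, seed)
  theta <- ang[1, "bend"]
  phi <- ang[1, "azimuth"]
  psi <- ang[1, "twist"]
  Rz <- function(a) matrix(c(cos(a), -sin(a), 0,
                             sin(a), cos(a), 0,
                             0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- function(a) matrix(c(cos(a), 0, sin(a),
                             0, 1, 0,
                             -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
  R <- Rz(phi) %*% Ry(theta) %*% Rz(psi - phi)
  list(rotation = R, translation = mech$L1 * R[, 3], angles = ang[1, ])
}

tri_tangents <- function(tri) tri[, c(3, 6, 9), drop = FALSE]

#' Grow a bare-DNA chain base pair by base pair
#'
#' @param n_bp number of base pairs.
#' @param mech a [dna_mechanics()] object.
#' @param seed optional RNG seed.
#' @return object of class `dna_chain`: `pos` ((n_bp + 1) x 3 positions, nm)
#'   and `tri` ((n_bp + 1) x 9 row-major triads), starting from the identity
#'   frame at the origin.
#' @export
grow_dna <- function(n_bp, mech = dna_mechanics(), seed = NULL) {
  stop_if_not_scalar(n_bp, "n_bp", positive = TRUE)
  res <- with_seed(seed, .grow_dna_cpp(as.integer(n_bp), mech$lp, mech$lt,
                                       mech$L1, mech$tau))
  structure(list(pos = res$pos, tri = res$tri, mech = mech, seed = seed),
            class = "dna_chain")
}

#' Tangent-tangent autocorrelation of a grown chain
#'
#' @param chain a `dna_chain` (or any object with a `tri` matrix).
#' @param max_lag_bp largest separation in bp.
#' @return data.frame with `lag_bp`, `s_nm` (contour separation), and `corr`.
#' @export
tangent_autocorrelation <- function(chain, max_lag_bp) {
  tri <- if (is.list(chain)) chain$tri else chain
  tg <- tri_tangents(tri)
  n <- nrow(tg)
  L1 <- if (is.list(chain) && !is.null(chain$mech)) chain$mech$L1 else 0.332
  lags <- seq_len(min(max_lag_bp, n - 1))
  corr <- vapply(lags, function(k) {
    mean(rowSums(tg[1:(n - k), , drop = FALSE] *
                   tg[(k + 1):n, , drop = FALSE]))
  }, numeric(1))
  data.frame(lag_bp = lags, s_nm = lags * L1, corr = corr)
}

#' Estimate the bend persistence length from tangent correlations
#'
#' Fits log correlation against contour separation over `(0, fit_range_nm]`
#' and returns the decay length `-1/slope` in nm.
#'
#' @param ac data.frame from [tangent_autocorrelation()] (correlations may be
#'   averaged over chains first).
#' @param fit_range_nm upper end of the fitted separation range (nm).
#' @return decay length in nm.
#' @export
fit_persistence_length <- function(ac, fit_range_nm = 100) {
  keep <- ac$s_nm <= fit_range_nm & ac$corr > 0
  fit <- stats::lm(log(ac$corr[keep]) ~ ac$s_nm[keep])
  -1 / unname(stats::coef(fit)[2])
}

#' Grow a 3D chromatin fiber from sampled linker lengths
#'
#' Alternates nucleosome kinks (the fixed entry/exit transform of `geom`)
#' with linker growth (per-bp Boltzmann-sampled bend/twist steps) to build an
#' open chain of `M` nucleosomes. The recorded position and orientation of
#' each nucleosome is its DNA entry pose; the first nucleosome sits at the
#' origin with the identity orientation. When a `linker_state` is supplied,
#' only its first `M - 1` linkers are used -- the periodic closure linker of
#' the 1D model has no 3D counterpart.
#'
#' @param linkers a `linker_state` or an integer vector of `M - 1` linker
#'   lengths (bp, all >= 1).
#' @param geom a [nucleosome_geometry()] object.
#' @param mech a [dna_mechanics()] object.
#' @param seed optional RNG seed.
#' @param record_bp record per-bp frames of the linker DNA (memory heavy for
#'   long fibers; nucleosome poses are always recorded).
#' @return object of class `chain_config`: `nuc_pos` (M x 3, nm), `nuc_tri`
#'   (M x 9 row-major triads), `linkers` (bp), and when `record_bp` is TRUE
#'   `bp_pos`, `bp_tri`, `linker_map` (1-based linker index of each bp).
#' @export
grow_chain <- function(linkers, geom = nucleosome_geometry(),
                       mech = dna_mechanics(), seed = NULL,
                       record_bp = TRUE) {
  if (inherits(linkers, "linker_state")) {
    M <- length(linkers$lengths)
    lens <- linkers$lengths[seq_len(M - 1)]
  } else {
    lens <- as.integer(linkers)
    if (any(is.na(lens)) || any(lens < 1)) {
      stop("linker lengths must be integers >= 1")
    }
  }
  res <- with_seed(seed, .grow_chain_cpp(as.integer(lens), geom$translation,
                                         as.numeric(t(geom$rotation)),
                                         mech$lp, mech$lt, mech$L1, mech$tau,
                                         record_bp))
  structure(list(nuc_pos = res$nuc_pos, nuc_tri = res$nuc_tri,
                 linkers = as.integer(lens),
                 bp_pos = res$bp_pos, bp_tri = res$bp_tri,
                 linker_map = res$linker_map,
                 geom = geom, mech = mech, seed = seed),
            class = "chain_config")
}

#' @export
print.chain_config <- function(x, ...) {
  cat(sprintf("Chromatin fiber: %d nucleosomes, %d linker bp%s\n",
              nrow(x$nuc_pos), sum(x$linkers),
              if (is.null(x$bp_pos)) " (bp frames not recorded)" else ""))
  invisible(x)
}

#' Write a chain configuration as columnar CSV
#'
#' One row per recorded site: `type` ("nucleosome" or "bp"), `index`, the
#' position in nm, and the nine triad entries (row-major).
#'
#' @param config a `chain_config`.
#' @param path output CSV path.
#' @export
write_chain <- function(config, path) {
  stopifnot(inherits(config, "chain_config"))
  tri_names <- paste0("t", rep(1:3, each = 3), rep(1:3, 3))
  nuc <- data.frame(type = "nucleosome", index = seq_len(nrow(config$nuc_pos)),
                    x = config$nuc_pos[, 1], y = config$nuc_pos[, 2],
                    z = config$nuc_pos[, 3])
  nuc[tri_names] <- config$nuc_tri
  out <- nuc
  if (!is.null(config$bp_pos) && nrow(config$bp_pos) > 0) {
    bp <- data.frame(type = "bp", index = seq_len(nrow(config$bp_pos)),
                     x = config$bp_pos[, 1], y = config$bp_pos[, 2],
                     z = config$bp_pos[, 3])
    bp[tri_names] <- config$bp_tri
    out <- rbind(nuc, bp)
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export nucleosome positions as a pseudo-atom PDB file
#'
#' Writes one CA pseudo-atom per nucleosome (coordinates in Angstrom = 10 x
#' nm) for quick visualization in molecular viewers.
#'
#' @param config a `chain_config`.
#' @param path output PDB path.
#' @export
write_pdb <- function(config, path) {
  stopifnot(inherits(config, "chain_config"))
  pos <- config$nuc_pos * 10
  lines <- sprintf(
    "ATOM  %5d  CA  NUC A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(pos)) %% 100000, seq_len(nrow(pos)) %% 10000,
    pos[, 1], pos[, 2], pos[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}
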