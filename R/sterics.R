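#' Nucleosome steric repulsion parameters
#'
#' @param V0 scale of the repulsive potential (kBT).
#' @param R nucleosome radius (nm); the potential is truncated to zero at
#'   separations D >= 2R.
#' @return object of class `steric_params`.
#' @export
steric_params <- function(V0 = 1.0, R = 4.19) {
  stop_if_not_scalar(V0, "V0", positive = TRUE)
  stop_if_not_scalar(R, "R", positive = TRUE)
  structure(list(V0 = V0, R = R), class = "steric_params")
}

#' Shifted Lennard-Jones pair repulsion
#'
#' V0 \[(2R/D)^12 - 2 (2R/D)^6 + 1\] for D < 2R and 0 otherwise: zero-valued
#' at contact (D = 2R) and non-negative everywhere. Coincident nucleosomes
#' (D = 0) return a large finite energy that guarantees rejection rather
#' than an error.
#'
#' @param D pair distance(s), nm.
#' @param params a [steric_params()] object.
#' @return pair energy in kBT (vectorized).
#' @export
pair_steric_energy <- function(D, params = steric_params()) {
  cut <- 2 * params$R
  out <- numeric(length(D))
  inside <- D < cut
  tiny <- D < 1e-6
  x6 <- (cut / D[inside & !tiny])^6
  out[inside & !tiny] <- params$V0 * (x6^2 - 2 * x6 + 1)
  out[tiny] <- 1e12
  out
}

#' Total nucleosome steric energy of a configuration
#'
#' Sums the shifted Lennard-Jones repulsion over all unordered nucleosome
#' pairs; invariant under global rotation/translation and under relabeling.
#'
#' @param config a `chain_config` or an N x 3 position matrix (nm).
#' @param params a [steric_params()] object.
#' @return total steric energy in kBT.
#' @export
steric_energy <- function(config, params = steric_params()) {
  pos <- if (inherits(config, "chain_config")) config$nuc_pos else
    as.matrix(config)
  D <- stats::dist(pos)
  sum(pair_steric_energy(as.numeric(D), params))
}

#' Count overlapping nucleosome pairs
#'
#' @param config a `chain_config` or position matrix.
#' @param R nucleosome radius (nm); pairs closer than 2R overlap.
#' @return integer count.
#' @export
count_overlaps <- function(config, R = 4.19) {
  pos <- if (inherits(config, "chain_config")) config$nuc_pos else
    as.matrix(config)
  sum(as.numeric(stats::dist(pos)) < 2 * R)
}

#' Coarse-grained elastic model of linker DNA
#'
#' Quadratic deformation energy of the inter-nucleosome virtual bond (the
#' linker running from the DNA exit pose of one nucleosome to the entry pose
#' of the next), with moduli derived from the wormlike-chain constants. For a
#' linker of contour length L = l * L1 the energy is
#' lp/(2L) (theta_1^2 + theta_2^2) + lt/(2L) (psi - tau L)^2 +
#' k_s/2 (|r| - L)^2, where theta_1, theta_2 are the bend angles between the
#' bond vector r and the exit/entry tangents, psi is the twist between the
#' bounding frames, and k_s = stretch_scale lp^2 / L^4 is the stiff-limit
#' WLC estimate of the longitudinal stiffness. Transverse (shear)
#' displacement is penalized implicitly through the two bend half-joints.
#' The energy is zero at the ground-state geometry (straight bond of length
#' L with natural twist) and scales quadratically in small deformations.
#'
#' @param lp,lt,L1,tau wormlike-chain constants, as in [dna_mechanics()].
#' @param stretch_scale dimensionless prefactor of the derived stretch
#'   stiffness.
#' @return object of class `elastic_model`.
#' @export
elastic_model <- function(lp = 50, lt = 100, L1 = 0.332, tau = 2 * pi / 10.5,
                          stretch_scale = 90) {
  stop_if_not_scalar(lp, "lp", positive = TRUE)
  stop_if_not_scalar(lt, "lt", positive = TRUE)
  stop_if_not_scalar(L1, "L1", positive = TRUE)
  stop_if_not_scalar(stretch_scale, "stretch_scale", positive = TRUE)
  structure(list(lp = lp, lt = lt, L1 = L1, tau = tau,
                 stretch_scale = stretch_scale),
            class = "elastic_model")
}

wrap_pi <- function(a) ((a + pi) %% (2 * pi)) - pi

#' Elastic energy of inter-nucleosome linkers
#'
#' Pure-R evaluation of the [elastic_model()] quadratic form from a chain
#' configuration's nucleosome poses (the compiled Monte Carlo relaxer carries
#' its own evaluation of the same form; the two are cross-checked in the test
#' suite).
#'
#' @param config a `chain_config`.
#' @param model an [elastic_model()] object.
#' @param linker_index linker indices to evaluate (default all).
#' @return numeric vector of per-linker energies (kBT).
#' @export
elastic_energy <- function(config, model = elastic_model(),
                           linker_index = NULL) {
  stopifnot(inherits(config, "chain_config"))
  N <- nrow(config$nuc_pos)
  if (is.null(linker_index)) linker_index <- seq_len(N - 1)
  if (any(linker_index < 1 | linker_index > N - 1)) {
    stop("linker index out of range")
  }
  geom <- config$geom
  vapply(linker_index, function(j) {
    Qa <- matrix(config$nuc_tri[j, ], 3, 3, byrow = TRUE)
    Qb <- matrix(config$nuc_tri[j + 1, ], 3, 3, byrow = TRUE)
    L <- config$linkers[j] * model$L1
    p_out <- config$nuc_pos[j, ] + as.numeric(Qa %*% geom$translation)
    F_out <- Qa %*% geom$rotation
    r <- config$nuc_pos[j + 1, ] - p_out
    rn <- sqrt(sum(r^2))
    th1 <- th2 <- 0
    if (rn > 1e-9) {
      u <- r / rn
      th1 <- acos(max(-1, min(1, sum(F_out[, 3] * u))))
      th2 <- acos(max(-1, min(1, sum(Qb[, 3] * u))))
    }
    Mrot <- t(F_out) %*% Qb
    tw <- atan2(Mrot[2, 1] - Mrot[1, 2], Mrot[1, 1] + Mrot[2, 2])
    dev <- wrap_pi(tw - model$tau * config$linkers[j]) # tau is rad per bp
    ks <- model$stretch_scale * model$lp^2 / L^4
    model$lp / (2 * L) * (th1^2 + th2^2) + model$lt / (2 * L) * dev^2 +
      ks / 2 * (rn - L)^2
  }, numeric(1))
}

#' Construct a chain configuration at the elastic ground state
#'
#' Places nucleosomes so every virtual bond is straight with its natural
#' twist; useful as a reference for elastic-energy tests and as a relaxed
#' starting structure.
#'
#' @param linkers integer vector of linker lengths (bp).
#' @param geom a [nucleosome_geometry()] object.
#' @param mech a [dna_mechanics()] object.
#' @return a `chain_config` whose [elastic_energy()] is zero.
#' @export
ground_state_chain <- function(linkers, geom = nucleosome_geometry(),
                               mech = dna_mechanics()) {
  lens <- as.integer(linkers)
  M <- length(lens) + 1
  pos <- matrix(0, M, 3)
  tri <- matrix(0, M, 9)
  Rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  Q <- diag(3)
  p <- c(0, 0, 0)
  for (m in seq_len(M)) {
    pos[m, ] <- p
    tri[m, ] <- as.numeric(t(Q))
    if (m == M) break
    p_out <- p + as.numeric(Q %*% geom$translation)
    F_out <- Q %*% geom$rotation
    L <- lens[m] * mech$L1
    p <- p_out + L * F_out[, 3]
    Q <- F_out %*% Rz(mech$tau * lens[m])
  }
  structure(list(nuc_pos = pos, nuc_tri = tri, linkers = lens,
                 bp_pos = NULL, bp_tri = NULL, linker_map = NULL,
                 geom = geom, mech = mech, seed = NULL),
            class = "chain_config")
}

#' Monte Carlo move parameters
#'
#' @param probs proposal probabilities for (crankshaft, terminal pivot,
#'   single-nucleosome) moves; must sum to 1.
#' @param amp_crank crankshaft rotation amplitude (rad).
#' @param amp_pivot terminal-segment rotation amplitude (rad).
#' @param amp_single_t single-nucleosome translation amplitude (nm).
#' @param amp_single_r single-nucleosome orientation amplitude (rad).
#' @param seg_max largest moved segment (nucleosomes).
#' @return object of class `move_params`.
#' @export
move_params <- function(probs = c(crank = 0.4, pivot = 0.3, single = 0.3),
                        amp_crank = 0.6, amp_pivot = 0.4,
                        amp_single_t = 0.4, amp_single_r = 0.3,
                        seg_max = 20) {
  if (length(probs) != 3 || any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    stop("'probs' must be three non-negative values summing to 1")
  }
  structure(list(probs = unname(probs), amp_crank = amp_crank,
                 amp_pivot = amp_pivot, amp_single_t = amp_single_t,
                 amp_single_r = amp_single_r, seg_max = as.integer(seg_max)),
            class = "move_params")
}

rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle); t_ <- 1 - c_
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(t_ * x * x + c_, t_ * x * y - s_ * z, t_ * x * z + s_ * y,
           t_ * x * y + s_ * z, t_ * y * y + c_, t_ * y * z - s_ * x,
           t_ * x * z - s_ * y, t_ * y * z + s_ * x, t_ * z * z + c_),
         3, 3, byrow = TRUE)
}

apply_rigid <- function(config, idx, Rm, pivot) {
  for (i in idx) {
    config$nuc_pos[i, ] <- pivot + as.numeric(Rm %*%
                                                (config$nuc_pos[i, ] - pivot))
    Q <- matrix(config$nuc_tri[i, ], 3, 3, byrow = TRUE)
    config$nuc_tri[i, ] <- as.numeric(t(Rm %*% Q))
  }
  config
}

#' Propose a single Monte Carlo move
#'
#' Draws one of the three move types at the configured probabilities and
#' returns the trial configuration together with a move log. Crankshaft
#' rotations leave the positions of both anchor nucleosomes unchanged; all
#' moves are rigid motions of the affected segment and are exactly
#' invertible.
#'
#' @param config a `chain_config`.
#' @param mp a [move_params()] object.
#' @param seed optional RNG seed.
#' @return list with `config` (trial), `type`, `moved` (index range), and the
#'   move's `rotation`/`pivot` (where applicable).
#' @export
propose_move <- function(config, mp = move_params(), seed = NULL) {
  stopifnot(inherits(config, "chain_config"))
  N <- nrow(config$nuc_pos)
  with_seed(seed, {
    u <- runif(1)
    type <- if (u < mp$probs[1] && N >= 3) "crank"
            else if (u < mp$probs[1] + mp$probs[2]) "pivot" else "single"
    if (type == "crank") {
      pa <- sample.int(N - 2, 1)
      m <- sample.int(min(mp$seg_max, N - 1 - pa), 1)
      qa <- pa + m + 1
      moved <- (pa + 1):(qa - 1)
      v <- config$nuc_pos[qa, ] - config$nuc_pos[pa, ]
      axis <- if (sqrt(sum(v^2)) > 1e-9) v else stats::rnorm(3)
      ang <- mp$amp_crank * (2 * runif(1) - 1)
      Rm <- rotation_about_axis(axis, ang)
      pivot <- config$nuc_pos[pa, ]
      trial <- apply_rigid(config, moved, Rm, pivot)
      list(config = trial, type = type, moved = range(moved),
           anchors = c(pa, qa), rotation = Rm, pivot = pivot)
    } else if (type == "pivot") {
      head <- runif(1) < 0.5
      m <- sample.int(min(mp$seg_max, N - 1), 1)
      if (head) { moved <- 1:m; kpiv <- m + 1 }
      else { moved <- (N - m + 1):N; kpiv <- N - m }
      axis <- stats::rnorm(3)
      ang <- mp$amp_pivot * (2 * runif(1) - 1)
      Rm <- rotation_about_axis(axis, ang)
      pivot <- config$nuc_pos[kpiv, ]
      trial <- apply_rigid(config, moved, Rm, pivot)
      list(config = trial, type = type, moved = range(moved),
           anchors = kpiv, rotation = Rm, pivot = pivot)
    } else {
      k <- sample.int(N, 1)
      shift <- mp$amp_single_t * (2 * runif(3) - 1)
      trial <- config
      trial$nuc_pos[k, ] <- trial$nuc_pos[k, ] + shift
      if (mp$amp_single_r > 0) {
        axis <- stats::rnorm(3)
        ang <- mp$amp_single_r * (2 * runif(1) - 1)
        Rm <- rotation_about_axis(axis, ang)
        Q <- matrix(trial$nuc_tri[k, ], 3, 3, byrow = TRUE)
        trial$nuc_tri[k, ] <- as.numeric(t(Rm %*% Q))
      }
      list(config = trial, type = type, moved = c(k, k), shift = shift)
    }
  })
}

#' Metropolis relaxation of a chromatin configuration
#'
#' Runs nucleosome-resolution Metropolis Monte Carlo with elastic-plus-steric
#' acceptance on the grown configuration. Per-bp frames are dropped from the
#' result (the relaxer operates on nucleosome poses only). Energy totals are
#' maintained incrementally and returned for bookkeeping checks.
#'
#' @param config a `chain_config`.
#' @param elastic an [elastic_model()] object.
#' @param steric a [steric_params()] object.
#' @param n_steps number of Monte Carlo steps.
#' @param seed optional RNG seed.
#' @param mp a [move_params()] object.
#' @param trace_every record the energy trace every this many steps (0
#'   disables).
#' @return list with `config` (relaxed `chain_config`), `trace` (data.frame
#'   of step, elastic, steric), `elastic_total`, `steric_total`
#'   (incrementally maintained), and `acceptance` (per move type).
#' @export
relax <- function(config, elastic = elastic_model(),
                  steric = steric_params(), n_steps = 1e5, seed = NULL,
                  mp = move_params(), trace_every = 1000) {
  stopifnot(inherits(config, "chain_config"))
  stop_if_not_scalar(n_steps, "n_steps", positive = TRUE)
  res <- with_seed(seed, .relax_cpp(
    config$nuc_pos, config$nuc_tri, config$linkers,
    config$geom$translation, as.numeric(t(config$geom$rotation)),
    elastic$lp, elastic$lt, elastic$L1, elastic$tau, elastic$stretch_scale,
    steric$V0, steric$R, as.integer(n_steps), mp$probs,
    mp$amp_crank, mp$amp_pivot, mp$amp_single_t, mp$amp_single_r,
    mp$seg_max, as.integer(trace_every)))
  out <- config
  out$nuc_pos <- res$pos
  out$nuc_tri <- res$tri
  out$bp_pos <- NULL
  out$bp_tri <- NULL
  out$linker_map <- NULL
  acc <- data.frame(type = c("crank", "pivot", "single"),
                    proposed = res$n_proposed, accepted = res$n_accepted)
  acc$rate <- ifelse(acc$proposed > 0, acc$accepted / acc$proposed, NA)
  list(config = out, trace = as.data.frame(res$trace),
       elastic_total = res$elastic_total, steric_total = res$steric_total,
       acceptance = acc)
}
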