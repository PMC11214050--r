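test_that("the shifted Lennard-Jones pair energy matches direct substitution", {
  p <- steric_params(V0 = 1, R = 4.19)
  expect_equal(pair_steric_energy(2 * 4.19, p), 0)
  expect_equal(pair_steric_energy(4.19, p), 2^12 - 2 * 2^6 + 1) # 3969 V0
  expect_equal(pair_steric_energy(10, p), 0)
  expect_true(all(pair_steric_energy(seq(0.5, 8.3, by = 0.1), p) > 0))
  # coincident nucleosomes are a certain rejection, not an error
  expect_gt(pair_steric_energy(0, p), 1e11)
  p2 <- steric_params(V0 = 2.5, R = 4.19)
  expect_equal(pair_steric_energy(4.19, p2), 2.5 * 3969)
})

test_that("total steric energy is invariant under rigid motion", {
  set.seed(40)
  pos <- matrix(rnorm(30, sd = 5), 10, 3)
  p <- steric_params()
  e0 <- steric_energy(pos, p)
  ax <- c(1, 2, 3) / sqrt(14)
  R <- nucleoclust:::rotation_about_axis(ax, 0.7)
  moved <- sweep(pos %*% t(R), 2, c(5, -3, 2), `+`)
  expect_equal(steric_energy(moved, p), e0, tolerance = 1e-10)
  # relabeling symmetry
  expect_equal(steric_energy(pos[10:1, ], p), e0, tolerance = 1e-10)
})

test_that("elastic energy vanishes at the ground state and scales quadratically", {
  set.seed(41)
  lens <- sample(10:60, 5, replace = TRUE)
  gs <- ground_state_chain(lens)
  expect_lt(max(abs(elastic_energy(gs))), 1e-10)
  # quadratic scaling: doubling a small displacement quadruples the energy
  d1 <- d2 <- gs
  d1$nuc_pos[3, 1] <- d1$nuc_pos[3, 1] + 0.01
  d2$nuc_pos[3, 1] <- d2$nuc_pos[3, 1] + 0.02
  e1 <- sum(elastic_energy(d1))
  e2 <- sum(elastic_energy(d2))
  expect_equal(e2 / e1, 4, tolerance = 0.05)
  expect_error(elastic_energy(gs, linker_index = 9), "out of range")
})

test_that("R and compiled elastic evaluations agree with a reference form", {
  set.seed(42)
  cfg <- grow_chain(sample(5:60, 14, replace = TRUE), seed = 43)
  eR <- elastic_energy(cfg)
  eC <- nucleoclust:::.elastic_bonds_cpp(
    cfg$nuc_pos, cfg$nuc_tri, cfg$linkers, cfg$geom$translation,
    as.numeric(t(cfg$geom$rotation)), 50, 100, 0.332, 2 * pi / 10.5, 90)
  expect_equal(eR, eC, tolerance = 1e-10)
  # independently coded quadratic form agrees on a perturbed 2-nucleosome system
  gs <- ground_state_chain(30L)
  gs$nuc_pos[2, ] <- gs$nuc_pos[2, ] + c(0.4, -0.2, 0.3)
  Rp <- nucleoclust:::rotation_about_axis(c(0, 1, 0), 0.1)
  Q <- matrix(gs$nuc_tri[2, ], 3, 3, byrow = TRUE)
  gs$nuc_tri[2, ] <- as.numeric(t(Rp %*% Q))
  want <- reference_bond_energy(gs$nuc_pos[1, ], gs$nuc_tri[1, ],
                                gs$nuc_pos[2, ], gs$nuc_tri[2, ], 30L,
                                gs$geom)
  expect_equal(elastic_energy(gs), want, tolerance = 1e-10)
  expect_gt(want, 0)
})

test_that("proposed moves respect their geometric contracts", {
  cfg <- grow_chain(rep(30L, 19), seed = 44)
  # zero amplitude leaves the configuration untouched
  mp0 <- move_params(amp_crank = 0, amp_pivot = 0, amp_single_t = 0,
                     amp_single_r = 0)
  tr <- propose_move(cfg, mp0, seed = 1)
  expect_equal(tr$config$nuc_pos, cfg$nuc_pos, tolerance = 1e-12)
  expect_equal(tr$config$nuc_tri, cfg$nuc_tri, tolerance = 1e-12)
  # crankshaft preserves both anchors
  mp_crank <- move_params(probs = c(1, 0, 0))
  tr <- propose_move(cfg, mp_crank, seed = 2)
  expect_identical(tr$type, "crank")
  expect_equal(tr$config$nuc_pos[tr$anchors, ], cfg$nuc_pos[tr$anchors, ],
               tolerance = 1e-12)
  # move + inverse move restores coordinates
  moved <- tr$moved[1]:tr$moved[2]
  undone <- nucleoclust:::apply_rigid(tr$config, moved, t(tr$rotation), tr$pivot)
  expect_equal(undone$nuc_pos, cfg$nuc_pos, tolerance = 1e-9)
  expect_equal(undone$nuc_tri, cfg$nuc_tri, tolerance = 1e-9)
})

test_that("relaxation bookkeeping matches full energy recomputation", {
  cfg <- grow_chain(sample(5:50, 29, replace = TRUE), seed = 45)
  state <- cfg
  for (chunk in 1:3) {
    r <- relax(state, n_steps = 1000, seed = 50 + chunk, trace_every = 0)
    expect_lt(abs(r$elastic_total - sum(elastic_energy(r$config))), 1e-8)
    expect_lt(abs(r$steric_total - steric_energy(r$config)), 1e-8)
    state <- r$config
  }
})

test_that("two-nucleosome Metropolis sampling matches direct Boltzmann draws", {
  # translation-only moves with frozen orientations: the bond vector r then
  # has stationary density exp(-E(r)) with E = (lp/L) theta^2 +
  # (ks/2)(|r| - L)^2, so cos(theta) and |r| have closed-form marginals that
  # can be sampled directly by rejection.
  l_bp <- 45L
  gs <- ground_state_chain(l_bp)
  el <- elastic_model()
  L <- l_bp * el$L1
  ks <- el$stretch_scale * el$lp^2 / L^4
  mp <- move_params(probs = c(0, 0, 1), amp_single_t = 1.2, amp_single_r = 0)
  # collect a thinned trajectory (100 steps between samples decorrelates the
  # two translational degrees of freedom at this amplitude)
  set.seed(78)
  n_samp <- 2500
  us <- rs <- numeric(n_samp)
  state <- gs
  for (i in seq_len(n_samp)) {
    out <- relax(state, el, steric_params(V0 = 1e-12), n_steps = 100,
                 seed = NULL, mp = mp, trace_every = 0)
    state <- out$config
    p_out <- state$nuc_pos[1, ] +
      as.numeric(matrix(state$nuc_tri[1, ], 3, 3, byrow = TRUE) %*%
                   state$geom$translation)
    F_out <- matrix(state$nuc_tri[1, ], 3, 3, byrow = TRUE) %*%
      state$geom$rotation
    v <- state$nuc_pos[2, ] - p_out
    rs[i] <- sqrt(sum(v^2))
    us[i] <- sum(v / rs[i] * F_out[, 3])
  }
  # direct Boltzmann reference by rejection sampling
  ref_u <- local({
    out <- numeric(0)
    while (length(out) < 20000) {
      cand <- runif(40000, -1, 1)
      keep <- runif(40000) < exp(-(el$lp / L) * acos(cand)^2)
      out <- c(out, cand[keep])
    }
    out[1:20000]
  })
  ref_r <- local({
    out <- numeric(0)
    rmax <- L + 4 / sqrt(ks)
    while (length(out) < 20000) {
      cand <- rnorm(40000, L, 1 / sqrt(ks))
      keep <- cand > 0 & runif(40000) < (cand / rmax)^2
      out <- c(out, cand[keep])
    }
    out[1:20000]
  })
  keep <- 101:n_samp # discard burn-in from the ground-state start
  us <- us[keep]
  rs <- rs[keep]
  qs <- seq(0.1, 0.9, by = 0.2)
  expect_lt(max(abs(quantile(us, qs) - quantile(ref_u, qs))), 0.03)
  expect_lt(max(abs(quantile(rs, qs) - quantile(ref_r, qs))), 0.06)
  breaks_u <- c(-1, quantile(ref_u, seq(0.125, 0.875, by = 0.125)), 1)
  obs <- table(cut(us, breaks_u))
  expect_gt(chisq.test(obs, p = rep(1 / 8, 8))$p.value, 0.01)
})

test_that("relaxation relieves deliberate steric overlaps", {
  # compress a grown fiber to force overlaps, then relax
  set.seed(60)
  cfg <- grow_chain(sample(15:40, 39, replace = TRUE), seed = 61)
  squeezed <- cfg
  squeezed$nuc_pos <- cfg$nuc_pos * 0.25
  before <- count_overlaps(squeezed)
  expect_gt(before, 0)
  r <- relax(squeezed, n_steps = 30000, seed = 62, trace_every = 0)
  after <- count_overlaps(r$config)
  expect_lt(after, before)
})
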