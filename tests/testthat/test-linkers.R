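test_that("linker parameters derive lambda and z from the mean length", {
  lp <- linker_params(l0 = 45)
  expect_equal(lp$lambda, -log(1 - 1 / 45))
  expect_equal(lp$z, 1 - 1 / 45)
  expect_error(linker_params(l0 = 1), "exceed 1")
  expect_error(linker_params(l0 = 45, l_c = 0), "l_c")
})

test_that("the interaction-free distribution is geometric with mean l0", {
  d <- linker_distribution(0, linker_params())
  l <- 1:400
  expect_equal(dlinker(l, d), (1 / 45) * (44 / 45)^(l - 1), tolerance = 1e-12)
  # closed-form tail: total mass is exactly 1
  z <- d$z
  expect_equal(sum(dlinker(1:3000, d)) + z^3000 / (1 - z) / d$N, 1,
               tolerance = 1e-12)
  expect_equal(d$p_short, 1 - (44 / 45)^15, tolerance = 1e-12)
})

test_that("any finite delta_phi yields a normalized two-branch law", {
  for (dphi in c(-8, -2, -0.3, 0)) {
    d <- linker_distribution(dphi, linker_params())
    z <- d$z
    total <- sum(dlinker(1:5000, d)) + z^5000 / (1 - z) / d$N
    expect_equal(total, 1, tolerance = 1e-12)
  }
  # strongly negative delta_phi concentrates all mass below the cutoff
  d <- linker_distribution(-40, linker_params())
  expect_gt(d$p_short, 1 - 1e-10)
})

test_that("inverse-CDF sampling reproduces the analytic law", {
  d0 <- linker_distribution(0, linker_params())
  x <- sample_linker(d0, 1e6, seed = 7)
  expect_true(all(x >= 1))
  expect_lt(abs(mean(x) - 45), 0.5)
  d <- linker_distribution(-10, linker_params())
  y <- sample_linker(d, 1e6, seed = 8)
  expect_lt(abs(mean(y <= 15) - d$p_short), 0.002)
  expect_true(all(y >= 1))
})

test_that("delta_free_energy is non-positive and vanishes without coupling", {
  s <- c(2L, 2L, 2L, 0L)
  gamma <- c(1L, 1L, 0L, 1L)
  # J = 0 decouples gamma from the partition function entirely
  pJ0 <- binding_params(J_int = 0, mu_hp1 = -9.7)
  expect_equal(delta_free_energy(2, s, gamma, pJ0), 0, tolerance = 1e-10)
  # empty reservoir: no HP1 bound, interactions irrelevant
  pmu <- binding_params(mu_hp1 = -60)
  expect_lt(abs(delta_free_energy(2, s, gamma, pmu)), 1e-10)
  # generally non-positive
  set.seed(31)
  for (r in 1:8) {
    M <- sample(3:7, 1)
    s2 <- sample(0:2, M, replace = TRUE)
    g2 <- sample(0:1, M, replace = TRUE)
    p <- random_binding_params()
    for (i in seq_len(M)) {
      expect_lte(delta_free_energy(i, s2, g2, p), 1e-12)
    }
  }
  expect_error(delta_free_energy(9, s, gamma), "out of range")
})

test_that("delta_free_energy matches the enumeration oracle", {
  p <- binding_params(mu_hp1 = -9.7)
  s <- rep(2L, 4)
  gamma <- rep(1L, 4)
  for (i in 1:4) {
    g1 <- gamma; g1[i] <- 1L
    g0 <- gamma; g0[i] <- 0L
    want <- enum_ensemble(s, g1, p)$Phi - enum_ensemble(s, g0, p)$Phi
    got <- delta_free_energy(i, s, gamma, p)
    expect_lt(abs(got - want) / max(1e-12, abs(want)), 1e-10)
  }
})

test_that("the sampler is deterministic given a seed", {
  pat <- generate_marks(60, 0.2, 5, seed = 2, check_size = FALSE)
  a <- run_sampler(pat, n_sweeps = 20, seed = 5)
  b <- run_sampler(pat, n_sweeps = 20, seed = 5)
  expect_identical(a$lengths, b$lengths)
  expect_identical(a$trace, b$trace)
  c <- run_sampler(pat, n_sweeps = 20, seed = 6)
  expect_false(identical(a$lengths, c$lengths))
})

test_that("gamma indicators always match the 15-bp cutoff", {
  pat <- generate_marks(100, 0.3, 5, seed = 3, check_size = FALSE)
  st <- run_sampler(pat, binding_params(mu_hp1 = -9.6), n_sweeps = 30,
                    seed = 4)
  expect_identical(st$gamma, as.integer(st$lengths <= 15))
  expect_true(all(st$lengths >= 1))
})

test_that("without coupling the stationary law is the bare geometric", {
  pat <- generate_marks(1000, 0.5, 5, seed = 6, check_size = FALSE)
  st <- run_sampler(pat, binding_params(J_int = 0, mu_hp1 = -9.7),
                    n_sweeps = 100, seed = 7, record_gamma = FALSE)
  # pool the final sweeps' linker lengths; each is an exact conditional
  # draw, which at J = 0 is the unconditional geometric law
  draws <- st$lengths
  for (k in 1:49) {
    st <- run_sampler(pat, binding_params(J_int = 0, mu_hp1 = -9.7),
                      n_sweeps = 1, seed = 100 + k, init = st)
    draws <- c(draws, st$lengths)
  }
  emp <- stats::ecdf(draws)
  l <- 1:400
  ks <- max(abs(emp(l) - (1 - (44 / 45)^l)))
  expect_lt(ks, 0.01)
})

test_that("marking and chemical potential raise the short-linker fraction", {
  M <- 500
  unmarked <- as_epigenetic_pattern(rep(0L, M))
  marked <- as_epigenetic_pattern(rep(2L, M))
  lo <- run_sampler(unmarked, binding_params(mu_hp1 = -9.8), n_sweeps = 80,
                    seed = 11)
  hi <- run_sampler(marked, binding_params(mu_hp1 = -9.6), n_sweeps = 80,
                    seed = 11)
  f_lo <- mean(lo$trace[41:80])
  f_hi <- mean(hi$trace[41:80])
  # baseline is the interaction-free branch mass
  expect_lt(abs(f_lo - (1 - (44 / 45)^15)), 0.05)
  expect_gt(f_hi, f_lo)
})

test_that("convergence diagnostics flag settled traces", {
  expect_false(sampler_converged(rep(0.3, 20)))
  expect_true(sampler_converged(rep(0.3, 80)))
  trend <- seq(0.1, 0.9, length.out = 80)
  expect_false(sampler_converged(trend))
})

test_that("linker states serialize to CSV", {
  pat <- generate_marks(50, 0.2, 5, seed = 8, check_size = FALSE)
  st <- run_sampler(pat, n_sweeps = 5, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_linker_state(st, path, pattern = pat)
  df <- read.csv(path)
  expect_identical(df$l, st$lengths)
  expect_identical(df$s, pat$s)
})
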