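test_that("binding free energy reproduces the five branches", {
  p <- binding_params(mu_hp1 = -9.7)
  # unbound nucleosomes carry no free energy, whatever their marks
  expect_equal(binding_free_energy(0:2, c(0, 0, 0), p), rep(0, 3))
  expect_equal(binding_free_energy(0, 1, p), 9.7 - log(2))
  expect_equal(binding_free_energy(1, 1, p), 9.7 - log(1 + exp(1.5)))
  expect_equal(binding_free_energy(2, 1, p), 9.7 - 1.5 - log(2))
  expect_equal(binding_free_energy(2, 2, p), 19.4 - 3.0 - 3.92)
  expect_equal(binding_free_energy(0, 2, p), 19.4 - 3.92)
  expect_error(binding_free_energy(3, 1, p), "integers")
  expect_error(binding_free_energy(1, -1, p), "integers")
})

test_that("printed defaults are preserved exactly", {
  p <- binding_params()
  expect_identical(p$eps_m, -1.5)
  expect_identical(p$J_int, -3.92)
  expect_identical(p$l_c, 15L)
})

test_that("pair interaction follows J * gamma * sigma_i * sigma_j", {
  p <- binding_params()
  expect_equal(interaction_free_energy(2, 2, 1, p), -15.68)
  expect_equal(interaction_free_energy(2, 2, 0, p), 0)
  expect_equal(interaction_free_energy(0, 2, 1, p), 0)
  expect_equal(interaction_free_energy(1, 2, 1, p), 2 * -3.92)
})

test_that("transfer matrix composes the half-site and bond weights", {
  p <- binding_params(mu_hp1 = -9.7)
  Tm <- transfer_matrix(2, 2, 1, p)
  expect_equal(dim(Tm), c(3, 3))
  expect_true(all(Tm > 0))
  # phi_bind(0) = 0 and phi_int(0, .) = 0 force entry (0,0) = 1
  expect_equal(Tm["0", "0"], 1)
  expect_equal(Tm["2", "2"], exp(-12.48 + 15.68))
  # without an interaction the matrix factorizes into an outer product
  T0 <- transfer_matrix(0, 0, 0, p)
  expect_equal(qr(T0)$rank, 1)
  h <- exp(-binding_free_energy(0, 0:2, p) / 2)
  expect_equal(unname(T0), outer(h, h))
})

test_that("transfer-matrix evaluation matches exhaustive enumeration", {
  p <- binding_params(mu_hp1 = -9.7)
  # non-interacting array
  o <- enum_ensemble(rep(0L, 4), rep(0L, 4), p)
  tm <- evaluate_ensemble(rep(0L, 4), rep(0L, 4), p)
  expect_lt(abs(tm$log_xi - o$log_xi) / abs(o$log_xi), 1e-10)
  # mixed marks, fully interacting
  s <- c(2L, 2L, 0L, 1L, 0L)
  o <- enum_ensemble(s, rep(1L, 5), p)
  tm <- evaluate_ensemble(s, rep(1L, 5), p)
  expect_lt(abs(tm$log_xi - o$log_xi) / abs(o$log_xi), 1e-10)
  expect_lt(max(abs(tm$occupancy - o$occupancy)), 1e-10)
  expect_equal(tm$Phi, -tm$log_xi)
})

test_that("randomized small systems agree with enumeration", {
  set.seed(20)
  for (rep in 1:12) {
    M <- sample(2:6, 1)
    s <- sample(0:2, M, replace = TRUE)
    gamma <- sample(0:1, M, replace = TRUE)
    p <- random_binding_params()
    o <- enum_ensemble(s, gamma, p)
    tm <- evaluate_ensemble(s, gamma, p)
    expect_lt(abs(tm$log_xi - o$log_xi) /
                max(1e-12, abs(o$log_xi)), 1e-10)
    expect_lt(max(abs(tm$occupancy - o$occupancy)), 1e-10)
    expect_true(all(tm$occupancy >= 0 & tm$occupancy <= 2))
  }
})

test_that("cyclic rotation leaves Phi invariant and permutes occupancies", {
  set.seed(21)
  s <- sample(0:2, 8, replace = TRUE)
  gamma <- sample(0:1, 8, replace = TRUE)
  p <- binding_params(mu_hp1 = -7)
  base <- evaluate_ensemble(s, gamma, p)
  for (k in c(1, 3)) {
    rot <- function(x) c(x[-seq_len(k)], x[seq_len(k)])
    r <- evaluate_ensemble(rot(s), rot(gamma), p)
    expect_equal(r$Phi, base$Phi, tolerance = 1e-10)
    expect_equal(r$occupancy, rot(base$occupancy), tolerance = 1e-10)
  }
})

test_that("occupancy is monotone in chemical potential and in marking", {
  set.seed(22)
  s <- sample(0:2, 30, replace = TRUE)
  gamma <- rep(1L, 30)
  mus <- seq(-11, -6, by = 0.5)
  occ <- sapply(mus, function(mu) {
    evaluate_ensemble(s, gamma, binding_params(mu_hp1 = mu))$occupancy
  })
  expect_true(all(diff(t(occ)) >= -1e-12))
  # fully marked nucleosomes bind at least as much as unmarked ones
  one <- evaluate_ensemble(s, gamma, binding_params(mu_hp1 = -9.6))$occupancy
  if (any(s == 2) && any(s == 0)) {
    expect_gte(min(one[s == 2]), max(one[s == 0]))
  }
})

test_that("the unbound limit empties the array", {
  s <- c(2L, 2L, 1L, 0L)
  r <- evaluate_ensemble(s, rep(1L, 4), binding_params(mu_hp1 = -60))
  expect_lt(max(r$occupancy), 1e-10)
  expect_lt(abs(r$Phi), 1e-10)
})

test_that("ensemble evaluation validates its inputs", {
  expect_error(evaluate_ensemble(c(0L, 1L), c(1L, 0L, 1L)), "one indicator")
  expect_error(evaluate_ensemble(c(0L, 3L), c(1L, 0L)), "integers")
})
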