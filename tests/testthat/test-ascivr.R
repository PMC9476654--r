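test_that("switching function satisfies the adiabatic endpoint conditions", {
  T <- 25000
  expect_equal(switching_lambda(0, T), 0)
  expect_equal(switching_lambda(T, T), 1)
  h <- 1e-3
  expect_lt(abs(switching_lambda(h, T) - switching_lambda(0, T)) / h, 1e-9)
  expect_lt(abs(switching_lambda(T, T) - switching_lambda(T - h, T)) / h, 1e-9)
  t <- seq(0, T, length.out = 101)
  expect_true(all(diff(switching_lambda(t, T)) >= 0))   # monotone switch-on
})

test_that("shell conditions sit exactly on the harmonic ZPE shell", {
  omega_cm1 <- c(420, 800, 1500)
  omega <- convert_energy(omega_cm1, "cm1", "hartree")
  ics <- harmonic_shell_conditions(omega_cm1, 400, seed = 61)
  e_mode <- ics$p^2 / 2 + omega^2 * ics$q^2 / 2
  expect_equal(e_mode, matrix(omega / 2, 3, 400), tolerance = 1e-12)
  # phase-averaged <q^2> matches hbar/(2 omega)
  big <- harmonic_shell_conditions(500, 20000, seed = 62)
  expect_equal(mean(big$q^2), 1 / (2 * convert_energy(500, "cm1", "hartree")),
               tolerance = 0.02)
  expect_identical(harmonic_shell_conditions(500, 7, seed = 9),
                   harmonic_shell_conditions(500, 7, seed = 9))
  expect_error(harmonic_shell_conditions(c(500, -30), 5), "quantized")
})

test_that("coherent-state overlap matches the quadrature oracle and its limits", {
  gamma <- 0.002
  expect_equal(abs(coherent_overlap(0.1, 1, 0.1, 1, gamma)), 1, tolerance = 1e-12)
  set.seed(63)
  for (rep in 1:8) {
    p1 <- rnorm(1, sd = 0.05); q1 <- rnorm(1, sd = 4)
    p2 <- rnorm(1, sd = 0.05); q2 <- rnorm(1, sd = 4)
    expect_equal(coherent_overlap(p1, q1, p2, q2, gamma),
                 quad_coherent_overlap(p1, q1, p2, q2, gamma),
                 tolerance = 1e-8)
  }
  # 1-D modulus decay law
  dq <- 2.5; dp <- 0.03
  expect_equal(abs(coherent_overlap(0, 0, dp, dq, gamma)),
               exp(-gamma * dq^2 / 4 - dp^2 / (4 * gamma)), tolerance = 1e-12)
  expect_error(coherent_overlap(0, 0, 0, 0, -1), "positive")
})

test_that("harmonic propagation is exact: unit determinant, linear HK phase, exact peak", {
  omega_cm1 <- 500
  omega <- convert_energy(omega_cm1, "cm1", "hartree")
  pes <- harmonic_nd(omega_cm1)
  conf <- as_config(t_switch = 2000, t_sc = 25000, step = 10, n_traj = 6,
                    seed = 64)
  sc <- run_ascivr(pes, omega_cm1, conf)
  expect_equal(sc$rejection_rate, 0)
  expect_equal(sc$zpe_cm1, omega_cm1 / 2, tolerance = 0.5)
  for (tr in sc$trajectories) {
    expect_lt(tr$det_err, 1e-8)   # symplectic integrator on a linear system
    expect_equal(tr$hk_phase, -omega * tr$times / 2, tolerance = 1e-4)
  }
  # switching between identical Hamiltonians preserves the shell energy
  ics <- harmonic_shell_conditions(omega_cm1, 4, seed = 65)
  for (k in 1:4) {
    sw <- adiabatic_switch(pes, omega_cm1, ics$p[, k], ics$q[, k], conf)
    expect_equal(convert_energy(sw$energy, "hartree", "cm1"), omega_cm1 / 2,
                 tolerance = 1e-6)
  }
})

test_that("adiabatic switching relaxes the shell toward the true quantized energy", {
  m <- 1800
  mo <- morse_potential(De = 0.02, a = 1.0, mass = m)
  mw <- make_potential(function(y) mo$value(y / sqrt(m)),
                       grad = function(y) mo$grad(y / sqrt(m)) / sqrt(m),
                       hess = function(y) mo$hess(y / sqrt(m)) / m, dim = 1)
  e0 <- morse_levels(mo)[1L]
  conf <- as_config(t_switch = 8000, step = 10)
  ics <- harmonic_shell_conditions(mo$omega_cm1, 16, seed = 66)
  es <- vapply(1:16, function(k) {
    adiabatic_switch(mw, mo$omega_cm1, ics$p[, k], ics$q[, k], conf)$energy
  }, 0)
  e_mean <- convert_energy(mean(es), "hartree", "cm1")
  expect_lt(abs(e_mean - e0), abs(e_mean - mo$omega_cm1 / 2))
  expect_lt(abs(e_mean - e0), 5)
  # reversing the switch returns to the harmonic shell within adiabatic error
  sw <- adiabatic_switch(mw, mo$omega_cm1, ics$p[, 1L], ics$q[, 1L], conf)
  sw_back <- adiabatic_switch(mw, mo$omega_cm1, sw$p, sw$q, conf,
                              reverse = TRUE)
  expect_lt(abs(convert_energy(sw_back$energy, "hartree", "cm1") -
                  mo$omega_cm1 / 2), 12)
})

test_that("Morse spectral density peaks at the analytic ground state", {
  m <- 1800
  mo <- morse_potential(De = 0.02, a = 1.0, mass = m)
  mw <- make_potential(function(y) mo$value(y / sqrt(m)),
                       grad = function(y) mo$grad(y / sqrt(m)) / sqrt(m),
                       hess = function(y) mo$hess(y / sqrt(m)) / m, dim = 1)
  lv <- morse_levels(mo)
  sc <- run_ascivr(mw, mo$omega_cm1,
                   as_config(t_switch = 6000, t_sc = 50000, step = 10,
                             n_traj = 10, seed = 67),
                   energy_grid_cm1 = seq(0, 2200, by = 1))
  expect_lt(abs(sc$zpe_cm1 - lv[1L]), 5)
  # trajectories from a hotter shell expose the first excited level near E1
  ics <- harmonic_shell_conditions(mo$omega_cm1, 10, seed = 68)
  conf <- as_config(t_switch = 6000, t_sc = 50000, step = 10, n_traj = 10,
                    seed = 68)
  gam <- convert_energy(mo$omega_cm1, "cm1", "hartree")
  trajs <- lapply(1:10, function(k) {
    propagate_semiclassical(mw, sqrt(3) * ics$p[, k], sqrt(3) * ics$q[, k],
                            gam, conf)
  })
  dens <- spectral_density(trajs, seq(0, 2500, by = 1))
  expect_true(any(abs(dens$peaks_cm1 - lv[2L]) < 30))
})

test_that("2-D separable spectrum shows the ZPE and even combination peaks", {
  freqs <- c(500, 920)
  pes <- harmonic_nd(freqs)
  sc <- run_ascivr(pes, freqs,
                   as_config(t_switch = 2000, t_sc = 30000, step = 10,
                             n_traj = 8, seed = 69))
  expect_equal(sc$zpe_cm1, sum(freqs) / 2, tolerance = 0.5)
  # fundamentals appear at quantized offsets ZPE + omega_k
  expect_true(any(abs(sc$density$peaks_cm1 - (710 + 500)) < 5))
  expect_true(any(abs(sc$density$peaks_cm1 - (710 + 920)) < 5))
})

test_that("chaotic coupled fixture rejects trajectories; energy is conserved on smooth ones", {
  # Henon-Heiles-type cubic coupling scaled to the mass-weighted amplitudes
  om <- convert_energy(c(700, 950), "cm1", "hartree")
  lam <- 1e-7
  chaotic <- make_potential(
    function(y) sum(om^2 * y^2) / 2 + lam * (y[1L]^2 * y[2L] - y[2L]^3 / 3),
    grad = function(y) c(om[1L]^2 * y[1L] + 2 * lam * y[1L] * y[2L],
                         om[2L]^2 * y[2L] + lam * (y[1L]^2 - y[2L]^2)),
    hess = function(y) matrix(c(om[1L]^2 + 2 * lam * y[2L], 2 * lam * y[1L],
                                2 * lam * y[1L], om[2L]^2 - 2 * lam * y[2L]),
                              2), dim = 2)
  ics <- harmonic_shell_conditions(c(700, 950), 10, seed = 70)
  conf <- as_config(t_switch = 1000, t_sc = 30000, step = 10, n_traj = 10,
                    det_tol = 0.01, seed = 70)
  gam <- convert_energy(c(700, 950), "cm1", "hartree")
  # hot initial conditions (3x the shell amplitude) drive the chaotic region
  trajs <- lapply(1:10, function(k) {
    propagate_semiclassical(chaotic, 3 * ics$p[, k], 3 * ics$q[, k], gam, conf)
  })
  n_rej <- sum(vapply(trajs, function(tr) tr$rejected, TRUE))
  expect_gt(n_rej, 0L)
  expect_lt(n_rej, 10L)
  # a cold, regular trajectory of the same system conserves energy tightly
  tr <- propagate_semiclassical(chaotic, 0.3 * ics$p[, 1L], 0.3 * ics$q[, 1L],
                                gam, conf)
  expect_false(tr$rejected)
  e_end <- sum(tr$p_final^2) / 2 + chaotic$value(tr$q_final)
  expect_lt(abs(e_end - tr$energy) / tr$energy, 1e-6)
})
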