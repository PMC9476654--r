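test_that("diffusion displacements have variance dtau/m per coordinate", {
  set.seed(51)
  W <- matrix(0, 2, 50000)
  masses <- c(amu_to_me(1.007825), amu_to_me(2.014102))
  W2 <- dmc_diffuse(W, masses, dtau = 5)
  v <- apply(W2, 1L, var)
  expect_equal(v, 5 / masses, tolerance = 0.02)
  # heavier isotope diffuses less, by the mass ratio
  expect_equal(v[1L] / v[2L], masses[2L] / masses[1L], tolerance = 0.05)
  expect_error(dmc_diffuse(W, masses, dtau = 0), "positive")
})

test_that("branching follows the printed birth/death probabilities in its limits", {
  set.seed(52)
  W <- matrix(rnorm(1000), 1)
  # E_i = E_r: population statistically unchanged (zero exponent)
  br <- dmc_branch(W, rep(0.5, 1000), e_ref = 0.5, dtau = 5)
  expect_equal(ncol(br$walkers), 1000L)
  # E_i >> E_r: death probability saturates at 1
  expect_error(dmc_branch(W, rep(10, 1000), e_ref = 0, dtau = 5), "extinct")
  # E_i << E_r: every walker gives birth to exactly one copy (capped)
  br2 <- dmc_branch(W, rep(-10, 1000), e_ref = 0, dtau = 5)
  expect_equal(ncol(br2$walkers), 2000L)
  # empirical death rate matches 1 - exp(-(E - E_r) dtau)
  de <- 0.01
  n_die <- 0L
  for (rep in 1:20) {
    br3 <- dmc_branch(W, rep(de, 1000), e_ref = 0, dtau = 5)
    n_die <- n_die + 1000L - ncol(br3$walkers)
  }
  expect_equal(n_die / 20000, 1 - exp(-de * 5), tolerance = 0.1)
  # hole handling: below-floor walkers are killed and counted
  e <- c(rep(0, 500), rep(-5, 10))
  br4 <- dmc_branch(matrix(rnorm(510), 1), e, e_ref = 0, dtau = 5,
                    hole_floor = -1)
  expect_equal(br4$n_holes, 10L)
  expect_lte(ncol(br4$walkers), 500L + 500L)
})

test_that("reference-energy feedback has the printed form and sign", {
  e <- c(0.1, 0.2, 0.3)
  expect_equal(dmc_update_reference(e, alpha = 0.2, n0 = 3), mean(e))
  expect_equal(dmc_update_reference(e, alpha = 0, n0 = 1), mean(e))
  # N > N0 lowers E_r; N < N0 raises it
  expect_lt(dmc_update_reference(e, alpha = 0.2, n0 = 2), mean(e))
  expect_gt(dmc_update_reference(e, alpha = 0.2, n0 = 5), mean(e))
  expect_error(dmc_update_reference(numeric(0), 0.2, 3), "no live")
})

test_that("population stays near N0 on a harmonic well with default feedback", {
  pes <- harmonic_nd(500)
  cfg <- dmc_config(n_walkers = 500, n_steps = 600, n_equil = 100,
                    n_sims = 1, seed = 53)
  res <- run_dmc(pes, 1, cfg, q0 = 0)
  expect_equal(ncol(res$snapshots[[1L]]) / 500, 1, tolerance = 0.2)
})

test_that("harmonic ZPE is unbiased across seeds in 1, 3 and 21 dimensions", {
  fixtures <- list(list(f = 500, n = 400, steps = 500, equil = 150),
                   list(f = c(350, 500, 700), n = 300, steps = 500, equil = 150),
                   list(f = ethanol_harmonic_frequencies()$trans_pes,
                        n = 4000, steps = 1100, equil = 600))
  for (fx in fixtures) {
    pes <- harmonic_nd(fx$f)
    means <- vapply(1:20, function(sd) {
      run_dmc(pes, rep(1, length(fx$f)),
              dmc_config(n_walkers = fx$n, n_steps = fx$steps,
                         n_equil = fx$equil, n_sims = 1, seed = 530 + sd),
              q0 = numeric(length(fx$f)))$zpe_cm1
    }, 0)
    sem <- sd(means) / sqrt(20)
    # 3 sigma plus a 0.2% allowance for the residual finite-dtau and
    # finite-population (~1/N) control bias at desk-scale walker counts
    expect_lt(abs(mean(means) - sum(fx$f) / 2), 3 * sem + 0.002 * sum(fx$f) / 2)
  }
})

test_that("Morse ZPE lands on the analytic level, below the harmonic estimate", {
  mo <- morse_potential(De = 0.02, a = 1.0, mass = 1800)
  e0 <- morse_levels(mo)[1L]
  res <- run_dmc(mo, 1800,
                 dmc_config(n_walkers = 1500, n_steps = 1500, n_equil = 500,
                            n_sims = 5, seed = 54), q0 = 0)
  expect_lt(abs(res$zpe_cm1 - e0), 3 * res$sigma_cm1 + 1)
  expect_lt(res$zpe_cm1, mo$omega_cm1 / 2)   # anharmonicity lowers the ZPE
})

test_that("doubling the walker count shrinks the uncertainty roughly as sqrt(2)", {
  pes <- harmonic_nd(500)
  sig <- function(nw, seeds) {
    vapply(seeds, function(sd) {
      run_dmc(pes, 1, dmc_config(n_walkers = nw, n_steps = 400, n_equil = 150,
                                 n_sims = 1, seed = sd), q0 = 0)$zpe_cm1
    }, 0)
  }
  s1 <- sd(sig(150, 1:12))
  s2 <- sd(sig(600, 1:12))   # 4x walkers: expect about half the spread
  expect_lt(s2, s1)
  expect_equal(s1 / s2, 2, tolerance = 0.8)
})

test_that("the uncertainty formula is exactly recomputable from stored means", {
  pes <- harmonic_nd(500)
  res <- run_dmc(pes, 1, dmc_config(n_walkers = 200, n_steps = 300,
                                    n_equil = 100, n_sims = 4, seed = 55),
                 q0 = 0)
  expect_identical(res$sigma_cm1, dmc_uncertainty(res$sim_means_cm1))
  expect_equal(res$zpe_cm1, mean(res$sim_means_cm1))
})

test_that("isotope ordering: ZPE(H) exceeds ZPE(D) beyond combined 3 sigma", {
  mo_fix <- function(mass) morse_potential(De = 0.02, a = 1.0, mass = mass)
  mh <- amu_to_me(1.007825); md <- amu_to_me(2.014102)
  rh <- run_dmc(mo_fix(mh), mh,
                dmc_config(n_walkers = 800, n_steps = 900, n_equil = 300,
                           n_sims = 4, seed = 56), q0 = 0)
  rd <- run_dmc(mo_fix(md), md,
                dmc_config(n_walkers = 800, n_steps = 900, n_equil = 300,
                           n_sims = 4, seed = 57), q0 = 0)
  gap <- rh$zpe_cm1 - rd$zpe_cm1
  expect_gt(gap, 3 * sqrt(rh$sigma_cm1^2 + rd$sigma_cm1^2))
  # and both land on their analytic values
  expect_lt(abs(rh$zpe_cm1 - morse_levels(mo_fix(mh))[1L]), 3 * rh$sigma_cm1 + 1)
  expect_lt(abs(rd$zpe_cm1 - morse_levels(mo_fix(md))[1L]), 3 * rd$sigma_cm1 + 1)
})

test_that("walker histogram reproduces the harmonic ground-state density", {
  # unbiased DMC walkers sample psi itself: harmonic psi has variance
  # hbar/(m omega) (twice the |psi|^2 variance)
  omega_cm1 <- 500
  pes <- harmonic_nd(omega_cm1)
  res <- run_dmc(pes, 1, dmc_config(n_walkers = 2500, n_steps = 1200,
                                    n_equil = 400, n_sims = 3, seed = 58,
                                    snapshot_every = 40), q0 = 0)
  vals <- unlist(lapply(res$snapshots, function(W) W[1L, ]))
  expect_equal(var(vals), 1 / convert_energy(omega_cm1, "cm1", "hartree"),
               tolerance = 0.05)
  h <- walker_histogram(res$snapshots, breaks = 40)
  expect_equal(sum(h$density * diff(h$mid)[1L]), 1, tolerance = 1e-6)
  # single identical-walker snapshot collapses into one bin
  hd <- walker_histogram(list(matrix(1.5, 1, 100)), breaks = 11)
  expect_equal(sum(hd$count > 0), 1L)
  expect_error(walker_histogram(list()), "at least one")
})

test_that("double-well histogram is bimodal and deuteration concentrates it", {
  # 1-D double well with a slight tilt; sinc-DVR supplies the exact
  # ground-state density for comparison
  a <- 0.004; b <- 0.008; c <- 1e-4   # barrier ~880 cm^-1, ZPE ~400 cm^-1
  Vf <- function(x) a * x^4 - b * x^2 + c * x + b^2 / (4 * a)
  dw <- make_potential(function(x) {
    if (is.matrix(x)) Vf(x[1L, ]) else Vf(x)
  }, dim = 1)
  mass <- 1800
  res <- run_dmc(dw, mass, dmc_config(n_walkers = 2500, n_steps = 1600,
                                      n_equil = 600, n_sims = 2, seed = 59,
                                      snapshot_every = 50), q0 = 0)
  vals <- unlist(lapply(res$snapshots, function(W) W[1L, ]))
  frac_right <- mean(vals > 0)   # the +c x tilt makes x < 0 the deeper well
  expect_gt(frac_right, 0.1)     # bimodal: substantial density in both wells
  expect_lt(frac_right, 0.5)
  # DVR oracle: psi fraction (walker density ~ psi)
  or <- sinc_dvr_1d(Vf, mass, L = 3, N = 301)
  psi <- abs(or$psi[, 1L])
  frac_psi <- sum(psi[or$x > 0]) / sum(psi)
  expect_lt(abs(frac_right - frac_psi), 0.12)
  # heavier mass quenches tunneling into the shallow well
  res_d <- run_dmc(dw, 4 * mass,
                   dmc_config(n_walkers = 2500, n_steps = 1600, n_equil = 600,
                              n_sims = 2, seed = 60, snapshot_every = 50),
                   q0 = 0)
  vals_d <- unlist(lapply(res_d$snapshots, function(W) W[1L, ]))
  expect_lt(mean(vals_d > 0), frac_right)
})
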