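test_that("harmonic oscillator oracle has the exact ZPE and a flat minimum", {
  pes <- harmonic_nd(2)
  expect_equal(pes$zpe_cm1, 1)
  expect_equal(pes$grad(0), 0, tolerance = 1e-12)
  freqs <- ethanol_harmonic_frequencies()$trans_pes
  pes21 <- harmonic_nd(freqs)
  expect_equal(pes21$zpe_cm1, sum(freqs) / 2)
  expect_equal(pes21$grad(numeric(21)), numeric(21), tolerance = 1e-12)
})

test_that("Morse level formula passes its closed-form identities", {
  mo <- morse_potential(De = 0.02, a = 1.0, mass = 1800)
  # De = omega^2 / (4 omega x_e)
  expect_equal(convert_energy(mo$De, "hartree", "cm1"),
               mo$omega_cm1^2 / (4 * mo$wexe_cm1), tolerance = 1e-10)
  lv <- morse_levels(mo)
  expect_length(lv, floor(mo$omega_cm1 / (2 * mo$wexe_cm1) - 0.5) + 1L)
  expect_true(all(diff(lv) > 0))
  # harmonic limit: small anharmonicity reproduces (n + 1/2) omega
  mo2 <- morse_potential(De = 50, a = 0.01, mass = 1800)
  lv2 <- morse_levels(mo2)[1:5]
  expect_equal(lv2, mo2$omega_cm1 * (0.5 + 0:4), tolerance = 1e-3)
})

test_that("constrained torsion model reproduces every printed stationary value", {
  model <- fixture_torsion_model()
  expect_lt(attr(model, "max_residual"), 0.5)
  to_rad <- pi / 180
  # symmetry invariants hold to machine precision on random angles
  set.seed(31)
  th <- runif(50, 0, 2 * pi); ph <- runif(50, 0, 2 * pi)
  expect_equal(torsion_eval(model, th + 2 * pi / 3, ph),
               torsion_eval(model, th, ph), tolerance = 1e-10)
  expect_equal(torsion_eval(model, -th, -ph),
               torsion_eval(model, th, ph), tolerance = 1e-10)
  # methyl barriers at trans and gauche
  expect_equal(cut_barrier(cut_1d(model, "ch3", 0))$barrier, 1208,
               tolerance = 1e-4)
  bg <- cut_barrier(cut_1d(model, "ch3", 120))
  expect_equal(bg$barrier, 1324, tolerance = 1e-4)
  expect_equal(bg$min, 38, tolerance = 1e-3)
  # methyl barriers at the isomerization saddles
  expect_equal(cut_barrier(cut_1d(model, "ch3", 60))$barrier, 1283,
               tolerance = 1e-3)
  expect_equal(cut_barrier(cut_1d(model, "ch3", 180))$barrier, 1404,
               tolerance = 1e-3)
  # hydroxyl path: trans 0, eclipsed 377, gauche 38, syn 472
  oh <- cut_1d(model, "oh", 0)
  expect_equal(oh(0), 0, tolerance = 1e-6)
  expect_equal(oh(60 * to_rad), 377, tolerance = 1e-4)
  expect_equal(oh(120 * to_rad), 38, tolerance = 1e-4)
  expect_equal(oh(pi), 472, tolerance = 1e-4)
  # stationarity at the constrained points
  for (pt in list(c(0, 60), c(0, 120), c(60, 60), c(60, 120))) {
    g <- torsion_grad(model, pt[1] * to_rad, pt[2] * to_rad)
    expect_lt(abs(g$d_theta), 1e-6)
  }
  g <- torsion_grad(model, 0, 120 * to_rad)
  expect_lt(abs(g$d_phi), 1e-6)
  # all-zero constraints give the identically zero surface
  zero <- fit_torsion2d(list(torsion_constraint(0, 0, 0),
                             torsion_constraint(60, 0, 0),
                             torsion_constraint(0, 120, 0, c("theta", "phi"))))
  expect_equal(max(abs(torsion_eval(zero, th, ph))), 0, tolerance = 1e-8)
  expect_equal(cut_1d(zero, "oh", 0)(th), numeric(50), tolerance = 1e-8)
})

test_that("the trans minimum is global and the gauche pair sits 38 above it", {
  model <- fixture_torsion_model()
  th <- seq(0, 2 * pi, length.out = 241)[-241]
  ph <- seq(0, 2 * pi, length.out = 241)[-241]
  V <- outer(th, ph, function(a, b) torsion_eval(model, a, b))
  expect_equal(min(V), 0, tolerance = 1e-3)
  # local minimization near (0, 120 deg)
  opt <- optim(c(0, 2 * pi / 3), function(x) torsion_eval(model, x[1], x[2]),
               method = "BFGS")
  expect_equal(opt$value, 38, tolerance = 1e-3)
})

test_that("minimum-barrier path is geared: axis-aligned runs through the low gates", {
  model <- fixture_torsion_model()
  mep <- minimum_energy_path(model, c(0, -120), c(360, 120),
                             n_theta = 121, n_phi = 81)
  # bottleneck equals the smallest constrained methyl saddle (1208), never
  # a straight diagonal over the high ridges (>= 1660)
  expect_lt(mep$max_energy, 1208 + 5)
  expect_gt(mep$max_energy, 1100)
  expect_true(all(mep$segments$axis %in% c("theta", "phi")))
  expect_gte(nrow(mep$segments), 3L)      # alternating runs, both axes used
  expect_setequal(unique(mep$segments$axis), c("theta", "phi"))
  # endpoints must be minima
  expect_error(minimum_energy_path(model, c(30, -120), c(360, 120)),
               "not a local minimum")
  # independent grid-search oracle for the bottleneck: brute threshold scan
  th <- seq(0, 2 * pi, length.out = 61)
  ph <- seq(-2 * pi / 3, 2 * pi / 3, length.out = 41)
  V <- outer(th, ph, function(a, b) torsion_eval(model, a, b))
  thresholds <- sort(unique(as.numeric(V)))
  conn <- function(thr) {
    ok <- V <= thr
    lab <- matrix(0L, nrow(V), ncol(V)); lab[1, 1] <- 1L
    repeat {
      new <- lab
      new[-1, ] <- pmax(new[-1, ], lab[-nrow(V), ])
      new[-nrow(V), ] <- pmax(new[-nrow(V), ], lab[-1, ])
      new[, -1] <- pmax(new[, -1], lab[, -ncol(V)])
      new[, -ncol(V)] <- pmax(new[, -ncol(V)], lab[, -1])
      new[!ok] <- 0L
      if (identical(new, lab)) break
      lab <- new
    }
    lab[nrow(V), ncol(V)] == 1L
  }
  oracle <- thresholds[which(vapply(thresholds, conn, TRUE))[1L]]
  expect_equal(mep$max_energy, oracle, tolerance = 0.02)
  # separable landscape degenerates to two independent axis moves
  cmat <- matrix(0, 3, 2)
  cmat[1, 1] <- 300; cmat[1, 2] <- -150; cmat[3, 1] <- -150
  sep <- torsion_model2d(cmat, matrix(0, 2, 1))   # 150(1-cos3t)+150(1-cos2p)
  mep2 <- minimum_energy_path(sep, c(0, 0), c(120, 180),
                              n_theta = 61, n_phi = 61)
  expect_lte(nrow(mep2$segments), 2L)
})

test_that("path energies are unimodal between adjacent stationary points", {
  model <- fixture_torsion_model()
  mep <- minimum_energy_path(model, c(0, 0), c(120, 0),
                             n_theta = 121, n_phi = 41)
  e <- mep$energies
  i_max <- which.max(e)
  expect_true(all(diff(e[1:i_max]) > -0.5))
  expect_true(all(diff(e[i_max:length(e)]) < 0.5))
})
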