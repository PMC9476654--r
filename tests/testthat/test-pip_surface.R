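test_that("Morse variables follow the definition and canonical ordering", {
  g <- geometry(c("H", "H"), c(0, 0, 0, 2, 0, 0))
  expect_equal(morse_variables(g, lambda = 2), exp(-1), tolerance = 1e-12)
  expect_error(morse_variables(g, lambda = -1), "positive")
  set.seed(21)
  g9 <- geometry(rep(c("H", "C", "O"), 3), rnorm(27, sd = 2))
  expect_length(morse_variables(g9), 36L)
  # coincident atoms give x = 1, not an error
  g0 <- geometry(c("H", "H"), numeric(6))
  expect_equal(morse_variables(g0), 1)
})

test_that("orbit counts match a brute-force enumeration and Burnside on small systems", {
  cases <- list(list(sig = c(2, 1), deg = 3), list(sig = c(3, 1), deg = 3),
                list(sig = c(2, 2), deg = 3), list(sig = c(4, 1), deg = 2),
                list(sig = c(3, 2), deg = 2), list(sig = c(2, 2, 2), deg = 2))
  for (cs in cases) {
    basis <- generate_pip_basis(cs$sig, cs$deg)
    expect_equal(basis$n_p, brute_orbit_count(cs$sig, cs$deg),
                 info = paste(paste(cs$sig, collapse = ""), cs$deg))
    expect_equal(basis$n_p, pip_orbit_count_burnside(cs$sig, cs$deg))
  }
  # two distinct atoms, degree 1: the constant and x12
  expect_equal(generate_pip_basis(c(1, 1), 1)$n_p, 2L)
})

test_that("every basis function is invariant under same-class permutations", {
  basis <- generate_pip_basis(c(3, 2), 3)
  labels <- c("H", "H", "H", "O", "O")
  set.seed(22)
  for (rep in 1:20) {
    x <- rnorm(15, sd = 2)
    g <- geometry(labels, x)
    perm3 <- sample(1:3); perm2 <- sample(4:5)
    xp <- x
    for (a in 1:3) xp[3 * (a - 1) + 1:3] <- x[3 * (perm3[a] - 1) + 1:3]
    for (a in 4:5) xp[3 * (a - 1) + 1:3] <- x[3 * (perm2[a - 3] - 1) + 1:3]
    gp <- geometry(labels, xp)
    expect_equal(pip_design(basis, list(gp))$A[1L, ],
                 pip_design(basis, list(g))$A[1L, ], tolerance = 1e-10)
  }
})

test_that("planted coefficients are recovered exactly from noiseless data", {
  basis <- generate_pip_basis(c(2, 1, 1), 2)
  labels <- c("H", "H", "O", "C")
  set.seed(23)
  coef_true <- rnorm(basis$n_p, sd = 0.01)
  geoms <- lapply(1:120, function(k) geometry(labels, rnorm(12, sd = 1.5)))
  A <- pip_design(basis, geoms)$A
  recs <- lapply(seq_along(geoms), function(k) {
    energy_record(geoms[[k]], sum(A[k, ] * coef_true))
  })
  fit <- fit_surface(basis, recs)
  expect_lt(fit$rmse_energy, 1e-8)
  expect_equal(fit$coefficients, coef_true, tolerance = 1e-6)
  expect_false(fit$rank_deficient)
  # underdetermined fit: zero residual, flagged minimum-norm
  fit2 <- fit_surface(basis, recs[1:10])
  expect_lt(fit2$rmse_energy, 1e-8)
  expect_true(fit2$rank_deficient)
})

test_that("analytic basis gradients agree with finite differences and help the fit", {
  basis <- generate_pip_basis(c(2, 1), 2)
  labels <- c("H", "H", "O")
  set.seed(24)
  g <- geometry(labels, rnorm(9, sd = 1.5))
  des <- pip_design(basis, list(g), gradients = TRUE)
  h <- 1e-6
  for (c in 1:9) {
    xp <- g$coords; xp[c] <- xp[c] + h
    xm <- g$coords; xm[c] <- xm[c] - h
    fd <- (pip_design(basis, list(geometry(labels, xp)))$A[1L, ] -
             pip_design(basis, list(geometry(labels, xm)))$A[1L, ]) / (2 * h)
    expect_equal(des$A[1L + c, ], fd, tolerance = 1e-6)
  }
  # gradient-including fit lowers the gradient test error on a real corpus
  mol <- make_model_molecule(c(2, 1), c("H", "O"), seed = 31)
  corpus <- sample_corpus(mol, 60, seed = 31)
  recs <- corpus_records(corpus, "high")
  b2 <- generate_pip_basis(c(2, 1), 3)
  fit_e <- fit_surface(b2, recs[1:40])
  fit_g <- fit_surface(b2, recs[1:40], use_gradients = TRUE)
  err_e <- evaluate_fit(fit_e, recs[41:60], gradients = TRUE)$rmse_gradient
  err_g <- evaluate_fit(fit_g, recs[41:60], gradients = TRUE)$rmse_gradient
  expect_lt(err_g, err_e)
})

test_that("correction fit recovers a planted low-order difference and composes exactly", {
  basis <- generate_pip_basis(c(2, 1, 1), 2)
  labels <- c("H", "H", "O", "C")
  set.seed(25)
  geoms <- lapply(1:100, function(k) geometry(labels, rnorm(12, sd = 1.2)))
  A <- pip_design(basis, geoms)$A
  low_e <- rnorm(100, sd = 0.05)
  delta_true <- as.numeric(A %*% rnorm(basis$n_p, sd = 0.002))
  low <- lapply(1:100, function(k) energy_record(geoms[[k]], low_e[k]))
  high <- lapply(1:100, function(k) energy_record(geoms[[k]], low_e[k] + delta_true[k],
                                                  tag = "high-level"))
  dfit <- fit_delta(basis, low, high)
  expect_lt(dfit$fit$rmse_energy, 1e-8)
  expect_equal(dfit$shift_hartree, min(delta_true), tolerance = 1e-12)
  # high = low exactly: the correction is identically zero after the shift
  dzero <- fit_delta(basis, low, lapply(low, function(r) {
    energy_record(r$geom, r$energy, tag = "high-level")
  }))
  expect_equal(dzero$shift_hartree, 0, tolerance = 1e-14)
  expect_lt(dzero$fit$rmse_energy, 1e-8)
  # composed surface equals base + correction pointwise; planted model is
  # reproduced to well below 1e-6 cm^-1
  v_low <- make_potential(function(x) 0.01 * sum(x^2),
                          dim = 12, domain = "test quadratic")
  comp <- compose_delta(v_low, dfit)
  set.seed(26)
  for (rep in 1:20) {
    x <- rnorm(12, sd = 1.2)
    expect_equal(comp$value(x),
                 v_low$value(x) + dfit$potential$value(x) + dfit$shift_hartree,
                 tolerance = 1e-12)
  }
  pred_high <- vapply(geoms, function(g) {
    dfit$potential$value(g$coords) + dfit$shift_hartree
  }, 0)
  rmse <- convert_energy(sqrt(mean((pred_high - delta_true)^2)), "hartree", "cm1")
  expect_lt(rmse, 1e-6)
  expect_error(fit_delta(basis, low[1:5], high[1:4]), "paired")
})
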