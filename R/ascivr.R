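#' Adiabatically switched semiclassical IVR
#'
#' Two-step semiclassical quantization in mass-weighted coordinates
#' (unit masses, hbar = 1): trajectories start on the harmonic
#' zero-point-energy shell, are adiabatically relaxed onto the true
#' Hamiltonian by a switched propagation, then evolved classically while
#' accumulating the action, the Herman-Kluk prefactor phase from the
#' monodromy matrix, and coherent-state overlaps; the time-averaged
#' spectral density peaks at the vibrational eigenvalues, the lowest peak
#' being the ZPE.
#'
#' @name ascivr
NULL

#' AS SCIVR configuration
#'
#' Defaults are the published protocol (switching and semiclassical times
#' of 25 000 au, 10 au steps, 1 percent monodromy-determinant tolerance);
#' the trajectory count defaults to a desk-scale 200 rather than the
#' full-dimensional 5400.
#'
#' @param t_switch adiabatic switching time T_AS, au.
#' @param t_sc semiclassical evolution time T, au.
#' @param step integrator step, au.
#' @param n_traj number of trajectories.
#' @param det_tol rejection threshold on |det M - 1|.
#' @param seed RNG seed.
#' @export
as_config <- function(t_switch = 25000, t_sc = 25000, step = 10,
                      n_traj = 200, det_tol = 0.01, seed = 1L) {
  if (t_switch <= 0 || t_sc <= 0 || step <= 0) stop("times must be positive")
  if (det_tol <= 0 || det_tol >= 1) stop("det_tol must be in (0, 1)")
  structure(list(t_switch = t_switch, t_sc = t_sc, step = step,
                 n_traj = as.integer(n_traj), det_tol = det_tol,
                 seed = as.integer(seed)),
            class = "vq_as_config")
}

#' Adiabatic switching function
#'
#' lambda(t) = t/T - sin(2 pi t / T) / (2 pi): rises smoothly from 0 to 1
#' with vanishing first derivative at both endpoints, the conditions the
#' adiabatic theorem needs at the switch boundaries.
#'
#' @param t time, au (vectorized).
#' @param t_switch total switching time T_AS, au.
#' @export
switching_lambda <- function(t, t_switch) {
  t / t_switch - sin(2 * pi * t / t_switch) / (2 * pi)
}

#' Harmonic zero-point-energy shell initial conditions
#'
#' Each mode carries exactly action 1/2 (energy omega/2) with a uniformly
#' random phase: q_k = sin(phi_k)/sqrt(omega_k), p_k = sqrt(omega_k)
#' cos(phi_k). Every draw sits exactly on the harmonic ZPE shell.
#'
#' @param omega_cm1 harmonic frequencies, cm^-1 (all > 0).
#' @param n number of draws.
#' @param seed RNG seed.
#' @return list with matrices `p` and `q` (modes x draws).
#' @export
harmonic_shell_conditions <- function(omega_cm1, n, seed = 1L) {
  if (any(omega_cm1 <= 0)) stop("imaginary/zero frequencies cannot be quantized")
  omega <- convert_energy(omega_cm1, "cm1", "hartree")
  nv <- length(omega)
  rs <- .derive_rng_state(seed, "as-shell")
  on.exit(.restore_rng_state(rs))
  phi <- matrix(stats::runif(nv * n, 0, 2 * pi), nv)
  list(p = sqrt(omega) * cos(phi), q = sin(phi) / sqrt(omega))
}

# determinant of a (small) complex matrix via eigenvalues; base det() is
# real-only
.cdet <- function(M) {
  if (length(M) == 1L) return(M[1L])
  prod(eigen(M, only.values = TRUE)$values)
}

# Forest-Ruth 4th-order symplectic coefficients
.fr_coeff <- local({
  g <- 1 / (2 - 2^(1/3))
  list(c = c(g / 2, (1 - g) / 2, (1 - g) / 2, g / 2),
       d = c(g, 1 - 2 * g, g, 0))
})

#' Adiabatically switch one trajectory onto the true Hamiltonian
#'
#' Propagates under H(t) = (1 - lambda(t)) H_harm + lambda(t) H_anh with a
#' fourth-order symplectic (Forest-Ruth) integrator; the exit phase-space
#' point seeds the semiclassical run.
#'
#' @param pes `vq_potential` in mass-weighted coordinates.
#' @param omega_cm1 harmonic frequencies defining H_harm.
#' @param p0,q0 initial momenta/coordinates (harmonic shell).
#' @param config an [as_config()].
#' @param reverse swap the roles: H(t) = lambda(t) H_harm +
#'   (1 - lambda(t)) H_anh, i.e. switch an anharmonically quantized point
#'   back onto the harmonic Hamiltonian (round-trip checks).
#' @return list `p`, `q` at t = T_AS, plus `energy` under the final
#'   Hamiltonian (H_anh, or H_harm when `reverse`).
#' @export
adiabatic_switch <- function(pes, omega_cm1, p0, q0, config, reverse = FALSE) {
  omega2 <- convert_energy(omega_cm1, "cm1", "hartree")^2
  h <- config$step
  nstep <- round(config$t_switch / h)
  cc <- .fr_coeff$c; dd <- .fr_coeff$d
  p <- p0; q <- q0
  t <- 0
  for (s in seq_len(nstep)) {
    tt <- t
    for (j in 1:4) {
      q <- q + cc[j] * h * p
      tt <- tt + cc[j] * h
      if (dd[j] != 0) {
        lam <- switching_lambda(tt, config$t_switch)
        if (reverse) lam <- 1 - lam
        f <- -((1 - lam) * omega2 * q + lam * pes$grad(q))
        p <- p + dd[j] * h * f
      }
    }
    t <- t + h
    if (!all(is.finite(p)) || !all(is.finite(q))) {
      stop("adiabatic switching diverged at t = ", t, " au")
    }
  }
  e_final <- if (reverse) sum(p^2) / 2 + sum(omega2 * q^2) / 2 else
    sum(p^2) / 2 + pes$value(q)
  list(p = p, q = q, energy = e_final)
}

#' Propagate a semiclassical trajectory with monodromy and HK phase
#'
#' Classical propagation under the true Hamiltonian accumulating: the
#' action S_t = integral(p.qdot - H) dt; the four monodromy blocks via the
#' variational equations integrated with the same symplectic splitting;
#' the Herman-Kluk prefactor phase phi_t = arg det^(1/2) of the HK block
#' combination, branch-tracked by continuity; and the overlap of a
#' reference coherent state with the moving coherent state. The trajectory
#' is cut (flagged rejected) the first time |det M - 1| exceeds the
#' configured tolerance.
#'
#' @param pes `vq_potential` in mass-weighted coordinates with Hessian
#'   (analytic or finite-difference fallback).
#' @param p0,q0 starting phase-space point (exit of the switching run).
#' @param gamma coherent-state width vector (diagonal Gamma), numerically
#'   the harmonic frequencies in au.
#' @param config an [as_config()].
#' @param p_ref,q_ref reference coherent-state center; defaults to the
#'   origin (the equilibrium with zero momentum).
#' @return a `vq_sc_trajectory`: times, `action`, `hk_phase`, `overlap`
#'   (complex), `det_err` (max |det M - 1| seen), `rejected`, `energy`.
#' @export
propagate_semiclassical <- function(pes, p0, q0, gamma, config,
                                    p_ref = NULL, q_ref = NULL) {
  nv <- length(q0)
  if (is.null(p_ref)) p_ref <- numeric(nv)
  if (is.null(q_ref)) q_ref <- numeric(nv)
  h <- config$step
  nstep <- round(config$t_sc / h)
  cc <- .fr_coeff$c; dd <- .fr_coeff$d
  hessfun <- if (!is.null(pes$hess)) pes$hess else {
    function(x) hessian_fd(pes, x, step = 1e-4)
  }
  p <- p0; q <- q0
  Mqq <- Mpp <- diag(1, nv); Mqp <- Mpq <- matrix(0, nv, nv)
  times <- seq(0, nstep) * h
  action <- numeric(nstep + 1L)
  hk_phase <- numeric(nstep + 1L)
  overlap <- complex(nstep + 1L)
  overlap[1L] <- coherent_overlap(p_ref, q_ref, p, q, gamma)
  lag0 <- sum(p^2) / 2 - pes$value(q)
  arg_prev <- 0   # det combination starts at det(I) = 1
  det_err <- 0
  rejected <- FALSE
  cut <- nstep + 1L
  e0 <- sum(p0^2) / 2 + pes$value(q0)
  for (s in seq_len(nstep)) {
    for (j in 1:4) {
      q <- q + cc[j] * h * p
      Mqq <- Mqq + cc[j] * h * Mpq
      Mqp <- Mqp + cc[j] * h * Mpp
      if (dd[j] != 0) {
        K <- hessfun(q)
        p <- p - dd[j] * h * (pes$grad(q))
        Mpq <- Mpq - dd[j] * h * K %*% Mqq
        Mpp <- Mpp - dd[j] * h * K %*% Mqp
      }
    }
    if (!all(is.finite(p)) || !all(is.finite(q))) {
      # escaped/diverged trajectory: unusable, flag as rejected
      rejected <- TRUE; cut <- s; break
    }
    lag1 <- sum(p^2) / 2 - pes$value(q)
    action[s + 1L] <- action[s] + h * (lag0 + lag1) / 2
    lag0 <- lag1
    # HK prefactor determinant, pinned to exp(-i omega t) on a harmonic
    # potential with gamma = omega; branch via stepwise continuity
    D <- 0.5 * (Mqq + (1 / gamma) * t(gamma * t(Mpp)) +
                  1i * (Mpq / gamma) - 1i * t(gamma * t(Mqp)))
    dt_det <- .cdet(D)
    arg_now <- arg_prev + Arg(dt_det / exp(1i * arg_prev))
    arg_prev <- arg_now
    hk_phase[s + 1L] <- arg_now / 2
    overlap[s + 1L] <- coherent_overlap(p_ref, q_ref, p, q, gamma)
    M <- rbind(cbind(Mqq, Mqp), cbind(Mpq, Mpp))
    derr <- abs(det(M) - 1)
    det_err <- max(det_err, derr)
    if (derr > config$det_tol) { rejected <- TRUE; cut <- s + 1L; break }
  }
  keep <- seq_len(min(cut, nstep + 1L))
  structure(list(times = times[keep], action = action[keep],
                 hk_phase = hk_phase[keep], overlap = overlap[keep],
                 det_err = det_err, rejected = rejected,
                 energy = e0,
                 p_final = p, q_final = q),
            class = "vq_sc_trajectory")
}

#' Overlap of two coherent states with shared diagonal width
#'
#' Closed-form Gaussian overlap <g(p1, q1) | g(p2, q2)> for configuration-
#' space coherent states g(x) ~ exp(-gamma (x - q)^2 / 2 + i p (x - q)).
#'
#' @param p1,q1 bra center.
#' @param p2,q2 ket center.
#' @param gamma positive width vector (diagonal Gamma matrix).
#' @return complex scalar.
#' @export
coherent_overlap <- function(p1, q1, p2, q2, gamma) {
  if (any(gamma <= 0)) stop("Gamma must be positive definite")
  dq <- q1 - q2; dp <- p1 - p2
  prod(exp(-gamma * dq^2 / 4 - dp^2 / (4 * gamma) +
             1i * (p1 + p2) * dq / 2))
}

#' Time-averaged semiclassical spectral density
#'
#' I(E) = < (1 / 2 pi hbar T) | integral_0^T dt exp{i (S_t + E t + phi_t)}
#' <Psi | g(p_t, q_t)> |^2 > averaged over accepted trajectories. Peaks sit
#' at the vibrational eigenvalues; the lowest peak is the ZPE estimate.
#'
#' @param trajectories list of `vq_sc_trajectory` (rejected ones are
#'   dropped; truncated ones contribute their surviving span).
#' @param energy_grid_cm1 energies at which to evaluate I, cm^-1.
#' @return a `vq_spectral_density`: `energy_cm1`, `intensity`, `peaks_cm1`
#'   (interpolated local maxima, ascending), `n_used`, `n_rejected`.
#' @export
spectral_density <- function(trajectories, energy_grid_cm1) {
  used <- Filter(function(tr) !tr$rejected, trajectories)
  n_rej <- length(trajectories) - length(used)
  if (!length(used)) {
    stop("all ", length(trajectories), " trajectories rejected by the ",
         "monodromy-determinant tolerance; nothing to average")
  }
  e_au <- convert_energy(energy_grid_cm1, "cm1", "hartree")
  intensity <- numeric(length(e_au))
  for (tr in used) {
    h <- tr$times[2L] - tr$times[1L]
    Tn <- tr$times[length(tr$times)]
    amp <- exp(1i * (tr$action + tr$hk_phase)) * tr$overlap
    # trapezoid weights over the surviving span
    wt <- rep(h, length(tr$times)); wt[c(1L, length(wt))] <- h / 2
    ph <- exp(1i * outer(e_au, tr$times))
    Fe <- as.numeric(abs(ph %*% (amp * wt)))
    intensity <- intensity + Fe^2 / (2 * pi * Tn)
  }
  intensity <- intensity / length(used)
  t_max <- max(vapply(used, function(tr) tr$times[length(tr$times)], 0))
  lobe_cm1 <- convert_energy(2 * pi / t_max, "hartree", "cm1")
  peaks <- .find_peaks(energy_grid_cm1, intensity, merge_radius = 5 * lobe_cm1)
  structure(list(energy_cm1 = energy_grid_cm1, intensity = intensity,
                 peaks_cm1 = peaks, n_used = length(used),
                 n_rejected = n_rej, lobe_width_cm1 = lobe_cm1),
            class = "vq_spectral_density")
}

# Local maxima above 2% of the global maximum, quadratically interpolated.
# The finite-time window makes each line a sinc^2 whose sidelobes (a few
# percent of the parent, within ~4 lobe widths 2*pi/T) would register as
# spurious peaks; candidates within merge_radius of a stronger accepted
# peak are dropped, so genuine lines must be separated by more than the
# merge radius (5 lobe widths by default) to resolve.
.find_peaks <- function(x, y, rel_floor = 0.02, merge_radius = 0) {
  n <- length(y)
  idx <- which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
  idx <- idx[y[idx] > rel_floor * max(y)]
  if (!length(idx)) return(numeric(0))
  pos <- vapply(idx, function(i) {
    dy1 <- y[i] - y[i - 1L]; dy2 <- y[i] - y[i + 1L]
    denom <- dy1 + dy2
    off <- if (denom > 0) 0.5 * (dy1 - dy2) / denom else 0
    x[i] + off * (x[2L] - x[1L])
  }, 0)
  ord <- order(y[idx], decreasing = TRUE)
  kept <- numeric(0)
  for (k in ord) {
    if (!length(kept) || all(abs(pos[k] - kept) > merge_radius)) {
      kept <- c(kept, pos[k])
    }
  }
  sort(kept)
}

#' @export
print.vq_spectral_density <- function(x, ...) {
  cat("<vq_spectral_density>", length(x$energy_cm1), "grid points |",
      x$n_used, "trajectories used,", x$n_rejected, "rejected | lowest peak",
      if (length(x$peaks_cm1)) round(x$peaks_cm1[1L], 1) else NA, "cm-1\n")
  invisible(x)
}

#' Full AS SCIVR chain: shell conditions, switch, propagate, spectrum
#'
#' @param pes `vq_potential` in mass-weighted coordinates.
#' @param omega_cm1 harmonic frequencies at the minimum (define the shell,
#'   H_harm, and the coherent-state widths Gamma).
#' @param config an [as_config()].
#' @param energy_grid_cm1 spectral grid; default 1 cm^-1 spacing from 0 to
#'   twice the harmonic ZPE.
#' @return list: `density` (a `vq_spectral_density`), `zpe_cm1` (lowest
#'   peak), `rejection_rate`, `trajectories`.
#' @export
run_ascivr <- function(pes, omega_cm1, config, energy_grid_cm1 = NULL) {
  if (is.null(energy_grid_cm1)) {
    energy_grid_cm1 <- seq(0, sum(omega_cm1) * 1.2 + 200, by = 1)
  }
  gamma <- convert_energy(omega_cm1, "cm1", "hartree")
  ics <- harmonic_shell_conditions(omega_cm1, config$n_traj, config$seed)
  # reference state: coherent state at the equilibrium geometry carrying the
  # harmonic ZPE-shell momenta, so excited lines keep nonzero overlap
  p_ref <- sqrt(gamma)
  trajs <- vector("list", config$n_traj)
  for (k in seq_len(config$n_traj)) {
    sw <- adiabatic_switch(pes, omega_cm1, ics$p[, k], ics$q[, k], config)
    trajs[[k]] <- propagate_semiclassical(pes, sw$p, sw$q, gamma, config,
                                          p_ref = p_ref)
  }
  dens <- spectral_density(trajs, energy_grid_cm1)
  list(density = dens,
       zpe_cm1 = if (length(dens$peaks_cm1)) dens$peaks_cm1[1L] else NA_real_,
       rejection_rate = dens$n_rejected / config$n_traj,
       trajectories = trajs)
}

#' Transform a Cartesian potential to mass-weighted displacement coordinates
#'
#' y = sqrt(m) (x - q_ref): the representation the semiclassical module
#' works in (unit masses, so q-dot = p).
#'
#' @param pes Cartesian `vq_potential`.
#' @param masses per-coordinate masses (m_e), length 3N.
#' @param q_ref reference (equilibrium) Cartesian coordinates.
#' @return `vq_potential` over y.
#' @export
mass_weighted_potential <- function(pes, masses, q_ref) {
  ms <- sqrt(masses)
  value <- function(y) {
    if (is.matrix(y)) pes$value(q_ref + y / ms) else pes$value(q_ref + y / ms)
  }
  grad <- if (!is.null(pes$grad)) function(y) pes$grad(q_ref + y / ms) / ms
  hess <- if (!is.null(pes$hess)) {
    function(y) pes$hess(q_ref + y / ms) / outer(ms, ms)
  }
  make_potential(value, grad = grad, hess = hess, dim = length(q_ref),
                 domain = pes$domain)
}
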