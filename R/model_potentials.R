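#' N-dimensional harmonic oscillator potential
#'
#' Separable quadratic potential with prescribed normal-mode frequencies:
#' V = 1/2 sum_k m_k omega_k^2 x_k^2. With the default unit masses the
#' coordinates are mass-weighted normal coordinates; the exact quantum ZPE
#' is half the frequency sum, which makes this the primary analytic oracle
#' for the diffusion Monte Carlo and semiclassical modules.
#'
#' @param freqs_cm1 mode frequencies, cm^-1 (all > 0).
#' @param masses per-coordinate masses (m_e); default 1 (mass-weighted).
#' @return a `vq_potential` over `length(freqs_cm1)` coordinates with
#'   analytic gradient and Hessian; attribute `zpe_cm1` holds the exact ZPE.
#' @export
harmonic_nd <- function(freqs_cm1, masses = rep(1, length(freqs_cm1))) {
  if (any(freqs_cm1 <= 0)) stop("all frequencies must be positive")
  omega <- convert_energy(freqs_cm1, "cm1", "hartree")
  k <- masses * omega^2
  value <- function(x) {
    if (is.matrix(x)) colSums(k * x * x) / 2 else sum(k * x * x) / 2
  }
  pot <- make_potential(value,
                        grad = function(x) k * x,
                        hess = function(x) diag(k, length(k)),
                        dim = length(k), domain = "all space")
  pot$zpe_cm1 <- sum(freqs_cm1) / 2
  pot$freqs_cm1 <- freqs_cm1
  pot$masses <- masses
  pot
}

#' One-dimensional Morse oscillator
#'
#' V(r) = D_e (1 - exp(-a (r - r_e)))^2, with analytic level structure
#' E_n = omega_e (n + 1/2) - omega_e x_e (n + 1/2)^2 where
#' omega_e = a sqrt(2 D_e / m) and omega_e x_e = a^2 / (2 m) (atomic units).
#'
#' @param De well depth, hartree.
#' @param a range parameter, bohr^-1.
#' @param mass reduced mass, m_e.
#' @param re equilibrium distance, bohr.
#' @return a `vq_potential` (1 coordinate) with fields `De`, `a`, `mass`,
#'   `re`, `omega_cm1` and `wexe_cm1`.
#' @export
morse_potential <- function(De, a, mass, re = 0) {
  if (De <= 0 || a <= 0 || mass <= 0) stop("De, a and mass must be positive")
  value <- function(x) {
    y <- 1 - exp(-a * (x - re))
    v <- De * y * y
    if (is.matrix(x)) as.numeric(v) else v
  }
  grad <- function(x) {
    ex <- exp(-a * (x - re))
    2 * De * (1 - ex) * a * ex
  }
  hess <- function(x) {
    ex <- exp(-a * (x - re))
    matrix(2 * De * a^2 * ex * (2 * ex - 1), 1, 1)
  }
  pot <- make_potential(value, grad = grad, hess = hess, dim = 1L,
                        domain = "r > dissociation tail")
  pot$De <- De; pot$a <- a; pot$mass <- mass; pot$re <- re
  pot$omega_cm1 <- convert_energy(a * sqrt(2 * De / mass), "hartree", "cm1")
  pot$wexe_cm1 <- convert_energy(a^2 / (2 * mass), "hartree", "cm1")
  pot
}

#' Bound levels of a Morse oscillator
#'
#' @param morse a [morse_potential()].
#' @return numeric vector of bound levels (cm^-1, measured from the
#'   potential minimum), from n = 0 up to dissociation.
#' @export
morse_levels <- function(morse) {
  w <- morse$omega_cm1; wx <- morse$wexe_cm1
  nmax <- floor(w / (2 * wx) - 0.5)
  if (nmax < 0) stop("no bound levels for these parameters")
  n <- 0:nmax
  w * (n + 0.5) - wx * (n + 0.5)^2
}

# --- coupled two-rotor torsional model -------------------------------------

#' Periodic Fourier model of two coupled hindered rotors
#'
#' V(theta, phi) = sum_jk c_jk cos(j phi) cos(3 k theta)
#'              + sum_jk d_jk sin(j phi) sin(3 k theta)
#' with theta the three-fold (methyl-type) rotor angle and phi the hydroxyl
#' rotor angle, both in radians. The form enforces exactly: three-fold
#' periodicity in theta, 2 pi periodicity in phi, and the simultaneous
#' reflection symmetry V(-theta, -phi) = V(theta, phi) of the enantiomeric
#' gauche pair. The sin*sin block carries the gearing (cross) coupling.
#'
#' @param cmat (J+1) x (K+1) matrix of cos*cos coefficients (cm^-1), rows
#'   j = 0..J, columns k = 0..K.
#' @param dmat J x K matrix of sin*sin coefficients, rows j = 1..J.
#' @param I_oh,I_ch3 rotor moments of inertia (amu bohr^2) carried along
#'   for the DVR modules.
#' @return object of class `vq_torsion2d`.
#' @export
torsion_model2d <- function(cmat, dmat, I_oh = 2.7, I_ch3 = 10.5) {
  structure(list(cmat = cmat, dmat = dmat, J = nrow(cmat) - 1L,
                 K = ncol(cmat) - 1L, I_oh = I_oh, I_ch3 = I_ch3),
            class = "vq_torsion2d")
}

#' Evaluate a two-rotor torsion model
#' @param model a `vq_torsion2d`.
#' @param theta,phi angles in radians (vectorized, recycled).
#' @return potential in cm^-1.
#' @export
torsion_eval <- function(model, theta, phi) {
  n <- max(length(theta), length(phi))
  theta <- rep_len(theta, n); phi <- rep_len(phi, n)
  v <- numeric(n)
  for (j in 0:model$J) {
    for (k in 0:model$K) {
      v <- v + model$cmat[j + 1L, k + 1L] * cos(j * phi) * cos(3 * k * theta)
      if (j >= 1L && k >= 1L) {
        v <- v + model$dmat[j, k] * sin(j * phi) * sin(3 * k * theta)
      }
    }
  }
  v
}

#' Gradient of a torsion model
#' @inheritParams torsion_eval
#' @return list with `d_theta` and `d_phi` (cm^-1 per radian).
#' @export
torsion_grad <- function(model, theta, phi) {
  n <- max(length(theta), length(phi))
  theta <- rep_len(theta, n); phi <- rep_len(phi, n)
  dt <- dp <- numeric(n)
  for (j in 0:model$J) {
    for (k in 0:model$K) {
      cjk <- model$cmat[j + 1L, k + 1L]
      dt <- dt - cjk * cos(j * phi) * 3 * k * sin(3 * k * theta)
      dp <- dp - cjk * j * sin(j * phi) * cos(3 * k * theta)
      if (j >= 1L && k >= 1L) {
        djk <- model$dmat[j, k]
        dt <- dt + djk * sin(j * phi) * 3 * k * cos(3 * k * theta)
        dp <- dp + djk * j * cos(j * phi) * sin(3 * k * theta)
      }
    }
  }
  list(d_theta = dt, d_phi = dp)
}

#' A stationary-point constraint on the torsion model
#'
#' Encodes one piece of printed cut information: the value of the surface
#' at a stationary angle pair, and/or that the surface is stationary there
#' along one or both angles. Angles in degrees.
#'
#' @param theta_deg,phi_deg the angle pair.
#' @param value_cm1 target energy relative to the global (trans) minimum,
#'   or NA for a pure stationarity constraint.
#' @param stationary character subset of `c("theta", "phi")`.
#' @export
torsion_constraint <- function(theta_deg, phi_deg, value_cm1 = NA,
                               stationary = character()) {
  if (!is.na(value_cm1) && value_cm1 < 0) {
    stop("target energies are relative to the trans minimum and must be >= 0")
  }
  structure(list(theta = theta_deg * pi / 180, phi = phi_deg * pi / 180,
                 value = value_cm1, stationary = stationary),
            class = "vq_torsion_constraint")
}

#' Published stationary values of the ethanol torsional landscape
#'
#' The constraint set transcribed from the printed cuts: methyl-torsion
#' barriers of 1208 (trans) and 1324 cm^-1 (gauche), methyl barriers at the
#' two isomerization saddles of 1283 (eclipsed) and 1404 cm^-1 (syn), the
#' hydroxyl-path saddle energies 377 (eclipsed) and 472 cm^-1 (syn), and
#' the gauche minimum 38 cm^-1 above trans. Convention: trans at
#' (theta, phi) = (0, 0); gauche at phi = +/-120 deg; methyl maxima at
#' theta = 60 deg on each cut. Stationarity along symmetry lines
#' (phi = 0/180, theta = 0/60 with no sin terms active) is automatic from
#' the functional form; the explicit stationarity flags cover the rest.
#'
#' @return list of [torsion_constraint()]s.
#' @export
ethanol_torsion_constraints <- function() {
  list(
    torsion_constraint(0, 0, 0),                              # trans minimum
    torsion_constraint(60, 0, 1208),                          # trans methyl barrier
    torsion_constraint(0, 60, 377, c("theta", "phi")),        # eclipsed TS1
    torsion_constraint(60, 60, 1660, "theta"),                # methyl max at TS1 (377+1283)
    torsion_constraint(0, 120, 38, c("theta", "phi")),        # gauche minimum
    torsion_constraint(60, 120, 1362, "theta"),               # gauche methyl max (38+1324)
    torsion_constraint(0, 180, 472),                          # syn TS2
    torsion_constraint(60, 180, 1876)                         # methyl max at TS2 (472+1404)
  )
}

# constraint rows over the packed coefficient vector [c (col-major), d]
.torsion_rows <- function(constr, J, K) {
  nc <- (J + 1L) * (K + 1L)
  nd <- J * K
  rows <- list(); targets <- numeric(0)
  crow <- function(kind, th, ph) {
    r <- numeric(nc + nd)
    idx <- 0L
    for (k in 0:K) for (j in 0:J) {     # column-major over cmat
      idx <- idx + 1L
      r[idx] <- switch(kind,
        value   = cos(j * ph) * cos(3 * k * th),
        d_theta = -cos(j * ph) * 3 * k * sin(3 * k * th),
        d_phi   = -j * sin(j * ph) * cos(3 * k * th))
    }
    for (k in 1:K) for (j in 1:J) {
      idx <- idx + 1L
      r[idx] <- switch(kind,
        value   = sin(j * ph) * sin(3 * k * th),
        d_theta = sin(j * ph) * 3 * k * cos(3 * k * th),
        d_phi   = j * cos(j * ph) * sin(3 * k * th))
    }
    r
  }
  for (cs in constr) {
    if (!is.na(cs$value)) {
      rows[[length(rows) + 1L]] <- crow("value", cs$theta, cs$phi)
      targets <- c(targets, cs$value)
    }
    for (s in cs$stationary) {
      rows[[length(rows) + 1L]] <-
        crow(if (s == "theta") "d_theta" else "d_phi", cs$theta, cs$phi)
      targets <- c(targets, 0)
    }
  }
  list(A = do.call(rbind, rows), b = targets, nc = nc, nd = nd)
}

#' Fit the two-rotor Fourier model to stationary-point constraints
#'
#' Solves the (linear) constraint system for the Fourier coefficients by
#' weighted minimum-norm least squares. The freedom left by a constraint
#' set much smaller than the coefficient count is resolved by minimizing
#' the weighted coefficient norm with weights growing as
#' `harmonic_decay[1]^j * harmonic_decay[2]^k`, i.e. the smoothest
#' (lowest-harmonic) surface consistent with every constraint. A plain
#' (unweighted) minimum-norm solution is available with
#' `harmonic_decay = c(1, 1)` but admits spurious high-harmonic wells
#' between the constrained points. Orders are raised automatically until
#' the system is feasible (max residual below `tol_value_cm1`).
#'
#' @param constraints list of [torsion_constraint()]s.
#' @param orders `c(J, K)` maximum Fourier orders; default `c(6, 3)`.
#' @param I_oh,I_ch3 rotor inertias passed through to the model.
#' @param tol_value_cm1 feasibility tolerance on constraint residuals.
#' @param harmonic_decay per-order weight growth factors `c(g_phi, g_theta)`.
#' @return a fitted `vq_torsion2d` with attribute `max_residual`.
#' @export
fit_torsion2d <- function(constraints, orders = c(6, 3), I_oh = 2.7,
                          I_ch3 = 10.5, tol_value_cm1 = 0.5,
                          harmonic_decay = c(2, 4)) {
  J <- orders[1L]; K <- orders[2L]
  g1 <- harmonic_decay[1L]; g2 <- harmonic_decay[2L]
  repeat {
    sys <- .torsion_rows(constraints, J, K)
    w <- c(as.numeric(outer(0:J, 0:K, function(j, k) g1^j * g2^k)),
           as.numeric(outer(1:J, 1:K, function(j, k) g1^j * g2^k)))
    sol <- .svd_solve(sweep(sys$A, 2L, w, "/"), sys$b)
    coef <- sol$coef / w
    resid <- max(abs(sys$A %*% coef - sys$b))
    if (resid < tol_value_cm1) break
    if (J > 24L) {
      stop("torsion constraint set infeasible: max residual ",
           signif(resid, 4), " cm^-1 at orders (", J, ",", K, ")")
    }
    J <- J + 2L; K <- K + 1L
  }
  cmat <- matrix(coef[seq_len(sys$nc)], J + 1L, K + 1L)
  dmat <- matrix(coef[sys$nc + seq_len(sys$nd)], J, K)
  model <- torsion_model2d(cmat, dmat, I_oh = I_oh, I_ch3 = I_ch3)
  attr(model, "max_residual") <- resid
  model
}

#' @export
print.vq_torsion2d <- function(x, ...) {
  cat("<vq_torsion2d> orders (J,K) = (", x$J, ",", x$K, ") | I_OH =",
      x$I_oh, "amu bohr^2 | I_CH3 =", x$I_ch3, "amu bohr^2\n")
  invisible(x)
}

#' One-dimensional cut through the torsion model
#'
#' @param model a `vq_torsion2d`.
#' @param which `"oh"`: potential vs phi at fixed theta; `"ch3"`: potential
#'   vs theta at fixed phi.
#' @param fixed_deg the fixed angle, degrees.
#' @return a function of the free angle (radians), 2 pi periodic, returning
#'   cm^-1; attributes `which` and `fixed_deg`.
#' @export
cut_1d <- function(model, which = c("oh", "ch3"), fixed_deg = 0) {
  which <- match.arg(which)
  fx <- fixed_deg * pi / 180
  f <- if (which == "oh") {
    function(phi) torsion_eval(model, fx, phi)
  } else {
    function(theta) torsion_eval(model, theta, fx)
  }
  attr(f, "which") <- which
  attr(f, "fixed_deg") <- fixed_deg
  f
}

#' Barrier of a 1-D periodic cut (max minus min on a fine grid)
#' @param cut a function from [cut_1d()] (or any periodic function of one
#'   angle in radians).
#' @param n grid resolution.
#' @return list with `min`, `max`, `barrier` (cm^-1) and their angles (deg).
#' @export
cut_barrier <- function(cut, n = 7200) {
  ang <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  v <- cut(ang)
  list(min = min(v), max = max(v), barrier = max(v) - min(v),
       angle_min_deg = ang[which.min(v)] * 180 / pi,
       angle_max_deg = ang[which.max(v)] * 180 / pi)
}

#' Minimum-barrier path between two minima of the torsion model
#'
#' Finds the axis-aligned minimax path on a grid: among all grid paths from
#' `start` to `end` moving only along theta or phi (the way the geared
#' staircase moves), the one whose highest crossed energy is lowest. The
#' bottleneck energy is located by bisection over an energy threshold with
#' a flood-fill connectivity test, and the path itself is the shortest
#' breadth-first route inside the passable corridor. The returned segment
#' list exposes the gearing: on a coupled landscape the route alternates
#' theta and phi runs through the low saddle gates instead of running
#' straight.
#'
#' @param model a `vq_torsion2d`.
#' @param start,end `c(theta, phi)` in degrees; must be local minima.
#' @param n_theta,n_phi grid resolution over the covering rectangle.
#' @return list: `path` (matrix of theta/phi in degrees), `energies`,
#'   `max_energy` (the bottleneck), `segments` (data.frame of axis-aligned
#'   runs with axis "theta"/"phi").
#' @export
minimum_energy_path <- function(model, start, end, n_theta = 181, n_phi = 121) {
  to_rad <- pi / 180
  .check_min <- function(pt) {
    g <- torsion_grad(model, pt[1] * to_rad, pt[2] * to_rad)
    h <- 1e-4
    v0 <- torsion_eval(model, pt[1] * to_rad, pt[2] * to_rad)
    probe <- c(
      torsion_eval(model, pt[1] * to_rad + h, pt[2] * to_rad),
      torsion_eval(model, pt[1] * to_rad - h, pt[2] * to_rad),
      torsion_eval(model, pt[1] * to_rad, pt[2] * to_rad + h),
      torsion_eval(model, pt[1] * to_rad, pt[2] * to_rad - h))
    if (max(abs(g$d_theta), abs(g$d_phi)) > 1e-2 || any(probe < v0)) {
      stop("path endpoint (", pt[1], ", ", pt[2], ") deg is not a local minimum")
    }
  }
  .check_min(start); .check_min(end)
  th <- seq(min(start[1], end[1]), max(start[1], end[1]), length.out = n_theta)
  ph <- seq(min(start[2], end[2]), max(start[2], end[2]), length.out = n_phi)
  V <- outer(th * to_rad, ph * to_rad, function(a, b) torsion_eval(model, a, b))
  is <- which.min(abs(th - start[1])); js <- which.min(abs(ph - start[2]))
  ie <- which.min(abs(th - end[1])); je <- which.min(abs(ph - end[2]))
  connected <- function(thr) {
    ok <- V <= thr
    if (!ok[is, js] || !ok[ie, je]) return(FALSE)
    reach <- matrix(FALSE, n_theta, n_phi)
    reach[is, js] <- TRUE
    repeat {
      grown <- reach
      grown[-1, ] <- grown[-1, ] | reach[-n_theta, ]
      grown[-n_theta, ] <- grown[-n_theta, ] | reach[-1, ]
      grown[, -1] <- grown[, -1] | reach[, -n_phi]
      grown[, -n_phi] <- grown[, -n_phi] | reach[, -1]
      grown <- grown & ok
      if (grown[ie, je]) return(TRUE)
      if (all(grown == reach)) return(FALSE)
      reach <- grown
    }
  }
  levels <- sort(unique(as.numeric(V)))
  lo <- 1L; hi <- length(levels)
  while (lo < hi) {        # smallest threshold that connects the endpoints
    mid <- (lo + hi) %/% 2L
    if (connected(levels[mid])) hi <- mid else lo <- mid + 1L
  }
  bottleneck <- levels[lo]
  # shortest path inside the corridor by BFS with parent pointers
  ok <- V <= bottleneck
  nid <- function(i, j) (j - 1L) * n_theta + i
  prev <- integer(n_theta * n_phi)
  visited <- matrix(FALSE, n_theta, n_phi)
  queue <- nid(is, js); visited[is, js] <- TRUE
  target <- nid(ie, je)
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    if (u == target) break
    i <- (u - 1L) %% n_theta + 1L; j <- (u - 1L) %/% n_theta + 1L
    for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
      if (nb[1L] < 1L || nb[1L] > n_theta || nb[2L] < 1L || nb[2L] > n_phi) next
      if (visited[nb[1L], nb[2L]] || !ok[nb[1L], nb[2L]]) next
      visited[nb[1L], nb[2L]] <- TRUE
      v <- nid(nb[1L], nb[2L])
      prev[v] <- u
      queue <- c(queue, v)
    }
  }
  nodes <- target
  while (nodes[1L] != nid(is, js)) nodes <- c(prev[nodes[1L]], nodes)
  ii <- (nodes - 1L) %% n_theta + 1L; jj <- (nodes - 1L) %/% n_theta + 1L
  path <- cbind(theta = th[ii], phi = ph[jj])
  energies <- V[cbind(ii, jj)]
  runs <- rle(ifelse(diff(ii) != 0L, "theta", "phi"))
  list(path = path, energies = energies, max_energy = max(energies),
       segments = data.frame(axis = runs$values, steps = runs$lengths))
}
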