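#' Periodic (azimuthal) discrete variable representation
#'
#' Grid methods for hindered-rotor levels on the 0 to 2 pi circle: the
#' kinetic matrix has the closed periodic-DVR form, the potential is
#' diagonal on the grid, and dense diagonalization gives levels and
#' wavefunctions. A direct-product version handles two coupled rotors.
#'
#' @name dvr
NULL

#' Rotor moment of inertia
#'
#' Stored internally in m_e bohr^2; constructed from the amu bohr^2 value
#' (the "value/(N_AV m_e)" spelling seen in the hindered-rotor literature
#' is numerically amu bohr^2).
#'
#' @param amu_bohr2 moment of inertia in amu bohr^2.
#' @return a `vq_rotor` with fields `I_me_bohr2` and `B_cm1` (rotational
#'   constant hbar^2 / 2I).
#' @export
rotor_spec <- function(amu_bohr2) {
  if (amu_bohr2 <= 0) stop("moment of inertia must be positive")
  I_me <- amu_to_me(amu_bohr2)
  structure(list(I_amu_bohr2 = amu_bohr2, I_me_bohr2 = I_me,
                 B_cm1 = convert_energy(1 / (2 * I_me), "hartree", "cm1")),
            class = "vq_rotor")
}

#' Estimate a rotor moment of inertia as mu r^2
#'
#' The bond-rotor estimate: reduced mass of the rotating pair times the
#' squared bond length. For the hydroxyl rotor of ethanol this gives about
#' 3.2 amu bohr^2.
#'
#' @param mu_amu reduced mass, amu.
#' @param r_bohr bond length, bohr.
#' @return moment of inertia, amu bohr^2.
#' @export
rotor_inertia_estimate <- function(mu_amu, r_bohr) {
  if (mu_amu <= 0 || r_bohr <= 0) stop("mu and r must be positive")
  mu_amu * r_bohr^2
}

# periodic-DVR kinetic matrix on N (odd) grid points over [0, 2pi)
.periodic_kinetic <- function(N, I_me) {
  if (N %% 2L == 0L) stop("periodic DVR needs an odd grid size, got ", N)
  Tm <- matrix(0, N, N)
  diag(Tm) <- (N * N - 1) / 12
  if (N > 1L) {
    for (dd in seq_len(N - 1L)) {
      val <- (-1)^dd * cos(pi * dd / N) / (2 * sin(pi * dd / N)^2)
      idx <- seq_len(N - dd)
      Tm[cbind(idx, idx + dd)] <- val
      Tm[cbind(idx + dd, idx)] <- val
    }
  }
  Tm / (2 * I_me)   # hartree
}

#' One-dimensional periodic DVR for a hindered rotor
#'
#' Diagonalizes -hbar^2/(2I) d2/dphi2 + V(phi) on the uniform grid
#' phi_j = 2 pi j / N (N odd), using the closed-form periodic DVR kinetic
#' matrix.
#'
#' @param V function of the angle (radians) returning the potential in
#'   cm^-1, 2 pi periodic.
#' @param rotor a [rotor_spec()] (or a bare amu bohr^2 number).
#' @param N odd grid size; should exceed twice the highest Fourier order
#'   of V.
#' @return a `vq_dvr_levels`: `levels_cm1` (relative to the lowest),
#'   `e0_cm1` (the absolute lowest eigenvalue), `grid` (radians),
#'   `wavefunctions` (columns, grid-orthonormal), `N`.
#' @export
periodic_dvr_1d <- function(V, rotor, N = 161L) {
  if (!inherits(rotor, "vq_rotor")) rotor <- rotor_spec(rotor)
  N <- as.integer(N)
  grid <- 2 * pi * seq(0L, N - 1L) / N
  H <- .periodic_kinetic(N, rotor$I_me_bohr2) +
    diag(convert_energy(V(grid), "cm1", "hartree"))
  ev <- eigen(H, symmetric = TRUE)
  vals <- convert_energy(rev(ev$values), "hartree", "cm1")
  vecs <- ev$vectors[, rev(seq_len(N)), drop = FALSE]
  structure(list(levels_cm1 = vals - vals[1L], e0_cm1 = vals[1L],
                 grid = grid, wavefunctions = vecs, N = N,
                 rotor = rotor),
            class = "vq_dvr_levels")
}

#' @export
print.vq_dvr_levels <- function(x, ...) {
  cat("<vq_dvr_levels> N =", x$N, "| lowest levels (cm-1):",
      paste(round(utils::head(x$levels_cm1, 8L), 1), collapse = ", "), "\n")
  invisible(x)
}

#' Hydroxyl-torsion levels and wavefunctions from the 2-D model
#'
#' Solves the 1-D periodic DVR on the hydroxyl cut of a fitted torsion
#' model at the trans methyl angle (theta = 0) and reports, besides the
#' levels, the "leak" diagnostic: the ground-state amplitude at the gauche
#' angles (+/- 120 deg) relative to its maximum. Substantial gauche
#' amplitude of a trans-localized ground state is the quantum
#' delocalization signature seen in the walker histograms.
#'
#' @param model a fitted `vq_torsion2d`.
#' @param I_oh hydroxyl rotor inertia (amu bohr^2); default from the model.
#' @param N odd grid size.
#' @return a `vq_dvr_levels` plus `leak`: list with `rel_amplitude`
#'   (|psi0(+/-120 deg)| / max |psi0|) and the gauche grid angles used.
#' @export
dvr_1d_oh_torsion <- function(model, I_oh = NULL, N = 361L) {
  if (is.null(I_oh)) I_oh <- model$I_oh
  cut <- cut_1d(model, "oh", fixed_deg = 0)
  res <- periodic_dvr_1d(cut, rotor_spec(I_oh), N = N)
  psi0 <- abs(res$wavefunctions[, 1L])
  gidx <- c(which.min(abs(res$grid - 2 * pi / 3)),
            which.min(abs(res$grid - 4 * pi / 3)))
  res$leak <- list(rel_amplitude = max(psi0[gidx]) / max(psi0),
                   gauche_angles_deg = res$grid[gidx] * 180 / pi)
  res
}

#' Two-dimensional direct-product DVR for the coupled rotors
#'
#' H = T_phi x 1 + 1 x T_theta + V(theta, phi) diagonal on the product
#' grid. With `omit_cross_terms = TRUE` every coefficient coupling the two
#' angles (j >= 1 and k >= 1, both the cos*cos and sin*sin blocks) is
#' zeroed first, leaving the separable surface f(theta) + g(phi) with no
#' cross terms between functions of the two angles.
#'
#' @param model a fitted `vq_torsion2d`.
#' @param I_oh,I_ch3 rotor inertias (amu bohr^2); default from the model.
#' @param N_phi,N_theta odd grid sizes. The full published grids are
#'   161 x 81; the default here is a desk-scale 81 x 41, converged to about
#'   1e-4 cm^-1 for barriers below 1500 cm^-1 (dense 13k-dim eigensolves
#'   take minutes on one core).
#' @param omit_cross_terms drop every angle-coupling coefficient
#'   (j >= 1 and k >= 1), leaving the separable comparison surface.
#' @param n_levels number of levels to report.
#' @param dim_cap guard against accidental huge dense diagonalizations.
#' @return a `vq_dvr2d_levels`: `levels_cm1` (relative to the lowest),
#'   `e0_cm1`, `assignments` (nodal quantum numbers v_phi, v_theta and e/o
#'   parity label), grids, and the eigenvector matrix.
#' @export
dvr_2d <- function(model, I_oh = NULL, I_ch3 = NULL, N_phi = 81L,
                   N_theta = 41L, omit_cross_terms = FALSE, n_levels = 12L,
                   dim_cap = 16000L) {
  if (is.null(I_oh)) I_oh <- model$I_oh
  if (is.null(I_ch3)) I_ch3 <- model$I_ch3
  N_phi <- as.integer(N_phi); N_theta <- as.integer(N_theta)
  if (N_phi %% 2L == 0L || N_theta %% 2L == 0L) {
    stop("periodic DVR needs odd grid sizes")
  }
  if (N_phi * N_theta > dim_cap) {
    stop("grid ", N_phi, " x ", N_theta, " exceeds the dense cap (",
         dim_cap, " points); reduce the grids or raise dim_cap")
  }
  m <- model
  if (omit_cross_terms) {
    m$dmat[] <- 0
    m$cmat[2:(m$J + 1L), 2:(m$K + 1L)] <- 0
  }
  Tphi <- .periodic_kinetic(N_phi, amu_to_me(I_oh))
  Tth <- .periodic_kinetic(N_theta, amu_to_me(I_ch3))
  gphi <- 2 * pi * seq(0L, N_phi - 1L) / N_phi
  gth <- 2 * pi * seq(0L, N_theta - 1L) / N_theta
  Vg <- outer(gth, gphi, function(a, b) torsion_eval(m, a, b))  # theta x phi
  H <- kronecker(Tphi, diag(1, N_theta)) + kronecker(diag(1, N_phi), Tth) +
    diag(convert_energy(as.numeric(Vg), "cm1", "hartree"))
  ev <- eigen(H, symmetric = TRUE)
  ntot <- N_theta * N_phi
  vals <- convert_energy(rev(ev$values), "hartree", "cm1")
  n_levels <- min(n_levels, ntot)
  vecs <- ev$vectors[, ntot - seq_len(n_levels) + 1L, drop = FALSE]
  assignments <- t(vapply(seq_len(n_levels), function(k) {
    .assign_2d(matrix(vecs[, k], N_theta, N_phi), gth, gphi)
  }, numeric(3)))
  lab <- ifelse(assignments[, 3L] > 0.5, "o", "e")
  structure(list(levels_cm1 = vals[seq_len(n_levels)] - vals[1L],
                 e0_cm1 = vals[1L],
                 assignments = data.frame(level = seq_len(n_levels),
                                          v_oh = assignments[, 1L],
                                          v_ch3 = assignments[, 2L],
                                          parity = lab),
                 grid_theta = gth, grid_phi = gphi,
                 wavefunctions = vecs,
                 N_theta = N_theta, N_phi = N_phi,
                 omit_cross_terms = omit_cross_terms),
            class = "vq_dvr2d_levels")
}

# nodal-count assignment of a 2-D eigenfunction: node counts of the
# dominant-row/column profiles plus odd/even parity under phi -> -phi
.assign_2d <- function(psi, gth, gphi) {
  amax <- which(abs(psi) == max(abs(psi)), arr.ind = TRUE)[1L, ]
  prof_phi <- psi[amax[1L], ]    # along phi at the dominant theta row
  prof_th <- psi[, amax[2L]]
  count_nodes <- function(v) {
    v <- v[abs(v) > 0.02 * max(abs(v))]
    if (length(v) < 2L) return(0)
    sum(diff(sign(v)) != 0)
  }
  # parity under phi -> -phi (grid index reversal, phi_0 fixed)
  N <- length(gphi)
  rev_idx <- c(1L, N:2L)
  flipped <- psi[, rev_idx]
  odd <- sum((psi + flipped)^2) < sum((psi - flipped)^2)
  c(count_nodes(prof_phi), count_nodes(prof_th), as.numeric(odd))
}

#' @export
print.vq_dvr2d_levels <- function(x, ...) {
  cat("<vq_dvr2d_levels>", x$N_theta, "x", x$N_phi, "grid",
      if (x$omit_cross_terms) "(cross terms omitted)", "| levels (cm-1):",
      paste(round(utils::head(x$levels_cm1, 8L), 1), collapse = ", "), "\n")
  invisible(x)
}

#' Level table in the published comparison layout
#'
#' Runs the 2-D DVR with and without cross terms and tabulates the lowest
#' transitions relative to the ground level.
#'
#' @inheritParams dvr_2d
#' @return data.frame: level, v_oh, v_ch3, parity, full_cm1,
#'   no_cross_cm1.
#' @export
dvr_2d_table <- function(model, I_oh = NULL, I_ch3 = NULL, N_phi = 81L,
                         N_theta = 41L, n_levels = 12L) {
  full <- dvr_2d(model, I_oh, I_ch3, N_phi, N_theta,
                 omit_cross_terms = FALSE, n_levels = n_levels)
  sep <- dvr_2d(model, I_oh, I_ch3, N_phi, N_theta,
                omit_cross_terms = TRUE, n_levels = n_levels)
  data.frame(level = seq_len(n_levels),
             v_oh = full$assignments$v_oh,
             v_ch3 = full$assignments$v_ch3,
             parity = full$assignments$parity,
             full_cm1 = round(full$levels_cm1, 1),
             no_cross_cm1 = round(sep$levels_cm1, 1))
}
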