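#' Finite-difference Hessian of a potential
#'
#' Central differences on the analytic gradient when the evaluator has one
#' (first order in the energy, so effectively second-order accurate after
#' symmetrization), else a double central difference on energies. The
#' asymmetry of the raw matrix before symmetrization is recorded as a
#' quality diagnostic in attribute `"asymmetry"`.
#'
#' @param pes a `vq_potential`.
#' @param geom a `vq_geometry` or flat coordinate vector (bohr).
#' @param step displacement, bohr.
#' @return symmetric Hessian matrix (hartree/bohr^2).
#' @export
hessian_fd <- function(pes, geom, step = 1e-3) {
  if (step <= 0) stop("step must be positive")
  x <- if (inherits(geom, "vq_geometry")) geom$coords else as.numeric(geom)
  n <- length(x)
  H <- matrix(0, n, n)
  if (!is.null(pes$hess)) {
    H <- pes$hess(x)
    attr(H, "asymmetry") <- max(abs(H - t(H)))
    return((H + t(H)) / 2)
  }
  if (!is.null(pes$grad)) {
    for (k in seq_len(n)) {
      xp <- x; xp[k] <- x[k] + step
      xm <- x; xm[k] <- x[k] - step
      H[, k] <- (pes$grad(xp) - pes$grad(xm)) / (2 * step)
    }
  } else {
    f0 <- pes$value(x)
    for (k in seq_len(n)) {
      for (l in k:n) {
        if (k == l) {
          xp <- x; xp[k] <- x[k] + step
          xm <- x; xm[k] <- x[k] - step
          H[k, k] <- (pes$value(xp) - 2 * f0 + pes$value(xm)) / step^2
        } else {
          xpp <- x; xpp[k] <- x[k] + step; xpp[l] <- x[l] + step
          xpm <- x; xpm[k] <- x[k] + step; xpm[l] <- x[l] - step
          xmp <- x; xmp[k] <- x[k] - step; xmp[l] <- x[l] + step
          xmm <- x; xmm[k] <- x[k] - step; xmm[l] <- x[l] - step
          H[k, l] <- H[l, k] <-
            (pes$value(xpp) - pes$value(xpm) - pes$value(xmp) + pes$value(xmm)) /
            (4 * step^2)
        }
      }
    }
  }
  asym <- max(abs(H - t(H)))
  H <- (H + t(H)) / 2
  attr(H, "asymmetry") <- asym
  H
}

#' Normal-mode analysis
#'
#' Mass-weights the Hessian, projects out rigid translations and (for >= 3
#' non-collinear atoms) infinitesimal rotations about the input geometry,
#' and diagonalizes. Frequencies are returned in cm^-1, sorted ascending,
#' with imaginary frequencies reported as negative numbers (so a first-order
#' saddle shows exactly one negative entry).
#'
#' @param hessian symmetric Cartesian Hessian (hartree/bohr^2).
#' @param masses per-atom masses (m_e).
#' @param geom a `vq_geometry` or flat coordinate vector, used for the
#'   rotation projector.
#' @param n_project number of external modes to drop; default 6 (nonlinear).
#' @return a `vq_normal_modes`: `frequencies` (cm^-1, length 3N - 6),
#'   `modes` (mass-weighted orthonormal columns), `projected_frequencies`
#'   (the dropped external-mode magnitudes), `q_eq`, `masses`.
#' @export
nm_analyze <- function(hessian, masses, geom, n_project = 6L) {
  if (any(masses <= 0)) stop("masses must be positive")
  x <- if (inherits(geom, "vq_geometry")) geom$coords else as.numeric(geom)
  natoms <- length(masses)
  n <- 3L * natoms
  if (!isTRUE(all.equal(hessian, t(hessian), tolerance = 1e-7))) {
    stop("hessian must be symmetric (symmetrize first)")
  }
  msqrt <- sqrt(rep(masses, each = 3L))
  mw <- hessian / outer(msqrt, msqrt)
  # external space: translations and rotations in mass-weighted coordinates
  ext <- matrix(0, n, 6L)
  xyz <- matrix(x, nrow = 3L)
  com <- as.numeric(xyz %*% masses) / sum(masses)
  rel <- xyz - com
  for (d in 1:3) ext[seq(d, n, by = 3L), d] <- msqrt[seq(d, n, by = 3L)]
  for (at in seq_len(natoms)) {
    r <- rel[, at]
    rows <- 3L * (at - 1L) + 1:3
    m <- msqrt[rows[1L]]
    ext[rows, 4L] <- m * c(0, -r[3L], r[2L])
    ext[rows, 5L] <- m * c(r[3L], 0, -r[1L])
    ext[rows, 6L] <- m * c(-r[2L], r[1L], 0)
  }
  qr_ext <- qr(ext)
  ext_basis <- qr.Q(qr_ext)[, seq_len(qr_ext$rank), drop = FALSE]
  P <- diag(n) - ext_basis %*% t(ext_basis)
  mw_proj <- P %*% mw %*% P
  ev <- eigen((mw_proj + t(mw_proj)) / 2, symmetric = TRUE)
  freq_all <- sign(ev$values) * sqrt(abs(ev$values))
  freq_all <- convert_energy(freq_all, "hartree", "cm1")
  ord <- order(freq_all)
  freq_all <- freq_all[ord]
  vecs <- ev$vectors[, ord, drop = FALSE]
  # the n_project smallest-|freq| modes are the projected external ones
  drop_idx <- order(abs(freq_all))[seq_len(min(n_project, n))]
  keep <- setdiff(seq_len(n), sort(drop_idx))
  structure(list(frequencies = freq_all[keep],
                 modes = vecs[, keep, drop = FALSE],
                 projected_frequencies = freq_all[sort(drop_idx)],
                 q_eq = x, masses = masses),
            class = "vq_normal_modes")
}

#' @export
print.vq_normal_modes <- function(x, ...) {
  cat("<vq_normal_modes>", length(x$frequencies), "modes,",
      round(min(x$frequencies)), "-", round(max(x$frequencies)), "cm-1\n")
  invisible(x)
}

#' Harmonic zero-point energy
#'
#' Half the sum of the (real) harmonic frequencies plus an electronic
#' offset, e.g. the electronic energy of a local minimum above the global
#' one, so conformer ZPEs share a common zero.
#'
#' @param freqs_cm1 harmonic frequencies, cm^-1 (all > 0).
#' @param offset_cm1 electronic offset, cm^-1.
#' @return ZPE in cm^-1.
#' @export
harmonic_zpe <- function(freqs_cm1, offset_cm1 = 0) {
  if (any(freqs_cm1 <= 0)) stop("harmonic ZPE needs all-real (positive) frequencies")
  sum(freqs_cm1) / 2 + offset_cm1
}

#' Published harmonic frequencies of the ethanol conformers
#'
#' The 21 harmonic mode frequencies (cm^-1) of trans- and gauche-ethanol
#' from the corrected coupled-cluster-quality surface and the corresponding
#' direct ab initio values, as tabulated in the source study. Shipped as a
#' plain-text table; used to reproduce the harmonic ZPEs (17 568 and,
#' with the 38 cm^-1 electronic offset, 17 621 cm^-1).
#'
#' @return data.frame with columns `mode`, `trans_pes`, `trans_ab`,
#'   `gauche_pes`, `gauche_ab`.
#' @export
ethanol_harmonic_frequencies <- function() {
  path <- system.file("extdata", "ethanol_harmonic_freqs.csv",
                      package = "vibquant")
  if (!nzchar(path)) {     # running from a source tree (tests via load_all)
    path <- file.path("inst", "extdata", "ethanol_harmonic_freqs.csv")
  }
  utils::read.csv(path)
}
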