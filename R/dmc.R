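#' Unbiased diffusion Monte Carlo
#'
#' Imaginary-time random walk of a walker ensemble: Gaussian diffusion with
#' per-coordinate variance dtau/m, birth/death branching against a
#' reference energy, and population feedback on the reference energy. The
#' long-time average of the reference energy estimates the zero-point
#' energy; the steady-state walker distribution samples the ground-state
#' wavefunction.
#'
#' @name dmc
NULL

#' DMC run configuration
#'
#' Defaults follow the published protocol: step size 5 au, 30 000 steps of
#' which 20 000 equilibrate, an ensemble of simulations whose spread gives
#' the statistical uncertainty. Desk-scale fixtures usually pass smaller
#' `n_steps`/`n_walkers`.
#'
#' @param n_walkers initial walker count N(0).
#' @param dtau imaginary-time step, au.
#' @param n_steps total steps per simulation.
#' @param n_equil equilibration steps excluded from the ZPE average.
#' @param alpha population-feedback parameter (au^-1); default `1/dtau`.
#' @param n_sims number of independent simulations.
#' @param seed RNG seed.
#' @param hole_floor_cm1 a walker whose potential falls below (global
#'   minimum - hole_floor_cm1) counts as having entered a fitting "hole"
#'   and is killed.
#' @param snapshot_every save live-walker snapshots every so many
#'   post-equilibration steps (0 = final step only).
#' @export
dmc_config <- function(n_walkers = 2000, dtau = 5, n_steps = 30000,
                       n_equil = 20000, alpha = NULL, n_sims = 5, seed = 1L,
                       hole_floor_cm1 = 1000, snapshot_every = 0L) {
  if (n_steps <= n_equil) stop("n_steps must exceed n_equil")
  if (dtau <= 0 || n_walkers <= 0) stop("dtau and n_walkers must be positive")
  if (is.null(alpha)) alpha <- 1 / dtau
  structure(list(n_walkers = as.integer(n_walkers), dtau = dtau,
                 n_steps = as.integer(n_steps), n_equil = as.integer(n_equil),
                 alpha = alpha, n_sims = as.integer(n_sims),
                 seed = as.integer(seed), hole_floor_cm1 = hole_floor_cm1,
                 snapshot_every = as.integer(snapshot_every)),
            class = "vq_dmc_config")
}

#' Diffuse a walker ensemble one imaginary-time step
#'
#' Adds to every coordinate of every walker a Gaussian displacement of
#' standard deviation sqrt(dtau / m), with m the mass attached to that
#' coordinate (heavier isotopes diffuse less).
#'
#' @param walkers coordinate matrix, one column per walker.
#' @param masses per-coordinate masses (m_e), length nrow(walkers).
#' @param dtau imaginary-time step, au.
#' @return displaced walker matrix.
#' @export
dmc_diffuse <- function(walkers, masses, dtau) {
  if (dtau <= 0) stop("dtau must be positive")
  walkers + matrix(stats::rnorm(length(walkers), sd = sqrt(dtau / masses)),
                   nrow(walkers))
}

#' Branch a walker ensemble against the reference energy
#'
#' Implements the unbiased birth/death rule: with x = (E_i - E_r) dtau,
#' a walker above the reference dies with probability 1 - exp(-x), one
#' below it gives birth to a copy with probability exp(-x) - 1 (capped at
#' one offspring per step). Walkers whose potential lies below the hole
#' floor are unphysical-extrapolation casualties: they are killed and
#' counted separately.
#'
#' @param walkers coordinate matrix, one column per walker.
#' @param energies per-walker potential energies E_i (hartree).
#' @param e_ref current reference energy (hartree).
#' @param dtau imaginary-time step.
#' @param hole_floor potential value (hartree) below which a walker is a
#'   hole casualty; default -Inf disables the check.
#' @return list: `walkers` (surviving + born columns), `energies` matched,
#'   `n_holes` killed by the hole rule.
#' @export
dmc_branch <- function(walkers, energies, e_ref, dtau, hole_floor = -Inf) {
  x <- (energies - e_ref) * dtau
  u <- stats::runif(length(energies))
  hole <- energies < hole_floor
  die <- hole | (x > 0 & u < (1 - exp(-x)))
  birth <- !hole & x < 0 & u < (exp(-x) - 1)
  keep <- which(!die)
  born <- which(birth & !die)
  if (length(keep) == 0L) {
    stop("DMC population extinct (all walkers died); reference energy ",
         "feedback too weak or potential pathological")
  }
  list(walkers = cbind(walkers[, keep, drop = FALSE],
                       walkers[, born, drop = FALSE]),
       energies = c(energies[keep], energies[born]),
       n_holes = sum(hole))
}

#' Update the reference energy from the live population
#'
#' E_r = <V> - alpha (N - N0) / N0: the mean potential of the live walkers
#' with a feedback term that shrinks the population back toward N0.
#'
#' @param energies live-walker potential energies (hartree).
#' @param alpha feedback strength (au^-1).
#' @param n0 target population N(0).
#' @return reference energy, hartree.
#' @export
dmc_update_reference <- function(energies, alpha, n0) {
  if (!length(energies)) stop("no live walkers")
  mean(energies) - alpha * (length(energies) - n0) / n0
}

#' Run unbiased diffusion Monte Carlo
#'
#' @param pes a `vq_potential` whose `value` accepts a coordinate matrix.
#' @param masses per-coordinate masses (m_e). For a molecular surface pass
#'   `rep(atom_masses, each = 3)`.
#' @param config a [dmc_config()].
#' @param q0 starting coordinates (flat vector); walkers all start here.
#' @param e_min potential value at the global minimum (hartree), the zero
#'   of the reported ZPE.
#' @return a `vq_dmc_result`: `zpe_cm1`, `sigma_cm1` (standard deviation of
#'   the per-simulation means over sqrt(n_sims)), `sim_means_cm1`,
#'   `n_holes`, `snapshots` (list of walker matrices), `reference_trace`
#'   (last simulation, cm^-1).
#' @export
run_dmc <- function(pes, masses, config, q0, e_min = 0) {
  stopifnot(inherits(config, "vq_dmc_config"))
  hole_floor <- e_min - convert_energy(config$hole_floor_cm1, "cm1", "hartree")
  sim_means <- numeric(config$n_sims)
  n_holes <- 0L
  snapshots <- list()
  trace <- NULL
  rs <- .derive_rng_state(config$seed, "dmc")
  on.exit(.restore_rng_state(rs))
  for (sim in seq_len(config$n_sims)) {
    W <- matrix(q0, length(q0), config$n_walkers)
    e <- pes$value(W)
    e_ref <- dmc_update_reference(e, config$alpha, config$n_walkers)
    acc <- numeric(config$n_steps - config$n_equil)
    for (step in seq_len(config$n_steps)) {
      W <- dmc_diffuse(W, masses, config$dtau)
      e <- pes$value(W)
      br <- dmc_branch(W, e, e_ref, config$dtau, hole_floor)
      W <- br$walkers; e <- br$energies
      n_holes <- n_holes + br$n_holes
      e_ref <- dmc_update_reference(e, config$alpha, config$n_walkers)
      if (step > config$n_equil) {
        k <- step - config$n_equil
        acc[k] <- e_ref
        if (config$snapshot_every > 0L && k %% config$snapshot_every == 0L) {
          snapshots[[length(snapshots) + 1L]] <- W
        }
      }
    }
    if (config$snapshot_every == 0L) snapshots[[length(snapshots) + 1L]] <- W
    sim_means[sim] <- mean(acc) - e_min
    trace <- acc - e_min
  }
  sim_means_cm1 <- convert_energy(sim_means, "hartree", "cm1")
  structure(list(zpe_cm1 = mean(sim_means_cm1),
                 sigma_cm1 = stats::sd(sim_means_cm1) / sqrt(config$n_sims),
                 sim_means_cm1 = sim_means_cm1,
                 n_holes = n_holes, snapshots = snapshots,
                 reference_trace_cm1 = convert_energy(trace, "hartree", "cm1"),
                 config = config),
            class = "vq_dmc_result")
}

#' @export
print.vq_dmc_result <- function(x, ...) {
  cat("<vq_dmc_result> ZPE =", round(x$zpe_cm1, 1), "+/-",
      round(x$sigma_cm1, 1), "cm-1 (", length(x$sim_means_cm1),
      "simulations,", x$n_holes, "holes )\n")
  invisible(x)
}

#' DMC statistical uncertainty from per-simulation means
#'
#' The standard deviation of the independent simulation means divided by
#' the square root of the simulation count -- recomputable exactly from a
#' result's stored `sim_means_cm1`.
#'
#' @param sim_means_cm1 per-simulation ZPE means, cm^-1.
#' @return sigma, cm^-1.
#' @export
dmc_uncertainty <- function(sim_means_cm1) {
  stats::sd(sim_means_cm1) / sqrt(length(sim_means_cm1))
}

#' Histogram of an internal coordinate over walker snapshots
#'
#' Normalized density of a scalar coordinate extracted from every live
#' walker in every snapshot -- the DMC estimate of the ground-state
#' probability density in that coordinate (e.g. a torsional dihedral).
#'
#' @param snapshots list of walker matrices (from [run_dmc()]).
#' @param extract function mapping a coordinate column to a scalar; default
#'   identity on the first coordinate.
#' @param breaks passed to [graphics::hist()]-style binning via
#'   [base::cut()]; either a bin count or a vector of bin edges.
#' @return data.frame with `mid`, `density`, `count`; attribute `n_total`.
#' @export
walker_histogram <- function(snapshots, extract = function(col) col[1L],
                             breaks = 60) {
  if (!length(snapshots)) stop("need at least one walker snapshot")
  vals <- unlist(lapply(snapshots, function(W) apply(W, 2L, extract)))
  if (length(breaks) == 1L) {
    rng <- range(vals)
    if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1L], rng[2L], length.out = breaks + 1L)
  }
  h <- hist_counts(vals, breaks)
  width <- diff(breaks)
  dens <- h / (sum(h) * width)
  out <- data.frame(mid = (breaks[-1L] + breaks[-length(breaks)]) / 2,
                    density = dens, count = h)
  attr(out, "n_total") <- length(vals)
  out
}

# counts per bin (closed on the right, first bin closed both sides)
hist_counts <- function(x, breaks) {
  x <- x[x >= breaks[1L] & x <= breaks[length(breaks)]]
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(idx, nbins = length(breaks) - 1L)
}
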