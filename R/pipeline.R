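#' Config-driven end-to-end pipeline
#'
#' Chains the package stages -- synthetic data generation, low-level PIP
#' fit, correction fit, normal modes, DMC, AS SCIVR, torsion-model fit and
#' DVR -- from a single config list with one global seed. Every stage
#' writes plain-text artifacts into the output directory plus a manifest
#' of file hashes and derived seeds, so a rerun with the same config is
#' bit-identical.
#'
#' @param overrides named list merged over the defaults (one level deep).
#' @return the default config list.
#' @export
pipeline_config <- function(overrides = list()) {
  cfg <- list(
    seed = 1L,
    molecule = list(signature = c(3, 2, 1, 1, 1, 1),
                    elements = c("H", "H", "H", "O", "C", "C"),
                    delta_scale_cm1 = 300),
    corpus = list(n_train = 800, n_test = 250, energy_cap_cm1 = 35000,
                  gradients = FALSE),
    fit = list(degree_low = 2, degree_delta = 2, lambda_bohr = 2),
    dmc = list(n_walkers = 600, n_steps = 1500, n_equil = 500, dtau = 5,
               n_sims = 3, hole_floor_cm1 = 1000),
    ascivr = list(t_switch = 4000, t_sc = 8000, step = 10, n_traj = 12,
                  det_tol = 0.01),
    torsion = list(orders = c(6, 3), I_oh = 2.7, I_ch3 = 10.5),
    dvr = list(N_1d = 361, N_phi = 61, N_theta = 31, n_levels = 12)
  )
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  cfg
}

# per-stage derived seed, logged in the manifest
.stage_seed <- function(cfg, stage) {
  (as.integer(cfg$seed) * 131L + sum(utf8ToInt(stage))) %% 2000000000L
}

#' Run pipeline stages
#'
#' Stages: `"gen-data"`, `"fit-pes"`, `"fit-delta"`, `"normal-modes"`,
#' `"dmc"`, `"ascivr"`, `"torsion-fit"`, `"dvr1d"`, `"dvr2d"`, `"report"`.
#' Later stages consume the in-memory artifacts of earlier ones; a missing
#' prerequisite raises an error naming the stage that produces it.
#'
#' @param stages character vector of stage names, executed in the given
#'   order; default all, in dependency order.
#' @param config a [pipeline_config()] list.
#' @param outdir output directory for artifacts (created if needed).
#' @return invisibly, a list of stage results plus the manifest data.frame.
#' @export
run_pipeline <- function(stages = c("gen-data", "fit-pes", "fit-delta",
                                    "normal-modes", "dmc", "ascivr",
                                    "torsion-fit", "dvr1d", "dvr2d", "report"),
                         config = pipeline_config(), outdir = tempfile("vqrun")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  art <- list(config = config, outdir = outdir)
  manifest <- data.frame(stage = character(), artifact = character(),
                         md5 = character(), seed = integer())
  log_artifact <- function(stage, path, seed) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, artifact = basename(path),
      md5 = unname(tools::md5sum(path)), seed = seed))
  }
  need <- function(what, producer) {
    if (is.null(art[[what]])) {
      stop("missing upstream artifact '", what, "': run stage '", producer,
           "' first")
    }
    art[[what]]
  }

  for (stage in stages) {
    sseed <- .stage_seed(config, stage)
    if (stage == "gen-data") {
      mol <- make_model_molecule(config$molecule$signature,
                                 config$molecule$elements,
                                 seed = sseed,
                                 delta_scale_cm1 = config$molecule$delta_scale_cm1)
      corpus <- sample_corpus(mol, config$corpus$n_train + config$corpus$n_test,
                              config$corpus$energy_cap_cm1, seed = sseed,
                              gradients = config$corpus$gradients)
      art$mol <- mol
      art$train <- corpus_records(corpus, "low")[seq_len(config$corpus$n_train)]
      art$test <- corpus_records(corpus, "low")[config$corpus$n_train +
                                                  seq_len(config$corpus$n_test)]
      art$train_high <- corpus_records(corpus, "high")[seq_len(config$corpus$n_train)]
      path <- file.path(outdir, "corpus_low.dat")
      write_dataset(art$train, path)
      log_artifact(stage, path, sseed)
    } else if (stage == "fit-pes") {
      train <- need("train", "gen-data")
      basis <- generate_pip_basis(config$molecule$signature,
                                  config$fit$degree_low,
                                  lambda = config$fit$lambda_bohr)
      fit <- fit_surface(basis, train, use_gradients = config$corpus$gradients)
      art$fit_low <- fit
      art$v_ll <- pip_potential(fit, art$mol$labels)
      rep <- data.frame(n_p = basis$n_p, rmse_train_cm1 = fit$rmse_energy,
                        rmse_test_cm1 = evaluate_fit(fit, art$test)$rmse_energy)
      path <- file.path(outdir, "fit_low.csv")
      utils::write.csv(rep, path, row.names = FALSE)
      log_artifact(stage, path, sseed)
    } else if (stage == "fit-delta") {
      train <- need("train", "gen-data")
      basis <- generate_pip_basis(config$molecule$signature,
                                  config$fit$degree_delta,
                                  lambda = config$fit$lambda_bohr)
      dfit <- fit_delta(basis, train, art$train_high)
      art$delta <- dfit
      art$v_cc <- compose_delta(need("v_ll", "fit-pes"), dfit)
      path <- file.path(outdir, "fit_delta.csv")
      utils::write.csv(data.frame(shift_cm1 = dfit$shift_cm1,
                                  rmse_train_cm1 = dfit$fit$rmse_energy),
                       path, row.names = FALSE)
      log_artifact(stage, path, sseed)
    } else if (stage == "normal-modes") {
      mol <- need("mol", "gen-data")
      modes <- nm_analyze(hessian_fd(mol$high, mol$q_eq), mol$masses, mol$q_eq)
      art$modes <- modes
      path <- file.path(outdir, "frequencies.csv")
      utils::write.csv(data.frame(mode = seq_along(modes$frequencies),
                                  freq_cm1 = round(modes$frequencies, 2)),
                       path, row.names = FALSE)
      log_artifact(stage, path, sseed)
    } else if (stage == "dmc") {
      mol <- need("mol", "gen-data")
      cfgd <- config$dmc
      dres <- run_dmc(mol$high, rep(mol$masses, each = 3L),
                      dmc_config(n_walkers = cfgd$n_walkers, dtau = cfgd$dtau,
                                 n_steps = cfgd$n_steps, n_equil = cfgd$n_equil,
                                 n_sims = cfgd$n_sims, seed = sseed,
                                 hole_floor_cm1 = cfgd$hole_floor_cm1),
                      mol$q_eq, e_min = mol$e_min_high)
      art$dmc <- dres
      path <- file.path(outdir, "dmc_zpe.csv")
      utils::write.csv(data.frame(sim = seq_along(dres$sim_means_cm1),
                                  zpe_cm1 = dres$sim_means_cm1),
                       path, row.names = FALSE)
      log_artifact(stage, path, sseed)
      snap <- file.path(outdir, "walkers_final.xyz")
      write_xyz(lapply(seq_len(min(50L, ncol(dres$snapshots[[1L]]))),
                       function(k) geometry(mol$labels,
                                            dres$snapshots[[1L]][, k],
                                            mol$masses)),
                snap)
      log_artifact(stage, snap, sseed)
    } else if (stage == "ascivr") {
      mol <- need("mol", "gen-data")
      modes <- need("modes", "normal-modes")
      cfga <- config$ascivr
      mw <- mass_weighted_potential(mol$high, rep(mol$masses, each = 3L),
                                    mol$q_eq)
      # semiclassics on the lowest vibrational mode subspace is full-D for
      # the toy molecule; keep the run desk-scale
      conf <- as_config(t_switch = cfga$t_switch, t_sc = cfga$t_sc,
                        step = cfga$step, n_traj = cfga$n_traj,
                        det_tol = cfga$det_tol, seed = sseed)
      # project onto normal-coordinate representation via modes
      U <- modes$modes
      pes_nm <- make_potential(
        function(y) mw$value(U %*% y) - mol$e_min_high,
        grad = function(y) as.numeric(t(U) %*% mw$grad(U %*% y)),
        dim = ncol(U), domain = "normal-coordinate subspace")
      sc <- run_ascivr(pes_nm, modes$frequencies, conf)
      art$ascivr <- sc
      path <- file.path(outdir, "ascivr_spectrum.csv")
      utils::write.csv(data.frame(energy_cm1 = sc$density$energy_cm1,
                                  intensity = sc$density$intensity),
                       path, row.names = FALSE)
      log_artifact(stage, path, sseed)
    } else if (stage == "torsion-fit") {
      model <- fit_torsion2d(ethanol_torsion_constraints(),
                             orders = config$torsion$orders,
                             I_oh = config$torsion$I_oh,
                             I_ch3 = config$torsion$I_ch3)
      art$torsion <- model
      path <- file.path(outdir, "torsion_coefficients.csv")
      co <- rbind(
        data.frame(type = "cos", j = as.numeric(row(model$cmat)) - 1,
                   k = as.numeric(col(model$cmat)) - 1,
                   value = as.numeric(model$cmat)),
        data.frame(type = "sin", j = as.numeric(row(model$dmat)),
                   k = as.numeric(col(model$dmat)),
                   value = as.numeric(model$dmat)))
      utils::write.csv(co, path, row.names = FALSE)
      log_artifact(stage, path, sseed)
    } else if (stage == "dvr1d") {
      model <- need("torsion", "torsion-fit")
      res <- dvr_1d_oh_torsion(model, N = config$dvr$N_1d)
      art$dvr1d <- res
      path <- file.path(outdir, "dvr1d_levels.csv")
      utils::write.csv(data.frame(level = seq_len(8L),
                                  energy_cm1 = round(res$levels_cm1[1:8], 2)),
                       path, row.names = FALSE)
      log_artifact(stage, path, sseed)
    } else if (stage == "dvr2d") {
      model <- need("torsion", "torsion-fit")
      tab <- dvr_2d_table(model, N_phi = config$dvr$N_phi,
                          N_theta = config$dvr$N_theta,
                          n_levels = config$dvr$n_levels)
      art$dvr2d <- tab
      path <- file.path(outdir, "dvr2d_levels.csv")
      utils::write.csv(tab, path, row.names = FALSE)
      log_artifact(stage, path, sseed)
    } else if (stage == "report") {
      modes <- need("modes", "normal-modes")
      zpe_h <- harmonic_zpe(modes$frequencies)
      rep <- data.frame(method = c("harmonic",
                                   if (!is.null(art$dmc)) "dmc",
                                   if (!is.null(art$ascivr)) "ascivr"),
                        zpe_cm1 = c(round(zpe_h, 1),
                                    if (!is.null(art$dmc)) round(art$dmc$zpe_cm1, 1),
                                    if (!is.null(art$ascivr)) round(art$ascivr$zpe_cm1, 1)))
      path <- file.path(outdir, "zpe_report.csv")
      utils::write.csv(rep, path, row.names = FALSE)
      log_artifact(stage, path, sseed)
      art$report <- rep
    } else {
      stop("unknown stage: ", stage)
    }
  }
  mpath <- file.path(outdir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  art$manifest <- manifest
  invisible(art)
}
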