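#' Synthetic model molecules and training corpora
#'
#' The package ships no electronic-structure data. Instead, a model molecule
#' carries a pair of analytic surfaces that emulate a DFT-quality
#' ("low-level") and coupled-cluster-quality ("high-level") pair: the
#' high-level surface is a sum of pairwise Morse interactions whose
#' parameters depend only on the atom classes (hence exactly
#' permutationally invariant), and the low-level surface adds a smooth,
#' slowly varying class-symmetrized polynomial in the Morse variables --
#' the premise that makes a low-order correction fit work.
#'
#' @name synthetic_data
NULL

# unordered class-pair id for atoms i, j given per-atom class vector
.class_pair_id <- function(cls_i, cls_j, ncls) {
  a <- pmin(cls_i, cls_j); b <- pmax(cls_i, cls_j)
  (a - 1L) * ncls - ((a - 1L) * a) %/% 2L + b - a + 1L
}

# pairwise-Morse potential over all atom pairs, class-symmetric parameters;
# supports matrix input (3N x m). Returns vq_potential with analytic grad.
.pair_morse_potential <- function(natoms, pair_cp, De, a, re, domain) {
  pr <- pair_index(natoms)
  value <- function(x) {
    X <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
    m <- ncol(X)
    v <- numeric(m)
    for (p in seq_len(nrow(pr))) {
      i3 <- 3L * (pr[p, 1L] - 1L); j3 <- 3L * (pr[p, 2L] - 1L)
      dx <- X[i3 + 1:3, , drop = FALSE] - X[j3 + 1:3, , drop = FALSE]
      r <- sqrt(colSums(dx^2))
      cp <- pair_cp[p]
      y <- 1 - exp(-a[cp] * (r - re[cp]))
      v <- v + De[cp] * (y * y - 1)
    }
    if (is.matrix(x)) v else v[1L]
  }
  grad <- function(x) {
    g <- numeric(length(x))
    for (p in seq_len(nrow(pr))) {
      i3 <- 3L * (pr[p, 1L] - 1L); j3 <- 3L * (pr[p, 2L] - 1L)
      dx <- x[i3 + 1:3] - x[j3 + 1:3]
      r <- sqrt(sum(dx^2))
      cp <- pair_cp[p]
      ex <- exp(-a[cp] * (r - re[cp]))
      dVdr <- 2 * De[cp] * (1 - ex) * a[cp] * ex
      u <- dx / r
      g[i3 + 1:3] <- g[i3 + 1:3] + dVdr * u
      g[j3 + 1:3] <- g[j3 + 1:3] - dVdr * u
    }
    g
  }
  make_potential(value, grad = grad, dim = 3L * natoms, domain = domain)
}

# class-symmetrized smooth perturbation: c0 + sum_g c1_g S_g + c2_g S_g^2,
# S_g the sum of Morse variables over class-pair group g
.smooth_perturbation <- function(natoms, pair_cp, c1, c2, lambda, scale) {
  pr <- pair_index(natoms)
  ngrp <- length(c1)   # class-pair ids (some may have no atom pair)
  Svals <- function(x) {
    X <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
    xs <- matrix(0, ngrp, ncol(X))
    for (p in seq_len(nrow(pr))) {
      i3 <- 3L * (pr[p, 1L] - 1L); j3 <- 3L * (pr[p, 2L] - 1L)
      dx <- X[i3 + 1:3, , drop = FALSE] - X[j3 + 1:3, , drop = FALSE]
      xs[pair_cp[p], ] <- xs[pair_cp[p], ] + exp(-sqrt(colSums(dx^2)) / lambda)
    }
    xs
  }
  value <- function(x) {
    S <- Svals(x)
    v <- scale * colSums(c1 * S + c2 * S * S)
    if (is.matrix(x)) v else v[1L]
  }
  grad <- function(x) {
    S <- Svals(x)[, 1L]
    g <- numeric(length(x))
    for (p in seq_len(nrow(pr))) {
      gi <- pair_cp[p]
      i3 <- 3L * (pr[p, 1L] - 1L); j3 <- 3L * (pr[p, 2L] - 1L)
      dx <- x[i3 + 1:3] - x[j3 + 1:3]
      r <- sqrt(sum(dx^2))
      xv <- exp(-r / lambda)
      dVdx <- scale * (c1[gi] + 2 * c2[gi] * S[gi])
      dVdr <- dVdx * (-xv / lambda)
      u <- dx / r
      g[i3 + 1:3] <- g[i3 + 1:3] + dVdr * u
      g[j3 + 1:3] <- g[j3 + 1:3] - dVdr * u
    }
    g
  }
  list(value = value, grad = grad)
}

#' Build a synthetic model molecule with paired low/high-level surfaces
#'
#' @param signature equivalent-atom class sizes (sum = atom count >= 3).
#' @param elements one element symbol per class (recycled to atoms). The
#'   default 9-atom `c(3, 2, 1, 1, 1, 1)` molecule mimics an ethanol-like
#'   C2H6O composition: a methyl-type H3 class, an H2 class, and four
#'   distinct heavy/hydroxyl atoms.
#' @param seed RNG seed; identical seeds give bit-identical molecules.
#' @param delta_scale_cm1 target standard deviation scale of the low-minus-
#'   high perturbation over thermally displaced geometries (cm^-1). Default
#'   300 cm^-1, small against the ~35 000 cm^-1 sampling range, matching the
#'   premise that the correction surface varies slowly.
#' @return a `vq_model_molecule`: labels, masses, `high` and `low`
#'   `vq_potential`s, equilibrium geometry `q_eq`, and stored parameters.
#' @export
make_model_molecule <- function(signature = c(3, 2, 1, 1, 1, 1),
                                elements = c("H", "H", "H", "O", "C", "C"),
                                seed = 1L, delta_scale_cm1 = 300) {
  signature <- as.integer(signature)
  if (length(elements) != length(signature)) {
    stop("need one element per class: ", length(signature), " classes, got ",
         length(elements), " elements")
  }
  natoms <- sum(signature)
  if (natoms < 3L) stop("need at least 3 atoms")
  labels <- rep(elements, signature)
  masses <- element_mass(labels)
  cls <- rep(seq_along(signature), signature)
  ncls <- length(signature)
  pr <- pair_index(natoms)
  pair_cp <- .class_pair_id(cls[pr[, 1L]], cls[pr[, 2L]], ncls)
  ncp <- (ncls * (ncls + 1L)) %/% 2L

  rs <- .derive_rng_state(seed, "model-molecule")
  on.exit(.restore_rng_state(rs))
  De <- stats::runif(ncp, 0.04, 0.15)      # hartree
  a  <- stats::runif(ncp, 0.9, 1.4)        # bohr^-1
  re <- stats::runif(ncp, 2.2, 3.8)        # bohr
  high <- .pair_morse_potential(natoms, pair_cp, De, a, re,
                                "synthetic pairwise-Morse model")

  # seeded equilibrium search; retry starts until a true minimum is found
  q_eq <- NULL
  for (try in 1:25) {
    q0 <- as.numeric(stats::rnorm(3L * natoms, sd = 1.6)) +
      rep(3 * cos(seq_len(natoms) * 2), each = 3L) * 0.3
    opt <- stats::optim(q0, fn = high$value, gr = high$grad, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    opt <- stats::optim(opt$par, fn = high$value, gr = high$grad,
                        method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-15))
    if (max(abs(high$grad(opt$par))) > 1e-7) next
    H <- hessian_fd(high, opt$par, step = 1e-3)
    mw <- H / sqrt(outer(rep(masses, each = 3L), rep(masses, each = 3L)))
    ev <- eigen(mw, symmetric = TRUE, only.values = TRUE)$values
    nvib <- 3L * natoms - 6L
    if (ev[nvib] > 1e-10) { q_eq <- opt$par; break }   # all vib modes bound
  }
  if (is.null(q_eq)) stop("failed to locate a bound equilibrium for seed ", seed)

  # smooth perturbation, scaled on a probe cloud around equilibrium so its
  # spread is delta_scale_cm1 -- slowly varying against the Morse landscape
  c1 <- stats::rnorm(ncp); c2 <- stats::rnorm(ncp, sd = 0.3)
  probe <- matrix(q_eq, 3L * natoms, 60) +
    matrix(stats::rnorm(3L * natoms * 60, sd = 0.18), 3L * natoms)
  raw <- .smooth_perturbation(natoms, pair_cp, c1, c2, 2, 1)
  spread <- stats::sd(raw$value(probe))
  scale <- convert_energy(delta_scale_cm1, "cm1", "hartree") / spread
  pert <- .smooth_perturbation(natoms, pair_cp, c1, c2, 2, scale)
  low <- make_potential(function(x) high$value(x) + pert$value(x),
                        grad = function(x) high$grad(x) + pert$grad(x),
                        dim = 3L * natoms,
                        domain = "high-level + smooth class-symmetric perturbation")

  structure(list(signature = signature, elements = elements, labels = labels,
                 masses = masses, high = high, low = low,
                 perturbation = pert,
                 q_eq = q_eq,
                 e_min_high = high$value(q_eq), e_min_low = low$value(q_eq),
                 params = list(De = De, a = a, re = re, c1 = c1, c2 = c2,
                               scale = scale, seed = seed)),
            class = "vq_model_molecule")
}

#' @export
print.vq_model_molecule <- function(x, ...) {
  cat("<vq_model_molecule> signature", paste(x$signature, collapse = ""),
      "|", length(x$labels), "atoms:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Sample a geometry corpus by normal-mode displacement
#'
#' Draws seeded independent Gaussian displacements along the high-level
#' normal modes, with per-mode scale sqrt(kT_eff)/omega (classical
#' equipartition at an effective temperature), and rejects configurations
#' whose high-level energy exceeds `energy_cap_cm1` above the minimum.
#' Each record's effective temperature is drawn from a three-rung ladder
#' (kT, kT/2, kT/6), emulating the way an ab initio MD corpus is dense
#' near equilibrium while still reaching the cap, so the sampled energies
#' cover essentially the whole 0 to `energy_cap_cm1` window.
#'
#' @param mol a `vq_model_molecule`.
#' @param n number of records.
#' @param energy_cap_cm1 rejection cap above the high-level minimum (cm^-1).
#' @param seed RNG seed.
#' @param kt_cm1 effective temperature (cm^-1); default `energy_cap_cm1/15`.
#' @param gradients store analytic gradients on both surfaces.
#' @return a `vq_corpus`: geometries plus absolute low/high energies
#'   (hartree), their minima references, and optional gradients.
#' @export
sample_corpus <- function(mol, n, energy_cap_cm1 = 35000, seed = 1L,
                          kt_cm1 = NULL, gradients = TRUE) {
  if (n < 1L) stop("n must be >= 1")
  if (energy_cap_cm1 <= 0) stop("energy cap must be positive")
  if (is.null(kt_cm1)) kt_cm1 <- energy_cap_cm1 / 15
  kt <- convert_energy(kt_cm1, "cm1", "hartree")
  modes <- nm_analyze(hessian_fd(mol$high, mol$q_eq), mol$masses, mol$q_eq)
  omega_au <- convert_energy(modes$frequencies, "cm1", "hartree")
  sdvec <- if (kt > 0) sqrt(kt) / omega_au else rep(0, length(omega_au))
  cap <- convert_energy(energy_cap_cm1, "cm1", "hartree")
  msqrt <- sqrt(rep(mol$masses, each = 3L))

  rs <- .derive_rng_state(seed, "corpus")
  on.exit(.restore_rng_state(rs))
  geoms <- vector("list", n)
  e_high <- e_low <- numeric(n)
  grad_high <- grad_low <- if (gradients) vector("list", n) else NULL
  got <- 0L; tried <- 0L
  while (got < n) {
    batch <- max(64L, n - got)
    tried <- tried + batch
    rung <- sample(c(1, 0.5, 1/6), batch, replace = TRUE,
                   prob = c(0.5, 0.3, 0.2))
    qn <- matrix(stats::rnorm(length(sdvec) * batch, sd = sdvec), length(sdvec)) *
      rep(sqrt(rung), each = length(sdvec))
    disp <- (modes$modes %*% qn) / msqrt          # mass-weighted -> Cartesian
    X <- matrix(mol$q_eq, nrow = length(mol$q_eq), ncol = batch) + disp
    e <- mol$high$value(X) - mol$e_min_high
    ok <- which(e <= cap & e >= 0)
    for (k in ok) {
      if (got >= n) break
      got <- got + 1L
      geoms[[got]] <- geometry(mol$labels, X[, k], mol$masses)
      e_high[got] <- e[k] + mol$e_min_high
      e_low[got] <- mol$low$value(X[, k])
      if (gradients) {
        grad_high[[got]] <- mol$high$grad(X[, k])
        grad_low[[got]] <- mol$low$grad(X[, k])
      }
    }
    if (tried >= 200L && got / tried < 0.01) {
      stop("corpus sampling acceptance below 1% (cap ", energy_cap_cm1,
           " cm^-1 too low for kT ", kt_cm1, " cm^-1)")
    }
  }
  structure(list(mol_signature = mol$signature, labels = mol$labels,
                 geoms = geoms, e_high = e_high, e_low = e_low,
                 e_ref_high = mol$e_min_high, e_ref_low = mol$e_min_low,
                 grad_high = grad_high, grad_low = grad_low,
                 energy_cap_cm1 = energy_cap_cm1, kt_cm1 = kt_cm1,
                 seed = seed),
            class = "vq_corpus")
}

#' @export
print.vq_corpus <- function(x, ...) {
  e <- convert_energy(x$e_high - x$e_ref_high, "hartree", "cm1")
  cat("<vq_corpus>", length(x$geoms), "records | high-level energy range",
      round(min(e)), "-", round(max(e)), "cm-1\n")
  invisible(x)
}

#' Convert a corpus to energy/gradient records for one surface
#' @param corpus a `vq_corpus`.
#' @param level `"low"` or `"high"`.
#' @return list of `vq_record` with absolute energies.
#' @export
corpus_records <- function(corpus, level = c("low", "high")) {
  level <- match.arg(level)
  e <- if (level == "low") corpus$e_low else corpus$e_high
  gr <- if (level == "low") corpus$grad_low else corpus$grad_high
  tag <- if (level == "low") "low-level" else "high-level"
  lapply(seq_along(corpus$geoms), function(k) {
    energy_record(corpus$geoms[[k]], e[k],
                  gradient = if (is.null(gr)) NULL else gr[[k]], tag = tag)
  })
}

#' Data-selection plan for the sparse high-level subset
#'
#' Encodes the published selection recipe: take every `stride`-th geometry
#' (1-based: indices 1, 1+stride, ...) from the training pool, the first
#' half of the test pool, and `addon_count` high-energy geometries (above
#' `addon_threshold_cm1` relative to the pool minimum) from the remaining
#' half; then partition into final train/test sets with a seeded draw.
#'
#' @param train_pool,test_pool expected pool sizes.
#' @param stride selection stride over the training pool.
#' @param addon_count,addon_threshold_cm1 high-energy add-on rule.
#' @param train_size,test_size final partition sizes.
#' @param seed seed for the final partition.
#' @export
selection_plan <- function(train_pool = 8500, test_pool = 2500, stride = 8,
                           addon_count = 6, addon_threshold_cm1 = 30000,
                           train_size = 2069, test_size = 250, seed = 1L) {
  n_sel <- length(seq.int(1L, train_pool, by = stride)) +
    test_pool %/% 2L + addon_count
  if (train_size + test_size != n_sel) {
    stop("plan inconsistent: selection yields ", n_sel,
         " records but train+test = ", train_size + test_size)
  }
  structure(list(train_pool = train_pool, test_pool = test_pool,
                 stride = stride, addon_count = addon_count,
                 addon_threshold_cm1 = addon_threshold_cm1,
                 train_size = train_size, test_size = test_size, seed = seed),
            class = "vq_selection_plan")
}

#' Apply the sparse-selection recipe to low-level pools
#'
#' @param train_records,test_records record lists whose sizes match the
#'   plan's pools.
#' @param plan a [selection_plan()].
#' @return list with `selected` (the pooled records), `n_selected`,
#'   `train_ids`/`test_ids` (indices into `selected`), and the provenance of
#'   every selected record (`"stride"`, `"test-half"`, `"high-energy"`).
#' @export
select_ccsdt_subset <- function(train_records, test_records, plan) {
  if (length(train_records) != plan$train_pool ||
      length(test_records) != plan$test_pool) {
    stop("pool sizes (", length(train_records), ", ", length(test_records),
         ") do not match plan (", plan$train_pool, ", ", plan$test_pool, ")")
  }
  idx_stride <- seq.int(1L, plan$train_pool, by = plan$stride)
  half <- plan$test_pool %/% 2L
  idx_half <- seq_len(half)
  rest <- seq.int(half + 1L, plan$test_pool)
  e_rest <- vapply(test_records[rest], `[[`, 0, "energy")
  e_all <- c(vapply(train_records, `[[`, 0, "energy"),
             vapply(test_records, `[[`, 0, "energy"))
  thr <- min(e_all) + convert_energy(plan$addon_threshold_cm1, "cm1", "hartree")
  cand <- rest[e_rest > thr]
  if (length(cand) < plan$addon_count) {
    stop("only ", length(cand), " high-energy candidates above ",
         plan$addon_threshold_cm1, " cm^-1; plan needs ", plan$addon_count)
  }
  idx_addon <- cand[seq_len(plan$addon_count)]
  selected <- c(train_records[idx_stride], test_records[idx_half],
                test_records[idx_addon])
  origin <- c(rep("stride", length(idx_stride)),
              rep("test-half", length(idx_half)),
              rep("high-energy", length(idx_addon)))
  n_sel <- length(selected)
  rs <- .derive_rng_state(plan$seed, "selection-partition")
  on.exit(.restore_rng_state(rs))
  train_ids <- sort(sample.int(n_sel, plan$train_size))
  test_ids <- setdiff(seq_len(n_sel), train_ids)
  list(selected = selected, n_selected = n_sel,
       n_stride = length(idx_stride), origin = origin,
       train_ids = train_ids, test_ids = test_ids)
}

# --- seed plumbing ---------------------------------------------------------

# Derive an independent RNG stream from (seed, label) without disturbing the
# caller's RNG state; returns the previous state for .restore_rng_state().
.derive_rng_state <- function(seed, label) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  sub <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 10000L
  set.seed((as.integer(seed) %% 2000000000L) + sub)
  old
}

.restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
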