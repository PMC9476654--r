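#' Morse variables of a geometry
#'
#' Transforms every internuclear distance r_ab to the bounded fitting
#' coordinate x_ab = exp(-r_ab / lambda). Pairs follow the canonical
#' lexicographic (i < j) ordering of [pair_index()]. The range parameter
#' lambda defaults to 2 bohr.
#'
#' @param geom a `vq_geometry`.
#' @param lambda range parameter, bohr (> 0).
#' @return numeric vector of length n(n-1)/2, each value in (0, 1].
#' @export
morse_variables <- function(geom, lambda = 2) {
  if (lambda <= 0) stop("lambda must be positive")
  exp(-pair_distances(geom) / lambda)
}

# --- permutation machinery -------------------------------------------------

# all permutations of 1..n (n small)
.perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .perms(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub)))
  }
  do.call(rbind, out)
}

# atom permutation group induced by a class signature: atoms are ordered in
# class blocks (first class-size atoms interchangeable, then the next, ...).
# Returns a matrix, one atom permutation per row.
.signature_group <- function(signature) {
  stopifnot(all(signature >= 1))
  blocks <- lapply(signature, .perms)
  offs <- cumsum(c(0L, signature[-length(signature)]))
  g <- matrix(1L, nrow = 1L, ncol = 0L)
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]] + offs[b]
    g <- g[rep(seq_len(nrow(g)), each = nrow(blk)), , drop = FALSE]
    g <- cbind(g, blk[rep_len(seq_len(nrow(blk)), nrow(g)), , drop = FALSE])
  }
  g
}

# permutation induced on canonical pairs by an atom permutation:
# returns integer vector ip with ip[k] = index of the image of pair k
.induced_pair_perm <- function(atom_perm) {
  n <- length(atom_perm)
  pr <- pair_index(n)
  key <- function(i, j) (pmin(i, j) - 1L) * n + pmax(i, j)
  lookup <- integer(n * n)
  lookup[key(pr[, 1L], pr[, 2L])] <- seq_len(nrow(pr))
  lookup[key(atom_perm[pr[, 1L]], atom_perm[pr[, 2L]])]
}

# enumerate exponent matrices of all monomials with total degree <= maxdeg
# over m variables (row = monomial, includes the constant row of zeros)
.enumerate_monomials <- function(m, maxdeg) {
  E <- matrix(0L, 1L, m)     # constant
  if (maxdeg == 0L) return(E)
  tup <- matrix(seq_len(m), ncol = 1L)   # degree-1 tuples
  all_tup <- list(tup)
  if (maxdeg > 1L) {
    for (k in 2:maxdeg) {
      last <- tup[, k - 1L]
      counts <- m - last + 1L
      newv <- sequence(counts, from = last)
      rows <- rep(seq_len(nrow(tup)), counts)
      tup <- cbind(tup[rows, , drop = FALSE], newv)
      all_tup[[k]] <- tup
    }
  }
  for (k in seq_along(all_tup)) {
    t_k <- all_tup[[k]]
    Ek <- matrix(0L, nrow(t_k), m)
    for (col in seq_len(ncol(t_k))) {
      idx <- cbind(seq_len(nrow(t_k)), t_k[, col])
      Ek[idx] <- Ek[idx] + 1L
    }
    E <- rbind(E, Ek)
  }
  E
}

#' Permutationally invariant polynomial basis
#'
#' Generates the PIP basis for a molecule whose identical-atom structure is
#' given by a class signature (e.g. `c(3, 2, 1, 1, 1, 1)` for a 9-atom
#' molecule with one class of three and one class of two equivalent atoms).
#' Monomials in the n(n-1)/2 Morse variables of total degree up to
#' `max_degree` are grouped into orbits of the permutation group induced on
#' atom pairs; each basis function is the sum of the distinct monomials of
#' one orbit, so invariance holds by construction. The constant monomial is
#' a basis member.
#'
#' @param signature integer vector of equivalent-atom class sizes.
#' @param max_degree maximum total polynomial degree (>= 0).
#' @param lambda Morse range parameter (bohr) recorded for evaluation.
#' @return an object of class `vq_pip_basis` with element `n_p`, the basis
#'   size, and the orbit structure used by [pip_design()].
#' @export
generate_pip_basis <- function(signature, max_degree, lambda = 2) {
  if (max_degree < 0) stop("max_degree must be >= 0")
  signature <- as.integer(signature)
  natoms <- sum(signature)
  if (natoms < 2L) stop("need at least 2 atoms")
  m <- (natoms * (natoms - 1L)) %/% 2L
  E <- .enumerate_monomials(m, as.integer(max_degree))
  grp <- .signature_group(signature)
  ipers <- apply(grp, 1L, .induced_pair_perm)   # m x |G|
  # canonical orbit key: lexicographic minimum over the group of the
  # permuted exponent string (exponents are single digits for degree <= 9)
  keyfun <- function(M) do.call(paste0, as.data.frame(M))
  canon <- keyfun(E)
  if (ncol(grp) > 0L && nrow(grp) > 1L) {
    for (g in 2:nrow(grp)) {
      perm <- ipers[, g]
      # sigma sends variable k to perm[k]; the transformed monomial has
      # exponent e[k] on variable perm[k]
      Eg <- E
      Eg[, perm] <- E
      canon <- pmin(canon, keyfun(Eg))
    }
  }
  orbit_key <- unique(canon)
  orbit_id <- match(canon, orbit_key)
  structure(list(signature = signature, n_atoms = natoms, n_pairs = m,
                 lambda = lambda, max_degree = as.integer(max_degree),
                 exponents = E, orbit_id = orbit_id,
                 n_p = length(orbit_key)),
            class = "vq_pip_basis")
}

#' @export
print.vq_pip_basis <- function(x, ...) {
  cat("<vq_pip_basis> signature", paste(x$signature, collapse = ""),
      "| degree", x$max_degree, "| n_p =", x$n_p,
      "(", nrow(x$exponents), "monomials )\n")
  invisible(x)
}

#' Burnside orbit count for a PIP basis
#'
#' Independent count of symmetry-distinct monomials of total degree up to
#' `max_degree` via Burnside's lemma: for each group element, monomials
#' fixed by the induced pair permutation are counted from the cycle type by
#' a generating-function convolution, and the counts are averaged.
#'
#' @inheritParams generate_pip_basis
#' @return integer orbit count (includes the constant function).
#' @export
pip_orbit_count_burnside <- function(signature, max_degree) {
  signature <- as.integer(signature)
  grp <- .signature_group(signature)
  total <- 0
  for (g in seq_len(nrow(grp))) {
    ip <- .induced_pair_perm(grp[g, ])
    seen <- logical(length(ip))
    cyc <- integer(0)
    for (s in seq_along(ip)) {
      if (!seen[s]) {
        len <- 0L; t <- s
        while (!seen[t]) { seen[t] <- TRUE; t <- ip[t]; len <- len + 1L }
        cyc <- c(cyc, len)
      }
    }
    # number of exponent assignments constant on cycles with total degree
    # <= max_degree: coefficient sum of prod_c 1/(1 - x^len_c)
    co <- c(1, numeric(max_degree))
    for (len in cyc) {
      if (len <= max_degree) {
        for (d in seq(len, max_degree)) co[d + 1L] <- co[d + 1L] + co[d + 1L - len]
      }
    }
    total <- total + sum(co)
  }
  as.integer(round(total / nrow(grp)))
}

# --- design matrices and fitting -------------------------------------------

# monomial values for one Morse-variable vector x: prod x^e per row of E
.mono_values <- function(E, x) {
  v <- rep(1, nrow(E))
  for (col in seq_len(ncol(E))) {
    e <- E[, col]
    nz <- e > 0L
    if (any(nz)) v[nz] <- v[nz] * x[col]^e[nz]
  }
  v
}

#' PIP design matrix (and gradient rows) for a set of geometries
#'
#' Rows are basis-function values per geometry; with `gradients = TRUE` the
#' analytic derivative rows with respect to Cartesian coordinates (chain
#' rule through x = exp(-r/lambda)) are appended, 3N per geometry.
#'
#' @param basis a `vq_pip_basis`.
#' @param geoms list of `vq_geometry`.
#' @param gradients append Cartesian-derivative rows.
#' @return list with `A` (design matrix), `n_energy_rows`, `n_grad_rows`.
#' @export
pip_design <- function(basis, geoms, gradients = FALSE) {
  E <- basis$exponents
  oid <- basis$orbit_id
  np <- basis$n_p
  nE <- length(geoms)
  ncoord <- if (nE) length(geoms[[1L]]$coords) else 0L
  A_e <- matrix(0, nE, np)
  A_g <- if (gradients) matrix(0, nE * ncoord, np) else NULL
  for (r in seq_len(nE)) {
    g <- geoms[[r]]
    x <- morse_variables(g, basis$lambda)
    mv <- .mono_values(E, x)
    A_e[r, ] <- rowsum(mv, oid)[, 1L]
    if (gradients) {
      pr <- pair_index(n_atoms(g))
      rvec <- pair_distances(g)
      xyz <- coord_matrix(g)
      # dB/dx_v aggregated over orbit members
      for (v in seq_len(basis$n_pairs)) {
        e <- E[, v]
        nz <- e > 0L
        if (!any(nz)) next
        dmono <- numeric(nrow(E))
        dmono[nz] <- e[nz] * mv[nz] / x[v]
        dBdx <- rowsum(dmono, oid)[, 1L]
        # dx/dr = -x/lambda ; dr/dcoords = unit vector on atoms (i, j)
        i <- pr[v, 1L]; j <- pr[v, 2L]
        u <- (xyz[, i] - xyz[, j]) / rvec[v]
        fac <- -x[v] / basis$lambda
        rows_i <- (r - 1L) * ncoord + (3L * (i - 1L) + 1:3)
        rows_j <- (r - 1L) * ncoord + (3L * (j - 1L) + 1:3)
        A_g[rows_i, ] <- A_g[rows_i, ] + outer(u * fac, dBdx)
        A_g[rows_j, ] <- A_g[rows_j, ] - outer(u * fac, dBdx)
      }
    }
  }
  list(A = if (gradients) rbind(A_e, A_g) else A_e,
       n_energy_rows = nE, n_grad_rows = if (gradients) nE * ncoord else 0L)
}

# minimum-norm least squares by SVD with rank diagnostics
.svd_solve <- function(A, b, w = NULL) {
  if (!is.null(w)) { A <- A * w; b <- b * w }
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * sv$d[1L]
  keep <- sv$d > tol
  coef <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep])
  list(coef = as.numeric(coef), rank = sum(keep),
       condition = sv$d[1L] / sv$d[max(which(keep))],
       rank_deficient = sum(keep) < ncol(A))
}

#' Fit PIP coefficients to energies (and optionally gradients)
#'
#' Solves the joint linear least-squares problem for the basis coefficients
#' from absolute energies and, when requested, Cartesian gradients (analytic
#' basis derivatives through the Morse chain rule). Gradient rows are
#' down-weighted relative to energy rows by `grad_weight` (default 1/3N).
#' Rank deficiency is resolved by the minimum-norm solution and flagged.
#'
#' @param basis a `vq_pip_basis`.
#' @param records list of `vq_record` (gradients required per record only
#'   when `use_gradients = TRUE`).
#' @param use_gradients include gradient rows in the fit.
#' @param grad_weight weight of each gradient row relative to an energy row.
#' @return a `vq_pip_fit` with coefficients, train RMSEs (cm^-1 and
#'   cm^-1/bohr) and rank diagnostics.
#' @export
fit_surface <- function(basis, records, use_gradients = FALSE,
                        grad_weight = NULL) {
  geoms <- lapply(records, `[[`, "geom")
  energies <- vapply(records, `[[`, 0, "energy")
  des <- pip_design(basis, geoms, gradients = use_gradients)
  b <- energies
  w <- rep(1, des$n_energy_rows)
  if (use_gradients) {
    grads <- lapply(records, `[[`, "gradient")
    if (any(vapply(grads, is.null, TRUE))) {
      stop("use_gradients = TRUE but some records have no gradient")
    }
    ncoord <- length(geoms[[1L]]$coords)
    if (is.null(grad_weight)) grad_weight <- 1 / ncoord
    b <- c(b, unlist(grads))
    w <- c(w, rep(grad_weight, des$n_grad_rows))
  }
  sol <- .svd_solve(des$A, b, sqrt(w))
  pred <- as.numeric(des$A %*% sol$coef)
  res_e <- pred[seq_len(des$n_energy_rows)] - energies
  rmse_e <- convert_energy(sqrt(mean(res_e^2)), "hartree", "cm1")
  rmse_g <- NA_real_
  if (use_gradients) {
    res_g <- pred[-seq_len(des$n_energy_rows)] - b[-seq_len(des$n_energy_rows)]
    rmse_g <- convert_energy(sqrt(mean(res_g^2)), "hartree", "cm1")
  }
  structure(list(basis = basis, coefficients = sol$coef,
                 rmse_energy = rmse_e, rmse_gradient = rmse_g,
                 rank = sol$rank, condition = sol$condition,
                 rank_deficient = sol$rank_deficient,
                 n_records = length(records),
                 used_gradients = use_gradients),
            class = "vq_pip_fit")
}

#' @export
print.vq_pip_fit <- function(x, ...) {
  cat("<vq_pip_fit> n_p =", x$basis$n_p, "| train RMSE",
      signif(x$rmse_energy, 5), "cm-1",
      if (x$used_gradients) paste("|", signif(x$rmse_gradient, 5), "cm-1/bohr"),
      if (x$rank_deficient) "| RANK DEFICIENT (minimum-norm)", "\n")
  invisible(x)
}

#' Potential evaluator from a PIP fit
#'
#' The returned evaluator takes a flat Cartesian coordinate vector (bohr;
#' atom order must match the basis signature blocks) and returns the fitted
#' energy in hartree, with analytic gradient.
#'
#' @param fit a `vq_pip_fit`.
#' @param labels atom labels used to rebuild geometries internally.
#' @return a `vq_potential`.
#' @export
pip_potential <- function(fit, labels) {
  basis <- fit$basis
  coef <- fit$coefficients
  masses <- rep(1, length(labels))  # masses irrelevant for evaluation
  eval1 <- function(x) {
    g <- geometry(labels, x, masses)
    sum(pip_design(basis, list(g))$A[1L, ] * coef)
  }
  value <- function(x) {
    if (is.matrix(x)) apply(x, 2L, eval1) else eval1(x)
  }
  grad <- function(x) {
    g <- geometry(labels, x, masses)
    des <- pip_design(basis, list(g), gradients = TRUE)
    as.numeric(des$A[-1L, , drop = FALSE] %*% coef)
  }
  make_potential(value, grad = grad, dim = 3L * length(labels),
                 domain = "PIP fit; valid inside the training energy range")
}

#' Evaluate fit errors on a held-out record set
#' @param fit a `vq_pip_fit`.
#' @param records test records.
#' @param gradients also compute the gradient RMSE.
#' @return list with `rmse_energy` (cm^-1) and `rmse_gradient` (cm^-1/bohr).
#' @export
evaluate_fit <- function(fit, records, gradients = FALSE) {
  geoms <- lapply(records, `[[`, "geom")
  energies <- vapply(records, `[[`, 0, "energy")
  des <- pip_design(fit$basis, geoms, gradients = gradients)
  pred <- as.numeric(des$A %*% fit$coefficients)
  res_e <- pred[seq_len(des$n_energy_rows)] - energies
  out <- list(rmse_energy = convert_energy(sqrt(mean(res_e^2)), "hartree", "cm1"),
              rmse_gradient = NA_real_)
  if (gradients) {
    gtrue <- unlist(lapply(records, `[[`, "gradient"))
    res_g <- pred[-seq_len(des$n_energy_rows)] - gtrue
    out$rmse_gradient <- convert_energy(sqrt(mean(res_g^2)), "hartree", "cm1")
  }
  out
}

#' Fit the high-minus-low correction surface
#'
#' Trains a low-order PIP surface on the difference between paired
#' high-level and low-level energies, referenced so the minimum difference
#' maps to zero. The reference shift is returned (in cm^-1) and is added
#' back by [compose_delta()] so the composed surface reproduces absolute
#' high-level energies.
#'
#' @param basis a low-degree `vq_pip_basis` (degree 2 is the conventional
#'   choice for a slowly varying correction).
#' @param low_records,high_records paired record lists on identical
#'   geometries.
#' @return a `vq_delta_fit`: the underlying `vq_pip_fit`, the reference
#'   shift (cm^-1) and the correction `vq_potential`.
#' @export
fit_delta <- function(basis, low_records, high_records) {
  if (length(low_records) != length(high_records)) {
    stop("low/high record lists must be paired (equal length)")
  }
  for (k in seq_along(low_records)) {
    if (max(abs(low_records[[k]]$geom$coords - high_records[[k]]$geom$coords)) > 1e-10) {
      stop("record ", k, " is unpaired: geometries differ")
    }
  }
  diff_h <- vapply(high_records, `[[`, 0, "energy") -
    vapply(low_records, `[[`, 0, "energy")
  shift <- min(diff_h)
  target <- lapply(seq_along(low_records), function(k) {
    energy_record(low_records[[k]]$geom, diff_h[k] - shift, tag = "correction")
  })
  fit <- fit_surface(basis, target, use_gradients = FALSE)
  labels <- low_records[[1L]]$geom$labels
  structure(list(fit = fit, shift_cm1 = convert_energy(shift, "hartree", "cm1"),
                 shift_hartree = shift,
                 potential = pip_potential(fit, labels)),
            class = "vq_delta_fit")
}

#' Compose a base surface with a fitted correction
#'
#' Returns the corrected surface: base + correction + reference shift, so
#' that it tracks absolute high-level energies pointwise.
#'
#' @param v_ll base (low-level) `vq_potential`.
#' @param delta a `vq_delta_fit` (or a bare `vq_potential`, then
#'   `shift_hartree` applies).
#' @param shift_hartree reference shift when `delta` is a bare potential.
#' @return a `vq_potential` of class also `vq_composed`.
#' @export
compose_delta <- function(v_ll, delta, shift_hartree = 0) {
  if (inherits(delta, "vq_delta_fit")) {
    shift_hartree <- delta$shift_hartree
    delta <- delta$potential
  }
  shifted <- make_potential(function(x) {
    v <- delta$value(x)
    v + shift_hartree
  }, grad = delta$grad, dim = delta$dim, domain = delta$domain)
  out <- pot_add(v_ll, shifted)
  class(out) <- c("vq_composed", class(out))
  out$ref_shift_cm1 <- convert_energy(shift_hartree, "hartree", "cm1")
  out
}
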