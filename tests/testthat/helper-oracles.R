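# Independent oracles used across the test files. These deliberately avoid
# the package's own algorithms: orbit counting is a breadth-first orbit
# enumeration over explicit group elements, rotor levels come from a
# plane-wave variational diagonalization, line (non-periodic) problems from
# a sinc-DVR, and coherent-state overlaps from numerical quadrature.

# atom permutations of a class signature, brute force
signature_perms <- function(signature) {
  offs <- cumsum(c(0L, signature[-length(signature)]))
  block_perms <- lapply(seq_along(signature), function(b) {
    n <- signature[b]
    if (n == 1L) return(list(offs[b] + 1L))
    idx <- offs[b] + seq_len(n)
    lapply(asplit(gtools_permutations(n), 1L), function(p) idx[p])
  })
  grids <- expand.grid(lapply(block_perms, seq_along))
  lapply(seq_len(nrow(grids)), function(r) {
    unlist(lapply(seq_along(signature), function(b) {
      block_perms[[b]][[grids[r, b]]]
    }))
  })
}

# permutations of 1..n as a matrix (recursive, no extra packages)
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- gtools_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# brute-force orbit count of monomials (degree <= maxdeg over the pair
# variables) under the induced group: BFS orbit labelling with string keys
brute_orbit_count <- function(signature, maxdeg) {
  natoms <- sum(signature)
  pairs <- which(upper.tri(matrix(0, natoms, natoms)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  m <- nrow(pairs)
  pid <- function(i, j) which(pairs[, 1L] == pmin(i, j) & pairs[, 2L] == pmax(i, j))
  induced <- lapply(signature_perms(signature), function(ap) {
    vapply(seq_len(m), function(k) pid(ap[pairs[k, 1L]], ap[pairs[k, 2L]]), 0L)
  })
  # enumerate exponent vectors of total degree <= maxdeg
  expos <- list(integer(m))
  grow <- function(e, start, left) {
    if (left == 0L) return(NULL)
    for (v in start:m) {
      e2 <- e; e2[v] <- e2[v] + 1L
      expos[[length(expos) + 1L]] <<- e2
      grow(e2, v, left - 1L)
    }
  }
  if (maxdeg > 0L) grow(integer(m), 1L, maxdeg)
  keys <- vapply(expos, paste, "", collapse = ",")
  seen <- new.env(hash = TRUE)
  count <- 0L
  for (e in expos) {
    k0 <- paste(e, collapse = ",")
    if (!is.null(seen[[k0]])) next
    count <- count + 1L
    for (ip in induced) {
      img <- integer(m); img[ip] <- e
      seen[[paste(img, collapse = ",")]] <- TRUE
    }
  }
  count
}

# plane-wave variational levels of a periodic rotor: basis exp(i m phi),
# potential matrix elements from an FFT on a fine grid
plane_wave_rotor_levels <- function(V, I_amu_bohr2, M = 60, n_levels = 10) {
  I_me <- I_amu_bohr2 * 1822.888486209
  B <- 219474.6313632 / (2 * I_me)     # cm^-1
  ngrid <- 2048
  phi <- 2 * pi * seq(0, ngrid - 1) / ngrid
  vhat <- stats::fft(V(phi)) / ngrid    # V(phi) = sum_k vhat_k exp(i k phi)
  ms <- -M:M
  H <- matrix(0 + 0i, length(ms), length(ms))
  for (a in seq_along(ms)) {
    for (b in seq_along(ms)) {
      k <- ms[a] - ms[b]
      kk <- ((k %% ngrid) + ngrid) %% ngrid
      H[a, b] <- vhat[kk + 1L]
      if (a == b) H[a, b] <- H[a, b] + B * ms[a]^2
    }
  }
  ev <- sort(Re(eigen((H + Conj(t(H))) / 2, only.values = TRUE)$values))
  ev[seq_len(n_levels)] - ev[1L]
}

# sinc (Colbert-Miller line) DVR for a 1-D bound problem on [-L, L]
sinc_dvr_1d <- function(V, mass, L, N = 301) {
  x <- seq(-L, L, length.out = N)
  d <- x[2L] - x[1L]
  Tm <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      Tm[i, j] <- if (i == j) pi^2 / 3 else 2 * (-1)^(i - j) / (i - j)^2
    }
  }
  Tm <- Tm / (2 * mass * d^2)
  H <- Tm + diag(V(x))
  ev <- eigen(H, symmetric = TRUE)
  ord <- order(ev$values)
  list(x = x, levels = ev$values[ord], psi = ev$vectors[, ord, drop = FALSE])
}

# numerical quadrature overlap of two 1-D coherent states
# g(x; p, q) = (gamma/pi)^(1/4) exp(-gamma (x-q)^2 / 2 + i p (x-q))
quad_coherent_overlap <- function(p1, q1, p2, q2, gamma) {
  f <- function(x) {
    g1 <- (gamma / pi)^0.25 * exp(-gamma * (x - q1)^2 / 2 + 1i * p1 * (x - q1))
    g2 <- (gamma / pi)^0.25 * exp(-gamma * (x - q2)^2 / 2 + 1i * p2 * (x - q2))
    Conj(g1) * g2
  }
  lim <- max(abs(c(q1, q2))) + 12 / sqrt(gamma)
  xs <- seq(-lim, lim, length.out = 20001)
  h <- xs[2L] - xs[1L]
  vals <- f(xs)
  sum(vals) * h - (vals[1L] + vals[length(vals)]) * h / 2
}

# shared fixtures, built once per test run
fixture_env <- new.env()

fixture_molecule <- function() {
  if (is.null(fixture_env$mol)) fixture_env$mol <- make_model_molecule(seed = 42)
  fixture_env$mol
}

fixture_torsion_model <- function() {
  if (is.null(fixture_env$torsion)) {
    fixture_env$torsion <- fit_torsion2d(ethanol_torsion_constraints())
  }
  fixture_env$torsion
}

# cheap record list with prescribed energies (for selection-plan tests)
stub_records <- function(energies) {
  g <- geometry("H", c(0, 0, 0))
  lapply(energies, function(e) energy_record(g, e))
}
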