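#' Potential evaluator contract
#'
#' A potential evaluator wraps a function `geometry -> energy (hartree)`
#' with optional analytic gradient (hartree/bohr) and a declared validity
#' domain. The `value` function must also accept a matrix with 3N rows
#' (one column per configuration) and return a vector, which is what the
#' diffusion Monte Carlo ensemble propagation relies on for speed.
#'
#' @param value function of a flat coordinate vector (bohr) or 3N x m matrix.
#' @param grad optional gradient function (flat vector in, flat vector out).
#' @param hess optional Hessian function (3N x 3N matrix out).
#' @param dim number of coordinates the evaluator expects (3N), or NULL.
#' @param domain free-text description of the validity domain.
#' @return an object of class `vq_potential`.
#' @export
make_potential <- function(value, grad = NULL, hess = NULL, dim = NULL,
                           domain = "unspecified") {
  structure(list(value = value, grad = grad, hess = hess,
                 dim = dim, domain = domain),
            class = "vq_potential")
}

#' @export
print.vq_potential <- function(x, ...) {
  cat("<vq_potential> dim =", if (is.null(x$dim)) "?" else x$dim,
      "| gradient:", !is.null(x$grad), "| domain:", x$domain, "\n")
  invisible(x)
}

#' Evaluate a potential
#' @param pes a `vq_potential`.
#' @param x flat coordinate vector (or 3N x m matrix of configurations).
#' @return energy (hartree), scalar or vector.
#' @export
pot_value <- function(pes, x) pes$value(x)

#' Evaluate a potential gradient (analytic if available, else central FD)
#' @param pes a `vq_potential`.
#' @param x flat coordinate vector.
#' @param step finite-difference step (bohr) for the fallback.
#' @export
pot_grad <- function(pes, x, step = 1e-5) {
  if (!is.null(pes$grad)) return(pes$grad(x))
  g <- numeric(length(x))
  for (k in seq_along(x)) {
    xp <- x; xp[k] <- x[k] + step
    xm <- x; xm[k] <- x[k] - step
    g[k] <- (pes$value(xp) - pes$value(xm)) / (2 * step)
  }
  g
}

#' Sum of two potentials (used to compose a base surface with a correction)
#' @param a,b `vq_potential` objects on the same coordinates.
#' @return a `vq_potential` evaluating `a + b` pointwise (gradients add).
#' @export
pot_add <- function(a, b) {
  grad <- if (!is.null(a$grad) && !is.null(b$grad)) {
    function(x) a$grad(x) + b$grad(x)
  } else NULL
  make_potential(function(x) a$value(x) + b$value(x), grad = grad,
                 dim = a$dim %||% b$dim,
                 domain = paste0("sum(", a$domain, ", ", b$domain, ")"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
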