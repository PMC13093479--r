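#' Potential-energy-surface contract
#'
#' Wraps user-supplied energy (and optionally gradient / Hessian) callables
#' into the uniform interface the path machinery consumes. Missing derivatives
#' fall back to central finite differences of the energy, with steps in the
#' coordinate units the PES itself is defined in (bohr for molecular systems,
#' mass-weighted a.u. for model potentials defined directly in those
#' coordinates).
#'
#' @param energy function(x) -> hartree, x the full coordinate vector.
#' @param gradient optional function(x) -> gradient vector (hartree per
#'   coordinate unit).
#' @param hessian optional function(x) -> Hessian matrix.
#' @param fd_grad_step central-difference step for the gradient fallback.
#' @param fd_hess_step central-difference step for the Hessian fallback.
#' @param ... further fields stored on the object (e.g. a reference system).
#' @return an object of class \code{pes} with elements \code{energy},
#'   \code{gradient}, \code{hessian}.
#' @export
pes_contract <- function(energy, gradient = NULL, hessian = NULL,
                         fd_grad_step = 1e-4, fd_hess_step = 5e-3, ...) {
  stopifnot(is.function(energy))
  if (is.null(gradient)) {
    gradient <- function(x) fd_gradient(energy, x, step = fd_grad_step)
  }
  if (is.null(hessian)) {
    hessian <- function(x) fd_hessian(energy, x, step = fd_hess_step)
  }
  structure(list(energy = energy, gradient = gradient, hessian = hessian,
                 ...),
            class = "pes")
}

#' Finite-difference derivatives of a scalar function
#'
#' Central stencils: 2-point per coordinate for the gradient, 4-point mixed
#' differences for the Hessian (symmetrised).
#'
#' @param f function of a numeric vector returning a scalar.
#' @param x evaluation point.
#' @param step finite-difference step.
#' @return \code{fd_gradient}: numeric vector; \code{fd_hessian}: symmetric
#'   matrix.
#' @export
fd_gradient <- function(f, x, step = 1e-4) {
  n <- length(x)
  g <- numeric(n)
  for (i in seq_len(n)) {
    e <- numeric(n); e[i] <- step
    g[i] <- (f(x + e) - f(x - e)) / (2 * step)
  }
  g
}

#' @rdname fd_gradient
#' @export
fd_hessian <- function(f, x, step = 5e-3) {
  n <- length(x)
  H <- matrix(0, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) {
    ei <- numeric(n); ei[i] <- step
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / step^2
    if (i < n) for (j in (i + 1):n) {
      ej <- numeric(n); ej[j] <- step
      H[i, j] <- (f(x + ei + ej) - f(x + ei - ej) -
                  f(x - ei + ej) + f(x - ei - ej)) / (4 * step^2)
      H[j, i] <- H[i, j]
    }
  }
  H
}
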