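#' Normal-mode analysis at a stationary point
#'
#' Mass-weights the Cartesian Hessian, optionally projects out rigid
#' translations and rotations, and diagonalises in the remaining subspace.
#' Frequencies are reported as signed wavenumbers: omega_k =
#' sign(lambda_k) sqrt(|lambda_k|), so a negative entry encodes an imaginary
#' frequency. At a proper transition state of a nonlinear N-atom molecule this
#' yields exactly one imaginary and 3N-7 real modes.
#'
#' Translation/rotation handling uses an explicit orthonormal basis of the
#' mass-weighted translation (and, for molecules, rotation) space; the Hessian
#' is represented in the orthogonal complement, which is more robust than
#' relying on six numerically-zero eigenvalues.
#'
#' @param system a \code{\link{geometry}} or \code{\link{model_system}}.
#' @param hessian Cartesian Hessian (hartree per coordinate unit squared),
#'   dimension matching the coordinate vector.
#' @param project_tr project out translations/rotations; default \code{TRUE}
#'   for geometries, \code{FALSE} for model systems.
#' @param zero_tol modes with |omega| below this (cm^-1) are flagged as
#'   near-zero; more than the expected count triggers a warning.
#' @param imag_tol imaginary-mode detection threshold (cm^-1): eigenvalues
#'   below \code{-(imag_tol/hartree_to_cm1)^2} count as imaginary.
#' @return an object of class \code{mode_set}: \code{freq_cm1} (signed, sorted
#'   ascending by eigenvalue so any imaginary mode comes first),
#'   \code{vectors} (columns, orthonormal mass-weighted displacements),
#'   \code{n_zero} (number of projected-out modes), \code{n_imag},
#'   \code{system}, \code{x_ref}.
#' @export
normal_mode_analysis <- function(system, hessian,
                                 project_tr = inherits(system, "geometry"),
                                 zero_tol = 10, imag_tol = 10) {
  s <- as_coords(system)
  d <- length(s$x)
  hessian <- as.matrix(hessian)
  if (!all(dim(hessian) == d)) {
    stop("Hessian dimension does not match the coordinate count ", d)
  }
  asym <- max(abs(hessian - t(hessian)))
  scale <- max(abs(hessian), 1e-300)
  if (asym > 1e-8 * scale) {
    stop("Hessian is not symmetric (max asymmetry ", format(asym), ")")
  }
  hessian <- (hessian + t(hessian)) / 2
  sm <- sqrt(s$m)
  hmw <- hessian / outer(sm, sm)

  if (project_tr) {
    tr <- tr_basis(s$x, s$m)
    n_zero <- ncol(tr)
    # orthonormal basis of the complement
    q <- qr(cbind(tr, diag(d)))
    basis <- qr.Q(q)[, (n_zero + 1):d, drop = FALSE]
  } else {
    n_zero <- 0L
    basis <- diag(d)
  }

  hred <- crossprod(basis, hmw %*% basis)
  hred <- (hred + t(hred)) / 2
  e <- eigen(hred, symmetric = TRUE)
  ord <- order(e$values)
  lam <- e$values[ord]
  vec <- basis %*% e$vectors[, ord, drop = FALSE]
  # sign convention: largest-magnitude component positive
  for (k in seq_len(ncol(vec))) {
    if (vec[which.max(abs(vec[, k])), k] < 0) vec[, k] <- -vec[, k]
  }
  freq <- sign(lam) * sqrt(abs(lam)) * hartree_to_cm1
  lam_imag <- -(imag_tol / hartree_to_cm1)^2
  n_imag <- sum(lam < lam_imag)
  n_near_zero <- sum(abs(freq) < zero_tol)
  if (n_near_zero > 0L) {
    warning(n_near_zero, " retained mode(s) below ", zero_tol,
            " cm^-1 after projection; the Hessian or geometry may be inexact")
  }
  structure(list(freq_cm1 = freq, vectors = vec, n_zero = n_zero,
                 n_imag = n_imag, masses = s$m, x_ref = s$x,
                 molecular = s$molecular),
            class = "mode_set")
}

# orthonormal mass-weighted translation+rotation basis at configuration x
tr_basis <- function(x, m) {
  n <- length(x) / 3L
  xm <- matrix(x, ncol = 3L, byrow = TRUE)
  mass_atom <- m[seq(1L, length(m), by = 3L)]
  com <- colSums(xm * mass_atom) / sum(mass_atom)
  r <- sweep(xm, 2L, com)
  sm <- sqrt(mass_atom)
  vecs <- matrix(0, 3L * n, 6L)
  for (a in 1:3) vecs[seq(a, 3L * n, by = 3L), a] <- sm  # translations
  # rotations: sqrt(m) (e_a x r)
  for (a in 1:3) {
    e <- numeric(3); e[a] <- 1
    cr <- t(apply(r, 1L, function(ri) c(e[2] * ri[3] - e[3] * ri[2],
                                        e[3] * ri[1] - e[1] * ri[3],
                                        e[1] * ri[2] - e[2] * ri[1])))
    vecs[, 3L + a] <- as.numeric(t(cr * sm))
  }
  # orthonormalise, dropping null rotations (linear molecules)
  q <- qr(vecs)
  keep <- abs(diag(qr.R(q)))[seq_len(min(6L, ncol(vecs)))] > 1e-8 * max(sqrt(sum(m)))
  qr.Q(q)[, which(keep), drop = FALSE]
}

#' Construct a mode set from explicit vectors
#'
#' Advanced interface: builds a \code{mode_set} from caller-supplied
#' orthonormal mass-weighted displacement vectors, e.g. to relax along an
#' explicit coordinate axis instead of the eigenvector the Hessian gives.
#' Exactly one frequency must be negative (the mode treated as the path
#' direction).
#'
#' @param vectors matrix of orthonormal columns (mass-weighted).
#' @param freq_cm1 signed frequencies, one per column (negative = the path
#'   mode).
#' @param system the reference \code{geometry} or \code{model_system}.
#' @return a \code{mode_set}.
#' @export
make_mode_set <- function(vectors, freq_cm1, system) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != length(freq_cm1)) {
    stop("one frequency per column is required")
  }
  g <- crossprod(vectors)
  if (max(abs(g - diag(ncol(vectors)))) > 1e-10) {
    stop("vectors are not orthonormal")
  }
  s <- as_coords(system)
  if (nrow(vectors) != length(s$x)) {
    stop("vector length does not match the coordinate count")
  }
  structure(list(freq_cm1 = freq_cm1, vectors = vectors, n_zero = 0L,
                 n_imag = sum(freq_cm1 < 0), masses = s$m, x_ref = s$x,
                 molecular = s$molecular),
            class = "mode_set")
}

#' Extract the imaginary-frequency mode
#'
#' Returns the unit vector (mass-weighted) of the transition state's single
#' imaginary-frequency normal mode and the magnitude of its frequency. It is a
#' hard error if the mode set does not contain exactly one imaginary mode.
#'
#' @param modes a \code{mode_set} from \code{\link{normal_mode_analysis}}.
#' @return list with \code{q_im} (unit vector), \code{omega_cm1}
#'   (|frequency| in cm^-1), \code{index}.
#' @export
imaginary_mode <- function(modes) {
  stopifnot(inherits(modes, "mode_set"))
  if (modes$n_imag != 1L) {
    stop("expected exactly 1 imaginary mode, found ", modes$n_imag,
         "; not a first-order saddle point")
  }
  k <- which.min(modes$freq_cm1)
  list(q_im = modes$vectors[, k], omega_cm1 = abs(modes$freq_cm1[k]),
       index = k)
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("mode_set: %d modes (%d imaginary, %d projected out)\n",
              length(x$freq_cm1), x$n_imag, x$n_zero))
  cat("frequencies (cm^-1, negative = imaginary):\n")
  print(round(x$freq_cm1, 1))
  invisible(x)
}
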