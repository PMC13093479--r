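# Independent oracles and fixture builders shared across the test files.

# Lowest k eigenvalues of the 2nd-order finite-difference Hamiltonian
# -1/(2m) d2/dx2 + V on a uniform grid, by Sturm-sequence bisection on the
# tridiagonal matrix. Deliberately independent of the sinc-DVR code path.
fd_lowest <- function(vfun, dom, n, k = 2, mass = 1) {
  x <- seq(dom[1], dom[2], length.out = n)
  dx <- x[2] - x[1]
  diag_v <- vfun(x) + 1 / (mass * dx^2)
  off <- -0.5 / (mass * dx^2)
  count_below <- function(lam) {
    d <- diag_v[1] - lam
    cnt <- as.integer(d < 0)
    for (i in 2:n) {
      d <- diag_v[i] - lam - off^2 / d
      cnt <- cnt + (d < 0)
    }
    cnt
  }
  lo <- min(diag_v) - 2 * abs(off) - 1
  hi <- max(diag_v) + 2 * abs(off) + 1
  vapply(seq_len(k), function(j) {
    a <- lo; b <- hi
    for (it in 1:200) {
      m <- (a + b) / 2
      if (count_below(m) >= j) b <- m else a <- m
    }
    (a + b) / 2
  }, numeric(1))
}

# Toy bent triatomic held together by pairwise springs between all atom
# pairs; translation- and rotation-invariant by construction, equilibrium at
# the reference placement. Returns the geometry and the potential.
toy_triatomic <- function() {
  coords <- rbind(c(0, 0, 0),
                  c(1.8, 0, 0),
                  c(0.5, 1.6, 0))
  ks <- c(0.6, 0.45, 0.25)
  pairs <- rbind(c(1, 2), c(2, 3), c(1, 3))
  d0 <- apply(pairs, 1L, function(p) {
    sqrt(sum((coords[p[1], ] - coords[p[2], ])^2))
  })
  v <- function(x) {
    xm <- matrix(x, ncol = 3L, byrow = TRUE)
    sum(vapply(seq_len(3L), function(i) {
      p <- pairs[i, ]
      r <- sqrt(sum((xm[p[1], ] - xm[p[2], ])^2))
      0.5 * ks[i] * (r - d0[i])^2
    }, numeric(1)))
  }
  list(geom = geometry(c("O", "H", "H"), coords), v = v)
}

# 3x3 rotation matrix from Euler-style angles
rot3 <- function(a, b) {
  rz <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  rx <- rbind(c(1, 0, 0), c(0, cos(b), -sin(b)), c(0, sin(b), cos(b)))
  rz %*% rx
}

# coupled-model fixture with symmetric couplings on every bath mode: the TS
# Hessian is diagonal, q_im is exactly the Q0 axis, and the closed-form
# relaxed profile equals the pipeline's V(Q_im)
c_only_spec <- function() {
  coupled_model_spec(1400, 36, c(420, 640, 910, 1180, 1460, 1780),
                     c_coup = c(3.0e-8, 2.2e-8, 1.6e-8, 1.2e-8,
                                0.9e-8, 0.7e-8))
}

run_preset_splitting <- function(spec, effective_mass = 1, n_points = 801) {
  pes <- coupled_model_pes(spec)
  modes <- normal_mode_analysis(pes$system, pes$hessian(pes$system$x))
  prof <- build_path(pes, pes$system, modes, symmetric = TRUE,
                     energy_cap_cm1 = 9000)
  lt <- sinc_dvr_1d(prof, n_points = n_points,
                    effective_mass = effective_mass,
                    check_convergence = FALSE, n_states = 4)
  list(profile = prof, levels = lt,
       delta_cm1 = lt$energies_cm1[2] - lt$energies_cm1[1])
}
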