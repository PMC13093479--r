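#' Quartic symmetric double well
#'
#' V(Q) = V_b [ (Q/a)^2 - 1 ]^2: minima at Q = +/- a with V = 0, barrier V_b
#' at Q = 0, curvature 8 V_b / a^2 at the minima. The workhorse 1d fixture.
#'
#' @param v_b_cm1 barrier height in cm^-1.
#' @param a well position in mass-weighted a.u.
#' @return a function of Q returning hartree, with attributes
#'   \code{v_b_hartree} and \code{a}.
#' @export
quartic_double_well <- function(v_b_cm1, a) {
  if (v_b_cm1 <= 0 || a <= 0) stop("v_b_cm1 and a must be positive")
  vb <- cm2hartree(v_b_cm1)
  f <- function(q) vb * ((q / a)^2 - 1)^2
  attr(f, "v_b_hartree") <- vb
  attr(f, "a") <- a
  f
}

#' Gaussian-barrier double well
#'
#' V(Q) = 1/2 w0^2 Q^2 + A exp(-Q^2 / (2 s^2)): a harmonic base with a
#' Gaussian barrier at the origin, the classic functional form for
#' hydrogen-bond transfer profiles. Given the barrier height (above the
#' minima), the well position and the frequency of the outer harmonic
#' asymptote, A and s are solved for; the outer wall approaches the harmonic
#' base, so this well is far less anharmonic beyond the minima than the
#' quartic form -- the regime where a harmonic wall extension is a good
#' approximation.
#'
#' @param v_b_cm1 barrier height above the minima (cm^-1).
#' @param a well position (mass-weighted a.u.).
#' @param omega0_cm1 frequency of the underlying harmonic base (cm^-1).
#' @return a function of Q (hartree, zero at the minima), with attributes
#'   \code{v_b_hartree}, \code{a}, \code{A}, \code{sigma2},
#'   \code{omega_well_cm1} (curvature frequency at the minima).
#' @export
gaussian_double_well <- function(v_b_cm1, a, omega0_cm1) {
  if (v_b_cm1 <= 0 || a <= 0 || omega0_cm1 <= 0) {
    stop("v_b_cm1, a and omega0_cm1 must be positive")
  }
  vb <- cm2hartree(v_b_cm1)
  w0 <- cm2hartree(omega0_cm1)
  # stationarity at a and barrier height fix A and sigma^2:
  #   w0^2 t (exp(a^2 / 2t) - 1) = vb + w0^2 a^2 / 2,  t = sigma^2
  g <- function(t) w0^2 * t * expm1(a^2 / (2 * t)) - vb - w0^2 * a^2 / 2
  t_up <- a^2
  while (g(t_up) > 0) t_up <- t_up * 2
  t_lo <- a^2 / 2
  while (g(t_lo) < 0) t_lo <- t_lo / 2
  t <- stats::uniroot(g, c(t_lo, t_up), tol = 1e-15 * a^2)$root
  A <- vb + w0^2 * a^2 / 2 + w0^2 * t
  v_min <- w0^2 * a^2 / 2 + w0^2 * t  # value at the minima
  f <- function(q) 0.5 * w0^2 * q^2 + A * exp(-q^2 / (2 * t)) - v_min
  attr(f, "v_b_hartree") <- vb
  attr(f, "a") <- a
  attr(f, "A") <- A
  attr(f, "sigma2") <- t
  attr(f, "omega_well_cm1") <- hartree2cm(w0 * a / sqrt(t))
  f
}

#' Tabulate an analytic potential as a profile
#'
#' Convenience for feeding closed-form 1d potentials to the solver layer.
#'
#' @param f function of Q (hartree).
#' @param from,to,by grid specification (mass-weighted a.u.).
#' @param symmetric mark the profile symmetric.
#' @return a \code{\link{qim_profile}} with zero at the TS convention of
#'   \code{f} (whatever \code{f(0)} is, values are stored as given).
#' @export
profile_from_function <- function(f, from, to, by = 0.05,
                                  symmetric = FALSE) {
  q <- seq(from, to, by = by)
  qim_profile(q, f(q), provenance = "relaxed", zero = "ts",
              symmetric = symmetric)
}

#' Coupled double-well model specification
#'
#' A full-dimensional analytic stand-in for a molecular potential surface: a
#' quartic double well along Q_0 coupled to harmonic bath modes Q_i,
#'   V = V_dw(Q_0) + sum_i 1/2 w_i^2 Q_i^2 + sum_i c_i Q_0^2 Q_i
#'     + sum_i b_i Q_0 Q_i,
#' in mass-weighted coordinates (masses 1 unless overridden). Symmetric
#' couplings c_i preserve the double-well parity; bilinear couplings b_i make
#' the relaxed path genuinely curved in the full space. The relaxed profile
#' has the closed form
#'   V_rel(Q_0) = V_dw(Q_0) - sum_i (c_i Q_0^2 + b_i Q_0)^2 / (2 w_i^2),
#' exposed for oracle use. Note the closed form relaxes at \emph{frozen Q_0};
#' it coincides with the pipeline's V(Q_im) exactly when all bilinear
#' couplings vanish (then the transition-state Hessian is diagonal and q_im
#' is the Q_0 axis). With b_i != 0 the imaginary mode mixes into the bath and
#' the two parametrisations of the relaxed valley differ; use
#' \code{\link{make_mode_set}} to relax along the Q_0 axis explicitly if the
#' closed form is the quantity wanted.
#'
#' @param v_b_cm1 barrier height (cm^-1).
#' @param a well position (mass-weighted a.u.).
#' @param omega_cm1 bath frequencies (cm^-1), one per bath mode.
#' @param c_coup symmetric (Q_0^2 Q_i) coupling strengths, recycled.
#' @param b_coup bilinear (Q_0 Q_i) coupling strengths, recycled.
#' @param masses per-coordinate masses (length n_modes + 1), default 1.
#' @param well double-well form along Q_0: \code{"quartic"}
#'   (\code{\link{quartic_double_well}}) or \code{"gaussian"}
#'   (\code{\link{gaussian_double_well}}, harmonic base plus Gaussian
#'   barrier -- the more molecule-like outer wall).
#' @param omega0_cm1 harmonic-base frequency for the Gaussian well form.
#' @return object of class \code{coupled_model_spec}.
#' @export
coupled_model_spec <- function(v_b_cm1, a, omega_cm1, c_coup = 0,
                               b_coup = 0, masses = 1,
                               well = c("quartic", "gaussian"),
                               omega0_cm1 = NULL) {
  well <- match.arg(well)
  n <- length(omega_cm1)
  if (any(omega_cm1 <= 0)) stop("bath frequencies must be positive")
  if (well == "gaussian" && is.null(omega0_cm1)) {
    stop("the gaussian well form requires omega0_cm1")
  }
  spec <- list(v_b_cm1 = v_b_cm1, a = a,
               vb = cm2hartree(v_b_cm1),
               omega = cm2hartree(omega_cm1),
               c_coup = rep_len(c_coup, n),
               b_coup = rep_len(b_coup, n),
               n_modes = n,
               masses = rep_len(masses, n + 1L),
               well = well, omega0_cm1 = omega0_cm1)
  structure(spec, class = "coupled_model_spec")
}

#' Build the PES for a coupled double-well model
#'
#' Returns a \code{\link{pes_contract}} with analytic gradient and Hessian,
#' together with the model's transition-state \code{\link{model_system}}
#' (\code{$system}) and the closed-form relaxed profile
#' (\code{$relaxed}, a function of Q_0).
#'
#' @param spec a \code{\link{coupled_model_spec}}.
#' @return a \code{pes} object.
#' @export
coupled_model_pes <- function(spec) {
  stopifnot(inherits(spec, "coupled_model_spec"))
  vb <- spec$vb; a <- spec$a
  w2 <- spec$omega^2; cc <- spec$c_coup; bb <- spec$b_coup
  n <- spec$n_modes
  if (spec$well == "quartic") {
    vdw <- function(q) vb * ((q / a)^2 - 1)^2
    vdw1 <- function(q) 4 * vb * q * ((q / a)^2 - 1) / a^2
    vdw2 <- function(q) 4 * vb * (3 * q^2 / a^2 - 1) / a^2
  } else {
    gw <- gaussian_double_well(spec$v_b_cm1, a, spec$omega0_cm1)
    A <- attr(gw, "A"); s2 <- attr(gw, "sigma2")
    w02 <- cm2hartree(spec$omega0_cm1)^2
    vdw <- gw
    vdw1 <- function(q) w02 * q - (A / s2) * q * exp(-q^2 / (2 * s2))
    vdw2 <- function(q) {
      w02 - (A / s2) * (1 - q^2 / s2) * exp(-q^2 / (2 * s2))
    }
  }
  energy <- function(x) {
    q0 <- x[1]; qi <- x[-1]
    vdw(q0) + sum(w2 * qi^2) / 2 +
      sum(cc * q0^2 * qi) + sum(bb * q0 * qi)
  }
  gradient <- function(x) {
    q0 <- x[1]; qi <- x[-1]
    g0 <- vdw1(q0) + 2 * q0 * sum(cc * qi) + sum(bb * qi)
    c(g0, w2 * qi + cc * q0^2 + bb * q0)
  }
  hessian <- function(x) {
    q0 <- x[1]; qi <- x[-1]
    h <- diag(c(0, w2))
    h[1, 1] <- vdw2(q0) + 2 * sum(cc * qi)
    h[1, -1] <- h[-1, 1] <- 2 * cc * q0 + bb
    h
  }
  relaxed <- function(q0) {
    vdw(q0) - sapply(q0, function(q) sum((cc * q^2 + bb * q)^2 / (2 * w2)))
  }
  pes_contract(energy, gradient, hessian,
               system = model_system(numeric(n + 1L), masses = spec$masses),
               relaxed = relaxed, spec = spec)
}

#' Synthetic coupled-model presets
#'
#' Fixed-parameter coupled double-well models whose barrier heights and
#' splittings sit in the regime typical of intramolecular H-transfer
#' (barriers of order 1000-2500 cm^-1, ground splittings of order 1-100
#' cm^-1). They are synthetic fixtures -- not fits to any molecular
#' surface. Both use the Gaussian-barrier well form (whose outer wall tends
#' to the harmonic base, as molecular H-transfer wells are close to harmonic
#' over the zero-point amplitude) and six bath modes spanning 400-1800
#' cm^-1, three of them bilinearly coupled so the relaxed path is genuinely
#' curved in the full space.
#'
#' \code{malonaldehyde_like_preset}: barrier 1400 cm^-1, wells at
#' Q_im = +/- 36 a.u. \code{oxalate_like_preset}: barrier 1172 cm^-1, wells
#' at +/- 40 a.u.
#'
#' @return a \code{\link{coupled_model_spec}}.
#' @export
malonaldehyde_like_preset <- function() {
  coupled_model_spec(
    v_b_cm1 = 1400, a = 36,
    omega_cm1 = c(420, 640, 910, 1180, 1460, 1780),
    b_coup = c(0, 0, 0, 2.0e-6, 1.5e-6, 1.1e-6),
    well = "gaussian", omega0_cm1 = 400)
}

#' @rdname malonaldehyde_like_preset
#' @export
oxalate_like_preset <- function() {
  coupled_model_spec(
    v_b_cm1 = 1172, a = 40,
    omega_cm1 = c(450, 680, 930, 1210, 1490, 1820),
    b_coup = c(0, 0, 0, 1.8e-6, 1.4e-6, 1.0e-6),
    well = "gaussian", omega0_cm1 = 650)
}

#' Hydrogen-bonded chain model (donor-H-acceptor)
#'
#' A three-particle collinear model of heavy-atom-mediated H transfer: the
#' light particle x2 moves in a quartic double well along the proton-transfer
#' coordinate u = x2 - (x1 + x3)/2, the heavy end particles are harmonically
#' bound at -L and +L, and a cubic symmetric coupling g u^2 (y1 - y3)
#' (y1 = x1 + L, y3 = x3 - L) ties the well shape to the heavy-atom frame.
#' The potential is symmetric under the end-swap reflection
#' (x1, x2, x3) -> (-x3, -x2, -x1), so the two wells have equal depth; with
#' unequal end masses that reflection is no longer orthogonal in
#' mass-weighted coordinates and the relaxed V(Q_im) becomes asymmetric in
#' shape -- the isotope-induced zero-point asymmetry scenario.
#'
#' Coordinates are in bohr, masses in electron masses (defaults: O, H, O).
#'
#' @param masses_amu three masses in amu; default \code{c(15.9949, 1.00783,
#'   15.9949)} (16O, H, 16O).
#' @param v_b_cm1 double-well barrier (cm^-1).
#' @param a_u half-separation of the proton wells in u (bohr).
#' @param L heavy-atom rest position (bohr).
#' @param k_heavy heavy-atom force constant (hartree/bohr^2).
#' @param g cubic coupling (hartree/bohr^3).
#' @return a \code{pes} with \code{$system} at the transition state.
#' @export
oho_chain_pes <- function(masses_amu = c(15.9949, 1.00783, 15.9949),
                          v_b_cm1 = 2300, a_u = 0.85, L = 2.5,
                          k_heavy = 0.35, g = 0.04) {
  vb <- cm2hartree(v_b_cm1)
  ju <- c(-0.5, 1, -0.5)  # du/dx
  energy <- function(x) {
    u <- x[2] - (x[1] + x[3]) / 2
    y1 <- x[1] + L; y3 <- x[3] - L
    vb * ((u / a_u)^2 - 1)^2 + k_heavy * (y1^2 + y3^2) / 2 +
      g * u^2 * (y1 - y3)
  }
  gradient <- function(x) {
    u <- x[2] - (x[1] + x[3]) / 2
    y1 <- x[1] + L; y3 <- x[3] - L
    vp <- 4 * vb * u * ((u / a_u)^2 - 1) / a_u^2
    vp * ju + c(k_heavy * y1, 0, k_heavy * y3) +
      g * (2 * u * (y1 - y3) * ju + u^2 * c(1, 0, -1))
  }
  hessian <- function(x) {
    u <- x[2] - (x[1] + x[3]) / 2
    y1 <- x[1] + L; y3 <- x[3] - L
    vpp <- 4 * vb * (3 * u^2 / a_u^2 - 1) / a_u^2
    e13 <- c(1, 0, -1)
    vpp * outer(ju, ju) + diag(c(k_heavy, 0, k_heavy)) +
      g * (2 * (y1 - y3) * outer(ju, ju) +
           2 * u * (outer(ju, e13) + outer(e13, ju)))
  }
  pes_contract(energy, gradient, hessian,
               system = model_system(c(-L, 0, L),
                                     masses = masses_amu * amu_to_me))
}
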