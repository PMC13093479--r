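#' Tilt a symmetric double-well profile
#'
#' Adds a linear term alpha * Q_im to the relaxed potential, lowering one well
#' and raising the other; the barrier measured from the average of the two
#' minima is unchanged by a pure linear tilt. The resulting half energy
#' difference between the minima is recorded.
#'
#' @param profile a symmetric \code{\link{qim_profile}}.
#' @param alpha_cm1 tilt coefficient in cm^-1 per mass-weighted a.u.
#'   (positive alpha lowers the left well, raises the right).
#' @return a \code{qim_profile}; attribute \code{delta_e0_half_cm1} holds
#'   half the minima energy difference, attribute \code{alpha_cm1} the tilt.
#'   An error is raised if the tilt removes one of the wells.
#' @export
tilt_potential <- function(profile, alpha_cm1) {
  stopifnot(inherits(profile, "qim_profile"))
  alpha <- cm2hartree(alpha_cm1)
  out <- qim_profile(profile$q, profile$v + alpha * profile$q,
                     provenance = profile$provenance, zero = profile$zero,
                     e_zero = profile$e_zero,
                     symmetric = alpha_cm1 == 0 && profile$symmetric)
  st <- profile_structure(out)
  if (is.null(st)) {
    stop("tilt alpha = ", alpha_cm1,
         " cm^-1 removes one of the wells (no interior double-well left)")
  }
  attr(out, "alpha_cm1") <- alpha_cm1
  attr(out, "delta_e0_half_cm1") <- hartree2cm(abs(st$v_right - st$v_left)) / 2
  out
}

#' Zero-order (single-well) levels
#'
#' Levels of one well with tunneling suppressed, for the two-level analysis of
#' asymmetric double wells. The wells are divided at the barrier-top abscissa.
#' Two divider treatments are available: \code{"plateau"} (default) continues
#' the potential beyond the divider at the barrier-top value, so the
#' zero-order state decays under a flat barrier; \code{"hard"} places an
#' infinite wall at the divider by truncating the DVR domain there. The
#' plateau form tracks the two-level decomposition of the full problem much
#' more closely; the hard wall compresses the well and biases the level up by
#' a few percent of the well spacing.
#'
#' @param profile a double-well \code{qim_profile}.
#' @param side \code{"left"} or \code{"right"}.
#' @param wall divider treatment, see above.
#' @param n_points,effective_mass,n_states passed to
#'   \code{\link{sinc_dvr_1d}}.
#' @return a \code{level_table} for that well; attribute \code{q_top} records
#'   the divider abscissa.
#' @export
zero_order_levels <- function(profile, side = c("left", "right"),
                              wall = c("plateau", "hard"), n_points = 501,
                              effective_mass = 1, n_states = 10) {
  side <- match.arg(side)
  wall <- match.arg(wall)
  st <- profile_structure(profile)
  if (is.null(st)) stop("profile has no double-well structure")
  f <- spline_profile(profile)
  qb <- st$q_top
  rng <- range(profile$q)
  if (wall == "hard") {
    dom <- if (side == "left") c(rng[1], qb) else c(qb, rng[2])
    lt <- sinc_dvr_1d(f, domain = dom, n_points = n_points,
                      effective_mass = effective_mass, n_states = n_states,
                      check_convergence = FALSE)
  } else {
    vb <- st$v_top
    fw <- function(x) {
      inside <- if (side == "left") x <= qb else x >= qb
      y <- rep(vb, length(x))
      y[inside] <- f(x[inside])
      y
    }
    lt <- sinc_dvr_1d(fw, domain = rng, n_points = n_points,
                      effective_mass = effective_mass, n_states = n_states,
                      check_convergence = FALSE)
  }
  attr(lt, "q_top") <- qb
  attr(lt, "side") <- side
  lt
}

#' Two-level resonance model
#'
#' The lowest pair of an asymmetric double well is modelled by the 2x2
#' Hamiltonian with diagonal elements +d and -d (half the zero-order
#' detuning) and off-diagonal coupling hbar*Omega (the tunneling matrix
#' element). Its eigenvalue gap is Delta = 2 sqrt(d^2 + (hbar Omega)^2).
#' \code{two_level_splitting} evaluates the forward form;
#' \code{two_level_coupling} inverts it for the coupling, which requires
#' Delta >= 2|d|.
#'
#' @param d half the zero-order detuning (cm^-1).
#' @param hbar_omega tunneling coupling (cm^-1).
#' @param delta observed level separation (cm^-1).
#' @return splitting Delta, or coupling hbar*Omega, in cm^-1.
#' @export
two_level_splitting <- function(d, hbar_omega) {
  2 * sqrt(d^2 + hbar_omega^2)
}

#' @rdname two_level_splitting
#' @export
two_level_coupling <- function(delta, d) {
  if (any(delta < 2 * abs(d))) {
    stop("delta < 2|d|: no real tunneling coupling reproduces this gap")
  }
  sqrt((delta / 2)^2 - d^2)
}

#' Resonance scan over the well asymmetry
#'
#' Tilts a symmetric profile over a grid of alpha values and, at each point,
#' records the full-DVR splitting of the tracked pair, the zero-order
#' detuning from per-well DVR, the no-tunneling gap 2|d|, and the probability
#' of the tracked state in the original well. The tracked state starts as the
#' ground state at the first alpha and is followed across the scan by
#' wavefunction-overlap continuity, so it passes diabatically through the
#' avoided crossing; the original well is the side where that state sits at
#' the scan start (the left well when the scan starts at alpha = 0).
#'
#' @param profile symmetric \code{qim_profile}.
#' @param alpha_grid tilt values (cm^-1 per mass-weighted a.u.).
#' @param n_points DVR grid size.
#' @param effective_mass kinetic mass.
#' @param wall zero-order divider treatment (see
#'   \code{\link{zero_order_levels}}).
#' @return data.frame with columns \code{alpha}, \code{delta_e0_half},
#'   \code{d}, \code{delta_dvr}, \code{delta_no_tunneling},
#'   \code{p_original}, \code{p_other} (energies in cm^-1); attribute
#'   \code{hbar_omega0_cm1} holds the symmetric-case coupling (half the
#'   alpha = 0 splitting).
#' @export
resonance_scan <- function(profile, alpha_grid, n_points = 501,
                           effective_mass = 1,
                           wall = c("plateau", "hard")) {
  wall <- match.arg(wall)
  stopifnot(inherits(profile, "qim_profile"))
  lt0 <- sinc_dvr_1d(profile, n_points = n_points,
                     effective_mass = effective_mass, n_states = 4,
                     check_convergence = FALSE)
  hbar_omega0 <- (lt0$energies_cm1[2] - lt0$energies_cm1[1]) / 2

  prev_psi <- NULL
  original_side <- NULL
  rows <- vector("list", length(alpha_grid))
  for (k in seq_along(alpha_grid)) {
    tp <- tilt_potential(profile, alpha_grid[k])
    lt <- sinc_dvr_1d(tp, n_points = n_points,
                      effective_mass = effective_mass, n_states = 4,
                      check_convergence = FALSE)
    st <- profile_structure(tp)
    zl <- zero_order_levels(tp, "left", wall = wall, n_points = n_points,
                            effective_mass = effective_mass, n_states = 2)
    zr <- zero_order_levels(tp, "right", wall = wall, n_points = n_points,
                            effective_mass = effective_mass, n_states = 2)
    d <- (zr$energies_cm1[1] + hartree2cm(zr$e_ref) -
          zl$energies_cm1[1] - hartree2cm(zl$e_ref)) / 2
    delta_dvr <- lt$energies_cm1[2] - lt$energies_cm1[1]
    # track the state by overlap continuity
    if (is.null(prev_psi)) {
      tracked <- 1L
    } else {
      ov <- abs(crossprod(lt$wavefunctions[, 1:2], prev_psi))
      tracked <- which.max(ov)
      if (max(ov) < 0.5) {
        warning("level tracking weak at alpha = ", alpha_grid[k],
                " (max overlap ", round(max(ov), 3), ")")
      }
    }
    prev_psi <- lt$wavefunctions[, tracked]
    pr <- well_probabilities(lt, tracked, divider = st$q_top)
    if (is.null(original_side)) {
      original_side <- if (pr["p_right"] > pr["p_left"]) "right" else "left"
    }
    p_orig <- unname(if (original_side == "left") pr["p_left"]
                     else pr["p_right"])
    rows[[k]] <- data.frame(
      alpha = alpha_grid[k],
      delta_e0_half = attr(tp, "delta_e0_half_cm1"),
      d = d, delta_dvr = delta_dvr,
      delta_no_tunneling = 2 * abs(d),
      p_original = p_orig, p_other = 1 - p_orig)
  }
  out <- do.call(rbind, rows)
  attr(out, "hbar_omega0_cm1") <- hbar_omega0
  attr(out, "original_side") <- original_side
  out
}

#' Isotope-induced asymmetry analysis
#'
#' Re-runs the whole pipeline -- normal-mode analysis at the transition
#' state, relaxed-path construction, DVR -- with an isotopic mass variant.
#' The electronic potential is unchanged and the well depths remain equal,
#' but unequal masses make the mass-weighted reflection inexact, so the two
#' wells of V(Q_im) acquire different shapes and hence different zero-point
#' levels. The observed splitting is decomposed with the two-level model:
#' d from per-well zero-order levels and hbar*Omega =
#' sqrt((Delta/2)^2 - d^2).
#'
#' @param pes a \code{\link{pes_contract}}.
#' @param system the transition-state system with the \emph{reference}
#'   (symmetric) masses.
#' @param variant_masses masses for the isotopologue (same length/convention
#'   as the system's masses: per atom for geometries, per coordinate for
#'   model systems).
#' @param step,energy_cap_cm1 passed to \code{\link{build_path}}.
#' @param n_points DVR grid size.
#' @param wall zero-order divider treatment.
#' @return list with elements \code{symmetric} and \code{variant} (each:
#'   \code{profile}, \code{levels}, \code{delta_cm1}) and
#'   \code{decomposition} (data.frame: delta, d, hbar_omega, all cm^-1,
#'   for the variant).
#' @export
isotope_asymmetry <- function(pes, system, variant_masses, step = 0.05,
                              energy_cap_cm1 = NULL, n_points = 601,
                              wall = c("plateau", "hard")) {
  wall <- match.arg(wall)
  run_one <- function(sys, symmetric) {
    s <- as_coords(sys)
    h <- pes$hessian(s$x)
    modes <- normal_mode_analysis(sys, h)
    prof <- build_path(pes, sys, modes, step = step,
                       energy_cap_cm1 = energy_cap_cm1,
                       symmetric = symmetric)
    lt <- sinc_dvr_1d(prof, n_points = n_points, n_states = 6,
                      check_convergence = FALSE)
    list(profile = prof, levels = lt,
         delta_cm1 = lt$energies_cm1[2] - lt$energies_cm1[1])
  }
  variant_system <- if (inherits(system, "geometry")) {
    geometry(system$labels, system$coords, masses = variant_masses)
  } else {
    model_system(system$x, masses = variant_masses)
  }
  s <- as_coords(system); sv <- as_coords(variant_system)
  same <- isTRUE(all.equal(s$m, sv$m))
  sym <- run_one(system, symmetric = TRUE)
  var <- if (same) sym else run_one(variant_system, symmetric = FALSE)

  zl <- zero_order_levels(var$profile, "left", wall = wall,
                          n_points = n_points)
  zr <- zero_order_levels(var$profile, "right", wall = wall,
                          n_points = n_points)
  d <- abs(zr$energies_cm1[1] + hartree2cm(zr$e_ref) -
           zl$energies_cm1[1] - hartree2cm(zl$e_ref)) / 2
  delta <- var$delta_cm1
  hbar_omega <- if (delta >= 2 * d) two_level_coupling(delta, d) else NA_real_
  list(symmetric = sym, variant = var,
       decomposition = data.frame(delta_cm1 = delta, d_cm1 = d,
                                  hbar_omega_cm1 = hbar_omega))
}
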