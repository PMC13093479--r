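#' Relaxed-path profile container
#'
#' Tabulated relaxed potential V(Q_im) on a signed, strictly ascending grid of
#' mass-weighted path coordinates. Energies are in hartree relative to the
#' recorded zero (the transition state by default); each point carries a
#' provenance tag (\code{relaxed}, \code{mirrored}, \code{harmonic_extension}
#' or \code{irc_projection}).
#'
#' @param q numeric, strictly ascending Q_im grid (mass-weighted a.u.).
#' @param v energies in hartree relative to \code{zero}.
#' @param provenance character vector (recycled).
#' @param zero \code{"ts"} or \code{"min"}: what v = 0 refers to.
#' @param e_zero absolute energy of the zero reference (hartree), if known.
#' @param symmetric logical flag: profile asserted symmetric about q = 0.
#' @param geoms optional matrix of relaxed coordinates, one row per point.
#' @return object of class \code{qim_profile}.
#' @export
qim_profile <- function(q, v, provenance = "relaxed",
                        zero = c("ts", "min"), e_zero = NA_real_,
                        symmetric = FALSE, geoms = NULL) {
  zero <- match.arg(zero)
  q <- as.numeric(q); v <- as.numeric(v)
  if (length(q) != length(v)) stop("q and v disagree in length")
  if (any(diff(q) <= 0)) stop("q grid must be strictly ascending")
  if (any(!is.finite(v))) stop("non-finite energies in profile")
  provenance <- rep_len(as.character(provenance), length(q))
  if (!is.null(geoms)) {
    geoms <- as.matrix(geoms)
    if (nrow(geoms) != length(q)) stop("geoms rows must match grid length")
  }
  structure(list(q = q, v = v, provenance = provenance, zero = zero,
                 e_zero = e_zero, symmetric = symmetric, geoms = geoms),
            class = "qim_profile")
}

#' @export
print.qim_profile <- function(x, ...) {
  b <- profile_barrier_cm1(x)
  cat(sprintf(
    "qim_profile: %d points, Q_im in [%.3f, %.3f], zero at %s%s\n",
    length(x$q), min(x$q), max(x$q), x$zero,
    if (x$symmetric) ", symmetric" else ""))
  if (is.finite(b)) cat(sprintf("barrier (above minima): %.1f cm^-1\n", b))
  invisible(x)
}

#' @export
as.data.frame.qim_profile <- function(x, ...) {
  data.frame(q = x$q, v = x$v, provenance = x$provenance)
}

#' Barrier height of a profile
#'
#' Interior spline maximum between the two outermost minima, measured above
#' the lower minimum (in cm^-1). Returns \code{NA} when the profile has no
#' interior barrier.
#'
#' @param profile a \code{qim_profile}.
#' @return barrier height in cm^-1, or NA.
#' @export
profile_barrier_cm1 <- function(profile) {
  st <- profile_structure(profile)
  if (is.null(st)) return(NA_real_)
  hartree2cm(st$v_top - min(st$v_left, st$v_right))
}

# locate well minima and the interior barrier top on the spline
# returns NULL when no double-well structure is present
profile_structure <- function(profile) {
  f <- spline_profile(profile)
  q <- profile$q; v <- profile$v
  n <- length(q)
  # discrete local minima (interior)
  locmin <- which(v[2:(n - 1L)] < v[1:(n - 2L)] &
                  v[2:(n - 1L)] <= v[3:n]) + 1L
  if (length(locmin) < 2L) return(NULL)
  # the two deepest local minima define the wells
  locmin <- locmin[order(v[locmin])][1:2]
  il <- min(locmin); ir <- max(locmin)
  if (il == ir) return(NULL)
  refine_min <- function(i) {
    stats::optimize(f, c(q[max(1L, i - 1L)], q[min(n, i + 1L)]))
  }
  oL <- refine_min(il); oR <- refine_min(ir)
  if (oL$minimum >= oR$minimum) return(NULL)
  ot <- stats::optimize(f, c(oL$minimum, oR$minimum), maximum = TRUE)
  if (ot$objective <= max(oL$objective, oR$objective)) return(NULL)
  list(q_left = oL$minimum, v_left = oL$objective,
       q_right = oR$minimum, v_right = oR$objective,
       q_top = ot$maximum, v_top = ot$objective)
}

#' Constrained relaxation at a fixed path coordinate
#'
#' Minimises the potential over the transition-state normal-mode coordinates
#' orthogonal to the imaginary mode, with the displacement along q_im frozen
#' at \code{q_value}. The minimiser is Newton's method in the reduced
#' subspace with a trust-region safeguard (eigenvalue shift of the reduced
#' Hessian plus step-norm cap) so that early, possibly non-convex steps
#' remain downhill.
#'
#' @param pes a \code{\link{pes_contract}} object.
#' @param system the transition-state \code{geometry} or \code{model_system}.
#' @param modes the transition-state \code{mode_set}.
#' @param q_value path coordinate (mass-weighted a.u.).
#' @param warm_start starting coefficients of the orthogonal modes (default
#'   zeros).
#' @param frozen_modes optional indices (into the real modes, i.e. columns of
#'   the orthogonal-mode basis) held frozen at zero displacement.
#' @param gtol convergence threshold on the reduced-gradient infinity norm
#'   (hartree per mass-weighted a.u.).
#' @param max_iter maximum Newton iterations.
#' @param max_step trust cap on the Newton step norm (mass-weighted a.u.).
#' @param energy_cap if the relaxed energy exceeds this (hartree, absolute) an
#'   error is thrown; signals leaving the physical region.
#' @return list with \code{energy} (hartree), \code{coeffs}, \code{x}
#'   (relaxed coordinates), \code{iterations}, \code{grad_norm}.
#' @export
relax_at_qim <- function(pes, system, modes, q_value, warm_start = NULL,
                         frozen_modes = NULL, gtol = 1e-8, max_iter = 200,
                         max_step = 2.0, energy_cap = Inf) {
  if (!is.finite(q_value)) stop("q_value must be finite")
  im <- imaginary_mode(modes)
  vo <- modes$vectors[, -im$index, drop = FALSE]
  if (!is.null(frozen_modes)) vo <- vo[, -frozen_modes, drop = FALSE]
  s <- as_coords(system)
  sm <- sqrt(s$m)
  k <- ncol(vo)
  cc <- if (is.null(warm_start)) numeric(k) else as.numeric(warm_start)
  if (length(cc) != k) stop("warm_start length does not match mode count")

  xat <- function(cc) s$x + (q_value * im$q_im + as.numeric(vo %*% cc)) / sm
  ecur <- pes$energy(xat(cc))
  gnorm <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    x <- xat(cc)
    g <- crossprod(vo, pes$gradient(x) / sm)
    gnorm <- max(abs(g))
    if (gnorm < gtol) break
    h <- crossprod(vo, (pes$hessian(x) / outer(sm, sm)) %*% vo)
    h <- (h + t(h)) / 2
    ev_min <- min(eigen(h, symmetric = TRUE, only.values = TRUE)$values)
    shift <- if (ev_min < 1e-8) 1e-8 - ev_min else 0
    ok <- FALSE
    for (tries in 1:30) {
      step <- -solve(h + diag(shift, k), g)
      nrm <- sqrt(sum(step^2))
      if (nrm > max_step) step <- step * (max_step / nrm)
      enew <- pes$energy(xat(cc + step))
      if (is.finite(enew) && enew <= ecur + 1e-14 * max(1, abs(ecur))) {
        cc <- cc + as.numeric(step)
        ecur <- enew
        ok <- TRUE
        break
      }
      shift <- max(shift * 4, 1e-6)  # shrink the step, stay downhill
    }
    if (!ok) break  # cannot improve; report with last gradient norm
  }
  if (gnorm >= gtol && it >= max_iter) {
    stop(sprintf(
      "relaxation at Q_im = %g did not converge in %d iterations (|g| = %g)",
      q_value, max_iter, gnorm))
  }
  if (gnorm >= gtol) {
    stop(sprintf(
      "relaxation at Q_im = %g stalled (|g| = %g > gtol)", q_value, gnorm))
  }
  if (ecur > energy_cap) {
    stop(sprintf("relaxed energy %g exceeds the energy cap at Q_im = %g",
                 ecur, q_value))
  }
  list(energy = ecur, coeffs = cc, x = xat(cc), iterations = it,
       grad_norm = gnorm)
}

#' Build the relaxed path potential V(Q_im)
#'
#' Marches outward from the transition state (Q_im = 0) in increments of
#' \code{step}, relaxing the orthogonal modes at each point with the previous
#' point's coefficients as warm start, and continues past each minimum into
#' the repulsive wall until the energy has risen \code{energy_cap_cm1} above
#' the minimum. With \code{symmetric = TRUE} only the positive half is
#' computed and mirrored (with spot checks that the potential really is
#' symmetric); this halves the number of relaxations.
#'
#' @inheritParams relax_at_qim
#' @param step grid increment in mass-weighted a.u.
#' @param energy_cap_cm1 stop rule: march until V >= V_min +
#'   \code{energy_cap_cm1}; default \code{max(4 * barrier, 5000)} where the
#'   barrier is V(0) - V_min, decided on the fly.
#' @param symmetric mirror the positive half instead of computing both.
#' @param sym_tol tolerance (hartree) for the symmetry spot check.
#' @param max_points cap on grid points per side.
#' @param keep_geoms retain relaxed coordinates per point.
#' @param verbose print one line per relaxation.
#' @return a \code{\link{qim_profile}} with zero at the TS, plus attribute
#'   \code{n_relaxations}.
#' @export
build_path <- function(pes, system, modes, step = 0.05,
                       energy_cap_cm1 = NULL, symmetric = FALSE,
                       sym_tol = 1e-8, max_points = 4000,
                       frozen_modes = NULL, keep_geoms = FALSE,
                       gtol = 1e-8, verbose = FALSE) {
  if (step <= 0) stop("step must be positive")
  n_relax <- 0L
  relax <- function(q, warm) {
    n_relax <<- n_relax + 1L
    r <- relax_at_qim(pes, system, modes, q, warm_start = warm,
                      frozen_modes = frozen_modes, gtol = gtol)
    if (verbose) {
      message(sprintf("Q_im = %9.4f  V = %+.10f  iter = %2d  |g| = %.2e",
                      q, r$energy, r$iterations, r$grad_norm))
    }
    r
  }
  r0 <- relax(0, NULL)
  e_ts <- r0$energy

  march <- function(direction) {
    qs <- numeric(0); vs <- numeric(0); geoms <- list()
    warm <- r0$coeffs
    v_min <- e_ts
    i <- 0L
    repeat {
      i <- i + 1L
      if (i > max_points) {
        warning("max_points reached before the stop rule; wall may be short")
        break
      }
      q <- direction * i * step
      r <- relax(q, warm)
      warm <- r$coeffs
      qs <- c(qs, q); vs <- c(vs, r$energy)
      if (keep_geoms) geoms[[i]] <- r$x
      v_min <- min(v_min, r$energy)
      barrier <- e_ts - v_min
      cap <- if (is.null(energy_cap_cm1)) {
        max(4 * hartree2cm(barrier), 5000)
      } else energy_cap_cm1
      past_min <- v_min < e_ts && r$energy > vs[max(1L, i - 1L)]
      if (past_min && hartree2cm(r$energy - v_min) >= cap) break
    }
    list(q = qs, v = vs, geoms = geoms)
  }

  pos <- march(+1)
  if (symmetric) {
    # spot-check the claimed symmetry at a few negative points
    i_min <- which.min(pos$v)
    for (i in unique(pmin(length(pos$q), c(i_min %/% 2L + 1L, i_min)))) {
      rneg <- relax(-pos$q[i], r0$coeffs)
      if (abs(rneg$energy - pos$v[i]) > sym_tol) {
        stop(sprintf(
          "potential is not symmetric: |V(-q) - V(q)| = %.3e at q = %g",
          abs(rneg$energy - pos$v[i]), pos$q[i]))
      }
    }
    q <- c(-rev(pos$q), 0, pos$q)
    v <- c(rev(pos$v), e_ts, pos$v) - e_ts
    prov <- c(rep("mirrored", length(pos$q)), "relaxed",
              rep("relaxed", length(pos$q)))
    geoms <- NULL
    if (keep_geoms) {
      gm <- do.call(rbind, pos$geoms)
      geoms <- rbind(gm[rev(seq_len(nrow(gm))), , drop = FALSE] * NA,
                     matrix(r0$x, 1), gm)
    }
  } else {
    neg <- march(-1)
    q <- c(rev(neg$q), 0, pos$q)
    v <- c(rev(neg$v), e_ts, pos$v) - e_ts
    prov <- rep("relaxed", length(q))
    geoms <- NULL
    if (keep_geoms) {
      gm_n <- do.call(rbind, neg$geoms)
      gm_p <- do.call(rbind, pos$geoms)
      geoms <- rbind(gm_n[rev(seq_len(nrow(gm_n))), , drop = FALSE],
                     matrix(r0$x, 1), gm_p)
    }
  }
  out <- qim_profile(q, v, provenance = prov, zero = "ts", e_zero = e_ts,
                     symmetric = symmetric, geoms = geoms)
  attr(out, "n_relaxations") <- n_relax
  out
}

#' Harmonic extension of the repulsive wall
#'
#' Approximates the relaxed potential beyond a minimum from that minimum's
#' (mass-weighted, translation/rotation-projected) Hessian alone: minimising
#' the harmonic energy 1/2 d^T H d subject to a fixed displacement delta along
#' q_im has the closed form E(delta) = delta^2 / (2 q_im^T H^-1 q_im),
#' evaluated in the positive-definite complement subspace. This needs only a
#' frequency calculation at the minimum, no potential-surface scan.
#'
#' @param system the minimum-energy \code{geometry} or \code{model_system}.
#' @param hessian Cartesian Hessian at that minimum.
#' @param q_im the transition state's imaginary-mode unit vector
#'   (mass-weighted).
#' @param q_min the path coordinate of the minimum in the profile being
#'   extended.
#' @param delta_max extend to |delta| = \code{delta_max} beyond the minimum.
#' @param step grid increment in mass-weighted a.u.
#' @param v_min profile energy at the minimum (added to the segment so it
#'   lines up with the profile it extends).
#' @param direction +1 to extend to larger q, -1 to smaller; default follows
#'   the sign of \code{q_min}.
#' @param project_tr as in \code{\link{normal_mode_analysis}}.
#' @return a \code{qim_profile} segment with provenance
#'   \code{harmonic_extension} (the point at \code{q_min} itself is not
#'   included).
#' @export
harmonic_wall_extension <- function(system, hessian, q_im, q_min,
                                    delta_max, step = 0.05, v_min = 0,
                                    direction = sign(q_min),
                                    project_tr = inherits(system, "geometry")) {
  s <- as_coords(system)
  d <- length(s$x)
  sm <- sqrt(s$m)
  hmw <- as.matrix(hessian) / outer(sm, sm)
  hmw <- (hmw + t(hmw)) / 2
  if (project_tr) {
    tr <- tr_basis(s$x, s$m)
    q <- qr(cbind(tr, diag(d)))
    basis <- qr.Q(q)[, (ncol(tr) + 1):d, drop = FALSE]
  } else {
    basis <- diag(d)
  }
  hred <- crossprod(basis, hmw %*% basis)
  hred <- (hred + t(hred)) / 2
  ev <- eigen(hred, symmetric = TRUE)
  if (min(ev$values) <= 0) {
    stop("Hessian is not positive definite in the projected subspace; ",
         "not a minimum")
  }
  u <- crossprod(basis, q_im)
  if (sqrt(sum(u^2)) < 1e-8) {
    stop("q_im has no component in the positive-definite subspace")
  }
  # q_im^T H^-1 q_im within the subspace
  w <- ev$vectors %*% ((crossprod(ev$vectors, u)) / ev$values)
  compliance <- sum(u * w)
  k_eff <- 1 / compliance
  if (direction == 0) direction <- 1
  delta <- seq(step, delta_max, by = step)
  qv <- sort(q_min + direction * delta)
  qim_profile(q = qv, v = v_min + 0.5 * k_eff * (qv - q_min)^2,
              provenance = "harmonic_extension", zero = "ts",
              symmetric = FALSE)
}

#' Project an IRC (or any path) onto the imaginary-mode direction
#'
#' Converts a sequence of geometries with energies -- typically a steepest
#' descent path from an electronic-structure code -- into a path profile by
#' projecting each mass-weighted displacement from the transition state onto
#' q_im: Q_im,k = sqrt(m) (x_k - x_TS) . q_im. This recovers the portion of
#' V(Q_im) between the transition state and the minima without a global
#' potential surface, but provides no repulsive walls beyond the minima
#' (combine with \code{\link{harmonic_wall_extension}} for those).
#'
#' @param geometries matrix, one row per path point, columns the coordinate
#'   vector (same atom ordering as the TS).
#' @param energies energies (hartree) per point.
#' @param system the transition-state \code{geometry} or \code{model_system}.
#' @param q_im the imaginary-mode unit vector (mass-weighted).
#' @param e_zero energy zero subtracted from \code{energies}; default the
#'   energy of the path point closest to the TS.
#' @return a \code{qim_profile} (zero at TS, provenance
#'   \code{irc_projection}), sorted by Q_im; warns when the projected
#'   coordinate is not monotone along the path order.
#' @export
project_irc <- function(geometries, energies, system, q_im, e_zero = NULL) {
  geometries <- as.matrix(geometries)
  s <- as_coords(system)
  if (ncol(geometries) != length(s$x)) {
    stop("geometry columns do not match the TS coordinate count")
  }
  if (nrow(geometries) != length(energies)) {
    stop("geometries and energies disagree in length")
  }
  sm <- sqrt(s$m)
  qs <- as.numeric((sweep(geometries, 2L, s$x)) %*% (sm * q_im))
  if (max(abs(qs)) < 1e-10) {
    stop("path is orthogonal to q_im: all projections are zero")
  }
  dq <- diff(qs)
  if (any(dq > 0) && any(dq < 0)) {
    warning("projected coordinate is not monotone along the path order; ",
            "the path curls back relative to q_im")
  }
  if (is.null(e_zero)) e_zero <- energies[which.min(abs(qs))]
  ord <- order(qs)
  qs <- qs[ord]; vv <- energies[ord] - e_zero
  keep <- c(TRUE, diff(qs) > 1e-12)
  qim_profile(qs[keep], vv[keep], provenance = "irc_projection",
              zero = "ts", e_zero = e_zero)
}

#' Two-dimensional relaxed surface V(Q_im, Q_1)
#'
#' Relaxes all transition-state modes except the imaginary mode and one
#' chosen real mode on a rectangular grid of the two frozen coordinates,
#' with warm starts carried along each row.
#'
#' @inheritParams relax_at_qim
#' @param q1_index index of the second frozen mode among the \emph{real}
#'   modes, i.e. 1 refers to the first column of the orthogonal-mode basis
#'   (ascending frequency).
#' @param q_im_values,q1_values grid values for the two frozen coordinates.
#' @return object of class \code{surface_grid_2d}: \code{q_im}, \code{q1},
#'   \code{v} (matrix, rows follow \code{q_im}), \code{e_ts}, energies in
#'   hartree relative to the TS.
#' @export
build_surface_2d <- function(pes, system, modes, q_im_values, q1_index,
                             q1_values, frozen_modes = NULL, gtol = 1e-8,
                             verbose = FALSE) {
  im <- imaginary_mode(modes)
  vo_all <- modes$vectors[, -im$index, drop = FALSE]
  if (q1_index < 1L || q1_index > ncol(vo_all)) {
    stop("q1_index must identify a real TS mode (1..", ncol(vo_all), ")")
  }
  v1 <- vo_all[, q1_index]
  vo <- vo_all[, -q1_index, drop = FALSE]
  if (!is.null(frozen_modes)) {
    stop("frozen_modes combined with a 2d surface is not supported")
  }
  s <- as_coords(system)
  sm <- sqrt(s$m)
  k <- ncol(vo)
  q_im_values <- sort(q_im_values)
  q1_values <- sort(q1_values)
  nq <- length(q_im_values); np <- length(q1_values)
  v <- matrix(NA_real_, nq, np)

  relax_pt <- function(q, p, warm) {
    xat <- function(cc) {
      s$x + (q * im$q_im + p * v1 + as.numeric(vo %*% cc)) / sm
    }
    cc <- warm
    ecur <- pes$energy(xat(cc))
    for (it in seq_len(200L)) {
      x <- xat(cc)
      g <- crossprod(vo, pes$gradient(x) / sm)
      if (max(abs(g)) < gtol) break
      h <- crossprod(vo, (pes$hessian(x) / outer(sm, sm)) %*% vo)
      h <- (h + t(h)) / 2
      ev_min <- min(eigen(h, symmetric = TRUE, only.values = TRUE)$values)
      shift <- if (ev_min < 1e-8) 1e-8 - ev_min else 0
      moved <- FALSE
      for (tries in 1:30) {
        stp <- -solve(h + diag(shift, k), g)
        nrm <- sqrt(sum(stp^2))
        if (nrm > 2) stp <- stp * (2 / nrm)
        enew <- pes$energy(xat(cc + stp))
        if (is.finite(enew) && enew <= ecur + 1e-14 * max(1, abs(ecur))) {
          cc <- cc + as.numeric(stp); ecur <- enew; moved <- TRUE; break
        }
        shift <- max(shift * 4, 1e-6)
      }
      if (!moved) break
    }
    if (max(abs(g)) >= gtol) {
      stop(sprintf("2d relaxation failed at (Q_im, Q_1) = (%g, %g)", q, p))
    }
    list(e = ecur, cc = cc)
  }

  # start each row from the nearest-to-zero q1 column, then sweep outward
  j0 <- which.min(abs(q1_values))
  i0 <- which.min(abs(q_im_values))
  col_warm <- vector("list", np)
  warm <- numeric(k)
  for (ii in c(i0:nq, if (i0 > 1L) (i0 - 1L):1L)) {
    warm <- if (ii == i0 || is.null(col_warm[[j0]])) warm else col_warm[[j0]]
    r <- relax_pt(q_im_values[ii], q1_values[j0], warm)
    v[ii, j0] <- r$e
    col_warm[[j0]] <- r$cc
    row_warm <- r$cc
    for (jj in seq(j0 + 1L, np, length.out = max(0L, np - j0))) {
      r2 <- relax_pt(q_im_values[ii], q1_values[jj], row_warm)
      v[ii, jj] <- r2$e; row_warm <- r2$cc
    }
    row_warm <- r$cc
    for (jj in seq(j0 - 1L, 1L, length.out = max(0L, j0 - 1L))) {
      r2 <- relax_pt(q_im_values[ii], q1_values[jj], row_warm)
      v[ii, jj] <- r2$e; row_warm <- r2$cc
    }
    if (verbose) message("row Q_im = ", q_im_values[ii], " done")
  }
  e_ts <- pes$energy(s$x)
  structure(list(q_im = q_im_values, q1 = q1_values, v = v - e_ts,
                 e_ts = e_ts),
            class = "surface_grid_2d")
}

#' @export
print.surface_grid_2d <- function(x, ...) {
  cat(sprintf("surface_grid_2d: %d x %d grid, Q_im in [%g, %g], Q_1 in [%g, %g]\n",
              length(x$q_im), length(x$q1), min(x$q_im), max(x$q_im),
              min(x$q1), max(x$q1)))
  invisible(x)
}

#' Profile and surface file input/output
#'
#' Profiles are stored as plain text: comment headers
#' (\code{# qimpath profile}, \code{# zero:}, \code{# symmetric:}) followed by
#' three columns \code{Q_im  V  provenance} with V in hartree. Surfaces are
#' stored as \code{q_im q1 v} triples with a \code{# qimpath surface2d}
#' header. Round trips are lossless to full double precision.
#'
#' @param profile,surface objects to write.
#' @param path file path.
#' @return the read object, or (for writers) the path invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "qim_profile"))
  hdr <- c("# qimpath profile",
           "# units: mass-weighted a.u., hartree",
           paste0("# zero: ", profile$zero),
           paste0("# e_zero: ", format(profile$e_zero, digits = 17)),
           paste0("# symmetric: ", profile$symmetric))
  body <- sprintf("%s %s %s", format(profile$q, digits = 17),
                  format(profile$v, digits = 17), profile$provenance)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  get <- function(key, default) {
    h <- hdr[grepl(paste0("^# ", key, ":"), hdr)]
    if (length(h) == 0L) return(default)
    trimws(sub(paste0("^# ", key, ":"), "", h[1L]))
  }
  parts <- strsplit(trimws(body), "\\s+")
  q <- vapply(parts, function(p) as.numeric(p[1L]), numeric(1))
  v <- vapply(parts, function(p) as.numeric(p[2L]), numeric(1))
  prov <- vapply(parts, function(p) if (length(p) > 2L) p[3L] else "relaxed",
                 character(1))
  qim_profile(q, v, provenance = prov,
              zero = get("zero", "ts"),
              e_zero = suppressWarnings(as.numeric(get("e_zero", NA))),
              symmetric = identical(get("symmetric", "FALSE"), "TRUE"))
}

#' @rdname write_profile
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "surface_grid_2d"))
  hdr <- c("# qimpath surface2d",
           "# units: mass-weighted a.u., hartree",
           paste0("# e_ts: ", format(surface$e_ts, digits = 17)))
  g <- expand.grid(i = seq_along(surface$q_im), j = seq_along(surface$q1))
  body <- sprintf("%s %s %s",
                  format(surface$q_im[g$i], digits = 17),
                  format(surface$q1[g$j], digits = 17),
                  format(surface$v[cbind(g$i, g$j)], digits = 17))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_surface <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"),
                             function(p) as.numeric(p[1:3])))
  q_im <- sort(unique(m[, 1])); q1 <- sort(unique(m[, 2]))
  v <- matrix(NA_real_, length(q_im), length(q1))
  v[cbind(match(m[, 1], q_im), match(m[, 2], q1))] <- m[, 3]
  if (anyNA(v)) stop("surface file does not cover a full rectangular grid")
  hdr <- lines[grepl("^# e_ts:", lines)]
  e_ts <- if (length(hdr)) as.numeric(sub("^# e_ts:", "", hdr[1])) else NA_real_
  structure(list(q_im = q_im, q1 = q1, v = v, e_ts = e_ts),
            class = "surface_grid_2d")
}
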