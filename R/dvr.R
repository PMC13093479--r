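#' Cubic-spline interpolant of a path profile
#'
#' Wraps the tabulated relaxed potential in a cubic interpolant (exact at the
#' knots; cubic polynomials, including parabolas, are reproduced exactly).
#' Evaluation outside the tabulated range is an error: the profile carries no
#' information there and silent extrapolation would fabricate walls.
#'
#' @param profile a \code{\link{qim_profile}}, or anything with \code{$q} and
#'   \code{$v}; at least 4 points.
#' @return a function of Q_im returning hartree.
#' @export
spline_profile <- function(profile) {
  q <- profile$q; v <- profile$v
  if (length(q) < 4L) stop("need at least 4 profile points to spline")
  if (anyDuplicated(q)) stop("duplicate knots in profile")
  f <- stats::splinefun(q, v, method = "fmm")
  lo <- min(q); hi <- max(q)
  function(x) {
    if (any(x < lo - 1e-12) || any(x > hi + 1e-12)) {
      stop(sprintf("evaluation outside the tabulated range [%g, %g]", lo, hi))
    }
    f(pmin(pmax(x, lo), hi))
  }
}

# sinc-DVR kinetic matrix on a uniform grid (Colbert-Miller, infinite range):
# T_ij = hbar^2 (-1)^(i-j) / (2 m dx^2) * (pi^2/3 if i==j else 2/(i-j)^2)
sinc_kinetic <- function(n, dx, mass) {
  d <- outer(seq_len(n), seq_len(n), `-`)
  ifelse(d == 0L, pi^2 / 3, 2 / d^2) * (-1)^d / (2 * mass * dx^2)
}

#' One-dimensional sinc-DVR eigensolver
#'
#' Solves [-1/(2m) d^2/dQ^2 + V(Q)] psi = E psi on a uniform grid using the
#' sinc (uniform-grid) discrete variable representation, whose kinetic matrix
#' is exact for the basis and whose potential matrix is diagonal. With
#' mass-weighted coordinates in atomic units the effective mass is 1; an
#' explicit \code{effective_mass} (e.g. 2 for an H-to-D analogue) rescales the
#' kinetic term.
#'
#' Convergence is verified by re-solving on a doubled grid and comparing the
#' lowest levels; the result records the largest such change.
#'
#' @param potential a function of Q (hartree) or a \code{qim_profile} (then
#'   splined, and \code{domain} defaults to the tabulated range).
#' @param domain length-2 numeric, grid end points.
#' @param n_points number of grid points (>= 64).
#' @param effective_mass kinetic mass in units of the mass-weighting mass.
#' @param n_states number of eigenpairs retained (default \code{min(n, 60)}).
#' @param check_convergence run the doubling check.
#' @param conv_states,conv_tol_cm1 levels compared in the check and the
#'   tolerance for declaring convergence.
#' @return object of class \code{level_table}: \code{energies_cm1} and
#'   \code{energies_hartree} (relative to the potential minimum on the grid),
#'   \code{e_ref} (that minimum, hartree), \code{grid}, \code{v_grid},
#'   \code{wavefunctions} (columns, unit norm as DVR coefficient vectors),
#'   \code{mass}, \code{converged}, \code{conv_diff_cm1}.
#' @export
sinc_dvr_1d <- function(potential, domain = NULL, n_points = 501,
                        effective_mass = 1, n_states = NULL,
                        check_convergence = TRUE, conv_states = 8,
                        conv_tol_cm1 = 0.01) {
  if (inherits(potential, "qim_profile") ||
      (is.list(potential) && !is.function(potential))) {
    if (is.null(domain)) domain <- range(potential$q)
    potential <- spline_profile(potential)
  }
  if (is.null(domain)) stop("domain is required for a functional potential")
  if (n_points < 64L) stop("n_points must be at least 64")
  if (effective_mass <= 0) stop("effective_mass must be positive")

  solve_grid <- function(n) {
    x <- seq(domain[1], domain[2], length.out = n)
    vx <- potential(x)
    h <- sinc_kinetic(n, x[2] - x[1], effective_mass) + diag(vx)
    e <- eigen(h, symmetric = TRUE)
    list(x = x, vx = vx, values = rev(e$values),
         vectors = e$vectors[, n:1, drop = FALSE])
  }
  sol <- solve_grid(n_points)
  i_min <- which.min(sol$vx)
  if (i_min %in% c(1L, n_points)) {
    stop("domain does not contain the potential minimum in its interior")
  }
  # refine the reference below grid resolution: min-on-grid wobbles by
  # O(dx^2 * curvature) between grids, which would pollute level tables
  e_ref <- stats::optimize(potential,
                           c(sol$x[i_min - 1L], sol$x[i_min + 1L]))$objective
  e_ref <- min(e_ref, sol$vx[i_min])
  if (is.null(n_states)) n_states <- min(n_points, 60L)
  n_states <- min(n_states, n_points)

  converged <- NA
  conv_diff <- NA_real_
  if (check_convergence) {
    sol2 <- solve_grid(2L * n_points - 1L)
    k <- min(conv_states, n_points)
    conv_diff <- max(abs(sol$values[1:k] - sol2$values[1:k])) * hartree_to_cm1
    converged <- conv_diff < conv_tol_cm1
    if (!converged) {
      warning(sprintf(
        "DVR not converged: doubling the grid moves the lowest %d levels by %.4g cm^-1",
        k, conv_diff))
    }
  }
  eh <- sol$values[seq_len(n_states)] - e_ref
  structure(list(energies_cm1 = eh * hartree_to_cm1,
                 energies_hartree = eh,
                 e_ref = e_ref,
                 grid = sol$x, v_grid = sol$vx,
                 wavefunctions = sol$vectors[, seq_len(n_states), drop = FALSE],
                 mass = effective_mass, n_points = n_points,
                 domain = domain, dims = 1L,
                 converged = converged, conv_diff_cm1 = conv_diff),
            class = "level_table")
}

#' @export
print.level_table <- function(x, n = 10, ...) {
  cat(sprintf("level_table (%dd DVR, %s points%s)\n", x$dims,
              if (x$dims == 1L) x$n_points else
                paste(x$n_grid, collapse = " x "),
              if (isTRUE(x$converged)) ", converged" else ""))
  k <- min(n, length(x$energies_cm1))
  cat("lowest levels (cm^-1 above the potential minimum):\n")
  print(round(x$energies_cm1[seq_len(k)], 3))
  invisible(x)
}

# tensor-product cubic spline evaluation of a gridded surface at new axes
tensor_spline_grid <- function(qk, pk, v, qout, pout) {
  m1 <- t(apply(v, 1L, function(row) {
    stats::splinefun(pk, row, method = "fmm")(pout)
  }))
  if (length(pout) == 1L) m1 <- matrix(m1, ncol = 1L)
  apply(m1, 2L, function(col) {
    stats::splinefun(qk, col, method = "fmm")(qout)
  })
}

#' Two-dimensional sinc-DVR eigensolver
#'
#' Direct-product sinc-DVR Hamiltonian on the relaxed two-mode surface
#' V(Q_im, Q_1):
#' H = T_qim (x) 1 + 1 (x) T_q1 + diag(V). The surface is interpolated onto
#' the DVR product grid by a tensor-product cubic spline. A dense eigensolve
#' is used, guarded by \code{max_basis}.
#'
#' @param surface a \code{surface_grid_2d} (or list with \code{q_im},
#'   \code{q1}, \code{v}).
#' @param n_points length-2 integer, DVR points per axis (recycled).
#' @param domain optional list with elements \code{q_im}, \code{q1} (length-2
#'   ranges); defaults to the tabulated ranges.
#' @param effective_mass length-2 masses per axis (recycled).
#' @param n_states eigenpairs retained.
#' @param max_basis refuse product grids larger than this.
#' @return a \code{level_table} with \code{dims = 2}, \code{grid_q},
#'   \code{grid_p}; wavefunction columns are vec'd over the product grid
#'   (Q_1 index fastest).
#' @export
dvr_2d <- function(surface, n_points = c(48L, 48L), domain = NULL,
                   effective_mass = c(1, 1), n_states = 40L,
                   max_basis = 20000L) {
  n_points <- rep_len(as.integer(n_points), 2L)
  effective_mass <- rep_len(effective_mass, 2L)
  if (prod(n_points) > max_basis) {
    stop("product basis of ", prod(n_points),
         " exceeds max_basis = ", max_basis)
  }
  if (is.null(domain)) {
    domain <- list(q_im = range(surface$q_im), q1 = range(surface$q1))
  }
  xq <- seq(domain$q_im[1], domain$q_im[2], length.out = n_points[1])
  xp <- seq(domain$q1[1], domain$q1[2], length.out = n_points[2])
  vg <- tensor_spline_grid(surface$q_im, surface$q1, surface$v, xq, xp)
  tq <- sinc_kinetic(n_points[1], xq[2] - xq[1], effective_mass[1])
  tp <- sinc_kinetic(n_points[2], xp[2] - xp[1], effective_mass[2])
  # vec ordering: Q_1 (p) index fastest
  h <- kronecker(tq, diag(n_points[2])) + kronecker(diag(n_points[1]), tp)
  vvec <- as.numeric(t(vg))
  diag(h) <- diag(h) + vvec
  e <- eigen(h, symmetric = TRUE)
  nb <- prod(n_points)
  n_states <- min(n_states, nb)
  # refine the potential-minimum reference on a locally finer tensor grid
  ij <- arrayInd(which.min(vg), dim(vg))
  qf <- seq(xq[max(1L, ij[1] - 1L)], xq[min(n_points[1], ij[1] + 1L)],
            length.out = 41L)
  pf <- seq(xp[max(1L, ij[2] - 1L)], xp[min(n_points[2], ij[2] + 1L)],
            length.out = 41L)
  e_ref <- min(min(vg),
               min(tensor_spline_grid(surface$q_im, surface$q1, surface$v,
                                      qf, pf)))
  vals <- rev(e$values)[seq_len(n_states)] - e_ref
  structure(list(energies_cm1 = vals * hartree_to_cm1,
                 energies_hartree = vals,
                 e_ref = e_ref,
                 grid_q = xq, grid_p = xp,
                 v_grid = vg,
                 wavefunctions = e$vectors[, nb:(nb - n_states + 1L),
                                           drop = FALSE],
                 mass = effective_mass, n_grid = n_points,
                 dims = 2L, converged = NA, conv_diff_cm1 = NA_real_),
            class = "level_table")
}

# count sign changes of a sequence, ignoring near-zero entries
count_nodes <- function(psi, rel_tol = 1e-3) {
  s <- psi[abs(psi) > rel_tol * max(abs(psi))]
  if (length(s) < 2L) return(0L)
  sum(diff(sign(s)) != 0L)
}

#' Assign quantum numbers by nodal analysis
#'
#' For 1d tables: node count and (on symmetric domains) parity of each state.
#' For 2d tables: (n_im, n_1) from sign changes along each axis, counted on
#' the slice through the probability-weighted ridge (the row/column carrying
#' the largest marginal density); a state whose neighbouring slices disagree
#' is flagged ambiguous rather than guessed.
#'
#' @param lt a \code{level_table}.
#' @param states which states to assign (default all retained).
#' @return data.frame with \code{state}, \code{n_im}, (2d) \code{n_1},
#'   (1d) \code{parity}, \code{ambiguous}.
#' @export
assign_levels <- function(lt, states = seq_len(ncol(lt$wavefunctions))) {
  stopifnot(inherits(lt, "level_table"))
  if (lt$dims == 1L) {
    out <- data.frame(state = states, n_im = NA_integer_,
                      parity = NA_character_, ambiguous = FALSE)
    sym_dom <- abs(lt$domain[1] + lt$domain[2]) <
      1e-9 * diff(lt$domain)
    for (i in seq_along(states)) {
      psi <- lt$wavefunctions[, states[i]]
      out$n_im[i] <- count_nodes(psi)
      if (sym_dom) {
        ov <- sum(psi * rev(psi))
        out$parity[i] <- if (abs(ov) < 0.5) NA_character_
                         else if (ov > 0) "even" else "odd"
      }
    }
    return(out)
  }
  nq <- lt$n_grid[1]; np <- lt$n_grid[2]
  out <- data.frame(state = states, n_im = NA_integer_, n_1 = NA_integer_,
                    ambiguous = FALSE)
  for (i in seq_along(states)) {
    psi <- matrix(lt$wavefunctions[, states[i]], nrow = np)  # p fastest
    psi <- t(psi)                                            # nq x np
    dens_p <- colSums(psi^2); dens_q <- rowSums(psi^2)
    jp <- which.max(dens_p); jq <- which.max(dens_q)
    nodes_axis <- function(slice_of, j, along_q) {
      cnt <- function(jj) {
        if (along_q) count_nodes(psi[, jj]) else count_nodes(psi[jj, ])
      }
      main <- cnt(j)
      nb <- c(max(1L, j - 1L), min(if (along_q) np else nq, j + 1L))
      agree <- all(vapply(nb, cnt, integer(1)) == main)
      list(n = main, agree = agree)
    }
    aq <- nodes_axis(NULL, jp, along_q = TRUE)
    ap <- nodes_axis(NULL, jq, along_q = FALSE)
    out$n_im[i] <- aq$n
    out$n_1[i] <- ap$n
    out$ambiguous[i] <- !(aq$agree && ap$agree)
  }
  out
}

#' Tunneling splittings from a level table
#'
#' Pairs consecutive levels below the barrier (Delta_0 = E_1 - E_0,
#' Delta_1 = E_3 - E_2, ...) and reports the gap of each pair; levels above
#' the barrier are listed unpaired. If the potential on the grid has no
#' interior barrier between two wells, a warning notes that the system is not
#' a double well.
#'
#' @param lt a \code{level_table}.
#' @param barrier_cm1 barrier energy in cm^-1 relative to the potential
#'   minimum; default taken from the interior maximum of the grid potential.
#' @return data.frame with \code{pair}, \code{lower}, \code{upper} (state
#'   indices), \code{e_lower_cm1}, \code{e_upper_cm1}, \code{delta_cm1},
#'   \code{below_barrier}.
#' @export
level_splittings <- function(lt, barrier_cm1 = NULL) {
  stopifnot(inherits(lt, "level_table"))
  e <- lt$energies_cm1
  if (length(e) < 2L) stop("need at least 2 levels")
  if (is.null(barrier_cm1)) {
    if (lt$dims == 1L) {
      st <- profile_structure(list(q = lt$grid, v = lt$v_grid))
    } else {
      j0 <- which.min(abs(lt$grid_p))
      st <- profile_structure(list(q = lt$grid_q, v = lt$v_grid[, j0]))
    }
    if (is.null(st)) {
      warning("potential has no interior barrier between two wells; ",
              "not a double well")
      barrier_cm1 <- -Inf  # nothing pairs; all levels reported unpaired
    } else {
      barrier_cm1 <- hartree2cm(st$v_top - min(st$v_left, st$v_right))
    }
  }
  n <- length(e)
  pairs <- list()
  i <- 1L
  while (i + 1L <= n) {
    below <- e[i] < barrier_cm1 && e[i + 1L] < barrier_cm1
    if (!below) break
    pairs[[length(pairs) + 1L]] <- data.frame(
      pair = length(pairs), lower = i, upper = i + 1L,
      e_lower_cm1 = e[i], e_upper_cm1 = e[i + 1L],
      delta_cm1 = e[i + 1L] - e[i], below_barrier = TRUE)
    i <- i + 2L
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(pair = integer(0), lower = integer(0), upper = integer(0),
               e_lower_cm1 = numeric(0), e_upper_cm1 = numeric(0),
               delta_cm1 = numeric(0), below_barrier = logical(0))
  attr(out, "barrier_cm1") <- barrier_cm1
  attr(out, "unpaired") <- if (i <= n) seq(i, n) else integer(0)
  out
}

#' Left/right well probabilities of a state
#'
#' Integrates the DVR probability |psi_i|^2 on either side of a divider
#' (default: the barrier-top abscissa of the grid potential). DVR coefficient
#' vectors are unit-normalised, so the two numbers sum to 1; a grid point
#' falling exactly on the divider is split evenly.
#'
#' @param lt a 1d \code{level_table}.
#' @param state state index.
#' @param divider dividing Q_im value; must lie inside the domain.
#' @return named numeric \code{c(p_left, p_right)}.
#' @export
well_probabilities <- function(lt, state = 1L, divider = NULL) {
  stopifnot(inherits(lt, "level_table"), lt$dims == 1L)
  if (is.null(divider)) {
    st <- profile_structure(list(q = lt$grid, v = lt$v_grid))
    if (is.null(st)) stop("no interior barrier found; supply a divider")
    divider <- st$q_top
  }
  if (divider <= min(lt$grid) || divider >= max(lt$grid)) {
    stop("divider lies outside the grid domain")
  }
  p2 <- lt$wavefunctions[, state]^2
  p2 <- p2 / sum(p2)
  on_div <- abs(lt$grid - divider) < 1e-12
  p_left <- sum(p2[lt$grid < divider & !on_div]) + sum(p2[on_div]) / 2
  c(p_left = p_left, p_right = 1 - p_left)
}

#' Write a level table as CSV
#'
#' Columns: state index, energy (cm^-1 above the potential minimum), nodal
#' assignments, parity (1d) and well probabilities (1d double wells).
#'
#' @param lt a \code{level_table}.
#' @param path file path.
#' @param n_states rows to write.
#' @return the path, invisibly.
#' @export
write_level_table <- function(lt, path, n_states = length(lt$energies_cm1)) {
  n_states <- min(n_states, ncol(lt$wavefunctions))
  asn <- assign_levels(lt, seq_len(n_states))
  df <- data.frame(state = seq_len(n_states),
                   e_cm1 = round(lt$energies_cm1[seq_len(n_states)], 6))
  df <- cbind(df, asn[, setdiff(names(asn), "state"), drop = FALSE])
  if (lt$dims == 1L) {
    st <- profile_structure(list(q = lt$grid, v = lt$v_grid))
    if (!is.null(st)) {
      pr <- t(vapply(seq_len(n_states),
                     function(i) well_probabilities(lt, i, st$q_top),
                     numeric(2)))
      df$p_left <- round(pr[, 1], 8)
      df$p_right <- round(pr[, 2], 8)
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
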