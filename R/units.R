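#' Unit conversion constants
#'
#' All internal computation uses Hartree atomic units: energies in hartree,
#' lengths in bohr, masses in electron masses. With mass-weighted coordinates
#' in these units both hbar and the effective mass are unity, so the kinetic
#' operator along the path is simply -1/2 d^2/dQ^2. Energies are converted to
#' cm^-1 only at the reporting boundary.
#'
#' @format Numeric scalars.
#' @name units
NULL

#' @rdname units
#' @export
hartree_to_cm1 <- 219474.6313632

#' @rdname units
#' @export
amu_to_me <- 1822.888486

#' @rdname units
#' @export
bohr_to_angstrom <- 0.529177210903

#' Convert hartree to cm^-1
#' @param e energy in hartree
#' @return energy in cm^-1
#' @export
hartree2cm <- function(e) e * hartree_to_cm1

#' Convert cm^-1 to hartree
#' @param e energy in cm^-1
#' @return energy in hartree
#' @export
cm2hartree <- function(e) e / hartree_to_cm1

# standard atomic weights (amu) for the elements this package is likely to
# meet; "D" and "T" are accepted as explicit isotope labels
.atomic_weights <- c(
  H = 1.00782503, D = 2.01410178, T = 3.01604928,
  He = 4.002602, Li = 6.94, Be = 9.0121831, B = 10.81,
  C = 12.0, N = 14.003074, O = 15.99491462, F = 18.99840316,
  Ne = 20.1797, Na = 22.98976928, Mg = 24.305, Al = 26.9815385,
  Si = 28.085, P = 30.973762, S = 31.972071, Cl = 34.96885268,
  Ar = 39.948, K = 39.0983, Ca = 40.078, Br = 78.9183376, I = 126.904473
)

#' Atomic mass lookup
#'
#' Returns masses in electron-mass units for element symbols. Isotopes can be
#' requested with the labels \code{"D"}, \code{"T"}, \code{"18O"} (a leading
#' mass number uses that integer mass in amu is \emph{not} assumed; only a
#' small set of common isotopes is tabulated) or overridden per atom via
#' \code{overrides}.
#'
#' @param symbols character vector of element symbols.
#' @param overrides optional named numeric vector (amu), names are 1-based
#'   atom indices as characters or element symbols; index names win.
#' @return numeric vector of masses in electron masses.
#' @export
atomic_mass <- function(symbols, overrides = NULL) {
  extra <- c(`18O` = 17.9991596, `17O` = 16.9991317, `13C` = 13.00335484,
             `15N` = 15.0001089)
  tab <- c(.atomic_weights, extra)
  amu <- tab[symbols]
  if (anyNA(amu)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(amu)]), collapse = ", "))
  }
  amu <- unname(amu)
  if (!is.null(overrides)) {
    nm <- names(overrides)
    for (k in seq_along(overrides)) {
      idx <- suppressWarnings(as.integer(nm[k]))
      if (!is.na(idx)) {
        amu[idx] <- overrides[k]
      } else {
        amu[symbols == nm[k]] <- overrides[k]
      }
    }
  }
  amu * amu_to_me
}

#' Molecular geometry container
#'
#' Holds element labels, Cartesian coordinates in bohr and per-atom masses in
#' electron masses. The coordinate vector used by the rest of the machinery
#' is the row-major flattening (x1, y1, z1, x2, ...).
#'
#' @param labels character vector of element symbols (length N).
#' @param coords N x 3 numeric matrix of positions in bohr.
#' @param masses per-atom masses in electron masses; defaults to
#'   \code{atomic_mass(labels)}.
#' @return an object of class \code{geometry}.
#' @export
geometry <- function(labels, coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  n <- length(labels)
  if (nrow(coords) != n) stop("labels and coords disagree in length")
  if (is.null(masses)) masses <- atomic_mass(labels)
  if (length(masses) != n) stop("masses and labels disagree in length")
  if (any(masses <= 0)) stop("masses must be positive")
  structure(list(labels = labels, coords = coords, masses = masses),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("geometry: %d atoms [%s]\n", length(x$labels),
              paste(x$labels, collapse = " ")))
  invisible(x)
}

#' Non-molecular model system
#'
#' A bare coordinate vector with per-coordinate masses, for analytic model
#' potentials that do not live in 3N Cartesian space. Translation/rotation
#' projection does not apply to such systems.
#'
#' @param x numeric coordinate vector (model units; mass-weighted displacements
#'   are \code{sqrt(masses) * x}).
#' @param masses per-coordinate masses; default 1 (coordinates already
#'   mass-weighted).
#' @return an object of class \code{model_system}.
#' @export
model_system <- function(x, masses = 1) {
  x <- as.numeric(x)
  masses <- rep_len(as.numeric(masses), length(x))
  if (any(masses <= 0)) stop("masses must be positive")
  structure(list(x = x, masses = masses), class = "model_system")
}

# canonical representation: coordinate vector + per-coordinate masses
as_coords <- function(system) {
  if (inherits(system, "geometry")) {
    list(x = as.numeric(t(system$coords)),
         m = rep(system$masses, each = 3L),
         molecular = TRUE)
  } else if (inherits(system, "model_system")) {
    list(x = system$x, m = system$masses, molecular = FALSE)
  } else {
    stop("expected a 'geometry' or 'model_system' object")
  }
}

#' Mass weighting of displacement vectors
#'
#' Maps a displacement in the system's plain coordinates to mass-weighted
#' coordinates (component i scaled by sqrt(m_i)); \code{from_mass_weighted}
#' is the inverse.
#'
#' @param system a \code{geometry} or \code{model_system}.
#' @param displacement numeric vector, same length as the coordinate vector.
#' @return numeric vector of the same length.
#' @export
to_mass_weighted <- function(system, displacement) {
  s <- as_coords(system)
  if (length(displacement) != length(s$x)) {
    stop("displacement length ", length(displacement),
         " does not match coordinate count ", length(s$x))
  }
  displacement * sqrt(s$m)
}

#' @rdname to_mass_weighted
#' @export
from_mass_weighted <- function(system, displacement) {
  s <- as_coords(system)
  if (length(displacement) != length(s$x)) {
    stop("displacement length ", length(displacement),
         " does not match coordinate count ", length(s$x))
  }
  displacement / sqrt(s$m)
}

#' Read an XYZ file
#'
#' Standard XYZ: atom count, comment line, then "symbol x y z" rows with
#' coordinates in Angstrom (converted to bohr on read). The comment line is
#' preserved as an attribute.
#'
#' @param path file path.
#' @param mass_overrides passed to \code{\link{atomic_mass}}.
#' @return a \code{geometry}; attribute \code{comment} holds the comment line.
#' @export
read_xyz <- function(path, mass_overrides = NULL) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || length(lines) < n + 2L) stop("malformed XYZ file: ", path)
  comment <- lines[2L]
  rows <- strsplit(trimws(lines[3:(n + 2L)]), "\\s+")
  labels <- vapply(rows, `[[`, character(1), 1L)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  g <- geometry(labels, coords / bohr_to_angstrom,
                masses = atomic_mass(labels, mass_overrides))
  attr(g, "comment") <- comment
  g
}

#' Write an XYZ file
#'
#' @param geom a \code{geometry} (coordinates in bohr; written in Angstrom).
#' @param path file path.
#' @param comment comment line; defaults to the geometry's stored comment.
#' @export
write_xyz <- function(geom, path, comment = NULL) {
  if (is.null(comment)) comment <- attr(geom, "comment")
  if (is.null(comment)) comment <- ""
  ang <- geom$coords * bohr_to_angstrom
  lines <- c(as.character(length(geom$labels)), comment,
             sprintf("%-3s %18.12f %18.12f %18.12f",
                     geom$labels, ang[, 1], ang[, 2], ang[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Hessian matrix file
#'
#' Whitespace-delimited square matrix (hartree/bohr^2 for molecular systems),
#' row-major, optionally with \code{#} comment lines.
#'
#' @param path file path.
#' @param n expected dimension (optional check).
#' @return a symmetric numeric matrix.
#' @export
read_hessian <- function(path, n = NULL) {
  vals <- scan(path, comment.char = "#", quiet = TRUE)
  d <- sqrt(length(vals))
  if (d != round(d)) stop("Hessian file does not contain a square matrix")
  d <- as.integer(d)
  if (!is.null(n) && d != n) {
    stop("Hessian dimension ", d, " does not match expected ", n)
  }
  matrix(vals, d, d, byrow = TRUE)
}
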