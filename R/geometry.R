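#' Molecular geometry
#'
#' Constructs a molecular geometry: element symbols, atomic numbers and nuclear
#' positions in Bohr. All chargekit computations run in atomic units; positions
#' in Angstrom are converted only at I/O boundaries (see [read_xyz()]).
#'
#' @param symbols character vector of element symbols.
#' @param coords numeric matrix, n_atoms x 3, nuclear positions in Bohr.
#' @param total_charge integer total molecular charge in elementary charges.
#' @param label free-text identifier.
#' @return an object of class `"geometry"`: list with `symbols`, `z`, `coords`
#'   (Bohr), `total_charge`, `label`.
#' @examples
#' g <- geometry(c("O", "H", "H"),
#'               rbind(c(0, 0, 0), c(0, 0, 1.8), c(1.7, 0, -0.6)))
#' g$z
#' @export
geometry <- function(symbols, coords, total_charge = 0L, label = "") {
  coords <- as.matrix(coords)
  if (length(symbols) < 1L) stop("geometry needs at least one atom")
  if (nrow(coords) != length(symbols) || ncol(coords) != 3L) {
    stop("coords must be a length(symbols) x 3 matrix")
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (abs(total_charge - round(total_charge)) > 1e-9) {
    stop("total_charge must be an integer")
  }
  z <- element_number(symbols)
  if (length(symbols) > 1L) {
    d <- stats::dist(coords)
    if (min(d) < 1e-6) stop("coincident atoms: two atoms closer than 1e-6 Bohr")
  }
  structure(
    list(symbols = as.character(symbols), z = z, coords = unname(coords),
         total_charge = as.integer(round(total_charge)), label = label),
    class = "geometry"
  )
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry> %s: %d atoms, charge %+d\n",
              if (nzchar(x$label)) x$label else "(unnamed)",
              length(x$z), x$total_charge))
  invisible(x)
}

n_atoms <- function(geom) length(geom$z)

## Pairwise atom distances in Bohr.
atom_distances <- function(geom) {
  as.matrix(stats::dist(geom$coords))
}

## Distances from each atom to a set of points: n_atoms x n_points matrix.
point_atom_distances <- function(geom, points) {
  n <- n_atoms(geom)
  out <- matrix(0, n, nrow(points))
  for (a in seq_len(n)) {
    d2 <- (points[, 1] - geom$coords[a, 1])^2 +
      (points[, 2] - geom$coords[a, 2])^2 +
      (points[, 3] - geom$coords[a, 3])^2
    out[a, ] <- sqrt(d2)
  }
  out
}

#' Principal moments of inertia
#'
#' Moments of inertia (amu * Bohr^2) about the principal axes, using standard
#' atomic weights. Rotational constants are inversely proportional to these,
#' so agreement of all three moments is equivalent to agreement of rotational
#' constants, which is how duplicate species are detected.
#'
#' @param geom a [geometry()].
#' @return sorted numeric vector of the three principal moments.
#' @seealso [deduplicate_geometries()]
#' @export
principal_moments <- function(geom) {
  m <- element_mass(geom$symbols)
  com <- colSums(geom$coords * m) / sum(m)
  x <- sweep(geom$coords, 2, com)
  ixx <- sum(m * (x[, 2]^2 + x[, 3]^2))
  iyy <- sum(m * (x[, 1]^2 + x[, 3]^2))
  izz <- sum(m * (x[, 1]^2 + x[, 2]^2))
  ixy <- -sum(m * x[, 1] * x[, 2])
  ixz <- -sum(m * x[, 1] * x[, 3])
  iyz <- -sum(m * x[, 2] * x[, 3])
  tensor <- matrix(c(ixx, ixy, ixz, ixy, iyy, iyz, ixz, iyz, izz), 3, 3)
  sort(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values)
}
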