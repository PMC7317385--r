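#' Gaussian basis metadata
#'
#' chargekit carries basis metadata mainly to map atomic-orbital (AO) indices
#' to atoms; it performs no integral evaluation (overlap matrices are supplied
#' explicitly, see [wavefunction()]).
#'
#' @param ao_to_atom integer vector mapping each AO index to its atom (1-based).
#' @param shells optional list of shells, each
#'   `list(atom =, l =, exponents =, coefficients =)`.
#' @param n_atoms number of atoms the map must cover.
#' @return object of class `"gaussian_basis"`.
#' @export
gaussian_basis <- function(ao_to_atom, shells = NULL, n_atoms = max(ao_to_atom)) {
  ao_to_atom <- as.integer(ao_to_atom)
  if (length(ao_to_atom) < 1L) stop("empty AO map")
  if (any(ao_to_atom < 1L | ao_to_atom > n_atoms)) {
    stop("ao_to_atom references an invalid atom index")
  }
  if (!is.null(shells)) {
    for (sh in shells) {
      if (sh$atom < 1L || sh$atom > n_atoms) stop("shell references invalid atom")
      if (any(sh$exponents <= 0)) stop("shell exponents must be positive")
    }
  }
  structure(list(ao_to_atom = ao_to_atom, shells = shells),
            class = "gaussian_basis")
}

n_ao <- function(basis) length(basis$ao_to_atom)

#' Wavefunction state
#'
#' Self-describing container for everything the orbital-partition charges
#' need: geometry, basis-to-atom map, the one-particle density matrix P (in the
#' AO basis, electrons) and the AO overlap matrix S. The electron count must be
#' consistent: `trace(P S) = n_electrons`.
#'
#' @param geom a [geometry()].
#' @param basis a [gaussian_basis()].
#' @param P symmetric AO x AO density matrix.
#' @param S symmetric positive-definite AO x AO overlap matrix.
#' @param n_electrons electron count; default `sum(Z) - total_charge`.
#' @param tol tolerance for the `trace(P S)` consistency check.
#' @return object of class `"wavefunction"`.
#' @export
wavefunction <- function(geom, basis, P, S,
                         n_electrons = sum(geom$z) - geom$total_charge,
                         tol = 1e-8) {
  P <- as.matrix(P); S <- as.matrix(S)
  nao <- n_ao(basis)
  if (!all(dim(P) == nao) || !all(dim(S) == nao)) {
    stop("P and S must be ", nao, " x ", nao, " to match the basis")
  }
  if (max(abs(P - t(P))) > 1e-10) stop("density matrix P is not symmetric")
  if (max(abs(S - t(S))) > 1e-10) stop("overlap matrix S is not symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("overlap matrix S is not positive definite")
  tr <- sum(P * S)  # trace(P %*% S) for symmetric S
  if (abs(tr - n_electrons) > tol) {
    stop(sprintf("inconsistent electron count: trace(PS) = %.10g, expected %g",
                 tr, n_electrons))
  }
  structure(list(geometry = geom, basis = basis, P = P, S = S,
                 n_electrons = n_electrons),
            class = "wavefunction")
}

#' @export
print.wavefunction <- function(x, ...) {
  cat(sprintf("<wavefunction> %d atoms, %d AOs, %g electrons\n",
              n_atoms(x$geometry), n_ao(x$basis), x$n_electrons))
  invisible(x)
}

#' Read a wavefunction from the chargekit JSON container
#'
#' The container is a documented JSON dialect holding the geometry (symbols,
#' positions in Bohr, total charge), the AO-to-atom map (1-based), the density
#' matrix, the overlap matrix and the electron count. The overlap matrix is
#' stored explicitly so no integral engine is needed. Invariants (symmetry,
#' positive-definiteness, electron-count consistency) are checked on load; an
#' electron-count defect above `1e-6` is rejected as inconsistent.
#'
#' @param path path to the JSON file.
#' @return a [wavefunction()].
#' @seealso [write_wavefunction()]
#' @export
read_wavefunction <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  for (field in c("geometry", "basis", "density_matrix", "n_electrons")) {
    if (is.null(doc[[field]])) stop("wavefunction container missing '", field, "'")
  }
  if (is.null(doc$overlap_matrix)) stop("overlap required: container has no 'overlap_matrix'")
  g <- doc$geometry
  geom <- geometry(g$symbols, matrix(unlist(g$coords_bohr), ncol = 3,
                                     byrow = is.list(g$coords_bohr)),
                   total_charge = if (is.null(g$total_charge)) 0L else g$total_charge,
                   label = if (is.null(g$label)) basename(path) else g$label)
  basis <- gaussian_basis(doc$basis$ao_to_atom, n_atoms = n_atoms(geom))
  wavefunction(geom, basis, as.matrix(doc$density_matrix),
               as.matrix(doc$overlap_matrix), doc$n_electrons, tol = 1e-6)
}

#' Write a wavefunction to the chargekit JSON container
#' @param wfn a [wavefunction()].
#' @param path output path.
#' @export
write_wavefunction <- function(wfn, path) {
  doc <- list(
    geometry = list(symbols = wfn$geometry$symbols,
                    coords_bohr = wfn$geometry$coords,
                    total_charge = wfn$geometry$total_charge,
                    label = wfn$geometry$label),
    basis = list(ao_to_atom = wfn$basis$ao_to_atom),
    density_matrix = wfn$P,
    overlap_matrix = wfn$S,
    n_electrons = wfn$n_electrons
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Minimal-basis target for MBS projection
#'
#' Describes the minimal basis a wavefunction is projected onto: its overlap
#' matrix `S_mm`, the cross overlap `S_mf` between minimal and working basis
#' functions, and the minimal-basis AO-to-atom map. Fixtures supply these
#' analytically; real users export them from their integral code.
#'
#' @param S_mm minimal-basis overlap matrix (m x m, SPD).
#' @param S_mf cross overlap, minimal x working (m x n).
#' @param ao_to_atom 1-based atom index per minimal-basis function.
#' @return object of class `"minimal_basis"`.
#' @export
minimal_basis <- function(S_mm, S_mf, ao_to_atom) {
  S_mm <- as.matrix(S_mm); S_mf <- as.matrix(S_mf)
  m <- length(ao_to_atom)
  if (!all(dim(S_mm) == m)) stop("S_mm must be ", m, " x ", m)
  if (nrow(S_mf) != m) stop("S_mf must have one row per minimal function")
  if (max(abs(S_mm - t(S_mm))) > 1e-10) stop("S_mm is not symmetric")
  if (min(eigen(S_mm, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("S_mm is not positive definite")
  }
  structure(list(S_mm = S_mm, S_mf = S_mf,
                 ao_to_atom = as.integer(ao_to_atom)),
            class = "minimal_basis")
}
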