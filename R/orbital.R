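## Class IIa charges: Mulliken / Loewdin / Bickelhaupt in the working basis,
## and minimal-basis-projected variants (MBS-Mulliken, MBS-Bickelhaupt).

#' Overlap population matrix
#'
#' The gross overlap populations `q_ij = P_ij * S_ij` (elementwise product of
#' density and overlap matrices). Their total equals the electron count; how
#' the off-diagonal entries are condensed onto basis functions distinguishes
#' the Mulliken and Bickelhaupt variants, see [condense_populations()].
#'
#' @param wfn a [wavefunction()].
#' @return object of class `"overlap_populations"`: list with the AO x AO
#'   matrix `q` and the AO-to-atom map.
#' @export
overlap_populations <- function(wfn) {
  q <- wfn$P * wfn$S
  structure(list(q = q, ao_to_atom = wfn$basis$ao_to_atom,
                 n_electrons = wfn$n_electrons),
            class = "overlap_populations")
}

#' Condense overlap populations onto basis functions
#'
#' Mulliken splits each off-diagonal overlap population evenly between the two
#' basis functions:
#' `Q'_ii = q_ii + 1/2 sum_{j != i} (q_ij + q_ji)`.
#' Bickelhaupt weights the split by the diagonal populations instead:
#' `Q'_ii = q_ii + sum_{j != i} q_ii / (q_ii + q_jj) * (q_ij + q_ji)`,
#' so a function with the larger diagonal population claims the larger share.
#' Both variants redistribute, never create, population: the condensed
#' populations sum to the electron count. When a pair has
#' `|q_ii + q_jj| < 1e-10` the Bickelhaupt weight is undefined; the pair falls
#' back to an even split and the event is counted in the diagnostics.
#'
#' @param op an [overlap_populations()] object.
#' @param variant `"mulliken"` or `"bickelhaupt"`.
#' @return object of class `"shell_populations"`: list with per-AO `Q`
#'   (electrons), `variant`, `ao_to_atom` and `diagnostics`.
#' @export
condense_populations <- function(op, variant = c("mulliken", "bickelhaupt")) {
  variant <- match.arg(variant)
  q <- op$q
  n <- nrow(q)
  off <- q + t(q)
  diag(off) <- 0
  diagnostics <- list()
  if (variant == "mulliken") {
    Q <- diag(q) + 0.5 * rowSums(off)
  } else {
    d <- diag(q)
    denom <- outer(d, d, "+")
    bad <- abs(denom) < 1e-10
    w <- ifelse(bad, 0.5, outer(d, rep(1, n)) / ifelse(bad, 1, denom))
    diag(w) <- 0
    nbad <- (sum(bad) - sum(abs(2 * d) < 1e-10)) / 2
    if (nbad > 0) {
      diagnostics$zero_denominator_pairs <- nbad
      warning(nbad, " basis-function pair(s) with vanishing diagonal ",
              "populations; fell back to even split")
    }
    Q <- d + rowSums(w * off)
  }
  structure(list(Q = Q, variant = variant, ao_to_atom = op$ao_to_atom,
                 n_electrons = op$n_electrons, diagnostics = diagnostics),
            class = "shell_populations")
}

#' Atomic charges from condensed populations
#'
#' `q_A = Z_A - sum_{i in A} Q'_ii`. Because condensation conserves the total
#' population, the charges sum to the total molecular charge to machine
#' precision.
#'
#' @param shell_pop a [condense_populations()] result.
#' @param geom the [geometry()].
#' @param method method name recorded on the result.
#' @return a [charge_vector()].
#' @export
atom_charges <- function(shell_pop, geom,
                         method = shell_pop$variant) {
  pops <- vapply(seq_len(n_atoms(geom)), function(a) {
    sum(shell_pop$Q[shell_pop$ao_to_atom == a])
  }, numeric(1))
  charge_vector(geom$z - pops, geom, method,
                diagnostics = shell_pop$diagnostics, sum_tol = 1e-8)
}

#' Mulliken charges
#' @param wfn a [wavefunction()].
#' @return a [charge_vector()].
#' @export
mulliken_charges <- function(wfn) {
  atom_charges(condense_populations(overlap_populations(wfn), "mulliken"),
               wfn$geometry, method = "mulliken")
}

#' Bickelhaupt charges
#'
#' Mulliken-type analysis with off-diagonal overlap populations shared in
#' proportion to the diagonal populations rather than split evenly.
#' @param wfn a [wavefunction()].
#' @return a [charge_vector()].
#' @export
bickelhaupt_charges <- function(wfn) {
  atom_charges(condense_populations(overlap_populations(wfn), "bickelhaupt"),
               wfn$geometry, method = "bickelhaupt")
}

## Symmetric matrix powers via eigendecomposition.
mat_power_sym <- function(S, p, tol = 1e-12) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < tol && p < 0) {
    stop("matrix not positive definite (condition number ",
         format(max(e$values) / max(min(e$values), .Machine$double.xmin),
                digits = 3), ")")
  }
  e$vectors %*% (e$values^p * t(e$vectors))
}

#' Loewdin charges
#'
#' Populations are the diagonal of `S^(1/2) P S^(1/2)` summed per atom; the
#' symmetric orthogonalization makes the result independent of how overlap is
#' shared between functions.
#'
#' @param wfn a [wavefunction()].
#' @return a [charge_vector()].
#' @export
lowdin_charges <- function(wfn) {
  shalf <- mat_power_sym(wfn$S, 0.5)
  L <- shalf %*% wfn$P %*% shalf
  pops <- vapply(seq_len(n_atoms(wfn$geometry)), function(a) {
    sum(diag(L)[wfn$basis$ao_to_atom == a])
  }, numeric(1))
  charge_vector(wfn$geometry$z - pops, wfn$geometry, "lowdin", sum_tol = 1e-8)
}

## Occupied orbital coefficients of a closed-shell density matrix:
## P = 2 C C^T with C^T S C = I.
occupied_orbitals <- function(wfn) {
  n_occ <- round(wfn$n_electrons / 2)
  if (abs(wfn$n_electrons - 2 * n_occ) > 1e-8) {
    stop("closed-shell density expected (even electron count); supply an ",
         "alpha+beta-summed density for open shells")
  }
  shalf <- mat_power_sym(wfn$S, 0.5)
  sinvh <- mat_power_sym(wfn$S, -0.5)
  e <- eigen(shalf %*% (wfn$P / 2) %*% shalf, symmetric = TRUE)
  occ <- seq_len(n_occ)
  if (n_occ > 0 && any(abs(e$values[occ] - 1) > 1e-6)) {
    stop("density matrix is not idempotent (natural occupations ",
         paste(format(e$values[occ], digits = 4), collapse = ", "), ")")
  }
  sinvh %*% e$vectors[, occ, drop = FALSE]
}

#' Project a wavefunction onto a minimal basis
#'
#' Projects the occupied molecular orbitals onto the minimal basis,
#' `C_m = S_mm^{-1} S_mf C_occ`, then Loewdin-orthonormalizes the projected
#' orbitals within the minimal basis to restore idempotency and the electron
#' count. Minimal-basis Mulliken-type analyses applied to the result are
#' stable against working-basis pathologies (diffuse functions, near linear
#' dependence), unlike their full-basis counterparts.
#'
#' @param wfn a [wavefunction()] (closed shell, `P = 2 C C^T`).
#' @param mb a [minimal_basis()] whose cross overlap `S_mf` matches the
#'   working basis of `wfn`.
#' @return a [wavefunction()] in the minimal basis with
#'   `trace(P_m S_mm) = n_electrons`.
#' @export
project_minimal_basis <- function(wfn, mb) {
  if (ncol(mb$S_mf) != n_ao(wfn$basis)) {
    stop("cross overlap S_mf has ", ncol(mb$S_mf),
         " columns but the working basis has ", n_ao(wfn$basis), " functions")
  }
  c_occ <- occupied_orbitals(wfn)
  c_m <- solve(mb$S_mm, mb$S_mf %*% c_occ)
  ov <- t(c_m) %*% mb$S_mm %*% c_m
  ev <- eigen(ov, symmetric = TRUE, only.values = TRUE)$values
  if (ncol(c_m) > 0 && min(ev) < 1e-10 * max(max(ev), 1)) {
    stop("projected occupied orbitals are linearly dependent in the minimal ",
         "basis (condition number ",
         format(max(ev) / max(min(ev), .Machine$double.xmin), digits = 3), ")")
  }
  c_m <- c_m %*% mat_power_sym(ov, -0.5)
  P_m <- 2 * c_m %*% t(c_m)
  wavefunction(wfn$geometry,
               gaussian_basis(mb$ao_to_atom, n_atoms = n_atoms(wfn$geometry)),
               P_m, mb$S_mm, n_electrons = wfn$n_electrons, tol = 1e-8)
}

#' Minimal-basis-projected charges
#'
#' MBS-Mulliken and MBS-Bickelhaupt: [project_minimal_basis()] followed by
#' [condense_populations()] and [atom_charges()].
#'
#' @param wfn a [wavefunction()].
#' @param mb a [minimal_basis()].
#' @param variant `"mulliken"` or `"bickelhaupt"`.
#' @return a [charge_vector()] with method `"mbs-mulliken"` or
#'   `"mbs-bickelhaupt"`.
#' @export
mbs_charges <- function(wfn, mb, variant = c("mulliken", "bickelhaupt")) {
  variant <- match.arg(variant)
  pw <- project_minimal_basis(wfn, mb)
  atom_charges(condense_populations(overlap_populations(pw), variant),
               pw$geometry, method = paste0("mbs-", variant))
}
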