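## Shared fixture builders. Oracles here are computed with plain base-R code
## paths independent of the package functions they are used to check.

water_geometry <- function() {
  geometry(c("O", "H", "H"),
           rbind(c(0, 0, 0), c(0, 1.43, 1.1), c(0, -1.43, 1.1)),
           label = "water")
}

## Slater scene density evaluated with test-local code (not the package's).
ref_slater_density <- function(positions, populations, zetas, points) {
  rho <- numeric(nrow(points))
  for (a in seq_len(nrow(positions))) {
    r <- sqrt(colSums((t(points) - positions[a, ])^2))
    rho <- rho + populations[a] * zetas[a]^3 / (8 * pi) * exp(-zetas[a] * r)
  }
  rho
}

## A 4-function working basis + 2-function minimal basis built as Gram
## matrices of explicit vectors in R^6, so every overlap is exact linear
## algebra and the minimal functions lie in the working span.
projection_fixture <- function() {
  V <- cbind(c(1, 0.2, 0, 0, 0.1, 0),
             c(0.3, 1, 0.1, 0, 0, 0),
             c(0, 0.1, 1, 0.25, 0, 0.1),
             c(0, 0, 0.3, 1, 0.1, 0))
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  S_ff <- crossprod(V)
  Tmat <- cbind(c(1, 0.5, 0, 0), c(0, 0, 0.6, 1))  # minimal = combos per atom
  S_mm <- t(Tmat) %*% S_ff %*% Tmat
  S_mm <- S_mm / sqrt(diag(S_mm) %o% diag(S_mm))
  Tmat <- sweep(Tmat, 2, sqrt(diag(t(Tmat) %*% S_ff %*% Tmat)), "/")
  S_mf <- t(Tmat) %*% S_ff
  geom <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.5)))
  cvec <- c(0.9, 0.3, 0.4, 0.2)
  cvec <- cvec / sqrt(as.numeric(t(cvec) %*% S_ff %*% cvec))
  P <- 2 * tcrossprod(cvec)
  wfn <- wavefunction(geom, gaussian_basis(c(1L, 1L, 2L, 2L)), P, S_ff,
                      n_electrons = 2)
  mb <- minimal_basis(t(Tmat) %*% S_ff %*% Tmat, S_mf, c(1L, 2L))
  list(wfn = wfn, mb = mb, V = V, Tmat = Tmat, c = cvec, S_ff = S_ff)
}

expect_charges_equal <- function(cv, expected, tol = 1e-8) {
  testthat::expect_equal(cv$charges, expected, tolerance = tol,
                         ignore_attr = TRUE)
}
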