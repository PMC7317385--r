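test_that("overlap populations follow the closed two-orbital algebra", {
  ## symmetric case: c_a = c_b solves 2c^2(1+s) = 1
  c_sym <- sqrt(1 / (2 * (1 + 0.5)))
  sym <- make_polar_diatomic(0.5, c_sym)
  q <- overlap_populations(sym$wfn)$q
  expect_equal(q[1, 1], q[2, 2], tolerance = 1e-12)

  fx <- make_polar_diatomic(0.5, 0.8)
  q2 <- overlap_populations(fx$wfn)$q
  cb <- fx$coefficients[2]
  expect_equal(q2[1, 2], 2 * 0.8 * cb * 0.5, tolerance = 1e-12)
  expect_equal(sum(q2), 2, tolerance = 1e-12)

  ## S = identity: q is the diagonal of P
  geom <- fx$wfn$geometry
  P <- matrix(c(1.2, 0.4, 0.4, 0.8), 2, 2)
  w_id <- wavefunction(geom, gaussian_basis(c(1L, 2L)), P, diag(2),
                       n_electrons = 2)
  qi <- overlap_populations(w_id)$q
  expect_equal(qi, diag(diag(P)), tolerance = 1e-12)
})

test_that("condensation reproduces hand-evaluated Mulliken and Bickelhaupt shares", {
  op <- structure(list(q = matrix(c(0.6, 0.1, 0.1, 0.2), 2, 2),
                       ao_to_atom = c(1L, 2L), n_electrons = 1),
                  class = "overlap_populations")
  expect_equal(condense_populations(op, "mulliken")$Q, c(0.7, 0.3),
               tolerance = 1e-12)
  ## Bickelhaupt: Q1 = 0.6 + 0.6/0.8 * 0.2 = 0.75
  expect_equal(condense_populations(op, "bickelhaupt")$Q, c(0.75, 0.25),
               tolerance = 1e-12)

  ## equal diagonals degrade the weights to 1/2: Bickelhaupt = Mulliken
  opq <- structure(list(q = matrix(c(0.4, 0.15, 0.15, 0.4), 2, 2),
                        ao_to_atom = c(1L, 2L), n_electrons = 1.1),
                   class = "overlap_populations")
  expect_equal(condense_populations(opq, "bickelhaupt")$Q,
               condense_populations(opq, "mulliken")$Q, tolerance = 1e-14)

  ## no off-diagonal population: both variants return the diagonal
  opd <- structure(list(q = diag(c(0.5, 0.3, 0.2)),
                        ao_to_atom = c(1L, 1L, 2L), n_electrons = 1),
                   class = "overlap_populations")
  expect_equal(condense_populations(opd, "mulliken")$Q, c(0.5, 0.3, 0.2))
  expect_equal(condense_populations(opd, "bickelhaupt")$Q, c(0.5, 0.3, 0.2))

  ## vanishing diagonal pair: falls back to an even split with a warning
  opz <- structure(list(q = matrix(c(0, 0.1, 0.1, 0), 2, 2),
                        ao_to_atom = c(1L, 2L), n_electrons = 0.2),
                   class = "overlap_populations")
  expect_warning(cz <- condense_populations(opz, "bickelhaupt"),
                 "even split")
  expect_equal(cz$Q, c(0.1, 0.1), tolerance = 1e-14)
})

test_that("population is conserved for every variant on random states", {
  set.seed(7)
  for (rep in 1:5) {
    nao <- sample(3:6, 1)
    A <- matrix(rnorm(nao * nao), nao)
    S <- crossprod(A) + diag(nao)
    S <- S / sqrt(diag(S) %o% diag(S))
    P <- crossprod(matrix(rnorm(nao * nao), nao)) / nao
    nelec <- sum(P * S)
    ao_map <- sort(sample(1:2, nao, replace = TRUE))
    op <- structure(list(q = P * S, ao_to_atom = ao_map, n_electrons = nelec),
                    class = "overlap_populations")
    for (v in c("mulliken", "bickelhaupt")) {
      expect_equal(sum(condense_populations(op, v)$Q), nelec,
                   tolerance = 1e-12)
    }
  }
})

test_that("atomic charges conserve the molecular charge and match the oracle", {
  c_sym <- sqrt(1 / (2 * 1.5))
  sym <- make_polar_diatomic(0.5, c_sym)
  expect_charges_equal(mulliken_charges(sym$wfn), c(0, 0), tol = 1e-10)

  fx <- make_polar_diatomic(0.5, 0.8)
  expect_charges_equal(mulliken_charges(fx$wfn), fx$oracle_mulliken,
                       tol = 1e-12)

  ## 4-electron anion in 2 AOs: full occupation means P = 2 S^-1
  geom <- geometry(c("He", "H"), rbind(c(0, 0, 0), c(0, 0, 1.5)),
                   total_charge = -1L)
  S <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  w <- wavefunction(geom, gaussian_basis(c(1L, 2L)), 2 * solve(S), S,
                    n_electrons = 4)
  for (f in list(mulliken_charges, bickelhaupt_charges, lowdin_charges)) {
    expect_equal(sum(f(w)$charges), -1, tolerance = 1e-10)
  }
})

test_that("Loewdin charges match an explicit 2x2 matrix square root", {
  fx <- make_polar_diatomic(0.5, 0.8)
  s <- 0.5
  ## closed-form square root of [[1, s], [s, 1]]
  a <- (sqrt(1 + s) + sqrt(1 - s)) / 2
  b <- (sqrt(1 + s) - sqrt(1 - s)) / 2
  shalf <- matrix(c(a, b, b, a), 2, 2)
  L <- shalf %*% fx$wfn$P %*% shalf
  oracle <- c(1, 1) - diag(L)
  expect_charges_equal(lowdin_charges(fx$wfn), oracle, tol = 1e-12)

  ## S = identity: Loewdin coincides with Mulliken
  geom <- fx$wfn$geometry
  P <- matrix(c(1.3, 0.2, 0.2, 0.7), 2, 2)
  w_id <- wavefunction(geom, gaussian_basis(c(1L, 2L)), P, diag(2),
                       n_electrons = 2)
  expect_equal(lowdin_charges(w_id)$charges, mulliken_charges(w_id)$charges,
               tolerance = 1e-12)

  c_sym <- sqrt(1 / 3)
  sym <- make_polar_diatomic(0.5, c_sym)
  expect_charges_equal(lowdin_charges(sym$wfn), c(0, 0), tol = 1e-10)
})

test_that("minimal-basis projection is the identity when bases coincide", {
  fx <- make_polar_diatomic(0.5, 0.8)
  mb <- minimal_basis(fx$wfn$S, fx$wfn$S, c(1L, 2L))
  proj <- project_minimal_basis(fx$wfn, mb)
  expect_equal(proj$P, fx$wfn$P, tolerance = 1e-10)
  expect_equal(mbs_charges(fx$wfn, mb, "mulliken")$charges,
               mulliken_charges(fx$wfn)$charges, tolerance = 1e-10)
})

test_that("projection onto a smaller basis conserves electrons and yields finite charges", {
  px <- projection_fixture()
  proj <- project_minimal_basis(px$wfn, px$mb)
  expect_equal(sum(proj$P * proj$S), 2, tolerance = 1e-10)
  ## independent small-matrix oracle for the projected density
  c_m <- solve(px$mb$S_mm, px$mb$S_mf %*% px$c)
  nrm <- as.numeric(t(c_m) %*% px$mb$S_mm %*% c_m)
  P_oracle <- 2 * tcrossprod(c_m / sqrt(nrm))
  expect_equal(proj$P, P_oracle, tolerance = 1e-10)
  for (v in c("mulliken", "bickelhaupt")) {
    cv <- mbs_charges(px$wfn, px$mb, v)
    expect_true(all(is.finite(cv$charges)))
    expect_equal(sum(cv$charges), 0, tolerance = 1e-10)
  }
})

test_that("MBS charges ignore redundant working-basis functions", {
  px <- projection_fixture()
  base <- mbs_charges(px$wfn, px$mb, "bickelhaupt")$charges
  ## extend the working basis by an extra function the occupied orbital does
  ## not touch: same occupied space, so identical MBS charges
  V5 <- c(0.1, 0, 0.2, 0, 0.9, 0.3)
  V5 <- V5 / sqrt(sum(V5^2))
  Vx <- cbind(px$V, V5)
  S_ff <- crossprod(Vx)
  cvec <- c(px$c, 0)
  P <- 2 * tcrossprod(cvec)
  wfn_x <- wavefunction(px$wfn$geometry, gaussian_basis(c(1L, 1L, 2L, 2L, 2L)),
                        P, S_ff, n_electrons = 2)
  S_mf_x <- t(px$Tmat) %*% px$S_ff  # minimal functions still in the old span
  S_mf_x <- cbind(S_mf_x, t(px$Tmat) %*% crossprod(px$V, V5))
  mb_x <- minimal_basis(px$mb$S_mm, S_mf_x, c(1L, 2L))
  expect_equal(mbs_charges(wfn_x, mb_x, "bickelhaupt")$charges, base,
               tolerance = 1e-10)
})

test_that("charges are invariant under rigid rotation of an s-function state", {
  fx <- make_polar_diatomic(0.45, 0.7)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  geom_rot <- geometry(fx$wfn$geometry$symbols,
                       fx$wfn$geometry$coords %*% t(R))
  wfn_rot <- wavefunction(geom_rot, fx$wfn$basis, fx$wfn$P, fx$wfn$S,
                          n_electrons = 2)
  for (f in list(mulliken_charges, bickelhaupt_charges, lowdin_charges)) {
    expect_equal(f(wfn_rot)$charges, f(fx$wfn)$charges, tolerance = 1e-12)
  }
})

test_that("rank-deficient projections are rejected with a condition number", {
  px <- projection_fixture()
  mb_bad <- minimal_basis(px$mb$S_mm, matrix(0, 2, 4), c(1L, 2L))
  expect_error(project_minimal_basis(px$wfn, mb_bad), "linearly dependent")
})
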