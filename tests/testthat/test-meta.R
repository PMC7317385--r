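make_small_table <- function() {
  df <- expand.grid(molecule_id = c("m1", "m2"), atom_index = 1:3,
                    method = c("a", "b", "c"), stringsAsFactors = FALSE)
  df$element <- "C"
  set.seed(2)
  df$charge <- rnorm(nrow(df))
  charge_table(df[c("molecule_id", "atom_index", "element", "method",
                    "charge")])
}

test_that("observation assembly is strict complete-case", {
  tab <- make_small_table()
  obs <- assemble_observations(tab, c("a", "b", "c"))
  expect_equal(dim(obs$M), c(6L, 3L))
  expect_equal(obs$dropped, 0L)

  holed <- tab[!(tab$molecule_id == "m2" & tab$atom_index == 2 &
                   tab$method == "b"), ]
  obs2 <- assemble_observations(charge_table(holed), c("a", "b", "c"))
  expect_equal(nrow(obs2$M), 5L)
  expect_equal(obs2$dropped, 1L)

  only_a <- tab[tab$method == "a", ]
  only_a$charge[1] <- NA
  expect_error(assemble_observations(charge_table(only_a), c("a", "b")),
               "absent from table")
  two <- tab[tab$method %in% c("a", "b"), ]
  two$charge[two$method == "b"] <- NA
  expect_error(assemble_observations(charge_table(two), c("a", "b")),
               "fewer than 2 complete-case")
})

test_that("trivial charge distributions are filtered by symmetry fingerprints", {
  geoms <- list(
    he = geometry("He", matrix(0, 1, 3)),
    n2 = geometry(c("N", "N"), rbind(c(0, 0, 0), c(0, 0, 2.07))),
    water = water_geometry(),
    ## regular tetrahedron: all atoms equivalent
    p4 = geometry(rep("P", 4), 2.2 * rbind(c(1, 1, 1), c(1, -1, -1),
                                           c(-1, 1, -1), c(-1, -1, 1))),
    hf = geometry(c("H", "F"), rbind(c(0, 0, 0), c(0, 0, 1.73))))
  kept <- filter_trivial_geometries(geoms)
  expect_setequal(kept, c("water", "hf"))
})

test_that("duplicates are identified by stoichiometry and moments of inertia", {
  w <- water_geometry()
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  w_rot <- geometry(w$symbols, w$coords %*% t(R) + 2.5)
  ## a genuinely different conformer (stretched O-H)
  w_conf <- geometry(w$symbols, rbind(c(0, 0, 0), c(0, 1.43, 1.1),
                                      c(0, -1.9, 1.4)))
  kept <- deduplicate_geometries(list(a = w, b = w_rot, conf = w_conf))
  expect_setequal(kept, c("a", "conf"))

  ## enantiomers share all moments: collapsed (documented limitation)
  chir <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 2.0, 0), c(0, 0, 2.5))
  g1 <- geometry(c("C", "H", "F", "Cl"), chir)
  g2 <- geometry(c("C", "H", "F", "Cl"), chir %*% diag(c(1, 1, -1)))
  expect_equal(principal_moments(g1), principal_moments(g2),
               tolerance = 1e-12)
  expect_length(deduplicate_geometries(list(l = g1, r = g2)), 1L)
})

test_that("correlation matrices have unit diagonal and eigenvalues summing to dimension", {
  x <- cbind(a = 1:6, b = 2 * (1:6) + 3, c = rnorm(6))
  r <- charge_correlation(x)
  expect_equal(r["a", "b"], 1, tolerance = 1e-12)
  expect_equal(diag(r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(sum(eigen(r, only.values = TRUE)$values), 3, tolerance = 1e-10)
  expect_error(charge_correlation(cbind(a = rep(1, 5), b = rnorm(5))),
               "zero-variance")
})

test_that("PCA handles matrix and data input with the documented sign convention", {
  p_id <- pca_charges(diag(4), "correlation")
  expect_equal(p_id$values, rep(1, 4))

  v <- c(0.5, -0.3, 0.8)
  rank1 <- 2.5 * tcrossprod(v / sqrt(sum(v^2)))
  p1 <- pca_charges(rank1, "covariance")
  expect_equal(p1$values, c(2.5, 0, 0), tolerance = 1e-10)
  ## largest-magnitude loading entry is negative by convention
  expect_lt(p1$loadings[which.max(abs(p1$loadings[, 1])), 1], 0)

  expect_error(pca_charges(matrix(1:9, 3, 3)), "asymmetric")

  ft <- make_planted_factor_table(n_obs = 400, seed = 9)
  obs <- assemble_observations(ft$table, colnames(ft$data))
  p <- pca_charges(obs, "covariance")
  recon <- p$scores %*% t(p$loadings)
  expect_lt(max(abs(recon - scale(obs$M, TRUE, FALSE))), 1e-8)
  expect_true(all(abs(crossprod(p$loadings) - diag(ncol(obs$M))) < 1e-10))
})

test_that("planted two-factor structure is recovered by PCA", {
  ft <- make_planted_factor_table(n_obs = 5000, seed = 4)
  obs <- assemble_observations(ft$table, colnames(ft$data))
  p <- pca_charges(obs, "covariance")
  pop_eig <- eigen(ft$population_covariance, symmetric = TRUE)
  planted_frac <- sum(pop_eig$values[1:2]) / sum(pop_eig$values)
  got_frac <- sum(p$values[1:2]) / sum(p$values)
  expect_lt(abs(got_frac - planted_frac), 0.02)
  ang <- chargekit:::principal_angles(p$loadings[, 1:2],
                                      pop_eig$vectors[, 1:2])
  expect_lt(max(ang) * 180 / pi, 10)
})

test_that("backward elimination removes near-duplicate variables first", {
  set.seed(3)
  x <- matrix(rnorm(300), 100, 3)
  x <- cbind(x, x[, 3])  # exact duplicate pair
  colnames(x) <- c("p", "q", "r", "r_copy")
  be <- backward_eliminate(charge_correlation(x), 2)
  expect_true(be$eliminated[1] %in% c("r", "r_copy"))

  ## any remaining 2x2 block has (sum, difference)/sqrt(2) eigenvectors
  r2 <- charge_correlation(x[, c("p", "q")])
  ev <- eigen(r2, symmetric = TRUE)$vectors
  expect_equal(abs(ev), matrix(1 / sqrt(2), 2, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("GCD matches a brute-force projector computation", {
  set.seed(8)
  n <- 200
  X <- matrix(rnorm(n * 6), n, 6) %*%
    matrix(rnorm(36, sd = 0.6), 6, 6)
  colnames(X) <- letters[1:6]
  p <- pca_charges(X, "covariance")
  Xc <- scale(X, TRUE, FALSE)
  for (sub in combn(6, 2, simplify = FALSE)) {
    ## oracle: explicit projectors in observation space
    Ps <- Xc[, sub] %*% solve(crossprod(Xc[, sub]), t(Xc[, sub]))
    U <- qr.Q(qr(p$scores[, 1:2]))
    oracle <- sum(diag(Ps %*% tcrossprod(U))) / 2
    expect_equal(gcd_score(X, sub, 2), oracle, tolerance = 1e-8)
  }
  expect_equal(gcd_score(X, 1:6, 6), 1, tolerance = 1e-10)
  expect_error(gcd_score(cbind(X, dup = X[, 1]), c(1, 7), 2),
               "rank-deficient")
})

test_that("GCD is 1 for spanning subsets and 0 for orthogonal ones", {
  ## orthogonal design: variance concentrated on the first two coordinates
  S <- diag(c(5, 4, 0.1, 0.05))
  dimnames(S) <- list(letters[1:4], letters[1:4])
  expect_equal(gcd_score(S, c("a", "b"), 2), 1, tolerance = 1e-12)
  expect_equal(gcd_score(S, c("c", "d"), 2), 0, tolerance = 1e-12)
})

test_that("exhaustive subset selection finds planted representatives", {
  ## three tight groups of near-duplicates: the best 3-subset takes one
  ## member of each group
  set.seed(12)
  f <- matrix(rnorm(1500), 500, 3)
  X <- cbind(f[, 1] * 2.0, f[, 1] * 2.1 + rnorm(500, sd = 0.05),
             f[, 2] * 1.5, f[, 2] * 1.4 + rnorm(500, sd = 0.05),
             f[, 3] * 1.0, f[, 3] * 1.1 + rnorm(500, sd = 0.05))
  colnames(X) <- c("g1a", "g1b", "g2a", "g2b", "g3a", "g3b")
  res <- select_subset(X, 3, "exhaustive")
  groups <- substr(res$subset, 1, 2)
  expect_setequal(groups, c("g1", "g2", "g3"))
  expect_gt(res$criterion, 0.99)
  expect_error(select_subset(X, 6, "exhaustive"), "smaller than")
})

test_that("annealing matches the exhaustive optimum across seeds", {
  ft <- make_planted_factor_table(
    n_obs = 800,
    loadings = cbind(c(1, 1.1, 0.9, 0.5, 0.4, 1.2, 0.3, 0.8),
                     c(0.1, -0.8, 0.2, 0.9, -0.3, 0.1, 0.6, -0.2)),
    noise_sd = 0.1, seed = 21)
  S <- charge_covariance(assemble_observations(ft$table,
                                               rownames(ft$loadings)))
  ex <- select_subset(S, 3, "exhaustive")
  for (seed in c(1L, 7L, 13L)) {
    an <- select_subset(S, 3, "anneal", seed = seed)
    expect_setequal(an$subset, ex$subset)
    expect_equal(an$criterion, ex$criterion, tolerance = 1e-12)
  }
})

test_that("regression recovers exact linear combinations and rejects collinearity", {
  set.seed(6)
  X <- matrix(rnorm(900), 300, 3)
  y <- 2 + 0.5 * X[, 1] - 1.2 * X[, 2] + 0.3 * X[, 3]
  M <- cbind(X, y)
  colnames(M) <- c("u", "v", "w", "target")
  fit <- regress_charges(M, "target", c("u", "v", "w"))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients), c(0.5, -1.2, 0.3), tolerance = 1e-10)
  expect_equal(fit$intercept, 2, tolerance = 1e-10)

  noise <- cbind(M[, 1:3], target = rnorm(300))
  n1000 <- cbind(matrix(rnorm(3000), 1000, 3), rnorm(1000))
  colnames(n1000) <- colnames(M)
  expect_lt(regress_charges(n1000, "target", c("u", "v", "w"))$r_squared,
            0.05)

  Mc <- cbind(M, u2 = M[, "u"])
  expect_error(regress_charges(Mc, "target", c("u", "u2")), "collinear")
})

test_that("PC-fit R-squared is monotone and saturates for low-rank data", {
  set.seed(10)
  f <- rnorm(300)
  X <- outer(f, c(1, -0.5, 2, 0.3))
  colnames(X) <- letters[1:4]
  pf <- suppressWarnings(pc_fit_table(X + rnorm(1200, sd = 1e-8), 3))
  expect_true(all(pf[, 1] > 1 - 1e-6))

  ft <- make_planted_factor_table(n_obs = 600, seed = 14)
  pf2 <- pc_fit_table(assemble_observations(ft$table, rownames(ft$loadings)),
                      4)
  expect_true(all(apply(pf2, 1, function(r) all(diff(r) >= -1e-12))))
})

test_that("noise robustness is seed-deterministic and spares the leading components", {
  ft <- make_planted_factor_table(n_obs = 3000, seed = 17)
  obs <- assemble_observations(ft$table, rownames(ft$loadings))
  r1 <- noise_robustness(obs, 0.1, seed = 5, n_rep = 3)
  r2 <- noise_robustness(obs, 0.1, seed = 5, n_rep = 3)
  expect_identical(r1, r2)

  ## leading two PCs stable, higher PCs unstable for some replicate
  ang12 <- vapply(r1$replicates, function(r) r$subspace_angles_deg[["pc12"]],
                  numeric(1))
  ang123 <- vapply(r1$replicates, function(r) r$subspace_angles_deg[["pc123"]],
                   numeric(1))
  expect_lt(max(ang12), 10)
  expect_gt(max(ang123), 45)

  ## vanishing contamination leaves the spectrum essentially unchanged
  r0 <- noise_robustness(obs, 0.001, seed = 5, n_rep = 2)
  shift <- max(abs(r0$replicates[[1]]$eigenvalue_shift))
  expect_lt(shift / r0$original[1], 0.01)
})

test_that("covariance reconstruction from leading PCs matches the source spectrum", {
  set.seed(19)
  A <- matrix(rnorm(49), 7, 7)
  S_true <- crossprod(A) / 7
  e <- eigen(S_true, symmetric = TRUE)
  S_rec <- reconstruct_covariance(e$values[1:3], e$vectors[, 1:3],
                                  total_variance = sum(e$values))
  e_rec <- eigen(S_rec, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(e_rec[1:3], e$values[1:3], tolerance = 1e-10)
  expect_equal(sum(e_rec), sum(e$values), tolerance = 1e-10)
  expect_error(reconstruct_covariance(c(2, 1), e$vectors[, 1:2],
                                      total_variance = 1), "below the sum")
})
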