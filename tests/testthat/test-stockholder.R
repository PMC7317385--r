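## Shared grids/scenes for the stockholder family (built once per file).
hf_geom <- geometry(c("H", "F"), rbind(c(0, 0, 0), c(0, 0, 1.73)),
                    label = "hf_like")
hf_zetas <- c(2.0, 5.1)  # the bundled per-element exponents
hf_grid <- build_becke_grid(hf_geom, 60L, 14L)
hf_dists <- chargekit:::point_atom_distances(hf_geom, hf_grid$points)

test_that("Hirshfeld charges vanish on the promolecule and recover planted scenes", {
  db <- slater_proatom_db()
  rho_pro <- promolecule_density(hf_geom, db)(hf_grid$points)$total
  cv <- hirshfeld_charges(rho_pro, hf_geom, db, hf_grid)
  expect_lt(max(abs(cv$charges)), 1e-6)

  ## single ion: the whole density belongs to the one atom
  gi <- geometry("O", matrix(0, 1, 3), total_charge = 1L)
  grid1 <- build_becke_grid(gi, 60L, 14L)
  rho1 <- proatom_density(db, "O", 1L, sqrt(rowSums(grid1$points^2)))
  cv1 <- hirshfeld_charges(rho1, gi, db, grid1)
  expect_equal(cv1$charges, 1, tolerance = 1e-5, ignore_attr = TRUE)

  ## planted (0.5, 9.5) scene on a cube, against a brute-force Riemann
  ## oracle computed from the analytic formulas in test code
  sc <- make_slater_scene(c("H", "F"), hf_geom$coords, c(0.5, 9.5),
                          spacing = 0.2, margin = 6)
  pkg <- hirshfeld_charges(sc$field, db = sc$db)
  pts <- chargekit:::field_points(sc$field)
  vol <- voxel_volume(sc$field)
  rho <- as.vector(sc$field$values)
  pa <- rbind(ref_slater_density(hf_geom$coords[1, , drop = FALSE], 1,
                                 hf_zetas[1], pts),
              ref_slater_density(hf_geom$coords[2, , drop = FALSE], 9,
                                 hf_zetas[2], pts))
  wsum <- colSums(pa)
  oracle <- c(1, 9) - vapply(1:2, function(a) {
    sum(pa[a, ] / wsum * rho) * vol
  }, numeric(1))
  expect_equal(pkg$charges, oracle, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("Hirshfeld-I is a fixed point at planted fractional populations", {
  sc <- make_slater_scene(c("H", "F"), hf_geom$coords, c(0.7, 9.3),
                          spacing = 0.4, margin = 6)  # db only; density on Becke grid
  rho <- ref_slater_density(hf_geom$coords, c(0.7, 9.3), hf_zetas,
                            hf_grid$points)
  res <- hirshfeld_i_charges(rho, hf_geom, sc$db, hf_grid)
  expect_equal(res$charges$charges, c(0.3, -0.3), tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_lt(utils::tail(res$trace$max_delta, 1), 1e-6)

  ## iteration 0 equals plain Hirshfeld: tol = Inf stops after one evaluation
  h0 <- hirshfeld_i_charges(rho, hf_geom, sc$db, hf_grid, tol = Inf)
  h <- hirshfeld_charges(rho, hf_geom, sc$db, hf_grid)
  expect_equal(h0$charges$charges, h$charges, tolerance = 1e-14)
  expect_equal(nrow(h0$trace), 1L)
})

test_that("Hirshfeld-I keeps symmetric diatomics symmetric and respects the bracket", {
  g <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4)))
  grid <- build_becke_grid(g, 50L, 12L)
  rho <- ref_slater_density(g$coords, c(1, 1), c(2, 2), grid$points)
  db <- slater_proatom_db()
  res <- hirshfeld_i_charges(rho, g, db, grid)
  expect_lt(abs(res$charges$charges[1] - res$charges$charges[2]), 1e-7)

  ## a database without anion states cannot bracket growing populations
  db0 <- slater_proatom_db(charges = 0:1)
  rho_an <- ref_slater_density(g$coords, c(1.4, 0.6), c(2, 2), grid$points)
  expect_error(hirshfeld_i_charges(rho_an, g, db0, grid),
               "charge state -1, absent")
})

test_that("ISA recovers planted charges and spherical profiles", {
  ## single spherical atom: q = total charge, profile = spherical average
  gi <- geometry("H", matrix(0, 1, 3), total_charge = 0L)
  grid1 <- build_becke_grid(gi, 50L, 12L)
  r1 <- sqrt(rowSums(grid1$points^2))
  rho1 <- 1 / pi * exp(-2 * r1)  # H 1s density
  res1 <- isa_charges(rho1, gi, grid1)
  expect_equal(res1$charges$charges, 0, tolerance = 1e-4, ignore_attr = TRUE)
  mid <- res1$radii > 0.1 & res1$radii < 4
  expect_equal(res1$profiles[1, mid], 1 / pi * exp(-2 * res1$radii[mid]),
               tolerance = 0.02, ignore_attr = TRUE)

  ## planted two-Slater scene at 3 Bohr separation
  g2 <- geometry(c("H", "F"), rbind(c(0, 0, 0), c(0, 0, 3)))
  grid2 <- build_becke_grid(g2, 60L, 14L)
  rho2 <- ref_slater_density(g2$coords, c(0.5, 9.5), hf_zetas, grid2$points)
  res2 <- isa_charges(rho2, g2, grid2)
  expect_lt(max(abs(res2$charges$charges - c(0.5, -0.5))), 2e-3)

  ## symmetry
  g3 <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4)))
  grid3 <- build_becke_grid(g3, 50L, 12L)
  rho3 <- ref_slater_density(g3$coords, c(1, 1), c(2, 2), grid3$points)
  res3 <- isa_charges(rho3, g3, grid3)
  expect_equal(res3$charges$charges[1], res3$charges$charges[2],
               tolerance = 1e-8)
})

test_that("MBIS recovers in-family parameters and conserves charge", {
  ## single Slater atom: one-shell MBIS is exact in family
  gi <- geometry("H", matrix(0, 1, 3), total_charge = 0L)
  grid1 <- build_becke_grid(gi, 60L, 14L)
  r1 <- sqrt(rowSums(grid1$points^2))
  rho1 <- 1.0 / (8 * pi * 0.45^3) * exp(-r1 / 0.45)
  res1 <- mbis_charges(rho1, gi, grid1, tol = 1e-8)
  expect_equal(res1$proatoms[[1]]$N, 1.0, tolerance = 1e-4)
  expect_equal(res1$proatoms[[1]]$sigma, 0.45, tolerance = 1e-4)

  ## symmetric diatomic of identical Slater atoms: equal populations
  g2 <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4)))
  grid2 <- build_becke_grid(g2, 50L, 12L)
  rho2 <- ref_slater_density(g2$coords, c(1, 1), c(2, 2), grid2$points)
  res2 <- mbis_charges(rho2, g2, grid2, tol = 1e-7)
  expect_equal(res2$proatoms[[1]]$N, res2$proatoms[[2]]$N, tolerance = 1e-8)

  ## water-like 3-atom scene: total charge conserved at convergence
  g3 <- water_geometry()
  grid3 <- build_becke_grid(g3, 40L, 10L)
  rho3 <- ref_slater_density(g3$coords, c(8.6, 0.7, 0.7), c(4.4, 2, 2),
                             grid3$points)
  res3 <- mbis_charges(rho3, g3, grid3, tol = 1e-4, max_iter = 2000L)
  expect_lt(abs(sum(res3$charges$charges)), 1e-3)
})

test_that("stockholder weights partition unity and iterations are deterministic", {
  db <- slater_proatom_db()
  pro <- promolecule_density(hf_geom, db)(hf_grid$points)
  keep <- pro$total > 1e-12
  w <- sweep(pro$per_atom[, keep], 2, pro$total[keep], "/")
  expect_lt(max(abs(colSums(w) - 1)), 1e-12)

  rho <- ref_slater_density(hf_geom$coords, c(0.8, 9.2), hf_zetas,
                            hf_grid$points)
  sc_db <- make_slater_scene(c("H", "F"), hf_geom$coords, c(0.8, 9.2),
                             spacing = 0.5, margin = 6)$db
  r1 <- hirshfeld_i_charges(rho, hf_geom, sc_db, hf_grid)
  r2 <- hirshfeld_i_charges(rho, hf_geom, sc_db, hf_grid)
  expect_identical(r1$charges$charges, r2$charges$charges)
  expect_identical(r1$trace, r2$trace)
})

test_that("charge-sum defects stay within the grid normalization defect", {
  sc <- make_slater_scene(c("H", "F"), hf_geom$coords, c(0.5, 9.5),
                          spacing = 0.25, margin = 6)
  grid <- cube_to_grid(sc$field)
  rho <- as.vector(sc$field$values)
  nelec <- 10
  grid_defect <- abs(integrate_grid(rho, grid) - nelec)
  for (res in list(hirshfeld_charges(sc$field, db = sc$db),
                   hirshfeld_i_charges(sc$field, db = sc$db)$charges)) {
    expect_lte(abs(sum(res$charges) - sc$geometry$total_charge),
               1.5 * grid_defect + 1e-8)
  }
})
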