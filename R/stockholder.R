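## Class IIb1 fuzzy-domain charges: Hirshfeld, iterative Hirshfeld, ISA, MBIS.

## Grid points where the promolecule density falls below this value get zero
## stockholder weight for every atom and are excluded from integrals (avoids
## 0/0 in essentially empty space; affects charges far below grid accuracy).
PROMOL_UNDERFLOW <- 1e-12

## Accept either a volumetric_field (cube) or raw values + grid.
resolve_density <- function(density, grid = NULL) {
  if (inherits(density, "volumetric_field")) {
    if (is.null(grid)) grid <- cube_to_grid(density)
    values <- as.vector(density$values)
  } else {
    if (is.null(grid)) stop("a quadrature grid is required with raw values")
    values <- as.numeric(density)
  }
  if (length(values) != nrow(grid$points)) {
    stop("density values do not match the grid")
  }
  list(values = values, grid = grid)
}

## Charge-sum tolerance from the grid normalization defect.
grid_sum_tol <- function(rho, grid, geom) {
  nelec <- sum(geom$z) - geom$total_charge
  1.5 * abs(integrate_grid(rho, grid) - nelec) + 1e-8
}

#' Hirshfeld stockholder charges
#'
#' Each grid point is shared between atoms in proportion to neutral proatom
#' densities: `w_A = rho_A^0 / sum_B rho_B^0`, and
#' `q_A = Z_A - int w_A(r) rho(r) dr`. When the molecular density equals the
#' promolecule the deformation density vanishes and all charges are zero.
#'
#' @param density a [volumetric_field()] (cube) or numeric density values
#'   aligned with `grid`.
#' @param geom the [geometry()]; defaults to the cube's geometry.
#' @param db a [proatom_db()] with neutral entries for every element present.
#' @param grid a [quadrature_grid()]; defaults to the cube lattice.
#' @return a [charge_vector()] with the grid-normalization defect recorded in
#'   its diagnostics.
#' @export
hirshfeld_charges <- function(density, geom = NULL, db = slater_proatom_db(),
                              grid = NULL) {
  d <- resolve_density(density, grid)
  if (is.null(geom)) geom <- density$geometry
  pro <- promolecule_density(geom, db)(d$grid$points)
  keep <- pro$total > PROMOL_UNDERFLOW
  pops <- vapply(seq_len(n_atoms(geom)), function(a) {
    w <- numeric(length(d$values))
    w[keep] <- pro$per_atom[a, keep] / pro$total[keep]
    integrate_grid(w * d$values, d$grid)
  }, numeric(1))
  tol <- grid_sum_tol(d$values, d$grid, geom)
  charge_vector(geom$z - pops, geom, "hirshfeld",
                diagnostics = list(grid_points = length(d$values)),
                sum_tol = tol)
}

## One stockholder population evaluation at given proatom populations.
stockholder_populations <- function(values, grid, geom, db, populations) {
  pro <- promolecule_density(geom, db, populations)(grid$points)
  keep <- pro$total > PROMOL_UNDERFLOW
  vapply(seq_len(n_atoms(geom)), function(a) {
    w <- numeric(length(values))
    w[keep] <- pro$per_atom[a, keep] / pro$total[keep]
    integrate_grid(w * values, grid)
  }, numeric(1))
}

#' Iterative Hirshfeld (Hirshfeld-I) charges
#'
#' Fixed-point iteration on the proatom populations: starting from neutral
#' proatoms (so iteration 0 is plain Hirshfeld), each cycle re-partitions the
#' density with proatoms interpolated between the integer charge states that
#' bracket the current fractional populations, until
#' `max |Delta N_A| < tol`. The database must contain the bracketing charge
#' states; populations leaving the available bracket are an error (rather
#' than an extrapolation, which would use unphysical proatoms).
#'
#' @inheritParams hirshfeld_charges
#' @param tol population convergence tolerance (e; default 1e-6). `tol = Inf`
#'   returns the plain Hirshfeld populations after one evaluation.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   trace.
#' @return list with `charges` (a [charge_vector()], method
#'   `"hirshfeld-i"`) and `trace` (data.frame of per-iteration max
#'   population change).
#' @export
hirshfeld_i_charges <- function(density, geom = NULL,
                                db = slater_proatom_db(), grid = NULL,
                                tol = 1e-6, max_iter = 500L) {
  d <- resolve_density(density, grid)
  if (is.null(geom)) geom <- density$geometry
  n <- n_atoms(geom)
  pops <- as.numeric(geom$z)
  deltas <- numeric(0)
  for (it in seq_len(max_iter)) {
    ## check the interpolation bracket exists before evaluating
    for (a in seq_len(n)) {
      lo <- floor(pops[a] + 1e-12)
      qs <- geom$z[a] - c(lo, if (pops[a] - lo > 1e-12) lo + 1L)
      for (q in qs) {
        if (!has_proatom(db, geom$symbols[a], as.integer(q))) {
          stop(sprintf(
            "atom %d (%s): population %.4f needs proatom charge state %+d, absent from the database",
            a, geom$symbols[a], pops[a], q))
        }
      }
    }
    new_pops <- stockholder_populations(d$values, d$grid, geom, db, pops)
    delta <- max(abs(new_pops - pops))
    deltas <- c(deltas, delta)
    pops <- new_pops
    if (delta < tol) break
    if (it == max_iter) {
      stop("Hirshfeld-I did not converge in ", max_iter,
           " iterations (last max |dN| = ", format(delta, digits = 4), ")")
    }
  }
  trace <- data.frame(iteration = seq_along(deltas), max_delta = deltas)
  cv <- charge_vector(geom$z - pops, geom, "hirshfeld-i",
                      diagnostics = list(iterations = nrow(trace), tol = tol),
                      sum_tol = grid_sum_tol(d$values, d$grid, geom))
  list(charges = cv, trace = trace)
}

## Piecewise-linear interpolation of log-density profiles on radial nodes,
## constant below the first node and exponentially extrapolated beyond the
## last (continuing the outermost segment's slope).
interp_radial_log <- function(r_nodes, log_rho, r) {
  nr <- length(r_nodes)
  out <- numeric(length(r))
  out[r <= r_nodes[1]] <- log_rho[1]
  mid <- r > r_nodes[1] & r <= r_nodes[nr]
  if (any(mid)) out[mid] <- stats::approx(r_nodes, log_rho, xout = r[mid])$y
  hi <- r > r_nodes[nr]
  if (any(hi)) {
    slope <- (log_rho[nr] - log_rho[nr - 1]) / (r_nodes[nr] - r_nodes[nr - 1])
    out[hi] <- log_rho[nr] + slope * (r[hi] - r_nodes[nr])
  }
  exp(out)
}

## Triangular (hat) bin weights of distances onto radial nodes, in log space.
radial_hat_matrix <- function(r_nodes, d) {
  nr <- length(r_nodes)
  lx <- log(pmax(d, r_nodes[1] * 1e-3))
  ln <- log(r_nodes)
  idx <- findInterval(lx, ln)
  H <- matrix(0, nr, length(d))
  inb <- idx >= 1L & idx < nr
  if (any(inb)) {
    i <- idx[inb]
    t <- (lx[inb] - ln[i]) / (ln[i + 1] - ln[i])
    cols <- which(inb)
    H[cbind(i, cols)] <- 1 - t
    H[cbind(i + 1L, cols)] <- t
  }
  H[cbind(rep(1L, sum(idx < 1L)), which(idx < 1L))] <- 1
  H
}

#' Iterative Stockholder Approach (ISA) charges
#'
#' Proatom-free stockholder partitioning: the reference radial profile of each
#' atom is obtained self-consistently as the spherical average of its own
#' share of the molecular density. Each cycle (i) builds stockholder weights
#' from the current radial profiles, (ii) replaces each profile with the
#' spherical average of `w_A * rho` around atom A on a log-spaced radial shell
#' grid, until the largest relative profile change drops below `tol`. Initial
#' profiles are `exp(-r)`.
#'
#' @inheritParams hirshfeld_charges
#' @param n_shells number of log-spaced radial shells (default 64 between
#'   0.02 and 20 Bohr).
#' @param r_range inner and outer shell radii (Bohr).
#' @param tol convergence threshold on the max relative profile change.
#' @param max_iter iteration cap.
#' @return list with `charges` (method `"isa"`), `profiles`
#'   (n_atoms x n_shells matrix), `radii` and `trace`.
#' @export
isa_charges <- function(density, geom = NULL, grid = NULL, n_shells = 64L,
                        r_range = c(0.02, 20), tol = 1e-5, max_iter = 500L) {
  d <- resolve_density(density, grid)
  if (is.null(geom)) geom <- density$geometry
  n <- n_atoms(geom)
  r_nodes <- exp(seq(log(r_range[1]), log(r_range[2]), length.out = n_shells))
  dists <- point_atom_distances(geom, d$grid$points)
  hats <- lapply(seq_len(n), function(a) radial_hat_matrix(r_nodes, dists[a, ]))
  hat_norm <- lapply(hats, function(H) {
    s <- as.vector(H %*% d$grid$weights)
    s[s <= 0] <- Inf  # empty shells yield zero averages
    s
  })
  log_prof <- matrix(rep(-r_nodes, each = n), n, n_shells)  # exp(-r) start
  rels <- numeric(0)
  for (it in seq_len(max_iter)) {
    pro <- matrix(0, n, length(d$values))
    for (a in seq_len(n)) {
      pro[a, ] <- interp_radial_log(r_nodes, log_prof[a, ], dists[a, ])
    }
    tot <- colSums(pro)
    keep <- tot > PROMOL_UNDERFLOW
    new_log <- log_prof
    for (a in seq_len(n)) {
      f <- numeric(length(d$values))
      f[keep] <- pro[a, keep] / tot[keep] * d$values[keep]
      if (sum(f * d$grid$weights) < 1e-8) {
        stop("ISA profile collapse: atom ", a, " (", geom$symbols[a],
             ") is starved of density")
      }
      avg <- as.vector(hats[[a]] %*% (f * d$grid$weights)) / hat_norm[[a]]
      new_log[a, ] <- log(pmax(avg, 1e-280))
    }
    rel <- max(abs(exp(new_log) - exp(log_prof)) /
                 pmax(exp(log_prof), 1e-12))
    rels <- c(rels, rel)
    log_prof <- new_log
    if (rel < tol) break
    if (it == max_iter) {
      stop("ISA did not converge in ", max_iter, " iterations (last change ",
           format(rel, digits = 4), ")")
    }
  }
  pro <- matrix(0, n, length(d$values))
  for (a in seq_len(n)) {
    pro[a, ] <- interp_radial_log(r_nodes, log_prof[a, ], dists[a, ])
  }
  tot <- colSums(pro)
  keep <- tot > PROMOL_UNDERFLOW
  pops <- vapply(seq_len(n), function(a) {
    w <- numeric(length(d$values))
    w[keep] <- pro[a, keep] / tot[keep]
    integrate_grid(w * d$values, d$grid)
  }, numeric(1))
  trace <- data.frame(iteration = seq_along(rels), max_rel_change = rels)
  cv <- charge_vector(geom$z - pops, geom, "isa",
                      diagnostics = list(iterations = nrow(trace)),
                      sum_tol = grid_sum_tol(d$values, d$grid, geom))
  list(charges = cv, profiles = exp(log_prof), radii = r_nodes, trace = trace)
}

## Period row of an element = its MBIS shell count (H,He: 1; Li-Ne: 2;
## Na-Ar: 3).
mbis_shell_count <- function(z) {
  if (z <= 2) 1L else if (z <= 10) 2L else if (z <= 18) 3L
  else stop("MBIS parameterized for H-Ar only")
}

mbis_proatom_values <- function(Nk, sk, r) {
  out <- numeric(length(r))
  for (k in seq_along(Nk)) {
    out <- out + Nk[k] / (8 * pi * sk[k]^3) * exp(-r / sk[k])
  }
  out
}

#' Minimal Basis Iterative Stockholder (MBIS) charges
#'
#' Stockholder partitioning with parametric proatoms: each atom carries one
#' Slater shell per period row
#' (`rho_A(r) = sum_k N_k / (8 pi sigma_k^3) exp(-|r - R_A| / sigma_k)`),
#' and the shell populations and widths are updated self-consistently from
#' the atom's share of the density:
#' `N_k <- int rho w_A (shell_k / rho_A)` and
#' `sigma_k <- 1/(3 N_k) int rho w_A (shell_k / rho_A) |r - R_A|`.
#' Because proatoms are always members of the Slater family, nothing in the
#' scheme depends on isolated-atom reference densities (which for anions can
#' be unbound in vacuo). Shells whose population or width collapses are
#' pruned with a warning recorded in the diagnostics.
#'
#' @inheritParams hirshfeld_charges
#' @param tol convergence threshold on the largest parameter change.
#' @param max_iter iteration cap.
#' @return list with `charges` (method `"mbis"`), `proatoms` (per atom, a
#'   list with vectors `N` and `sigma`) and `trace`.
#' @export
mbis_charges <- function(density, geom = NULL, grid = NULL, tol = 1e-6,
                         max_iter = 500L) {
  d <- resolve_density(density, grid)
  if (is.null(geom)) geom <- density$geometry
  n <- n_atoms(geom)
  dists <- point_atom_distances(geom, d$grid$points)
  params <- lapply(seq_len(n), function(a) {
    z <- geom$z[a]
    K <- mbis_shell_count(z)
    Nk <- switch(K, z, c(2, z - 2), c(2, 8, z - 10))
    zeta <- 2 * z^((K - seq_len(K) + 1) / K)  # core steepest, valence softest
    list(N = as.numeric(Nk), sigma = 1 / zeta)
  })
  pruned <- 0L
  deltas <- numeric(0)
  for (it in seq_len(max_iter)) {
    pro <- matrix(0, n, length(d$values))
    for (a in seq_len(n)) {
      pro[a, ] <- mbis_proatom_values(params[[a]]$N, params[[a]]$sigma,
                                      dists[a, ])
    }
    tot <- colSums(pro)
    keep <- tot > PROMOL_UNDERFLOW
    delta <- 0
    for (a in seq_len(n)) {
      p <- params[[a]]
      newN <- p$N; news <- p$sigma
      for (k in seq_along(p$N)) {
        shell <- p$N[k] / (8 * pi * p$sigma[k]^3) * exp(-dists[a, ] / p$sigma[k])
        f <- numeric(length(d$values))
        ## w_A * shell_k / proatom_A = shell_k / promolecule
        f[keep] <- d$values[keep] * shell[keep] / tot[keep]
        newN[k] <- integrate_grid(f, d$grid)
        if (newN[k] > 1e-12) {
          news[k] <- integrate_grid(f * dists[a, ], d$grid) / (3 * newN[k])
        }
      }
      dead <- newN < 1e-6 | news < 1e-4
      if (any(dead) && length(newN) > 1L) {
        pruned <- pruned + sum(dead)
        warning("MBIS pruned ", sum(dead), " collapsed shell(s) on atom ", a)
        newN <- newN[!dead]; news <- news[!dead]
      }
      if (length(newN) == length(p$N)) {
        delta <- max(delta, max(abs(newN - p$N)), max(abs(news - p$sigma)))
      } else {
        delta <- max(delta, 1)  # shell structure changed; keep iterating
      }
      params[[a]] <- list(N = newN, sigma = news)
    }
    deltas <- c(deltas, delta)
    if (delta < tol) break
    if (it == max_iter) {
      stop("MBIS did not converge in ", max_iter, " iterations (last change ",
           format(delta, digits = 4), ")")
    }
  }
  trace <- data.frame(iteration = seq_along(deltas), max_delta = deltas)
  pops <- vapply(params, function(p) sum(p$N), numeric(1))
  cv <- charge_vector(geom$z - pops, geom, "mbis",
                      diagnostics = list(iterations = nrow(trace),
                                         pruned_shells = pruned),
                      sum_tol = grid_sum_tol(d$values, d$grid, geom))
  list(charges = cv, proatoms = params, trace = trace)
}
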