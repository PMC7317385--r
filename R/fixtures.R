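## Deterministic synthetic generators with closed-form oracles. Every charge
## scheme and meta-analysis stage can be tested against these with no
## external data.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Two-orbital polar diatomic fixture
#'
#' A closed-shell two-electron diatomic in a basis of one s function per
#' atom with overlap `S = [[1, s], [s, 1]]` and a doubly occupied orbital
#' `phi = c_A chi_A + c_B chi_B`; `c_B` is the positive root of the
#' normalization `c_A^2 + c_B^2 + 2 c_A c_B s = 1`, so `P = 2 c c'` is
#' idempotent with respect to S by construction. The closed-form Mulliken
#' charge `q_A = Z_A - 2 (c_A^2 + c_A c_B s)` ships as the oracle.
#'
#' @param s AO overlap in (0, 1).
#' @param c_a coefficient of the first atom's function.
#' @param separation internuclear distance (Bohr).
#' @param z atomic numbers of the two atoms (default H2).
#' @return list with `wfn` (a [wavefunction()]), `oracle_mulliken` (the
#'   closed-form charges) and `coefficients` `(c_a, c_b)`.
#' @export
make_polar_diatomic <- function(s = 0.5, c_a = 0.8, separation = 1.4,
                                z = c(1L, 1L)) {
  if (s <= 0 || s >= 1) stop("overlap s must be in (0, 1)")
  disc <- c_a^2 * s^2 + 1 - c_a^2
  if (disc < 0) stop("no positive root for c_B: |c_A| too large at this overlap")
  c_b <- -c_a * s + sqrt(disc)
  if (c_b <= 0) stop("no positive root for c_B")
  cvec <- c(c_a, c_b)
  S <- matrix(c(1, s, s, 1), 2, 2)
  P <- 2 * tcrossprod(cvec)
  symbols <- element_symbol(z)
  geom <- geometry(symbols,
                   rbind(c(0, 0, 0), c(0, 0, separation)),
                   total_charge = sum(z) - 2L,
                   label = sprintf("diatomic_s%g_cA%g", s, c_a))
  wfn <- wavefunction(geom, gaussian_basis(c(1L, 2L)), P, S, n_electrons = 2)
  pops <- 2 * (cvec^2 + c_a * c_b * s)
  list(wfn = wfn, oracle_mulliken = z - pops, coefficients = cvec)
}

## Analytic density of a Slater scene at arbitrary points.
slater_scene_density <- function(positions, populations, zetas, points) {
  rho <- numeric(nrow(points))
  for (a in seq_len(nrow(positions))) {
    r <- sqrt((points[, 1] - positions[a, 1])^2 +
                (points[, 2] - positions[a, 2])^2 +
                (points[, 3] - positions[a, 3])^2)
    rho <- rho + populations[a] * zetas[a]^3 / (8 * pi) * exp(-zetas[a] * r)
  }
  rho
}

#' Planted Slater scene fixture
#'
#' A molecular density built as a superposition of single-exponential Slater
#' atoms `N_A zeta_A^3/(8 pi) exp(-zeta_A |r - R_A|)` with planted per-atom
#' populations, sampled on a cube, together with a matching proatom database
#' (same exponents, charge states -1..+2) and the planted charges
#' `q_A = Z_A - N_A`. Because the scene density is exactly a promolecule of
#' the database, stockholder partitioners should recover the planted values;
#' the normalization `4 pi int rho r^2 dr = N` is analytic. The same exponent
#' must be used for all atoms of one element.
#'
#' @param symbols element symbols.
#' @param positions n x 3 nuclear positions (Bohr).
#' @param populations planted electron populations (sum must differ from the
#'   nuclear-charge sum by an integer).
#' @param zetas Slater exponents per atom (1/Bohr); default the bundled
#'   per-element exponents.
#' @param spacing cube spacing (Bohr, default 0.2; <= 0.25 recommended).
#' @param margin cube margin beyond the atoms (Bohr).
#' @return list with `field` (a [volumetric_field()]), `db` (a
#'   [proatom_db()]), `geometry`, `planted_charges`, and `tail_loss` (the
#'   largest fraction of any atom's density outside the cube margin; a value
#'   above 1e-3 triggers a warning).
#' @export
make_slater_scene <- function(symbols, positions, populations, zetas = NULL,
                              spacing = 0.2, margin = 6) {
  positions <- as.matrix(positions)
  z <- element_number(symbols)
  if (is.null(zetas)) zetas <- unname(SLATER_ZETA0[symbols])
  if (length(populations) != length(symbols) ||
      length(zetas) != length(symbols)) {
    stop("one population and one exponent per atom required")
  }
  for (el in unique(symbols)) {
    if (length(unique(zetas[symbols == el])) > 1L) {
      stop("element ", el, " appears with different exponents")
    }
  }
  total_charge <- sum(z) - sum(populations)
  if (abs(total_charge - round(total_charge)) > 1e-9) {
    stop("planted populations must give an integer total charge")
  }
  geom <- geometry(symbols, positions,
                   total_charge = as.integer(round(total_charge)),
                   label = "slater_scene")
  lo <- apply(positions, 2, min) - margin
  hi <- apply(positions, 2, max) + margin
  shape <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  axes <- diag(spacing, 3)
  ax <- lapply(1:3, function(d) lo[d] + (seq_len(shape[d]) - 1) * spacing)
  pts <- cbind(rep(ax[[1]], times = shape[2] * shape[3]),
               rep(rep(ax[[2]], each = shape[1]), times = shape[3]),
               rep(ax[[3]], each = shape[1] * shape[2]))
  rho <- slater_scene_density(positions, populations, zetas, pts)
  field <- volumetric_field(lo, axes, array(rho, dim = shape), geom)
  ## fraction of a Slater profile beyond radius R: (1 + x + x^2/2) e^(-x)
  x <- zetas * margin
  tail_loss <- max((1 + x + x^2 / 2) * exp(-x))
  if (tail_loss > 1e-3) {
    warning(sprintf("cube margin keeps only %.4f%% of the worst atom's density",
                    100 * (1 - tail_loss)))
  }
  entries <- list()
  for (el in unique(symbols)) {
    zel <- z[match(el, symbols)]
    zeta <- zetas[match(el, symbols)]
    for (q in -1:2) {
      if (zel - q < 0) next
      entries[[proatom_key(el, q)]] <- list(type = "slater", zeta = zeta,
                                            N = zel - q)
    }
  }
  list(field = field, db = proatom_db(entries, "slater scene fixture"),
       geometry = geom, planted_charges = z - populations,
       tail_loss = tail_loss)
}

#' Synthetic ESP fitting case
#'
#' CHELPG-style points around a geometry with the exact electrostatic
#' potential of planted nuclear-centred point charges; a correct constrained
#' least-squares fitter must recover the planted charges to machine
#' precision (the model is exactly realizable).
#'
#' @param geom a [geometry()].
#' @param charges planted per-atom charges (must sum to the geometry's total
#'   charge for the constrained fit to be consistent).
#' @param spacing,vdw_scale,outer_margin see [build_chelpg_points()].
#' @param noise_sd optional Gaussian noise added to the ESP values.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return an [esp_points()] set with the planted charges in its metadata.
#' @export
make_esp_case <- function(geom, charges, spacing = 0.5, vdw_scale = 1.0,
                          outer_margin = 2.8, noise_sd = 0, seed = 1L) {
  pts <- build_chelpg_points(geom, spacing, vdw_scale, outer_margin)
  v <- point_charge_esp(geom, charges, pts)
  if (noise_sd > 0) {
    v <- v + with_seed(seed, stats::rnorm(length(v), sd = noise_sd))
  }
  esp_points(pts, v, meta = list(planted = charges, noise_sd = noise_sd,
                                 spacing = spacing))
}

#' Planted low-rank factor-model charge table
#'
#' Statistical twin of a pooled charge survey: per-atom observations
#' `q = Lambda f + eps` with standard-normal factors and homoscedastic (or
#' per-method) Gaussian noise, so the population covariance is exactly
#' `Lambda Lambda' + diag(sd^2)`. The default loadings mirror the structure
#' such surveys find: a dominant all-positive "ionicity" factor plus a weaker
#' factor opposing one density-partitioning method against the rest.
#'
#' @param n_obs number of synthetic atoms.
#' @param loadings methods x factors matrix with method rownames.
#' @param noise_sd scalar or per-method noise standard deviation.
#' @param seed RNG seed (generation is deterministic given the seed).
#' @return list with `table` (a [charge_table()]), `data` (the n_obs x
#'   methods matrix), `loadings` and `population_covariance`.
#' @export
make_planted_factor_table <- function(n_obs = 2000L,
                                      loadings = default_factor_loadings(),
                                      noise_sd = 0.05, seed = 1L) {
  Lambda <- as.matrix(loadings)
  if (is.null(rownames(Lambda))) {
    rownames(Lambda) <- paste0("method", seq_len(nrow(Lambda)))
  }
  nf <- ncol(Lambda)
  if (nf > nrow(Lambda)) stop("more factors than methods")
  sd_vec <- rep(noise_sd, length.out = nrow(Lambda))
  X <- with_seed(seed, {
    f <- matrix(stats::rnorm(n_obs * nf), n_obs, nf)
    eps <- matrix(stats::rnorm(n_obs * nrow(Lambda)), n_obs, nrow(Lambda))
    f %*% t(Lambda) + sweep(eps, 2, sd_vec, "*")
  })
  colnames(X) <- rownames(Lambda)
  long <- do.call(rbind, lapply(seq_len(ncol(X)), function(m) {
    data.frame(molecule_id = sprintf("synth%06d", seq_len(n_obs)),
               atom_index = 1L, element = "C",
               method = colnames(X)[m], charge = X[, m],
               stringsAsFactors = FALSE)
  }))
  list(table = charge_table(long), data = X, loadings = Lambda,
       population_covariance = tcrossprod(Lambda) + diag(sd_vec^2))
}

#' Default loadings for the planted factor model
#'
#' Six methods, two factors: all methods load positively on factor 1 with
#' different amplitudes (the shared ionicity scale), and one
#' density-partitioning method opposes the others on factor 2.
#'
#' @return 6 x 2 loading matrix.
#' @export
default_factor_loadings <- function() {
  m <- cbind(c(0.30, 0.9, 1.0, 1.1, 0.8, 1.2),
             c(0.05, 0.1, 0.12, 0.1, -0.9, 0.15))
  rownames(m) <- c("hirshfeld", "mbis", "hirshfeld_i", "mbs_mulliken",
                   "qtaim_like", "esp_like")
  colnames(m) <- c("f1", "f2")
  m
}
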