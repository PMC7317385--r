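## Meta-analysis of per-atom charge tables: the statistical machinery that
## extracts "principal components of ionicity" from many charge schemes.

#' Assemble an observation matrix from a charge table
#'
#' One observation per atom, pooled over molecules; one column per requested
#' method. Atoms missing any requested method (holes) are dropped -
#' complete-case filtering, never imputation - and the dropped count is
#' recorded.
#'
#' @param table a [charge_table()].
#' @param methods character vector (>= 2) of method names to keep.
#' @return object of class `"observation_matrix"`: list with `M` (numeric
#'   matrix, atoms x methods), `meta` (molecule/atom/element per row) and
#'   `dropped` (number of incomplete atoms removed).
#' @export
assemble_observations <- function(table, methods) {
  if (length(methods) < 2L) stop("at least 2 methods required")
  missing_methods <- setdiff(methods, unique(table$method))
  if (length(missing_methods) > 0L) {
    stop("method(s) absent from table: ",
         paste(missing_methods, collapse = ", "))
  }
  sub <- table[table$method %in% methods, , drop = FALSE]
  key <- paste(sub$molecule_id, sub$atom_index, sep = "\r")
  ukey <- unique(key)
  M <- matrix(NA_real_, length(ukey), length(methods),
              dimnames = list(NULL, methods))
  M[cbind(match(key, ukey), match(sub$method, methods))] <- sub$charge
  complete <- stats::complete.cases(M)
  dropped <- sum(!complete)
  M <- M[complete, , drop = FALSE]
  if (nrow(M) < 2L) stop("fewer than 2 complete-case atoms")
  first <- match(ukey[complete], key)
  meta <- data.frame(molecule_id = sub$molecule_id[first],
                     atom_index = sub$atom_index[first],
                     element = sub$element[first],
                     stringsAsFactors = FALSE)
  structure(list(M = M, meta = meta, dropped = dropped),
            class = "observation_matrix")
}

obs_matrix <- function(x) {
  if (inherits(x, "observation_matrix")) x$M else as.matrix(x)
}

#' Remove molecules with trivial charge distributions
#'
#' Isolated atoms, homonuclear diatomics and clusters in which every atom is
#' symmetry-equivalent (e.g. tetrahedral P4) carry no information about how
#' charge schemes differ, since all their charges are fixed by symmetry and
#' charge conservation. A molecule is dropped when all its atoms share the
#' same fingerprint: the element plus the sorted list of (element, distance)
#' pairs to all other atoms.
#'
#' @param geometries named list of [geometry()] objects.
#' @param dist_tol distance rounding (Bohr) used in the fingerprint.
#' @return character vector of kept molecule names.
#' @export
filter_trivial_geometries <- function(geometries, dist_tol = 1e-4) {
  keep <- vapply(geometries, function(g) {
    n <- n_atoms(g)
    if (n == 1L) return(FALSE)
    d <- atom_distances(g)
    fp <- vapply(seq_len(n), function(a) {
      o <- setdiff(seq_len(n), a)
      ord <- order(g$symbols[o], round(d[a, o] / dist_tol))
      paste(g$symbols[a], paste(g$symbols[o][ord],
                                round(d[a, o][ord] / dist_tol),
                                collapse = ";"), sep = "|")
    }, character(1))
    length(unique(fp)) > 1L
  }, logical(1))
  names(geometries)[keep]
}

#' Remove duplicate species by rotational constants
#'
#' Two molecules are duplicates when they share the same stoichiometry and
#' all three principal moments of inertia agree within `rel_tol` (rotational
#' constants are inversely proportional to the moments). The first occurrence
#' is kept. Enantiomer pairs have identical moments and are collapsed - a
#' documented limitation of the criterion.
#'
#' @param geometries named list of [geometry()] objects.
#' @param rel_tol relative tolerance on each moment (default 1e-4).
#' @return character vector of kept molecule names.
#' @export
deduplicate_geometries <- function(geometries, rel_tol = 1e-4) {
  if (rel_tol <= 0) stop("rel_tol must be positive")
  stoich <- vapply(geometries, function(g) {
    tb <- table(g$symbols)
    paste(names(tb), tb, collapse = " ")
  }, character(1))
  moments <- lapply(geometries, principal_moments)
  n <- length(geometries)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (!keep[j] || stoich[i] != stoich[j]) next
      mi <- moments[[i]]; mj <- moments[[j]]
      if (all(abs(mi - mj) <= rel_tol * pmax(abs(mj), 1e-10))) {
        keep[i] <- FALSE
        break
      }
    }
  }
  names(geometries)[keep]
}

check_variance <- function(M) {
  v <- apply(M, 2, stats::var)
  if (any(v <= 0)) {
    stop("zero-variance method column(s): ",
         paste(colnames(M)[v <= 0], collapse = ", "))
  }
}

#' Correlation and covariance of an observation matrix
#'
#' Pearson correlation / covariance across methods, `n - 1` denominator.
#'
#' @param x an [assemble_observations()] result or a numeric matrix
#'   (atoms x methods).
#' @return symmetric matrix with method names.
#' @export
charge_correlation <- function(x) {
  M <- obs_matrix(x)
  if (nrow(M) < 2L) stop("need at least 2 observations")
  check_variance(M)
  stats::cor(M)
}

#' @rdname charge_correlation
#' @export
charge_covariance <- function(x) {
  M <- obs_matrix(x)
  if (nrow(M) < 2L) stop("need at least 2 observations")
  stats::cov(M)
}

#' Correlation matrix from a squared-correlation table
#'
#' Published charge-survey tables often print squared correlations R^2; for
#' eigen-analysis they are rebuilt into a correlation matrix by taking
#' positive square roots and forcing a unit diagonal (all correlations
#' between charge schemes are positive, so the positive root is the right
#' branch).
#'
#' @param r2 symmetric matrix of squared correlations.
#' @return correlation matrix.
#' @export
correlation_from_squared <- function(r2) {
  r2 <- as.matrix(r2)
  if (any(r2 < 0) || any(r2 > 1 + 1e-9)) stop("R^2 entries must lie in [0,1]")
  r <- sqrt(r2)
  diag(r) <- 1
  r
}

#' Principal component analysis of charge observations
#'
#' Eigen-decomposition of the correlation or covariance matrix, eigenvalues
#' descending. The loading sign is fixed so that each vector's
#' largest-magnitude entry is negative (the convention of published
#' charge-survey loading tables, where the leading "ionicity" component has
#' all methods pulling with negative sign); the convention is cosmetic and
#' recorded on the result. When observations are supplied (rather than a
#' matrix), scores are returned and `scores %*% t(loadings)` reproduces the
#' centered (and, for correlation, scaled) data.
#'
#' @param x an [assemble_observations()] result, a data matrix, or an
#'   already-computed symmetric correlation/covariance matrix.
#' @param kind `"correlation"` or `"covariance"`.
#' @return object of class `"pca_result"`: `values`, `loadings`, `scores`
#'   (NULL for matrix input), `explained` (variance fractions), `kind`,
#'   `sign_convention`.
#' @export
pca_charges <- function(x, kind = c("correlation", "covariance")) {
  kind <- match.arg(kind)
  ## a plain square matrix is taken as an already-computed cor/cov matrix;
  ## observation data always goes through assemble_observations or a
  ## rectangular atoms x methods matrix
  if (is.matrix(x) && nrow(x) == ncol(x) &&
      !inherits(x, "observation_matrix")) {
    if (max(abs(x - t(x))) >= 1e-8) {
      stop("asymmetric square input: not a correlation/covariance matrix")
    }
    C <- (x + t(x)) / 2
    data <- NULL
  } else {
    M <- obs_matrix(x)
    C <- if (kind == "correlation") charge_correlation(M) else
      charge_covariance(M)
    data <- if (kind == "correlation") scale(M, TRUE, TRUE) else
      scale(M, TRUE, FALSE)
  }
  e <- eigen(C, symmetric = TRUE)
  V <- e$vectors
  for (i in seq_len(ncol(V))) {
    peak <- which.max(abs(V[, i]))
    if (V[peak, i] > 0) V[, i] <- -V[, i]
  }
  rownames(V) <- colnames(C)
  scores <- if (!is.null(data)) data %*% V else NULL
  structure(list(values = e$values, loadings = V, scores = scores,
                 explained = e$values / sum(e$values), kind = kind,
                 sign_convention = "largest-magnitude loading negative"),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %s PCA, %d components\n", x$kind,
              length(x$values)))
  cat("eigenvalues:", paste(format(utils::head(x$values, 6), digits = 4),
                            collapse = ", "),
      if (length(x$values) > 6) "...\n" else "\n")
  invisible(x)
}

#' Backward elimination of near-redundant variables
#'
#' Iteratively removes the variable with the largest absolute coefficient in
#' the eigenvector of the smallest eigenvalue, recomputing on the reduced
#' correlation matrix - the textbook strategy for discarding variables that
#' only feed near-degenerate directions (a duplicated column is eliminated
#' first).
#'
#' @param corr correlation matrix with dimnames.
#' @param n_remove how many variables to eliminate (< dimension).
#' @return list with `eliminated` (in order) and `remaining`.
#' @export
backward_eliminate <- function(corr, n_remove) {
  corr <- as.matrix(corr)
  if (n_remove >= ncol(corr)) stop("n_remove must be < dimension")
  if (is.null(colnames(corr))) {
    colnames(corr) <- rownames(corr) <- paste0("V", seq_len(ncol(corr)))
  }
  eliminated <- character(0)
  for (step in seq_len(n_remove)) {
    e <- eigen(corr, symmetric = TRUE)
    low <- e$vectors[, ncol(corr)]
    victim <- which.max(abs(low))
    eliminated <- c(eliminated, colnames(corr)[victim])
    corr <- corr[-victim, -victim, drop = FALSE]
  }
  list(eliminated = eliminated, remaining = colnames(corr))
}

#' Generalized coefficient of determination (GCD) of a variable subset
#'
#' Subspace overlap between the span of a variable subset and the span of the
#' first k principal components: `GCD = trace(P_S P_K) / k`, with `P_S` the
#' projector onto the (centered) data columns of the subset and `P_K` onto
#' the first k PC score vectors. Equals 1 iff the subspaces coincide and 0
#' iff they are orthogonal. Computed directly from the covariance matrix:
#' `trace(P_S P_K) = sum_i v_i' S[, sub] S[sub, sub]^-1 S[sub, ] v_i / lambda_i`.
#'
#' @param x observations ([assemble_observations()] result or data matrix) or
#'   a covariance matrix.
#' @param subset column names or indices of the candidate variables.
#' @param k number of leading PCs to compare against (default `|subset|`).
#' @return GCD score in [0, 1].
#' @export
gcd_score <- function(x, subset, k = length(subset)) {
  S <- if (is.matrix(x) && nrow(x) == ncol(x) &&
           max(abs(x - t(x))) < 1e-8) x else charge_covariance(x)
  if (is.character(subset)) subset <- match(subset, colnames(S))
  if (anyNA(subset)) stop("subset names not found in the variables")
  if (k > ncol(S)) stop("k exceeds the number of variables")
  if (length(subset) != length(unique(subset))) stop("duplicate subset members")
  Sss <- S[subset, subset, drop = FALSE]
  ev <- eigen(Sss, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-12 * max(ev)) {
    stop("rank-deficient subset: its columns are linearly dependent")
  }
  e <- eigen(S, symmetric = TRUE)
  tr <- 0
  for (i in seq_len(k)) {
    if (e$values[i] < 1e-14 * e$values[1]) break  # null PCs contribute nothing
    b <- S[subset, , drop = FALSE] %*% e$vectors[, i]
    tr <- tr + as.numeric(crossprod(b, solve(Sss, b))) / e$values[i]
  }
  min(1, tr / k)
}

#' Select the most representative variable subset
#'
#' Finds the size-k subset maximizing the GCD criterion, either exhaustively
#' (guaranteed global optimum; limited to <= 20 variables) or by simulated
#' annealing with single-swap moves and geometric cooling under a fixed seed.
#'
#' @param x observations or a covariance matrix (see [gcd_score()]).
#' @param k subset size (< number of variables).
#' @param method `"exhaustive"` or `"anneal"`.
#' @param seed RNG seed for the annealer.
#' @param schedule annealing schedule:
#'   `list(t0 =, cooling =, steps =)`.
#' @return object of class `"subset_search"`: `subset` (names), `criterion`,
#'   `method`, `seed`, and for the annealer a `trace` of accepted moves.
#' @export
select_subset <- function(x, k, method = c("exhaustive", "anneal"),
                          seed = 1L,
                          schedule = list(t0 = 0.1, cooling = 0.97,
                                          steps = 3000L)) {
  method <- match.arg(method)
  S <- if (is.matrix(x) && nrow(x) == ncol(x) &&
           max(abs(x - t(x))) < 1e-8) x else charge_covariance(x)
  p <- ncol(S)
  if (k >= p) stop("k must be smaller than the number of variables")
  vars <- colnames(S)
  if (is.null(vars)) vars <- paste0("V", seq_len(p))
  score <- function(sub) {
    tryCatch(gcd_score(S, sub, k), error = function(e) -Inf)
  }
  if (method == "exhaustive") {
    if (p > 20L) stop("exhaustive search limited to <= 20 variables")
    best <- NULL; best_val <- -Inf
    combs <- utils::combn(p, k)
    for (ci in seq_len(ncol(combs))) {
      val <- score(combs[, ci])
      if (val > best_val) { best_val <- val; best <- combs[, ci] }
    }
    return(structure(list(subset = vars[best], criterion = best_val,
                          method = "exhaustive", seed = NA_integer_,
                          trace = NULL),
                     class = "subset_search"))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  cur <- sample.int(p, k)
  cur_val <- score(cur)
  best <- cur; best_val <- cur_val
  temp <- schedule$t0
  trace <- data.frame(step = integer(), criterion = numeric())
  for (step in seq_len(schedule$steps)) {
    out_var <- cur[sample.int(k, 1)]
    in_var <- sample(setdiff(seq_len(p), cur), 1)
    cand <- c(setdiff(cur, out_var), in_var)
    val <- score(cand)
    if (val >= cur_val ||
        stats::runif(1) < exp((val - cur_val) / max(temp, 1e-12))) {
      cur <- cand; cur_val <- val
      trace <- rbind(trace, data.frame(step = step, criterion = val))
      if (val > best_val) { best <- cur; best_val <- val }
    }
    temp <- temp * schedule$cooling
  }
  structure(list(subset = vars[sort(best)], criterion = best_val,
                 method = "anneal", seed = seed, trace = trace),
            class = "subset_search")
}

#' @export
print.subset_search <- function(x, ...) {
  cat(sprintf("<subset_search> {%s} GCD = %.4f (%s)\n",
              paste(x$subset, collapse = ", "), x$criterion, x$method))
  invisible(x)
}

#' Multiple regression of one charge method on others
#'
#' Ordinary least squares with intercept;
#' `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param x observations (see [assemble_observations()]).
#' @param target method name of the dependent variable.
#' @param predictors method names of the regressors.
#' @return list with `coefficients` (named, no intercept), `intercept` and
#'   `r_squared`.
#' @export
regress_charges <- function(x, target, predictors) {
  M <- obs_matrix(x)
  for (m in c(target, predictors)) {
    if (!m %in% colnames(M)) stop("method not in observations: ", m)
  }
  X <- cbind(1, M[, predictors, drop = FALSE])
  cn <- kappa(crossprod(X), exact = FALSE)
  if (!is.finite(cn) || cn > 1e12) {
    stop("collinear predictors (condition number ", format(cn, digits = 3), ")")
  }
  y <- M[, target]
  fit <- stats::lm.fit(X, y)
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  list(coefficients = stats::setNames(fit$coefficients[-1], predictors),
       intercept = unname(fit$coefficients[1]),
       r_squared = 1 - ssr / sst)
}

#' R-squared of each method against the leading principal components
#'
#' For every method, the OLS R^2 of its charges on the first 1..k PC score
#' vectors of the covariance (or correlation) PCA. Nested models make each
#' row non-decreasing in k.
#'
#' @param x observations.
#' @param max_pcs largest number of PCs to fit (<= number of methods).
#' @param kind PCA matrix kind, default `"covariance"`.
#' @return methods x max_pcs matrix of R^2 values.
#' @export
pc_fit_table <- function(x, max_pcs, kind = "covariance") {
  M <- obs_matrix(x)
  if (max_pcs > ncol(M)) stop("max_pcs exceeds the number of methods")
  p <- pca_charges(x, kind)
  out <- matrix(NA_real_, ncol(M), max_pcs,
                dimnames = list(colnames(M), paste0("pc1_", seq_len(max_pcs))))
  for (m in seq_len(ncol(M))) {
    y <- M[, m]
    sst <- sum((y - mean(y))^2)
    for (k in seq_len(max_pcs)) {
      fit <- stats::lm.fit(cbind(1, p$scores[, seq_len(k), drop = FALSE]), y)
      out[m, k] <- 1 - sum(fit$residuals^2) / sst
    }
  }
  out
}

## Principal angles (radians) between the spans of two orthonormal column sets.
principal_angles <- function(V1, V2) {
  q1 <- qr.Q(qr(V1)); q2 <- qr.Q(qr(V2))
  sv <- svd(crossprod(q1, q2))$d
  acos(pmin(1, pmax(-1, sv)))
}

#' Noise robustness of the principal-component structure
#'
#' Appends `ceiling(fraction * n)` synthetic atoms whose charges are drawn
#' independently from each method's empirical marginal distribution -
#' preserving scales but destroying cross-method correlation - then repeats
#' the PCA and reports, per replicate, the eigenvalue shifts of the leading
#' components and the principal angles between original and perturbed loading
#' subspaces (dimensions 1, 2, 3). Components whose angle stays small are
#' robust to contamination; components that swing past ~45 degrees are in
#' danger of drowning in the noise.
#'
#' @param x observations.
#' @param fraction contamination fraction in (0, 1), default 0.1.
#' @param seed RNG seed; results are identical across runs for a fixed seed.
#' @param n_rep number of replicates.
#' @param kind PCA matrix kind, default `"covariance"`.
#' @return list with `original` eigenvalues, and `replicates`: per replicate,
#'   `eigenvalues`, `eigenvalue_shift` and `subspace_angles_deg` (named
#'   pc1/pc12/pc123).
#' @export
noise_robustness <- function(x, fraction = 0.1, seed = 1L, n_rep = 5L,
                             kind = "covariance") {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  M <- obs_matrix(x)
  base <- pca_charges(M, kind)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  m_extra <- ceiling(fraction * nrow(M))
  reps <- lapply(seq_len(n_rep), function(rep) {
    noise <- matrix(0, m_extra, ncol(M), dimnames = list(NULL, colnames(M)))
    for (cc in seq_len(ncol(M))) {
      noise[, cc] <- sample(M[, cc], m_extra, replace = TRUE)
    }
    pert <- pca_charges(rbind(M, noise), kind)
    nk <- min(3L, ncol(M))
    ang <- vapply(seq_len(nk), function(j) {
      max(principal_angles(base$loadings[, seq_len(j), drop = FALSE],
                           pert$loadings[, seq_len(j), drop = FALSE]))
    }, numeric(1)) * 180 / pi
    list(eigenvalues = pert$values,
         eigenvalue_shift = pert$values - base$values,
         subspace_angles_deg = stats::setNames(
           ang, paste0("pc1", c("", "2", "23")[seq_len(nk)])))
  })
  list(original = base$values, replicates = reps, fraction = fraction,
       seed = seed)
}

#' Complete a covariance matrix from published leading principal components
#'
#' Surveys often print only the leading eigenvalues and loading vectors of a
#' covariance matrix. This rebuilds a full-rank covariance consistent with
#' that summary: the printed rank-m part `sum_i lambda_i v_i v_i'` (loadings
#' are renormalized to unit length) plus an isotropic remainder on its
#' orthogonal complement sized so the total variance matches
#' `total_variance`. The completion is the maximum-entropy choice given the
#' printed information; quantities dominated by the leading structure
#' (regressions on leading variables, GCD subset selection, PC fits) are
#' insensitive to it.
#'
#' @param eigenvalues leading eigenvalues (length m).
#' @param loadings p x m matrix of the printed loading vectors.
#' @param total_variance total variance (sum of all p eigenvalues); defaults
#'   to `sum(eigenvalues)` (rank-m reconstruction, no remainder).
#' @return p x p covariance matrix with the loadings' rownames.
#' @export
reconstruct_covariance <- function(eigenvalues, loadings,
                                   total_variance = sum(eigenvalues)) {
  V <- as.matrix(loadings)
  m <- length(eigenvalues)
  if (ncol(V) != m) stop("one loading column per eigenvalue required")
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  S <- V %*% (eigenvalues * t(V))
  p <- nrow(V)
  resid <- total_variance - sum(eigenvalues)
  if (resid < -1e-8) stop("total_variance below the sum of the eigenvalues")
  if (resid > 0 && p > m) {
    Q <- qr.Q(qr(V))
    S <- S + resid / (p - m) * (diag(p) - tcrossprod(Q))
  }
  dimnames(S) <- list(rownames(loadings), rownames(loadings))
  (S + t(S)) / 2
}
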