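#' Per-atom charge vector
#'
#' Container for the result of a population analysis: one partial charge per
#' atom (elementary charges), aligned with a [geometry()], plus the method name
#' and a diagnostics list (convergence and quadrature metadata). Every charge
#' scheme in chargekit returns one of these.
#'
#' @param charges numeric vector of per-atom charges in e.
#' @param geom the [geometry()] the charges belong to.
#' @param method method name, e.g. `"mulliken"`.
#' @param diagnostics named list of metadata (iterations, RRMS, grid defect...).
#' @param sum_tol tolerance for the charge-sum invariant check; schemes on
#'   numerical grids pass their grid-normalization defect here.
#' @return object of class `"charge_vector"`.
#' @export
charge_vector <- function(charges, geom, method, diagnostics = list(),
                          sum_tol = 1e-8) {
  charges <- as.numeric(charges)
  if (length(charges) != n_atoms(geom)) {
    stop("charge vector length does not match atom count")
  }
  if (!all(is.finite(charges))) stop("non-finite charges")
  defect <- abs(sum(charges) - geom$total_charge)
  if (defect > sum_tol) {
    stop(sprintf("charges sum to %.6g, expected %d (tolerance %.3g)",
                 sum(charges), geom$total_charge, sum_tol))
  }
  diagnostics$charge_sum_defect <- defect
  diagnostics$charge_sum_tol <- sum_tol
  structure(
    list(charges = charges, method = method, geometry = geom,
         diagnostics = diagnostics),
    class = "charge_vector"
  )
}

#' @export
print.charge_vector <- function(x, ...) {
  cat(sprintf("<charge_vector> method %s\n", x$method))
  df <- data.frame(atom = seq_along(x$charges),  # 1-based in printed reports
                   element = x$geometry$symbols,
                   charge = round(x$charges, 6))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.charge_vector <- function(x, ...,
                                        molecule_id = x$geometry$label) {
  data.frame(molecule_id = molecule_id,
             atom_index = seq_along(x$charges),
             element = x$geometry$symbols,
             method = x$method,
             charge = x$charges,
             stringsAsFactors = FALSE)
}
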