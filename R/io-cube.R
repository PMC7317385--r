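#' Volumetric scalar field
#'
#' A scalar field (electron density in e/Bohr^3 or ESP in Hartree/e) sampled on
#' a regular 3-D lattice, with origin and axis metadata in Bohr, plus the
#' molecular geometry it belongs to. This is the carrier for everything the
#' grid-based charge schemes consume.
#'
#' @param origin numeric length-3, lattice origin (Bohr).
#' @param axes 3 x 3 matrix, rows are the three step vectors (Bohr).
#' @param values 3-D array, `values[i, j, k]` for the voxel at
#'   `origin + (i-1) axes[1,] + (j-1) axes[2,] + (k-1) axes[3,]`.
#' @param geom the [geometry()].
#' @return object of class `"volumetric_field"`.
#' @export
volumetric_field <- function(origin, axes, values, geom) {
  axes <- as.matrix(axes)
  if (!all(dim(axes) == c(3L, 3L))) stop("axes must be 3x3")
  if (abs(det(axes)) < 1e-14) stop("axes are linearly dependent")
  if (length(dim(values)) != 3L) stop("values must be a 3-D array")
  if (!all(is.finite(values))) stop("non-finite field values")
  structure(
    list(origin = as.numeric(origin), axes = unname(axes),
         shape = dim(values), values = values, geometry = geom),
    class = "volumetric_field"
  )
}

#' @export
print.volumetric_field <- function(x, ...) {
  cat(sprintf("<volumetric_field> %d x %d x %d voxels, voxel volume %.4g Bohr^3\n",
              x$shape[1], x$shape[2], x$shape[3], voxel_volume(x)))
  invisible(x)
}

#' Voxel volume of a field's lattice (Bohr^3)
#' @param field a [volumetric_field()].
#' @export
voxel_volume <- function(field) abs(det(field$axes))

## All voxel centre positions as an (n1*n2*n3) x 3 matrix, in the same linear
## order as as.vector(field$values) (first array index fastest).
field_points <- function(field) {
  s <- field$shape
  i <- rep(seq_len(s[1]) - 1L, times = s[2] * s[3])
  j <- rep(rep(seq_len(s[2]) - 1L, each = s[1]), times = s[3])
  k <- rep(seq_len(s[3]) - 1L, each = s[1] * s[2])
  cbind(
    field$origin[1] + i * field$axes[1, 1] + j * field$axes[2, 1] + k * field$axes[3, 1],
    field$origin[2] + i * field$axes[1, 2] + j * field$axes[2, 2] + k * field$axes[3, 2],
    field$origin[3] + i * field$axes[1, 3] + j * field$axes[2, 3] + k * field$axes[3, 3]
  )
}

#' Read a Gaussian cube file
#'
#' Standard cube layout: two comment lines; a line with the atom count and
#' origin; three axis lines (voxel counts and step vectors, Bohr); one line per
#' atom (Z, nuclear charge, position); then the values with the third axis
#' running fastest. Orbital cubes (negative atom count) are rejected.
#'
#' @param path path to the cube file.
#' @return a [volumetric_field()].
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7L) stop("cube parse error: header truncated")
  nums <- function(s) as.numeric(strsplit(trimws(s), "[[:space:]]+")[[1]])
  hdr <- nums(lines[3])
  natoms <- as.integer(hdr[1])
  if (is.na(natoms)) stop("cube parse error: bad atom-count line")
  if (natoms < 0L) {
    stop("orbital cube (negative atom count) not supported; ",
         "export a plain density/ESP cube instead")
  }
  origin <- hdr[2:4]
  shape <- integer(3)
  axes <- matrix(0, 3, 3)
  for (d in 1:3) {
    v <- nums(lines[3 + d])
    shape[d] <- as.integer(v[1])
    if (is.na(shape[d]) || shape[d] < 1L) stop("cube parse error: axis line ", d)
    if (v[1] < 0) stop("cube axes in Angstrom (negative count) not supported")
    axes[d, ] <- v[2:4]
  }
  if (length(lines) < 6L + natoms) stop("cube parse error: atom block truncated")
  z <- integer(natoms)
  coords <- matrix(0, natoms, 3)
  for (a in seq_len(natoms)) {
    v <- nums(lines[6 + a])
    z[a] <- as.integer(v[1])
    coords[a, ] <- v[3:5]
  }
  vals <- as.numeric(unlist(strsplit(trimws(lines[(7 + natoms):length(lines)]),
                                     "[[:space:]]+"), use.names = FALSE))
  vals <- vals[!is.na(vals)]
  nexp <- prod(shape)
  if (length(vals) != nexp) {
    stop("cube parse error: expected ", nexp, " values, found ", length(vals))
  }
  ## file order: first axis slowest, third fastest -> array dim rev, then aperm
  arr <- aperm(array(vals, dim = rev(shape)), c(3, 2, 1))
  total_charge <- 0L
  m <- regmatches(lines[2], regexpr("charge=(-?[0-9]+)", lines[2]))
  if (length(m) == 1L && nzchar(m)) total_charge <- as.integer(sub("charge=", "", m))
  geom <- geometry(element_symbol(z), coords, total_charge = total_charge,
                   label = trimws(lines[1]))
  volumetric_field(origin, axes, arr, geom)
}

#' Write a Gaussian cube file
#'
#' Inverse of [read_cube()]; values are written with `%.6E` precision, so a
#' write/read round trip reproduces the field to about 1e-6 relative.
#'
#' @param field a [volumetric_field()].
#' @param path output path.
#' @export
write_cube <- function(field, path) {
  g <- field$geometry
  comment2 <- "chargekit cube"
  if (g$total_charge != 0L) {
    comment2 <- paste(comment2, sprintf("charge=%d", g$total_charge))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(g$label, comment2), con)
  fmt <- function(n, v) sprintf("%5d %11.6f %11.6f %11.6f", n, v[1], v[2], v[3])
  writeLines(fmt(n_atoms(g), field$origin), con)
  for (d in 1:3) writeLines(fmt(field$shape[d], field$axes[d, ]), con)
  for (a in seq_len(n_atoms(g))) {
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f",
                       g$z[a], as.numeric(g$z[a]), g$coords[a, 1],
                       g$coords[a, 2], g$coords[a, 3]), con)
  }
  ## third axis fastest
  v <- as.vector(aperm(field$values, c(3, 2, 1)))
  n <- length(v)
  idx <- seq(1L, n, by = 6L)
  lines <- vapply(idx, function(i) {
    paste(sprintf("%13.6E", v[i:min(i + 5L, n)]), collapse = " ")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}
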