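#' Read an XYZ geometry file
#'
#' Standard XYZ: an atom-count line, a comment line, then one
#' `element x y z` line per atom with coordinates in Angstrom. Positions are
#' converted to Bohr on read (1 Angstrom = 1.8897261246 Bohr). A
#' `charge=N` token in the comment line sets the total molecular charge;
#' otherwise the molecule is neutral.
#'
#' @param path path to the file.
#' @param label optional label; defaults to the file name.
#' @return a [geometry()] with coordinates in Bohr.
#' @export
read_xyz <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("XYZ parse error: fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) {
    stop("XYZ parse error at line 1: malformed atom count '", lines[1], "'")
  }
  if (length(lines) < 2L + n) {
    stop("XYZ parse error: expected ", n, " atom lines, found ",
         length(lines) - 2L)
  }
  comment <- lines[2]
  total_charge <- 0L
  m <- regmatches(comment, regexpr("charge=(-?[0-9]+)", comment))
  if (length(m) == 1L && nzchar(m)) {
    total_charge <- as.integer(sub("charge=", "", m))
  }
  symbols <- character(n)
  coords <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[2L + i]), "[[:space:]]+")[[1]]
    if (length(tok) < 4L) {
      stop("XYZ parse error at line ", 2L + i, ": '", lines[2L + i], "'")
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz)) {
      stop("XYZ parse error at line ", 2L + i, ": non-numeric coordinate")
    }
    symbols[i] <- tok[1]
    coords[i, ] <- xyz
  }
  element_number(symbols)  # errors early on unknown symbols
  geometry(symbols, coords * ANGSTROM, total_charge = total_charge,
           label = label)
}

#' Write an XYZ geometry file
#'
#' Inverse of [read_xyz()]: coordinates are converted Bohr to Angstrom and a
#' `charge=N` token is emitted for charged species.
#'
#' @param geom a [geometry()].
#' @param path output path.
#' @export
write_xyz <- function(geom, path) {
  comment <- geom$label
  if (geom$total_charge != 0L) {
    comment <- paste(comment, sprintf("charge=%d", geom$total_charge))
  }
  coords <- geom$coords / ANGSTROM
  lines <- c(
    as.character(n_atoms(geom)),
    comment,
    sprintf("%-3s %18.10f %18.10f %18.10f",
            geom$symbols, coords[, 1], coords[, 2], coords[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}
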