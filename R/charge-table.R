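#' Long-format per-atom charge table
#'
#' The observation set of the meta-analysis: one record per
#' (molecule, atom, method) with the charge in elementary charges. Missing
#' values are first-class "holes" (`NA` charges): they are carried through and
#' handled by complete-case filtering in [assemble_observations()], never
#' silently replaced by zero.
#'
#' @param records data.frame with columns `molecule_id`, `atom_index`,
#'   `element`, `method`, `charge`.
#' @return object of classes `"charge_table"` and `"data.frame"`.
#' @export
charge_table <- function(records) {
  need <- c("molecule_id", "atom_index", "element", "method", "charge")
  if (!all(need %in% names(records))) {
    stop("charge table needs columns: ", paste(need, collapse = ", "))
  }
  records <- as.data.frame(records)[need]
  records$molecule_id <- as.character(records$molecule_id)
  records$atom_index <- as.integer(records$atom_index)
  records$method <- as.character(records$method)
  records$charge <- as.numeric(records$charge)
  key <- paste(records$molecule_id, records$atom_index, records$method,
               sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate record for (%s, atom %d, %s)",
                 d$molecule_id, d$atom_index, d$method))
  }
  if (any(is.infinite(records$charge))) stop("non-finite charge values")
  class(records) <- c("charge_table", "data.frame")
  records
}

#' Read a charge table
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`"long_csv"`}{a CSV with columns
#'     `molecule_id,atom_index,element,method,charge`, one record per row.
#'     Empty charge cells become holes (`NA`).}
#'   \item{`"workbook"`}{a spreadsheet (xlsx) with one row per atom and one
#'     column per charge method, as distributed with published charge surveys.
#'     `column_map` must map spreadsheet column names to method names; an
#'     unmapped charge column is an error (identifier columns for molecule,
#'     atom index and element are recognised by the names given in
#'     `id_cols`). Empty cells become holes, never zeros. Requires the
#'     readxl package.}
#' }
#'
#' @param path file path.
#' @param dialect `"long_csv"` or `"workbook"`.
#' @param column_map named character vector: names are spreadsheet columns,
#'   values are method names (workbook dialect only).
#' @param sheet sheet name or index (workbook dialect only).
#' @param id_cols length-3 character vector naming the molecule, atom-index and
#'   element columns in the workbook.
#' @return a [charge_table()].
#' @export
read_charge_table <- function(path, dialect = c("long_csv", "workbook"),
                              column_map = NULL, sheet = 1,
                              id_cols = c("molecule_id", "atom_index",
                                          "element")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "long_csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    return(charge_table(df))
  }
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("the workbook dialect requires the readxl package")
  }
  if (is.null(column_map)) {
    stop("the workbook dialect requires an explicit column_map ",
         "(spreadsheet column -> method name)")
  }
  df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  if (!all(id_cols %in% names(df))) {
    stop("workbook is missing identifier column(s): ",
         paste(setdiff(id_cols, names(df)), collapse = ", "))
  }
  charge_cols <- setdiff(names(df), id_cols)
  unmapped <- setdiff(charge_cols, names(column_map))
  if (length(unmapped) > 0L) {
    stop("unmapped method column(s): ", paste(unmapped, collapse = ", "))
  }
  long <- do.call(rbind, lapply(charge_cols, function(cc) {
    data.frame(molecule_id = df[[id_cols[1]]],
               atom_index = df[[id_cols[2]]],
               element = df[[id_cols[3]]],
               method = unname(column_map[cc]),
               charge = as.numeric(df[[cc]]),
               stringsAsFactors = FALSE)
  }))
  charge_table(long)
}

#' Write a charge table as long CSV
#' @param table a [charge_table()].
#' @param path output path.
#' @export
write_charge_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Bind charge vectors into a charge table
#'
#' @param ... [charge_vector()] objects (or lists of them).
#' @return a [charge_table()].
#' @export
charge_table_from_vectors <- function(...) {
  cvs <- list(...)
  if (length(cvs) == 1L && !inherits(cvs[[1]], "charge_vector")) cvs <- cvs[[1]]
  charge_table(do.call(rbind, lapply(cvs, as.data.frame)))
}
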