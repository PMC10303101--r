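#' Write a cohort table to CSV
#'
#' Comma-delimited, '.' decimal point, header row of variable names, one row
#' per subject; missing values written as empty cells.
#'
#' @param cohort A `cohort_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Validates column names against the study schema (clinical variables,
#' element symbols, auxiliary and derived variables), rejects duplicate
#' subject ids, and reports malformed numeric cells with their row/column
#' coordinates. Empty cells become missing values.
#'
#' @param path CSV file with a `subject_id` column and one column per
#'   variable.
#' @param extra_variables Additional column names to accept beyond the study
#'   schema.
#' @return A `cohort_tbl` tibble.
#' @export
read_cohort_csv <- function(path, extra_variables = character(0)) {
  known <- c("subject_id", clinical_table()$name, element_schema()$symbol,
             auxiliary_table()$name, "diabetes", "mets", "obesity", "ti",
             extra_variables)
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  unknown <- setdiff(hdr, known)
  if (length(unknown) > 0) {
    hints <- purrr::map_chr(unknown, function(u) {
      near <- known[utils::adist(u, known, ignore.case = TRUE) <= 2]
      if (length(near) == 0) u
      else paste0(u, " (did you mean ", paste(near, collapse = ", "), "?)")
    })
    abort_autocmap(paste0("Unknown columns: ", paste(hints, collapse = "; ")),
                   "autocmap_schema_error")
  }
  # parse issues are collected from problems() and re-raised with coordinates
  tbl <- suppressWarnings(readr::read_csv(
    path, show_col_types = FALSE,
    col_types = do.call(readr::cols, c(
      list(.default = readr::col_double()),
      if ("subject_id" %in% hdr) list(subject_id = readr::col_character())
    ))))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    # problems() counts the header line; report data-row coordinates
    loc <- paste0("row ", probs$row - 1L, ", column ", hdr[probs$col],
                  " (", probs$actual, ")")
    abort_autocmap(paste0("Malformed numeric cells: ",
                          paste(utils::head(loc, 5), collapse = "; ")),
                   "autocmap_parse_error")
  }
  if ("subject_id" %in% names(tbl) && anyDuplicated(tbl$subject_id)) {
    dup <- unique(tbl$subject_id[duplicated(tbl$subject_id)])
    abort_autocmap(paste0("Duplicate subject ids: ",
                          paste(utils::head(dup, 5), collapse = ", ")),
                   "autocmap_schema_error")
  }
  as_cohort_tbl(tbl, units = study_units(names(tbl)))
}
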