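#' Examination-table column registry
#'
#' Canonical CSV schema for exam-level dose records: one row per examination,
#' decimal point, UTF-8. Columns mirror what a scanner dose report plus
#' topogram measurements provide.
#'
#' @return Named character vector mapping column names to types
#'   (`"character"` or `"numeric"`).
#' @export
exam_table_schema <- function() {
  c(
    patient_id = "character",
    sex = "character",
    age_years = "numeric",
    weight_kg = "numeric",
    height_cm = "numeric",
    lat_dim_a_cm = "numeric",
    ap_dim_b_cm = "numeric",
    topo_ctdivol_mgy = "numeric",
    topo_dlp_mgycm = "numeric",
    topo_length_mm = "numeric",
    scan_ctdivol_mgy = "numeric",
    scan_dlp_mgycm = "numeric",
    scan_length_mm = "numeric"
  )
}

check_exam_table <- function(exams) {
  if (!is.data.frame(exams)) {
    abort_schema("Examination table must be a data frame.")
  }
  schema <- exam_table_schema()
  missing <- setdiff(names(schema), names(exams))
  if (length(missing) > 0) {
    abort_schema(sprintf("Examination table is missing column(s): %s.",
                         paste(missing, collapse = ", ")),
                 missing_columns = missing)
  }
  if (nrow(exams) == 0) {
    abort_empty("Examination table has no rows.")
  }
  bad_sex <- !exams$sex %in% c("F", "M")
  if (any(bad_sex)) {
    abort_invalid(sprintf("`sex` must be 'F' or 'M'; offending row(s): %s.",
                          paste(which(bad_sex), collapse = ", ")))
  }
  for (col in c("weight_kg", "height_cm", "lat_dim_a_cm", "ap_dim_b_cm",
                "topo_length_mm", "scan_length_mm")) {
    bad <- !is.finite(exams[[col]]) | exams[[col]] <= 0
    if (any(bad)) {
      abort_invalid(sprintf("`%s` must be positive; offending row(s): %s.",
                            col, paste(which(bad), collapse = ", ")))
    }
  }
  for (col in c("topo_ctdivol_mgy", "topo_dlp_mgycm",
                "scan_ctdivol_mgy", "scan_dlp_mgycm")) {
    bad <- !is.finite(exams[[col]]) | exams[[col]] < 0
    if (any(bad)) {
      abort_invalid(sprintf("`%s` must be non-negative; offending row(s): %s.",
                            col, paste(which(bad), collapse = ", ")))
    }
  }
  invisible(exams)
}

#' Read an examination table from CSV
#'
#' @param path Path to a CSV file whose header matches [exam_table_schema()].
#' @return A tibble of typed examination records.
#' @export
read_exam_table <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("Examination file not found: '%s'.", path))
  }
  schema <- exam_table_schema()
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(names(schema), header)
  if (length(missing) > 0) {
    abort_schema(sprintf("File '%s' is missing column(s): %s.",
                         path, paste(missing, collapse = ", ")),
                 missing_columns = missing)
  }
  spec <- do.call(readr::cols, c(
    lapply(schema, function(tp) {
      if (tp == "character") readr::col_character() else readr::col_double()
    }),
    list(.default = readr::col_guess())
  ))
  exams <- suppressWarnings(
    readr::read_csv(path, col_types = spec, show_col_types = FALSE)
  )
  probs <- readr::problems(exams)
  if (nrow(probs) > 0) {
    abort_invalid(sprintf(
      "Could not parse '%s': %s.", path,
      paste(sprintf("row %d, column %d (%s expected, got '%s')",
                    probs$row, probs$col, probs$expected, probs$actual),
            collapse = "; ")
    ))
  }
  check_exam_table(exams)
  exams[, names(schema)]
}

#' Write an examination table to CSV
#'
#' Inverse of [read_exam_table()]; `write_exam_table()` then
#' [read_exam_table()] round-trips the table.
#'
#' @param exams Examination table following [exam_table_schema()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_exam_table <- function(exams, path) {
  check_exam_table(exams)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort_io(sprintf("Output directory does not exist: '%s'.", dir))
  }
  readr::write_csv(exams[, names(exam_table_schema())], path)
  invisible(path)
}
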