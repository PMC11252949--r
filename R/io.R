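# Delimited-text readers/writers for attenuation tables.
#
# Canonical schema (header required): subject_id, group, metabolite, b,
# signal[, sd] with b in ms/um^2 and signal dimensionless. CSV or TSV is
# chosen by file extension (.csv vs .tsv/.txt/.tab).

#' Read an attenuation table
#'
#' Reads a delimited text file of diffusion-weighted attenuations in the
#' canonical long schema and validates it (required columns, numeric cells,
#' no duplicated (subject, metabolite, b) rows). Tables whose columns are
#' named differently can be mapped with `col_map` rather than edited.
#'
#' @param path CSV or TSV file; the delimiter follows the extension.
#' @param normalize Normalise each curve to 1 at its lowest b on load
#'   (default `TRUE`, the convention all fits expect).
#' @param col_map Optional named character vector mapping canonical names to
#'   the file's columns, e.g. `c(subject_id = "animal", signal = "S")`.
#' @return A validated tibble of curves.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write_attenuation_table(generate_cohort(cohort_config(n_per_group = 1)), tf)
#' read_attenuation_table(tf)
#' @export
read_attenuation_table <- function(path, normalize = TRUE, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop(sprintf("parse error at row %d, column %d of %s: expected %s",
                 prob$row[1], prob$col[1], basename(path),
                 prob$expected[1]), call. = FALSE)
  }
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(raw)) {
        stop("col_map refers to absent column: ", col_map[[canon]],
             call. = FALSE)
      }
      names(raw)[names(raw) == col_map[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(curve_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s is missing column(s): %s", basename(path),
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in c("b", "signal", if ("sd" %in% names(raw)) "sd")) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      stop(sprintf("non-numeric value in column '%s' of %s (data row %s)",
                   col, basename(path),
                   ifelse(is.na(bad), "?", bad)), call. = FALSE)
    }
  }
  out <- validate_curves(raw)
  if (normalize) out <- normalize_curves(out)
  out
}

#' Write an attenuation table
#'
#' @param data Curve table (validated before writing).
#' @param path Output file; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @return `path`, invisibly.
#' @export
write_attenuation_table <- function(data, path) {
  validate_curves(data)
  keep <- intersect(c(curve_cols, "sd"), names(data))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(data[keep], path)
  } else {
    readr::write_tsv(data[keep], path)
  }
  invisible(path)
}
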