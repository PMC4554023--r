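# Flat-CSV cohort interchange: one row per eye, fixed column set, explicit
# cylinder-sign notation. The device's native exports are out of scope; this
# is the package's single input format.

#' Cohort CSV column names
#'
#' The fixed column order of the cohort interchange CSV. `sa_um` (corneal
#' spherical aberration) is optional on read and filled with `NA` when the
#' column is absent.
#'
#' @return Character vector of column names.
#' @export
cohort_columns <- function() {
  c("eye_id", "age_years",
    "ak_cyl_d", "ak_axis_deg",
    "tcrp3_cyl_d", "tcrp3_axis_deg",
    "tcrp4_cyl_d", "tcrp4_axis_deg",
    "ir_mm", "irregular_astig_um",
    "ant_radius_mm", "post_radius_mm",
    "ra_sphere_d", "ra_cyl_d", "ra_axis_deg", "ra_notation",
    "sa_um")
}

# Row-level validation; returns a character vector of problems (possibly
# empty). `lines`, when given, maps rows to file line numbers for messages.
validate_cohort <- function(cohort, lines = NULL) {
  problems <- character(0)
  note <- function(rows, msg) {
    if (!any(rows)) return()
    where <- if (is.null(lines)) {
      paste0("row ", which(rows))
    } else {
      paste0("line ", lines[which(rows)])
    }
    ids <- as.character(cohort$eye_id)[which(rows)]
    problems <<- c(problems,
                   paste0(where, " (eye ", ids, "): ", msg))
  }
  numeric_cols <- setdiff(cohort_columns(), c("eye_id", "ra_notation"))
  for (col in numeric_cols) {
    if (!col %in% names(cohort)) next
    v <- cohort[[col]]
    if (!is.numeric(v)) {
      problems <- c(problems, paste0("column `", col, "` is not numeric"))
      next
    }
    optional <- col == "sa_um"
    bad <- if (optional) !is.na(v) & !is.finite(v) else !is.finite(v)
    bad[is.na(bad)] <- TRUE
    if (optional) bad[is.na(v)] <- FALSE
    note(bad, paste0("non-finite `", col, "`"))
  }
  fin <- function(col) {
    v <- cohort[[col]]
    ifelse(is.na(v), FALSE, is.finite(v))
  }
  for (col in c("ak_axis_deg", "tcrp3_axis_deg", "tcrp4_axis_deg",
                "ra_axis_deg")) {
    v <- cohort[[col]]
    note(fin(col) & (v < 0 | v >= 180),
         paste0("`", col, "` outside [0, 180)"))
  }
  for (col in c("ak_cyl_d", "tcrp3_cyl_d", "tcrp4_cyl_d", "ir_mm",
                "irregular_astig_um")) {
    v <- cohort[[col]]
    note(fin(col) & v < 0, paste0("`", col, "` must be >= 0"))
  }
  for (col in c("age_years", "ant_radius_mm", "post_radius_mm")) {
    v <- cohort[[col]]
    note(fin(col) & v <= 0, paste0("`", col, "` must be > 0"))
  }
  notation <- as.character(cohort$ra_notation)
  note(!notation %in% c("pos", "neg"),
       '`ra_notation` must be "pos" or "neg"')
  cylv <- cohort$ra_cyl_d
  note(fin("ra_cyl_d") &
         ((notation == "pos" & cylv < 0) | (notation == "neg" & cylv > 0)),
       "`ra_cyl_d` sign inconsistent with `ra_notation`")
  problems
}

#' Read a cohort CSV
#'
#' Enforces the exact [cohort_columns()] header (the `sa_um` column may be
#' omitted) and validates every row; all violations are collected and
#' reported together with their line numbers.
#'
#' @param path Path to a cohort CSV.
#' @return Cohort data frame in schema column order.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop("cohort file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(eye_id = "character"))
  expected <- cohort_columns()
  got <- names(df)
  optional_missing <- identical(got, setdiff(expected, "sa_um"))
  if (!identical(got, expected) && !optional_missing) {
    stop("schema error: expected columns\n  ",
         paste(expected, collapse = ", "), "\ngot\n  ",
         paste(got, collapse = ", "), call. = FALSE)
  }
  if (optional_missing) df$sa_um <- NA_real_
  for (col in setdiff(expected, c("eye_id", "ra_notation"))) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$ra_notation <- as.character(df$ra_notation)
  if (nrow(df) == 0) {
    return(df[, expected])
  }
  problems <- validate_cohort(df, lines = seq_len(nrow(df)) + 1L)
  if (length(problems)) {
    stop("invalid rows in ", path, ":\n",
         paste(problems, collapse = "\n"), call. = FALSE)
  }
  df[, expected]
}

#' Write a cohort CSV
#'
#' Validates the cohort first (nothing is written on failure), formats
#' numeric columns to 6 significant digits and writes the schema columns in
#' their fixed order. Deterministic: identical cohorts give byte-identical
#' files.
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  expected <- cohort_columns()
  missing_cols <- setdiff(setdiff(expected, "sa_um"), names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"sa_um" %in% names(cohort)) cohort$sa_um <- NA_real_
  problems <- validate_cohort(cohort)
  if (length(problems)) {
    stop("invalid cohort, nothing written:\n",
         paste(problems, collapse = "\n"), call. = FALSE)
  }
  out <- cohort[, expected, drop = FALSE]
  for (col in setdiff(expected, c("eye_id", "ra_notation"))) {
    out[[col]] <- signif(out[[col]], 6)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
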