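#' Column layout of the patient-visit cohort table
#'
#' @return Character vector of the required column names, in order.
#' @export
cohort_columns <- function() {
  c("patient_id", "visit", "aliquot1", "aliquot2", "aliquot3", "aliquot4",
    "pct_er", "pct_bcl2", "pct_her2", "pct_ki67", "status", "pfs_months",
    "pfs_event", "event_type", "death_mbc", "reimaged_3mo")
}

valid_visits <- c("BL", "M1", "M2", "M3", "M12")

#' Read / write a cohort table as delimited text
#'
#' One row per patient-visit, fixed header ([cohort_columns()]); missing
#' marker percentages are empty fields. `write_cohort()` followed by
#' `read_cohort()` reproduces every value to full precision.
#'
#' @param path File path.
#' @return `read_cohort()`: the cohort data frame; `write_cohort()`: the
#'   path, invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  need <- cohort_columns()
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("malformed cohort header: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) return(df[, intersect(need, names(df)), drop = FALSE])
  bad <- which(!df$visit %in% valid_visits)
  if (length(bad))
    stop(sprintf("invalid visit label '%s' in row %d, column 'visit'",
                 df$visit[bad[1]], bad[1]), call. = FALSE)
  for (col in c("aliquot1", "aliquot2", "aliquot3", "aliquot4", "pfs_months")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    parse_fail <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(parse_fail))
      stop(sprintf("unparseable value '%s' in row %d, column '%s'",
                   df[[col]][parse_fail[1]], parse_fail[1], col), call. = FALSE)
    df[[col]] <- v
  }
  for (col in c("pfs_event", "death_mbc", "reimaged_3mo"))
    df[[col]] <- as.logical(df[[col]])
  df
}

#' @rdname read_cohort
#' @param cohort Cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  cols <- intersect(c(cohort_columns(), "latent_state"), names(cohort))
  utils::write.csv(cohort[, cols, drop = FALSE], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read / write a point table as YAML or JSON
#'
#' The serialized form carries `enum_breaks`, `enum_points`,
#' `marker_points` and `category_bounds`, so alternative weightings can be
#' stored and audited.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `read_point_table()`: a [point_table()].
#' @export
read_point_table <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  point_table(
    enum_breaks = as.numeric(raw$enum_breaks),
    enum_points = as.numeric(raw$enum_points),
    marker_points = lapply(raw$marker_points, function(m) unlist(m)),
    category_bounds = unlist(raw$category_bounds))
}

#' @rdname read_point_table
#' @param table A [point_table()].
#' @export
write_point_table <- function(table, path) {
  stopifnot(inherits(table, "point_table"))
  obj <- list(enum_breaks = table$enum_breaks,
              enum_points = table$enum_points,
              marker_points = lapply(table$marker_points, as.list),
              category_bounds = as.list(table$category_bounds))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(obj, path)
  invisible(path)
}
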