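#' Average the four aliquot CTC counts
#'
#' One blood draw is pooled and split into four 7.5 ml aliquots; the
#' arithmetic mean of the four counts is the draw's CTC level. The mean is
#' rounded half-up to the nearest integer before any category lookup, so an
#' average of 4.5 counts as 5 (elevated).
#'
#' @param counts Integer vector of exactly four non-negative aliquot counts.
#' @return List with `avg` (exact mean) and `rounded` (half-up integer).
#' @examples
#' average_ctc(c(5, 5, 4, 5))  # avg 4.75, rounded 5
#' @export
average_ctc <- function(counts) {
  if (length(counts) != 4L)
    stop("exactly four aliquot counts are required, got ", length(counts), call. = FALSE)
  if (anyNA(counts) || any(counts < 0))
    stop("aliquot counts must be non-negative and non-missing", call. = FALSE)
  avg <- mean(counts)
  list(avg = avg, rounded = round_half_up(avg))
}

# round() in R rounds half to even; the scoring protocol rounds half up.
round_half_up <- function(x) floor(x + 0.5)

#' CTC-enumeration points for a rounded average count
#'
#' @param rounded_avg Non-negative integer rounded average CTC count.
#' @param table A [point_table()].
#' @return Integer points (default table: <5 -> 0, 5--10 -> 1, 11--100 -> 3,
#'   >100 -> 4).
#' @export
enumeration_points <- function(rounded_avg, table = default_point_table()) {
  stopifnot(all(rounded_avg >= 0))
  idx <- findInterval(rounded_avg, table$enum_breaks + 1) + 1L
  table$enum_points[idx]
}

#' Marker positivity category
#'
#' Percent of CTC staining positive (2+ or 3+) for a marker is placed into
#' one of three staining categories: exactly 0%, 1--10% (any positive
#' fraction up to 10), or >10%.
#'
#' @param pct Percent in \[0, 100\].
#' @return Factor with levels `zero`, `low`, `high`.
#' @export
marker_category <- function(pct) {
  if (anyNA(pct) || any(pct < 0) || any(pct > 100))
    stop("marker percentage must be in [0, 100]", call. = FALSE)
  factor(ifelse(pct == 0, "zero", ifelse(pct <= 10, "low", "high")),
         levels = c("zero", "low", "high"))
}

eti_category <- function(total, table) {
  cb <- table$category_bounds
  factor(ifelse(total <= cb["low"], "low",
                ifelse(total <= cb["intermediate"], "intermediate", "high")),
         levels = c("low", "intermediate", "high"))
}

#' Compute the CTC endocrine therapy index for one blood draw
#'
#' The total score is the sum of the CTC-enumeration points and the
#' Bio-Score (the sum of the four marker Bio-Points), ranging 0--16. When
#' the rounded average count is below 5 CTC/7.5 ml WB the phenotyping assay
#' is not interpreted: the Bio-Score is 0 and the result is low by
#' definition, whatever the marker readings. When the count is elevated,
#' all four marker percentages must be interpretable; otherwise the index
#' is undetermined, as is any draw whose sample status is not `ok`.
#'
#' @param counts Four aliquot CTC counts.
#' @param markers Named numeric vector or list with `ER`, `BCL2`, `HER2`,
#'   `Ki67` percent-positive values (may be `NA` when undetermined).
#' @param status Sample status: `"ok"`, `"qns"`, `"preanalytic_error"` or
#'   `"technical_failure"`.
#' @param table A [point_table()].
#' @return An `eti_result`: list with `avg_ctc`, `rounded_avg`,
#'   `enum_points`, `bio_points`, `bio_score`, `total`, `category`,
#'   `elevated`, `determined`, `status`.
#' @examples
#' compute_eti(c(7, 6, 8, 7), c(ER = 0, BCL2 = 0, HER2 = 50, Ki67 = 40))
#' @export
compute_eti <- function(counts, markers = NULL, status = "ok",
                        table = default_point_table()) {
  status <- match.arg(status, c("ok", "qns", "preanalytic_error", "technical_failure"))
  if (status != "ok")
    return(undetermined_eti(status))
  a <- average_ctc(counts)
  enum <- enumeration_points(a$rounded, table)
  elevated <- a$rounded >= 5
  if (!elevated) {
    res <- list(avg_ctc = a$avg, rounded_avg = a$rounded, enum_points = enum,
                bio_points = c(ER = 0, BCL2 = 0, HER2 = 0, Ki67 = 0),
                bio_score = 0, total = enum,
                category = factor("low", levels = c("low", "intermediate", "high")),
                elevated = FALSE, determined = TRUE, status = status)
    return(structure(res, class = "eti_result"))
  }
  need <- c("ER", "BCL2", "HER2", "Ki67")
  mk <- unlist(markers)[need]
  if (length(mk) != 4L || anyNA(mk))
    return(undetermined_eti(status, avg = a$avg, rounded = a$rounded, elevated = TRUE))
  cats <- as.character(marker_category(mk))
  bp <- vapply(need, function(m) table$marker_points[[m]][[cats[match(m, need)]]],
               numeric(1))
  bio <- sum(bp)
  total <- enum + bio
  structure(
    list(avg_ctc = a$avg, rounded_avg = a$rounded, enum_points = enum,
         bio_points = bp, bio_score = bio, total = total,
         category = eti_category(total, table),
         elevated = TRUE, determined = TRUE, status = status),
    class = "eti_result")
}

undetermined_eti <- function(status, avg = NA_real_, rounded = NA_integer_,
                             elevated = NA) {
  structure(
    list(avg_ctc = avg, rounded_avg = rounded, enum_points = NA_real_,
         bio_points = c(ER = NA_real_, BCL2 = NA_real_, HER2 = NA_real_, Ki67 = NA_real_),
         bio_score = NA_real_, total = NA_real_,
         category = factor(NA, levels = c("low", "intermediate", "high")),
         elevated = elevated, determined = FALSE, status = status),
    class = "eti_result")
}

#' @export
print.eti_result <- function(x, ...) {
  if (!x$determined) {
    cat(sprintf("CTC-ETI: undetermined (status %s)\n", x$status))
    return(invisible(x))
  }
  cat(sprintf("CTC-ETI: %g (%s)\n", x$total, x$category))
  cat(sprintf("  average CTC %.2f (rounded %d, %selevated), enumeration points %g\n",
              x$avg_ctc, x$rounded_avg, if (x$elevated) "" else "not ", x$enum_points))
  cat(sprintf("  Bio-Score %g (ER %g, BCL2 %g, HER2 %g, Ki67 %g)\n",
              x$bio_score, x$bio_points["ER"], x$bio_points["BCL2"],
              x$bio_points["HER2"], x$bio_points["Ki67"]))
  invisible(x)
}

#' Score every patient-visit row of a cohort table
#'
#' Appends the index columns (`avg_ctc`, `rounded_avg`, `enum_points`,
#' `bio_score`, `eti_total`, `eti_category`, `elevated`, `determined`) to a
#' cohort table of the layout produced by [simulate_cohort()] or read by
#' [read_cohort()].
#'
#' @param cohort Cohort data frame, one row per patient-visit.
#' @param table A [point_table()].
#' @return The cohort with scoring columns appended.
#' @export
score_cohort <- function(cohort, table = default_point_table()) {
  stopifnot(is.data.frame(cohort))
  res <- lapply(seq_len(nrow(cohort)), function(i) {
    compute_eti(as.numeric(cohort[i, paste0("aliquot", 1:4)]),
                c(ER = cohort$pct_er[i], BCL2 = cohort$pct_bcl2[i],
                  HER2 = cohort$pct_her2[i], Ki67 = cohort$pct_ki67[i]),
                status = cohort$status[i], table = table)
  })
  cohort$avg_ctc <- vapply(res, `[[`, numeric(1), "avg_ctc")
  cohort$rounded_avg <- vapply(res, `[[`, numeric(1), "rounded_avg")
  cohort$enum_points <- vapply(res, `[[`, numeric(1), "enum_points")
  cohort$bio_score <- vapply(res, `[[`, numeric(1), "bio_score")
  cohort$eti_total <- vapply(res, `[[`, numeric(1), "total")
  cohort$eti_category <- vapply(res, function(r) as.character(r$category), character(1))
  cohort$elevated <- vapply(res, function(r) as.logical(r$elevated), logical(1))
  cohort$determined <- vapply(res, `[[`, logical(1), "determined")
  cohort
}

#' Enumerate every score the algorithm can produce
#'
#' Crosses the four enumeration categories with all 3^4 marker category
#' combinations and returns the resulting totals; used to audit the score
#' range and category bounds exhaustively.
#'
#' @param table A [point_table()].
#' @return Data frame with one row per combination: enumeration points, the
#'   four marker categories, `total` and `category`.
#' @export
enumerate_scores <- function(table = default_point_table()) {
  cats <- c("zero", "low", "high")
  grid <- expand.grid(enum = table$enum_points, ER = cats, BCL2 = cats,
                      HER2 = cats, Ki67 = cats, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  bio <- mapply(function(er, bc, he, ki) {
    table$marker_points$ER[[er]] + table$marker_points$BCL2[[bc]] +
      table$marker_points$HER2[[he]] + table$marker_points$Ki67[[ki]]
  }, grid$ER, grid$BCL2, grid$HER2, grid$Ki67)
  grid$total <- grid$enum + bio
  grid$category <- eti_category(grid$total, table)
  grid
}
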