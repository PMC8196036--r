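#' Point table for the CTC endocrine therapy index
#'
#' A point table holds the configurable weights of the modified CTC-ETI
#' algorithm: the CTC-enumeration cutpoints with their points, the per-marker
#' Bio-Point assignments for the three positivity categories (0%, 1--10%,
#' >10% of CTC staining positive), and the score bounds of the low /
#' intermediate / high categories.
#'
#' The shipped default reproduces every published constraint of the modified
#' algorithm: enumeration points 0 / 1 / 3 / 4 for average CTC <5, 5--10,
#' 11--100 and >100 per 7.5 ml whole blood; ER and BCL2 scored inversely to
#' positivity (positive staining suggests endocrine sensitivity, so it earns
#' low points) with ER carrying the largest marker weight; HER2 and Ki67
#' scored directly (positive staining suggests resistance); marker maxima
#' summing to 12 so the total score spans 0--16; and categories low 0--3,
#' intermediate 4--6, high 7--16. The exact per-marker values are
#' configurable because they are protocol-level constants rather than
#' published ones.
#'
#' @param enum_breaks Upper bounds (inclusive) of the enumeration categories
#'   on the rounded average CTC count; the last category is unbounded.
#' @param enum_points Points for each enumeration category; one more entry
#'   than `enum_breaks`.
#' @param marker_points Named list with entries `ER`, `BCL2`, `HER2`, `Ki67`,
#'   each a numeric vector of points named `zero`, `low`, `high`.
#' @param category_bounds Named numeric vector `c(low = 3, intermediate = 6)`:
#'   the largest total score in each of the first two categories; anything
#'   above the second bound is high.
#' @return An object of class `point_table`.
#' @examples
#' pt <- default_point_table()
#' validate_point_table(pt)
#' @export
point_table <- function(enum_breaks = c(4, 10, 100),
                        enum_points = c(0, 1, 3, 4),
                        marker_points = list(
                          ER   = c(zero = 4, low = 2, high = 0),
                          BCL2 = c(zero = 2, low = 1, high = 0),
                          HER2 = c(zero = 0, low = 2, high = 3),
                          Ki67 = c(zero = 0, low = 1, high = 3)),
                        category_bounds = c(low = 3, intermediate = 6)) {
  if (length(enum_points) != length(enum_breaks) + 1L)
    stop("`enum_points` must have one more entry than `enum_breaks`", call. = FALSE)
  if (is.unsorted(enum_breaks, strictly = TRUE))
    stop("`enum_breaks` must be strictly increasing", call. = FALSE)
  need <- c("ER", "BCL2", "HER2", "Ki67")
  if (!all(need %in% names(marker_points)))
    stop("`marker_points` must have entries ER, BCL2, HER2, Ki67", call. = FALSE)
  marker_points <- lapply(marker_points[need], function(m) {
    if (!all(c("zero", "low", "high") %in% names(m)))
      stop("each marker needs points named zero, low, high", call. = FALSE)
    m[c("zero", "low", "high")]
  })
  structure(
    list(enum_breaks = as.numeric(enum_breaks),
         enum_points = as.numeric(enum_points),
         marker_points = marker_points,
         category_bounds = category_bounds),
    class = "point_table")
}

#' @rdname point_table
#' @export
default_point_table <- function() point_table()

#' @export
print.point_table <- function(x, ...) {
  lab <- c(paste0("<=", x$enum_breaks), paste0(">", x$enum_breaks[length(x$enum_breaks)]))
  cat("CTC-ETI point table\n")
  cat("  enumeration points:", paste(sprintf("%s -> %g", lab, x$enum_points), collapse = ", "), "\n")
  for (m in names(x$marker_points))
    cat(sprintf("  %-4s Bio-Points: 0%% -> %g, 1-10%% -> %g, >10%% -> %g\n",
                m, x$marker_points[[m]]["zero"], x$marker_points[[m]]["low"],
                x$marker_points[[m]]["high"]))
  cat(sprintf("  categories: low 0-%g, intermediate %g-%g, high %g-%g\n",
              x$category_bounds["low"], x$category_bounds["low"] + 1,
              x$category_bounds["intermediate"], x$category_bounds["intermediate"] + 1,
              max_score(x)))
  invisible(x)
}

max_score <- function(table) {
  max(table$enum_points) + sum(vapply(table$marker_points, max, numeric(1)))
}

#' Audit a point table against the algorithm's structural constraints
#'
#' Checks the invariants the modified scoring algorithm is built on:
#' enumeration points non-decreasing in CTC count; ER and BCL2 points
#' non-increasing in positivity (positivity is a sensitivity signal), HER2
#' and Ki67 non-decreasing (a resistance signal); ER carrying at least as
#' much weight as every other marker; the maxima summing to a top score of
#' 16; and category bounds that partition the score range.
#'
#' @param table A [point_table()].
#' @return Character vector of violations; empty if the table is valid.
#' @export
validate_point_table <- function(table) {
  stopifnot(inherits(table, "point_table"))
  bad <- character(0)
  if (is.unsorted(table$enum_points))
    bad <- c(bad, "enumeration points must be non-decreasing in CTC count")
  for (m in c("ER", "BCL2")) {
    p <- table$marker_points[[m]]
    if (p["zero"] < p["low"] || p["low"] < p["high"])
      bad <- c(bad, sprintf("%s points must be non-increasing in positivity", m))
  }
  for (m in c("HER2", "Ki67")) {
    p <- table$marker_points[[m]]
    if (p["zero"] > p["low"] || p["low"] > p["high"])
      bad <- c(bad, sprintf("%s points must be non-decreasing in positivity", m))
  }
  maxima <- vapply(table$marker_points, max, numeric(1))
  if (any(maxima[names(maxima) != "ER"] > maxima["ER"]))
    bad <- c(bad, "ER must carry the maximum marker weight (overweighting)")
  if (max_score(table) != 16)
    bad <- c(bad, sprintf("maximum total score is %g, expected 16", max_score(table)))
  cb <- table$category_bounds
  if (!(cb["low"] >= 0 && cb["low"] < cb["intermediate"] && cb["intermediate"] < max_score(table)))
    bad <- c(bad, "category bounds must satisfy 0 <= low < intermediate < max score")
  unname(bad)
}
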