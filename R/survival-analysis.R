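#' Build survival records
#'
#' @param time Positive follow-up times in months.
#' @param event Logical event indicator (`TRUE` = progression/death observed).
#' @param group Group label per record (CTC dichotomy or index category).
#' @param patient_id Optional identifiers.
#' @return Data frame of class `surv_records`.
#' @export
surv_records <- function(time, event, group, patient_id = NULL) {
  if (length(time) == 0) stop("at least one survival record is required", call. = FALSE)
  if (anyNA(time) || any(time <= 0)) stop("survival times must be > 0", call. = FALSE)
  group <- as.character(group)
  if (anyNA(group) || any(!nzchar(group))) stop("group labels must be non-empty", call. = FALSE)
  out <- data.frame(
    patient_id = if (is.null(patient_id)) sprintf("r%d", seq_along(time)) else patient_id,
    time = as.numeric(time), event = as.logical(event), group = group,
    stringsAsFactors = FALSE)
  class(out) <- c("surv_records", "data.frame")
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' Ties between events and censorings at the same time are resolved events
#' first (the censored record is still at risk at the event time).
#'
#' @param records A [surv_records()] data frame (or anything with `time` and
#'   `event` columns).
#' @return Object of class `km_curve`: data frame of the distinct observed
#'   times with `n_risk`, `n_event`, `n_censor` and the survival estimate.
#' @export
km_estimate <- function(records) {
  if (NROW(records) == 0) stop("at least one survival record is required", call. = FALSE)
  tt <- sort(unique(records$time))
  n_risk <- vapply(tt, function(t) sum(records$time >= t), numeric(1))
  n_event <- vapply(tt, function(t) sum(records$time == t & records$event), numeric(1))
  n_censor <- vapply(tt, function(t) sum(records$time == t & !records$event), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = tt, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv),
            class = c("km_curve", "data.frame"))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d distinct times, %g events, median %s months\n",
              nrow(x), sum(x$n_event),
              if (is.na(km_median(x))) "not reached" else format(km_median(x))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Median survival time from a Kaplan-Meier curve
#'
#' @param curve A `km_curve`.
#' @return Smallest time at which the survival estimate is <= 0.5, or `NA`
#'   if the curve never reaches 0.5 (median not reached).
#' @export
km_median <- function(curve) {
  hit <- which(curve$surv <= 0.5 + 1e-12)
  if (!length(hit)) NA_real_ else curve$time[hit[1]]
}

# Per-event-time observed/expected/covariance bookkeeping shared by the
# k-sample logrank and the score-weighted trend statistic.
logrank_moments <- function(records, groups) {
  k <- length(groups)
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  g <- match(records$group, groups)
  for (t in sort(unique(records$time[records$event]))) {
    at_risk <- records$time >= t
    n_j <- sum(at_risk)
    d_j <- sum(records$time == t & records$event)
    n_ij <- vapply(seq_len(k), function(i) sum(at_risk & g == i), numeric(1))
    d_ij <- vapply(seq_len(k), function(i)
      sum(records$time == t & records$event & g == i), numeric(1))
    O <- O + d_ij
    E <- E + d_j * n_ij / n_j
    if (n_j > 1) {
      p <- n_ij / n_j
      V <- V + d_j * (n_j - d_j) / (n_j - 1) * (diag(p, k) - outer(p, p))
    }
  }
  list(O = O, E = E, V = V, groups = groups)
}

#' k-sample logrank test
#'
#' Standard observed-minus-expected chi-square logrank statistic on k - 1
#' degrees of freedom. For small instances an exact permutation p-value
#' (group labels permuted, statistic recomputed) is available.
#'
#' @param records A [surv_records()] data frame with >= 2 groups.
#' @param p_method `"chisq"` (default) or `"permutation"`.
#' @param n_perm Number of label permutations when `p_method = "permutation"`.
#' @param seed Seed for the permutation draw.
#' @return List with `statistic`, `df`, `p`, and the per-group
#'   observed/expected table.
#' @export
logrank_test <- function(records, p_method = c("chisq", "permutation"),
                         n_perm = 10000, seed = 1L) {
  p_method <- match.arg(p_method)
  groups <- sort(unique(records$group))
  k <- length(groups)
  if (k < 2) stop("logrank test needs at least two groups", call. = FALSE)
  if (any(table(factor(records$group, groups)) == 0))
    stop("every group must be non-empty", call. = FALSE)
  mom <- logrank_moments(records, groups)
  stat <- logrank_stat_from_moments(mom)
  p <- if (sum(mom$O) == 0) 1 else stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  if (p_method == "permutation") {
    obs <- stat
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      perm <- records
      perm$group <- sample(records$group)
      if (logrank_stat_from_moments(logrank_moments(perm, groups)) >= obs - 1e-12)
        hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  list(statistic = stat, df = k - 1, p = p,
       table = data.frame(group = groups, observed = mom$O, expected = mom$E))
}

logrank_stat_from_moments <- function(mom) {
  k <- length(mom$groups)
  if (sum(mom$O) == 0) return(0)
  d <- (mom$O - mom$E)[-k]
  Vsub <- mom$V[-k, -k, drop = FALSE]
  qr_v <- qr(Vsub)
  if (qr_v$rank < ncol(Vsub)) {
    # degenerate covariance (e.g. a single event): fall back to a
    # generalized inverse so the statistic stays defined
    sv <- svd(Vsub)
    pos <- sv$d > max(sv$d) * 1e-10
    inv <- sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
      t(sv$u[, pos, drop = FALSE])
    return(drop(t(d) %*% inv %*% d))
  }
  drop(t(d) %*% solve(Vsub, d))
}

#' Score-weighted logrank trend test over ordered groups
#'
#' The conventional one-degree-of-freedom trend statistic: the score-weighted
#' sum of observed-minus-expected event counts standardized by its
#' hypergeometric variance. The signed z statistic is returned so direction
#' is visible; the k-group heterogeneity logrank (k - 1 df) over the same
#' groups is reported alongside, covering the alternative reading of a
#' "trend test with 2 degrees of freedom" for three groups.
#'
#' @param records A [surv_records()] data frame with >= 3 groups.
#' @param group_order Ordered group labels, lowest first.
#' @param scores Numeric scores per ordered group (default `0, 1, 2, ...`).
#' @return List with `z`, `statistic` (z squared, 1 df), `p` (two-sided),
#'   `heterogeneity` (the k-group logrank result).
#' @export
trend_test_survival <- function(records, group_order = sort(unique(records$group)),
                                scores = seq_along(group_order) - 1) {
  k <- length(group_order)
  if (k < 3) stop("trend test needs at least three ordered groups", call. = FALSE)
  if (!setequal(group_order, unique(records$group)))
    stop("`group_order` must list exactly the groups present", call. = FALSE)
  mom <- logrank_moments(records, group_order)
  u <- sum(scores * (mom$O - mom$E))
  v <- drop(t(scores) %*% mom$V %*% scores)
  z <- if (v <= 0) 0 else u / sqrt(v)
  list(z = z, statistic = z^2,
       p = if (v <= 0) 1 else 2 * stats::pnorm(-abs(z)),
       heterogeneity = logrank_test(records))
}

#' Re-anchor a scored cohort at a follow-up visit (landmark analysis)
#'
#' Restricts to patients who have a usable scored sample at the landmark
#' visit and are still progression free (and uncensored) strictly beyond the
#' sample time, then measures survival from the sample date: re-anchored
#' time = original PFS time minus the visit time. Patients whose PFS time
#' falls on or before the sample date are excluded, as are visits whose
#' sample failed or whose index could not be determined when grouping by
#' category requires it.
#'
#' @param scored Cohort table already run through [score_cohort()].
#' @param visit Visit label (e.g. `"M1"`).
#' @param landmark_time Months of the landmark; defaults to the visit time
#'   in the generating configuration's schedule (1 / 2 / 3 / 12).
#' @param classifier Either `"elevated"` (CTC dichotomy `">=5"` / `"<5"`) or
#'   `"eti_category"`, or a function of the visit-row data frame returning a
#'   label per row (`NA` excludes the row).
#' @return A [surv_records()] data frame with attribute `exclusions`
#'   (counts of patients dropped for each reason).
#' @export
build_landmark <- function(scored, visit, landmark_time = NULL,
                           classifier = c("elevated", "eti_category")) {
  if (is.character(classifier)) {
    classifier <- match.arg(classifier)
    fn <- switch(classifier,
                 elevated = function(df) ifelse(df$elevated, ">=5", "<5"),
                 eti_category = function(df) df$eti_category)
  } else fn <- classifier
  if (is.null(landmark_time)) {
    cfg <- attr(scored, "config")
    landmark_time <- if (!is.null(cfg)) cfg$visit_schedule[[visit]] else
      stop("`landmark_time` must be given when the cohort carries no config",
           call. = FALSE)
  }
  all_ids <- unique(scored$patient_id)
  rows <- scored[scored$visit == visit & scored$status == "ok", , drop = FALSE]
  no_sample <- length(all_ids) - nrow(rows)
  lab <- fn(rows)
  undet <- is.na(lab)
  rows <- rows[!undet, , drop = FALSE]
  lab <- lab[!undet]
  # progression-free strictly beyond the sample date: zero or negative
  # re-anchored times cannot contribute
  alive <- rows$pfs_months > landmark_time
  excl <- list(no_sample = no_sample, undetermined = sum(undet),
               progressed_by_landmark = sum(!alive))
  rows <- rows[alive, , drop = FALSE]
  out <- surv_records(rows$pfs_months - landmark_time, rows$pfs_event,
                      lab[alive], rows$patient_id)
  attr(out, "exclusions") <- excl
  out
}

#' Four-way CTC change category between baseline and a follow-up sample
#'
#' @param baseline_elevated,followup_elevated Logical flags: average CTC
#'   >= 5/7.5 ml WB at baseline / at the follow-up sample.
#' @return Factor with levels `low`, `decrease`, `increase`, `high`:
#'   `low` = below 5 at both, `decrease` = elevated only at baseline,
#'   `increase` = elevated only at follow-up, `high` = elevated at both.
#' @export
ctc_change_category <- function(baseline_elevated, followup_elevated) {
  if (anyNA(baseline_elevated) || anyNA(followup_elevated))
    stop("elevation flags must be defined (not NA)", call. = FALSE)
  factor(ifelse(baseline_elevated,
                ifelse(followup_elevated, "high", "decrease"),
                ifelse(followup_elevated, "increase", "low")),
         levels = c("low", "decrease", "increase", "high"))
}
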