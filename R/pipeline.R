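#' Run the full analysis pipeline on a simulated or supplied cohort
#'
#' Executes the stages end to end: simulate (or load) the patient-visit
#' table, score every sample with the index, run the baseline and landmark
#' survival analyses (CTC dichotomy and index category), derive
#' rapid-progression status and the exact categorical statistics per visit,
#' compute the two-stage design operating characteristics, and optionally
#' run the retraining ensemble on the eligible baseline records. Every
#' stochastic stage flows from `seed`, so repeated runs of the same
#' configuration are identical.
#'
#' @param config A [cohort_config()], or `NULL` when `cohort` is supplied.
#' @param cohort Optional pre-built cohort table (as from [read_cohort()]).
#' @param table A [point_table()].
#' @param landmarks Follow-up visits to analyze as landmarks.
#' @param retrain `FALSE`, or a [retrain_config()] whose `train_n + val_n`
#'   will be adapted to the eligible cohort size (set `retrain = FALSE` to
#'   skip the stage).
#' @param seed Overrides `config$seed` when given.
#' @param out Optional directory: the report is written there as
#'   `report.json` plus the scored cohort CSV.
#' @return A nested list report (class `eti_report`).
#' @export
run_pipeline <- function(config = cohort_config(), cohort = NULL,
                         table = default_point_table(),
                         landmarks = c("M1", "M2", "M3"),
                         retrain = retrain_config(), seed = NULL, out = NULL) {
  stage <- "configure"
  report <- list()
  tryCatch({
    if (!is.null(seed) && !is.null(config)) config$seed <- as.integer(seed)
    stage <- "simulate"
    if (is.null(cohort)) cohort <- simulate_cohort(config)
    stage <- "score"
    scored <- score_cohort(cohort, table)
    report$seed <- if (!is.null(config)) config$seed else seed
    report$n_patients <- length(unique(scored$patient_id))
    report$category_by_visit <- category_tabulation(scored)

    stage <- "survival"
    base <- scored[scored$visit == "BL" & scored$status == "ok", , drop = FALSE]
    report$survival <- list(
      baseline_ctc = survival_section(base, "elevated"),
      baseline_eti = survival_section(base, "eti_category"))
    for (v in intersect(landmarks, unique(scored$visit))) {
      report$survival[[paste0("landmark_", v)]] <- list(
        ctc = landmark_section(scored, v, "elevated"),
        eti = landmark_section(scored, v, "eti_category"))
    }

    stage <- "rp"
    report$rp <- list(baseline_ctc = rp_section(scored, "BL", "elevated"),
                      baseline_eti = rp_section(scored, "BL", "eti_category"))
    for (v in intersect(landmarks, unique(scored$visit)))
      report$rp[[paste0("eti_", v)]] <- rp_section(scored, v, "eti_category")

    stage <- "design"
    d <- stage_design()
    report$design <- list(n = d$n, cutoff = d$cutoff,
                          alpha = stage_alpha(d), beta = stage_beta(d))

    stage <- "retrain"
    if (!isFALSE(retrain)) {
      elig <- eligible_records(scored)
      if (nrow(elig) >= 8 && length(unique(elig$rp)) == 2) {
        retrain$val_n <- max(1L, round(nrow(elig) * retrain$val_n /
                                         (retrain$train_n + retrain$val_n)))
        retrain$train_n <- nrow(elig) - retrain$val_n
        ens <- ensemble_validate(elig, retrain)
        report$retrain <- list(
          n_eligible = nrow(elig), n_rp = sum(elig$rp), auc = ens$auc,
          importance_tally = as.list(ens$importance_tally),
          probabilities = ens$probabilities)
      } else {
        report$retrain <- list(n_eligible = nrow(elig),
                               note = "too few eligible or single-class outcome; ensemble skipped")
      }
    }
    class(report) <- "eti_report"
    if (!is.null(out)) {
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_cohort(scored, file.path(out, "scored_cohort.csv"))
      jsonlite::write_json(strip_classes(report), file.path(out, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
    }
    report
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

category_tabulation <- function(scored) {
  out <- list()
  for (v in intersect(valid_visits, unique(scored$visit))) {
    rows <- scored[scored$visit == v, , drop = FALSE]
    det <- rows[rows$determined %in% TRUE, , drop = FALSE]
    out[[v]] <- list(
      n = nrow(rows), not_determined = sum(!rows$determined),
      low = sum(det$eti_category == "low"),
      intermediate = sum(det$eti_category == "intermediate"),
      high = sum(det$eti_category == "high"),
      elevated = sum(det$elevated))
  }
  out
}

group_records <- function(rows, classifier) {
  lab <- if (classifier == "elevated") ifelse(rows$elevated, ">=5", "<5") else rows$eti_category
  keep <- !is.na(lab) & rows$pfs_months > 0
  surv_records(rows$pfs_months[keep], rows$pfs_event[keep], lab[keep],
               rows$patient_id[keep])
}

survival_section <- function(rows, classifier) {
  rec <- group_records(rows, classifier)
  summarize_surv(rec)
}

landmark_section <- function(scored, visit, classifier) {
  rec <- build_landmark(scored, visit, classifier = classifier)
  c(summarize_surv(rec), list(exclusions = attr(rec, "exclusions")))
}

summarize_surv <- function(rec) {
  groups <- sort(unique(rec$group))
  medians <- lapply(groups, function(g) km_median(km_estimate(rec[rec$group == g, ])))
  names(medians) <- groups
  out <- list(n = nrow(rec), median_pfs = medians)
  if (length(groups) >= 2) {
    lr <- logrank_test(rec)
    out$logrank <- list(statistic = lr$statistic, df = lr$df, p = lr$p)
  }
  if (length(groups) >= 3 && all(c("low", "intermediate", "high") %in% groups)) {
    tr <- trend_test_survival(rec, group_order = c("low", "intermediate", "high"))
    out$trend <- list(z = tr$z, p = tr$p)
  }
  out
}

rp_section <- function(scored, visit, classifier) {
  res <- rp_by_group(scored, visit, classifier)
  list(
    n_assessable = res$n_assessable,
    table = as.list(as.data.frame.matrix(res$table)),
    rp_pct_ci = lapply(res$cis, function(ci) as.list(ci$percent)),
    fisher_rxc_p = res$fisher_rxc,
    fisher_high_low_p = if (is.null(res$fisher_high_low)) NULL else res$fisher_high_low$p,
    trend_p = if (is.null(res$trend)) NULL else res$trend$p,
    degenerate = if (nrow(res$table[rowSums(res$table) > 0, , drop = FALSE]) < 2)
      "all assessable patients fall in one category" else NULL)
}

#' @export
print.eti_report <- function(x, ...) {
  cat("CTC-ETI pipeline report\n")
  cat(sprintf("  %d patients, seed %s\n", x$n_patients, format(x$seed)))
  bl <- x$category_by_visit$BL
  if (!is.null(bl))
    cat(sprintf("  baseline: %d low / %d intermediate / %d high (%d not determined)\n",
                bl$low, bl$intermediate, bl$high, bl$not_determined))
  if (!is.null(x$survival$baseline_ctc$logrank))
    cat(sprintf("  baseline CTC logrank p = %.4g\n", x$survival$baseline_ctc$logrank$p))
  if (!is.null(x$rp$baseline_eti$fisher_high_low_p))
    cat(sprintf("  RP high-vs-low index Fisher p = %.4g\n", x$rp$baseline_eti$fisher_high_low_p))
  if (!is.null(x$retrain$auc))
    cat(sprintf("  retraining AUC = %.3f (%d eligible)\n", x$retrain$auc, x$retrain$n_eligible))
  invisible(x)
}
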