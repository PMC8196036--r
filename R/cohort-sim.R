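#' Configuration of the synthetic monitoring cohort
#'
#' Defines the statistical structure of a simulated endocrine-therapy
#' monitoring cohort: baseline prevalence of elevated CTC, the visit
#' schedule, per-aliquot count dispersion, latent-state-conditional marker
#' distributions, category-dependent progression-free survival (PFS)
#' medians, administrative censoring, visit missingness and the 3-month
#' reimaging mechanism that determines rapid-progression assessability.
#'
#' The generative model: each patient is either elevated (average baseline
#' CTC >= 5/7.5 ml WB) with probability `baseline_elevated_prev` or not.
#' Elevated patients draw a patient-level mean count `lambda` from a shifted
#' log-normal (5 + lognormal(meanlog, sdlog)); non-elevated patients are
#' zero-inflated with a small uniform mean. The four aliquot counts are
#' conditionally Poisson(lambda) -- only four replicate counts exist per
#' draw, and downstream analysis averages them, so a two-level
#' Poisson-mixing model is as much structure as the data can identify. A
#' latent endocrine-resistance state (more likely when CTC are elevated)
#' sets the Beta priors from which percent-positive marker values are
#' drawn, with marker-specific point mass at exactly 0%. PFS is exponential
#' with the median configured for the patient's baseline index category and
#' is administratively censored at `censor_horizon`. Elevation evolves over
#' follow-up visits by a two-state Markov chain (resistant patients tend to
#' stay elevated; sensitive patients tend to clear), reproducing the
#' declining prevalence of elevated CTC under therapy.
#'
#' @param n_patients Number of patients (default 120, the trial's design size).
#' @param baseline_elevated_prev Probability of elevated CTC at baseline
#'   (default 0.36).
#' @param visit_schedule Named numeric vector of visit times in months.
#' @param lambda_meanlog,lambda_sdlog Log-normal parameters of the elevated
#'   patients' mean count above the threshold of 5.
#' @param zero_inflation Probability a non-elevated patient's mean count is 0.
#' @param low_lambda_max Upper bound of the uniform mean for non-elevated,
#'   non-zero patients.
#' @param resistant_prob Named probabilities of the latent resistant state
#'   given baseline elevation status.
#' @param marker_priors Nested list `state -> marker -> c(zero, shape1,
#'   shape2)`: point mass at 0% and Beta parameters of the positive part.
#' @param retain_elevation Named per-state probability that an elevated
#'   patient is still elevated at the next visit.
#' @param gain_elevation Probability a non-elevated patient becomes elevated
#'   at the next visit.
#' @param median_pfs_by_category Named PFS medians (months) per baseline
#'   index category (defaults 6.9 / 8.5 / 2.8).
#' @param censor_horizon Administrative censoring time in months (12).
#' @param visit_missingness Named per-follow-up-visit probability that the
#'   sample is missing.
#' @param status_error_prob Probability a drawn sample is unusable
#'   (quantity-not-sufficient / pre-analytic / technical failure).
#' @param death_frac Probability a PFS event is a death rather than
#'   radiographic progression.
#' @param death_mbc_frac Probability such a death is due to metastatic
#'   breast cancer.
#' @param reimaging_missing_prob Probability the 3-month reimaging needed to
#'   assess rapid progression is unavailable.
#' @param seed Integer seed; every draw in [simulate_cohort()] flows from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 120,
                          baseline_elevated_prev = 0.36,
                          visit_schedule = c(BL = 0, M1 = 1, M2 = 2, M3 = 3, M12 = 12),
                          lambda_meanlog = log(15), lambda_sdlog = 1,
                          zero_inflation = 0.5, low_lambda_max = 1.5,
                          resistant_prob = c(non_elevated = 0.2, elevated = 0.7),
                          marker_priors = default_marker_priors(),
                          retain_elevation = c(sensitive = 0.45, resistant = 0.9),
                          gain_elevation = 0.02,
                          median_pfs_by_category = c(low = 6.9, intermediate = 8.5, high = 2.8),
                          censor_horizon = 12,
                          visit_missingness = c(M1 = 0.05, M2 = 0.05, M3 = 0.05, M12 = 0.45),
                          status_error_prob = 0.02,
                          death_frac = 0.15, death_mbc_frac = 0.8,
                          reimaging_missing_prob = 0.11,
                          seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

default_marker_priors <- function() {
  list(
    sensitive = list(ER   = c(zero = 0.05, shape1 = 4, shape2 = 2),
                     BCL2 = c(zero = 0.10, shape1 = 3, shape2 = 2),
                     HER2 = c(zero = 0.50, shape1 = 1, shape2 = 9),
                     Ki67 = c(zero = 0.40, shape1 = 1, shape2 = 6)),
    resistant = list(ER   = c(zero = 0.40, shape1 = 1, shape2 = 4),
                     BCL2 = c(zero = 0.30, shape1 = 1, shape2 = 4),
                     HER2 = c(zero = 0.20, shape1 = 2, shape2 = 4),
                     Ki67 = c(zero = 0.05, shape1 = 4, shape2 = 2)))
}

validate_cohort_config <- function(cfg) {
  chk_prob <- function(x, field) {
    if (anyNA(x) || any(x < 0) || any(x > 1))
      stop(sprintf("invalid cohort_config: `%s` must be a probability in [0, 1]", field),
           call. = FALSE)
  }
  if (length(cfg$n_patients) != 1 || is.na(cfg$n_patients) || cfg$n_patients < 1)
    stop("invalid cohort_config: `n_patients` must be >= 1", call. = FALSE)
  chk_prob(cfg$baseline_elevated_prev, "baseline_elevated_prev")
  chk_prob(cfg$zero_inflation, "zero_inflation")
  chk_prob(cfg$resistant_prob, "resistant_prob")
  chk_prob(cfg$retain_elevation, "retain_elevation")
  chk_prob(cfg$gain_elevation, "gain_elevation")
  chk_prob(cfg$visit_missingness, "visit_missingness")
  chk_prob(cfg$status_error_prob, "status_error_prob")
  chk_prob(cfg$reimaging_missing_prob, "reimaging_missing_prob")
  if (any(cfg$median_pfs_by_category <= 0))
    stop("invalid cohort_config: `median_pfs_by_category` medians must be > 0",
         call. = FALSE)
  if (is.unsorted(cfg$visit_schedule, strictly = TRUE) || cfg$visit_schedule[1] != 0)
    stop("invalid cohort_config: `visit_schedule` times must be strictly increasing from 0",
         call. = FALSE)
  if (cfg$censor_horizon <= 0)
    stop("invalid cohort_config: `censor_horizon` must be > 0", call. = FALSE)
  invisible(cfg)
}

draw_markers <- function(n, state, priors) {
  out <- matrix(NA_real_, n, 4, dimnames = list(NULL, c("ER", "BCL2", "HER2", "Ki67")))
  for (m in colnames(out)) {
    pr <- t(vapply(state, function(s) priors[[s]][[m]], numeric(3)))
    zero <- stats::runif(n) < pr[, "zero"]
    pct <- 100 * stats::rbeta(n, pr[, "shape1"], pr[, "shape2"])
    # positive part must land in the 1-10% or >10% staining categories
    out[, m] <- ifelse(zero, 0, pmax(pct, 0.1))
  }
  out
}

draw_lambda <- function(elevated, cfg) {
  n <- length(elevated)
  lam <- numeric(n)
  ne <- sum(elevated)
  if (ne > 0)
    lam[elevated] <- 5 + stats::rlnorm(ne, cfg$lambda_meanlog, cfg$lambda_sdlog)
  if (ne < n) {
    nn <- n - ne
    zero <- stats::runif(nn) < cfg$zero_inflation
    lam[!elevated] <- ifelse(zero, 0, stats::runif(nn, 0, cfg$low_lambda_max))
  }
  lam
}

#' Simulate a synthetic monitoring cohort
#'
#' Generates one patient-visit table with the layout of [cohort_columns()]:
#' four aliquot CTC counts, four percent-positive marker values (empty when
#' the count is below the phenotyping threshold of 5), sample status, PFS
#' time and event indicators, and rapid-progression assessability. The
#' output is deterministic given `config$seed`. Baseline samples are always
#' drawn; follow-up samples exist only while the patient is on study
#' (strictly before progression/censoring) and are then thinned by
#' [apply_visit_missingness()] if requested.
#'
#' @param config A [cohort_config()].
#' @param missingness Apply the configured per-visit missingness (default
#'   `TRUE`); set to `FALSE` to keep every on-study sample.
#' @return Data frame, one row per patient-visit, with attribute `config`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_patients = 50, seed = 7))
#' table(coh$visit)
#' @export
simulate_cohort <- function(config = cohort_config(), missingness = TRUE) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  sched <- config$visit_schedule
  pt_table <- default_point_table()

  elevated <- stats::runif(n) < config$baseline_elevated_prev
  state <- ifelse(stats::runif(n) <
                    config$resistant_prob[ifelse(elevated, "elevated", "non_elevated")],
                  "resistant", "sensitive")
  lambda <- draw_lambda(elevated, config)
  counts <- matrix(stats::rpois(4L * n, rep(lambda, each = 4L)), ncol = 4L, byrow = TRUE)
  markers <- draw_markers(n, state, config$marker_priors)

  # baseline index category fixes the patient's PFS hazard
  base_cat <- vapply(seq_len(n), function(i) {
    as.character(compute_eti(counts[i, ], markers[i, ], table = pt_table)$category)
  }, character(1))
  med <- config$median_pfs_by_category[base_cat]
  raw_t <- stats::rexp(n, rate = log(2) / med)
  pfs_event <- raw_t <= config$censor_horizon
  pfs_time <- pmin(raw_t, config$censor_horizon)
  is_death <- pfs_event & stats::runif(n) < config$death_frac
  death_mbc <- is_death & stats::runif(n) < config$death_mbc_frac
  event_type <- ifelse(!pfs_event, "none", ifelse(is_death, "death", "progression"))
  reimaged <- stats::runif(n) >= config$reimaging_missing_prob

  rows <- list()
  elev_now <- elevated
  for (v in names(sched)) {
    tv <- sched[[v]]
    if (tv > 0) {
      # elevation evolves between visits; counts and markers are redrawn
      retain <- config$retain_elevation[ifelse(state == "resistant", "resistant", "sensitive")]
      elev_now <- ifelse(elev_now, stats::runif(n) < retain,
                         stats::runif(n) < config$gain_elevation)
      lambda <- draw_lambda(elev_now, config)
      counts <- matrix(stats::rpois(4L * n, rep(lambda, each = 4L)), ncol = 4L, byrow = TRUE)
      markers <- draw_markers(n, state, config$marker_priors)
    }
    status <- ifelse(stats::runif(n) < config$status_error_prob,
                     sample(c("qns", "preanalytic_error", "technical_failure"),
                            n, replace = TRUE), "ok")
    # progressed patients give no sample on/after the event; patients still
    # on study at the horizon contribute the end-of-study draw
    on_study <- if (tv == 0) rep(TRUE, n) else
      (pfs_time > tv) | (!pfs_event & pfs_time >= tv)
    keep <- which(on_study)
    if (!length(keep)) next
    avg4 <- rowMeans(counts[keep, , drop = FALSE])
    show_mk <- round_half_up(avg4) >= 5
    mk <- markers[keep, , drop = FALSE]
    mk[!show_mk, ] <- NA_real_
    rows[[v]] <- data.frame(
      patient_id = sprintf("P%04d", keep), visit = v,
      aliquot1 = counts[keep, 1], aliquot2 = counts[keep, 2],
      aliquot3 = counts[keep, 3], aliquot4 = counts[keep, 4],
      pct_er = mk[, "ER"], pct_bcl2 = mk[, "BCL2"],
      pct_her2 = mk[, "HER2"], pct_ki67 = mk[, "Ki67"],
      status = status[keep], pfs_months = pfs_time[keep],
      pfs_event = pfs_event[keep], event_type = event_type[keep],
      death_mbc = death_mbc[keep], reimaged_3mo = reimaged[keep],
      latent_state = state[keep], stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, rows)
  cohort <- cohort[order(cohort$patient_id,
                         match(cohort$visit, names(sched))), , drop = FALSE]
  rownames(cohort) <- NULL
  attr(cohort, "config") <- config
  if (missingness) cohort <- apply_visit_missingness(cohort, config)
  cohort
}

#' Thin follow-up samples by the configured missingness
#'
#' Removes each follow-up patient-visit row independently with the per-visit
#' probability in `config$visit_missingness`; baseline rows are never
#' removed. Draws are taken from the current RNG state, so calling this
#' inside [simulate_cohort()] keeps the whole cohort a deterministic
#' function of the seed.
#'
#' @param cohort Patient-visit data frame.
#' @param config A [cohort_config()].
#' @return The thinned cohort.
#' @export
apply_visit_missingness <- function(cohort, config) {
  drop <- rep(FALSE, nrow(cohort))
  for (v in names(config$visit_missingness)) {
    at <- which(cohort$visit == v)
    if (length(at))
      drop[at] <- stats::runif(length(at)) < config$visit_missingness[[v]]
  }
  out <- cohort[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- attr(cohort, "config")
  out
}

#' Collapse a cohort table to one row per patient
#'
#' @param cohort Patient-visit data frame.
#' @return Data frame of the patient-level outcome fields.
#' @export
patient_outcomes <- function(cohort) {
  first <- cohort[!duplicated(cohort$patient_id), , drop = FALSE]
  out <- first[, c("patient_id", "pfs_months", "pfs_event", "event_type",
                   "death_mbc", "reimaged_3mo")]
  rownames(out) <- NULL
  out
}
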