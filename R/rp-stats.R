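#' Rapid-progression status of one patient
#'
#' Rapid progression (RP) is objective radiographic progression, or death
#' due to metastatic breast cancer, within 3 months of the baseline sample.
#' A patient with neither qualifying event by 3 months can only be scored
#' RP-negative if the 3-month reimaging was performed; otherwise the status
#' is unassessable and the patient is omitted from RP analyses.
#'
#' @param pfs_months PFS time in months.
#' @param pfs_event Logical: was progression/death observed.
#' @param event_type `"progression"`, `"death"` or `"none"`.
#' @param death_mbc Logical: for a death, was it due to metastatic breast
#'   cancer.
#' @param reimaged_3mo Logical: was the 3-month reimaging available.
#' @param window Months defining "rapid" (default 3).
#' @return Character vector: `"rp"`, `"no_rp"` or `"unassessable"`.
#' @export
rp_status <- function(pfs_months, pfs_event, event_type, death_mbc,
                      reimaged_3mo, window = 3.0) {
  qualifying <- pfs_event & pfs_months <= window &
    (event_type == "progression" | (event_type == "death" & death_mbc))
  ifelse(qualifying, "rp", ifelse(reimaged_3mo, "no_rp", "unassessable"))
}

#' Derive per-patient RP status for a cohort table
#'
#' @param cohort Patient-visit data frame with the outcome columns.
#' @param window Months defining "rapid" (default 3).
#' @return [patient_outcomes()] table with an `rp` column appended.
#' @export
cohort_rp_status <- function(cohort, window = 3.0) {
  po <- patient_outcomes(cohort)
  po$rp <- rp_status(po$pfs_months, po$pfs_event, po$event_type,
                     po$death_mbc, po$reimaged_3mo, window)
  po
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact conditional test with the probability-mass two-sided rule: the
#' p-value sums the hypergeometric probabilities of all tables with the
#' observed margins that are no more probable than the observed one. The
#' conditional maximum-likelihood odds ratio is reported.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return List with `odds_ratio` and `p` (two-sided). A zero margin gives
#'   `p = 1` and an undefined (`NA`) odds ratio.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(odds_ratio = NA_real_, p = 1))
  ft <- stats::fisher.test(table)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Two-sided exact test for an r x c table (Freeman-Halton)
#'
#' Exact conditional p-value over all tables with the observed margins,
#' as the generalization of Fisher's 2x2 test to larger tables.
#'
#' @param table r x c matrix of non-negative counts.
#' @param workspace Passed to [stats::fisher.test()]; raised for larger
#'   tables before giving up.
#' @return Two-sided p-value.
#' @export
fisher_exact_rxc <- function(table, workspace = 2e6) {
  table <- as.matrix(table)
  stopifnot(nrow(table) >= 2, ncol(table) >= 2, all(table >= 0))
  keep_r <- rowSums(table) > 0
  keep_c <- colSums(table) > 0
  table <- table[keep_r, keep_c, drop = FALSE]
  if (nrow(table) < 2 || ncol(table) < 2) return(1)
  stats::fisher.test(table, workspace = workspace)$p.value
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Central exact interval from Beta quantiles:
#' lower = qbeta(alpha/2; x, n - x + 1), upper = qbeta(1 - alpha/2; x + 1,
#' n - x), with the conventional endpoints 0 at x = 0 and 1 at x = n.
#'
#' @param successes,trials Non-negative integers, `successes <= trials`.
#' @param level Confidence level (default 0.95).
#' @return List of class `binomial_ci` with `successes`, `trials`,
#'   `estimate`, `lower`, `upper`, `level`, and `percent` -- the half-up
#'   rounded integer percent bounds used for reporting.
#' @examples
#' clopper_pearson(19, 24)  # 79%, 95% CI 58-93%
#' @export
clopper_pearson <- function(successes, trials, level = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials)
    stop("need 0 <= successes <= trials with trials >= 1", call. = FALSE)
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else stats::qbeta(alpha / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  structure(
    list(successes = successes, trials = trials,
         estimate = successes / trials, lower = lower, upper = upper,
         level = level,
         percent = c(estimate = round_half_up(100 * successes / trials),
                     lower = round_half_up(100 * lower),
                     upper = round_half_up(100 * upper))),
    class = "binomial_ci")
}

#' @export
print.binomial_ci <- function(x, ...) {
  cat(sprintf("%d/%d [%d%% (%d%% CI %d-%d%%)]\n", x$successes, x$trials,
              x$percent["estimate"], round(100 * x$level),
              x$percent["lower"], x$percent["upper"]))
  invisible(x)
}

#' Cochran-Armitage trend test for proportions over ordered categories
#'
#' Signed z statistic for a linear trend in success proportions across
#' ordered groups, with the two-sided normal p-value. The chi-square form
#' (z squared on 1 df) equals the classical score test for trend.
#'
#' @param successes,trials Integer vectors per ordered category (>= 3).
#' @param scores Numeric category scores (default `0, 1, 2, ...`).
#' @param p_method `"normal"` (default) or `"permutation"` (exact null via
#'   label permutation at the individual level).
#' @param n_perm,seed Permutation controls.
#' @return List with `z`, `statistic`, `p`.
#' @export
trend_test_proportions <- function(successes, trials,
                                   scores = seq_along(successes) - 1,
                                   p_method = c("normal", "permutation"),
                                   n_perm = 10000, seed = 1L) {
  p_method <- match.arg(p_method)
  k <- length(successes)
  if (k < 3) stop("trend test needs at least three ordered categories", call. = FALSE)
  stopifnot(length(trials) == k, length(scores) == k,
            all(successes >= 0), all(successes <= trials))
  z <- ca_z(successes, trials, scores)
  p <- if (is.na(z)) 1 else 2 * stats::pnorm(-abs(z))
  if (p_method == "permutation") {
    set.seed(seed)
    grp <- rep(seq_len(k), trials)
    x <- rep(rep(c(1L, 0L), k), as.vector(rbind(successes, trials - successes)))
    obs <- abs(z)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      xs <- sample(x)
      sp <- vapply(seq_len(k), function(i) sum(xs[grp == i]), numeric(1))
      zb <- ca_z(sp, trials, scores)
      if (!is.na(zb) && abs(zb) >= obs - 1e-12) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  list(z = if (is.na(z)) 0 else z, statistic = if (is.na(z)) 0 else z^2, p = p)
}

ca_z <- function(successes, trials, scores) {
  N <- sum(trials)
  pbar <- sum(successes) / N
  if (pbar <= 0 || pbar >= 1) return(NA_real_)
  u <- sum(scores * (successes - trials * pbar))
  v <- pbar * (1 - pbar) * (sum(trials * scores^2) - sum(trials * scores)^2 / N)
  if (v <= 0) return(NA_real_)
  u / sqrt(v)
}

#' Tabulate rapid progression against a grouping at one visit
#'
#' Builds the RP-by-group contingency table among assessable patients and
#' runs the headline statistics: the overall exact r x 2 test, the
#' high-vs-low 2x2 Fisher test when both extreme groups are present, a
#' Cochran-Armitage trend test for >= 3 groups, and a Clopper-Pearson
#' interval per group.
#'
#' @param scored Cohort run through [score_cohort()].
#' @param visit Visit label whose sample defines the grouping.
#' @param classifier `"elevated"` or `"eti_category"` (as in
#'   [build_landmark()]).
#' @param window RP window in months.
#' @return List with `table` (groups x rp/no_rp), `cis`, `fisher_rxc`,
#'   `fisher_high_low` (or NULL), `trend` (or NULL), `n_assessable`.
#' @export
rp_by_group <- function(scored, visit = "BL",
                        classifier = c("elevated", "eti_category"),
                        window = 3.0) {
  classifier <- match.arg(classifier)
  po <- cohort_rp_status(scored, window)
  rows <- scored[scored$visit == visit & scored$status == "ok", , drop = FALSE]
  rows <- merge(rows, po[, c("patient_id", "rp")], by = "patient_id")
  rows <- rows[rows$rp != "unassessable", , drop = FALSE]
  lab <- if (classifier == "elevated") ifelse(rows$elevated, ">=5", "<5") else rows$eti_category
  rows <- rows[!is.na(lab), , drop = FALSE]
  lab <- lab[!is.na(lab)]
  lv <- if (classifier == "elevated") c("<5", ">=5") else c("low", "intermediate", "high")
  lab <- factor(lab, levels = lv)
  tab <- table(group = lab, rp = factor(rows$rp, levels = c("rp", "no_rp")))
  present <- rowSums(tab) > 0
  cis <- lapply(rownames(tab)[present], function(gn)
    clopper_pearson(tab[gn, "rp"], sum(tab[gn, ])))
  names(cis) <- rownames(tab)[present]
  sub <- tab[present, , drop = FALSE]
  fisher_rxc_p <- if (nrow(sub) >= 2) fisher_exact_rxc(sub) else NA_real_
  hi_lo <- NULL
  if (all(c(lv[1], lv[length(lv)]) %in% rownames(sub))) {
    m2 <- tab[c(lv[length(lv)], lv[1]), , drop = FALSE]
    hi_lo <- fisher_exact_2x2(m2)
  }
  trend <- NULL
  if (nrow(sub) >= 3)
    trend <- trend_test_proportions(sub[, "rp"], rowSums(sub))
  list(table = tab, cis = cis, fisher_rxc = fisher_rxc_p,
       fisher_high_low = hi_lo, trend = trend, n_assessable = nrow(rows))
}
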