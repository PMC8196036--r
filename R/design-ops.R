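#' Two-stage exact binomial analytical-validity design
#'
#' Each stage observes `n` independent baseline assay attempts and rejects
#' the null hypothesis of an unacceptably low success rate (`p_null`) when
#' the number of successes reaches `cutoff`; otherwise the alternative of an
#' acceptable rate (`p_alt`) is rejected. The two stages are independent and
#' sequential, so each is characterized by its own exact binomial tails.
#'
#' @param n Attempts per stage (default 32).
#' @param cutoff Success threshold for rejecting the null (default 24).
#' @param p_null Success rate considered too low (default 0.60).
#' @param p_alt Desired success rate (default 0.80).
#' @return Object of class `stage_design`.
#' @export
stage_design <- function(n = 32, cutoff = 24, p_null = 0.60, p_alt = 0.80) {
  stopifnot(n >= 1, cutoff >= 0, cutoff <= n,
            p_null > 0, p_alt < 1, p_null < p_alt)
  structure(list(n = n, cutoff = cutoff, p_null = p_null, p_alt = p_alt),
            class = "stage_design")
}

#' @export
print.stage_design <- function(x, ...) {
  cat(sprintf("Exact binomial stage: reject p <= %.2f if successes >= %d/%d\n",
              x$p_null, x$cutoff, x$n))
  cat(sprintf("  alpha = %.4f (at p = %.2f), beta = %.4f (at p = %.2f)\n",
              stage_alpha(x), x$p_null, stage_beta(x), x$p_alt))
  invisible(x)
}

#' Type I error of one stage
#'
#' Exact upper binomial tail P(X >= cutoff) at the null success rate.
#'
#' @param design A [stage_design()].
#' @return Probability.
#' @examples
#' stage_alpha(stage_design())  # 0.057 at 24/32, p = 0.60
#' @export
stage_alpha <- function(design = stage_design()) {
  if (design$cutoff == 0) return(1)
  stats::pbinom(design$cutoff - 1, design$n, design$p_null, lower.tail = FALSE)
}

#' Type II error of one stage
#'
#' Exact lower binomial tail P(X <= cutoff - 1) at the alternative rate.
#'
#' @param design A [stage_design()].
#' @return Probability.
#' @examples
#' stage_beta(stage_design())  # 0.175 at 24/32, p = 0.80
#' @export
stage_beta <- function(design = stage_design()) {
  if (design$cutoff == 0) return(0)
  stats::pbinom(design$cutoff - 1, design$n, design$p_alt)
}

#' Smallest cutoff meeting the stage error targets
#'
#' @param n,p_null,p_alt As in [stage_design()].
#' @param alpha_target,beta_target Error probability targets in (0, 1).
#' @return The smallest cutoff whose exact alpha is within `alpha_target`
#'   and whose exact beta is within `beta_target`; `NA` if no cutoff
#'   satisfies both.
#' @export
find_cutoff <- function(n, p_null, p_alt, alpha_target, beta_target) {
  stopifnot(alpha_target > 0, alpha_target < 1, beta_target > 0, beta_target < 1)
  for (cutoff in 0:n) {
    d <- stage_design(n, cutoff, p_null, p_alt)
    if (stage_alpha(d) <= alpha_target) {
      return(if (stage_beta(d) <= beta_target) cutoff else NA_integer_)
    }
  }
  NA_integer_
}

#' Operating-characteristics table over all cutoffs
#'
#' @param n,p_null,p_alt As in [stage_design()].
#' @return Data frame with `cutoff`, `alpha`, `beta`.
#' @export
operating_characteristics <- function(n = 32, p_null = 0.60, p_alt = 0.80) {
  data.frame(
    cutoff = 0:n,
    alpha = vapply(0:n, function(co) stage_alpha(stage_design(n, co, p_null, p_alt)),
                   numeric(1)),
    beta = vapply(0:n, function(co) stage_beta(stage_design(n, co, p_null, p_alt)),
                  numeric(1)))
}

#' Simulated power of the exact three-category rapid-progression comparison
#'
#' Per replicate: draw the number of rapid progressors in each index
#' category as independent binomials at the configured category sizes and
#' RP probabilities, run the exact r x 2 (Freeman-Halton) test, and record
#' rejection at `alpha`. Power is the rejection fraction, with an exact
#' binomial Monte-Carlo confidence interval.
#'
#' @param n_total Total patients (default 120).
#' @param group_fracs Category allocation fractions (default 0.30 / 0.40 /
#'   0.30, giving sizes 36 / 48 / 36).
#' @param rp_probs RP probability per category (default 0.20 / 0.34 / 0.75).
#' @param alpha Two-sided significance level (default 0.05).
#' @param reps Replicates (>= 100; default 2000).
#' @param seed Integer seed.
#' @return List with `power`, `mc_ci` (95% Clopper-Pearson on the rejection
#'   fraction), `rejections`, `reps`, `group_sizes`.
#' @export
simulate_rp_power <- function(n_total = 120, group_fracs = c(0.30, 0.40, 0.30),
                              rp_probs = c(0.20, 0.34, 0.75), alpha = 0.05,
                              reps = 2000, seed = 1L) {
  stopifnot(abs(sum(group_fracs) - 1) < 1e-8, all(rp_probs > 0), all(rp_probs < 1),
            reps >= 100)
  sizes <- round_half_up(n_total * group_fracs)
  k <- length(sizes)
  set.seed(seed)
  rej <- 0L
  for (b in seq_len(reps)) {
    x <- stats::rbinom(k, sizes, rp_probs)
    tab <- cbind(rp = x, no_rp = sizes - x)
    if (fisher_exact_rxc(tab) < alpha) rej <- rej + 1L
  }
  ci <- clopper_pearson(rej, reps)
  list(power = rej / reps, mc_ci = c(lower = ci$lower, upper = ci$upper),
       rejections = rej, reps = reps, group_sizes = sizes)
}
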