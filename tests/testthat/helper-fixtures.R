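# Shared fixture builders and independent oracles used across the suite.

# Minimal scored-cohort-like table built by hand (bypasses the simulator) so
# landmark/RP bookkeeping can be checked against hand-computed expectations.
tiny_scored_cohort <- function() {
  df <- data.frame(
    patient_id = c("A", "A", "B", "C", "C", "D"),
    visit      = c("BL", "M1", "BL", "BL", "M1", "BL"),
    aliquot1 = 6, aliquot2 = 6, aliquot3 = 6, aliquot4 = 6,
    pct_er = 0, pct_bcl2 = 0, pct_her2 = 0, pct_ki67 = 0,
    status = "ok",
    pfs_months  = c(4, 4, 0.5, 8, 8, 2),
    pfs_event   = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    event_type  = c("progression", "progression", "progression", "none", "none", "death"),
    death_mbc   = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    reimaged_3mo = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  # patient B progresses before M1 (no M1 row); D has no M1 sample either
  sc <- score_cohort(df)
  attr(sc, "config") <- cohort_config(n_patients = 4)
  sc
}

# Exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables with the observed margins whose
# probability does not exceed the observed table's.
fisher_2x2_oracle <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exact two-sided p for an r x 2 table by full enumeration over all tables
# with the observed margins (multivariate hypergeometric probabilities).
fisher_rx2_oracle <- function(tab) {
  r <- nrow(tab)
  rs <- rowSums(tab)
  c1 <- sum(tab[, 1])
  log_prob <- function(x) {
    sum(lchoose(rs, x)) - lchoose(sum(rs), c1)
  }
  cells <- vector("list", r)
  grid <- list(integer(0))
  # enumerate first-column entries row by row under the margin constraints
  enum <- function(prefix, row) {
    rem <- c1 - sum(prefix)
    if (row > r) {
      if (rem == 0) return(list(prefix)) else return(list())
    }
    lo <- max(0, rem - sum(rs[row:r]) + rs[row])
    lo <- max(0, rem - sum(rs[-seq_len(row)]))
    hi <- min(rs[row], rem)
    if (lo > hi) return(list())
    out <- list()
    for (v in lo:hi) out <- c(out, enum(c(prefix, v), row + 1))
    out
  }
  tables <- enum(integer(0), 1)
  lp <- vapply(tables, log_prob, numeric(1))
  obs <- log_prob(tab[, 1])
  sum(exp(lp[lp <= obs + 1e-7]))
}

# Brute-force pairwise AUC: fraction of (positive, negative) pairs ranked
# correctly, ties counted one half.
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Logrank statistic via the survival package (independent route).
survdiff_stat <- function(records) {
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = records)
  unname(fit$chisq)
}
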