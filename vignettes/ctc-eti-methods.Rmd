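---
title: "Methods: the CTC endocrine therapy index, its trial statistics, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CTC endocrine therapy index, its trial statistics, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctceti)
```

## The scoring model

The CTC endocrine therapy index (CTC-ETI) is a composite prognostic score
for patients with ER-positive, HER2-negative metastatic breast cancer
starting a new endocrine therapy. One blood draw is pooled and divided
into four 7.5 ml aliquots; CTC are enumerated in each, and the arithmetic
mean of the four counts is the draw's CTC level. The modified algorithm
maps the rounded mean into enumeration points (<5 → 0, 5–10 → 1,
11–100 → 3, >100 → 4) and, when the mean is at least 5, adds a Bio-Score:
each of ER, BCL2, HER2 and Ki67 contributes Bio-Points according to the
percentage of CTC staining positive (2+ or 3+), categorized as 0%, 1–10%
or >10%. ER and BCL2 positivity signals endocrine sensitivity and earns
points inversely; HER2 and Ki67 positivity signals resistance and earns
points directly. The total spans 0–16 and is reported as low (0–3),
intermediate (4–6) or high (7–16). A draw averaging under 5 CTC is low by
definition: with so few cells the phenotyping percentages are not
interpreted, and the Bio-Score is zero.

Two protocol-level constants are not published and are therefore explicit,
configurable stand-ins rather than recovered values:

* **Per-marker Bio-Points.** The default table (ER 4/2/0, BCL2 2/1/0 for
  0% / 1–10% / >10%; HER2 0/2/3, Ki67 0/1/3) satisfies every published
  structural constraint — marker maxima summing to 12 so the maximum total
  is 16, ER carrying the largest marker weight ("overweighted" as the
  target of the therapy), monotone direction per marker, and the existence
  of low-category results at ≥5 CTC (elevated counts with favorable
  biology score as low as 1). `validate_point_table()` audits any
  alternative weighting against these constraints, and
  `enumerate_scores()` enumerates all 4 × 3⁴ category combinations.
* **Rounding.** The average is rounded half-up before every category
  lookup, and the elevated/not-elevated dichotomy uses the rounded value
  (so an average of 4.75 is treated as 5, elevated). Whether the study
  applied its brackets to the rounded or raw average is not stated; one
  rule is used consistently everywhere here.

## Survival analysis

Progression-free survival (PFS) runs from the baseline sample to
documented progression or death, administratively censored at 12 months.
`km_estimate()` is the product-limit estimator with events-first tie
handling; `km_median()` returns the smallest time at which the estimate
reaches one half, or `NA` when the curve never gets there (median not
reached). The k-sample logrank test uses the standard
observed-minus-expected chi-square form with the hypergeometric
covariance; for small instances an exact permutation p-value over group
relabelings is available, and the suite checks the statistic against an
independent implementation and the asymptotic p against an exact
permutation null.

For ordered index categories the package reports the conventional
one-degree-of-freedom score-weighted logrank trend statistic (default
scores 0, 1, 2), returned signed so direction is visible. The analysis
plan's description of a trend test "with 2 degrees of freedom" conflicts
with that convention for three groups; rather than resolve the ambiguity,
`trend_test_survival()` also returns the k-group heterogeneity logrank
(k − 1 degrees of freedom) so both readings are on the table.

Follow-up samples are analyzed by landmarking: `build_landmark()` keeps
patients with a usable sample at the visit whose PFS extends strictly
beyond the sample time, re-anchors time at the sample date, and reports
exclusion counts (no sample, index undetermined, progressed/censored by
the landmark). Zero or negative re-anchored times are excluded — a patient
whose PFS ends on the sample day cannot contribute follow-up time.

## Rapid progression and exact categorical statistics

Rapid progression (RP) is progression, or death due to metastatic breast
cancer, within 3 months of baseline. A patient with no qualifying event
can only be scored RP-negative if the 3-month reimaging happened;
otherwise the status is unassessable and the patient is omitted. Death
from other causes is a PFS event but not an RP event, so the cohort table
carries the event type alongside the cause-of-death flag.

Associations with RP use exact tests throughout: `fisher_exact_2x2()`
(two-sided by the probability-mass rule — the sum of hypergeometric
probabilities of margin-consistent tables no more probable than the
observed one, the dominant software convention; the study does not state
its software), `fisher_exact_rxc()` (the Freeman–Halton generalization),
and `trend_test_proportions()` (Cochran–Armitage, scores 0, 1, 2, with an
optional permutation p). Group-wise RP rates carry exact Clopper–Pearson
intervals from Beta quantiles, with percent bounds rounded half-up for
reporting. Since the extreme categories dominate the published contrasts,
`rp_by_group()` reports the high-vs-low 2×2 Fisher test alongside the
full r×2 test and, for three or more groups, the trend test — the printed
headline p-value could be either, so both are computed.

One reporting caveat surfaced while validating the interval arithmetic:
the exact central interval for 28/70 is 28.47–52.41%, which rounds to
28–52%, while 29–52% appears in print; no rounding convention reproduces
all five published intervals simultaneously, and the other four match the
half-up rule exactly. The package reports the exact computation.

## The two-stage analytical-validity design

Whether the assay can be run reliably on shipped specimens is judged by
two independent, sequential exact binomial stages: each observes 32
baseline attempts and rejects the hypothesis of an unacceptable success
rate (≤60%) when at least 24 succeed, otherwise rejecting the desired
rate (≥80%). `stage_alpha()` and `stage_beta()` are the exact binomial
tails — 0.057 and 0.175 at the published cutoff, within the design
targets of 0.06 and 0.20 — and `find_cutoff()` searches the smallest
cutoff meeting both targets. No error-spending across the stages is
applied, because the stages are analyzed independently.

The trial's power claim for the RP endpoint is reproduced by simulation:
`simulate_rp_power()` draws category RP counts binomially (36/48/36
patients at rates 0.20/0.34/0.75 by default), applies the exact r×2 test
at two-sided α = 0.05, and reports the rejection fraction with an exact
Monte-Carlo interval. Two thousand replicates put the power near 99%,
comfortably above the designed 90%; the companion logrank half of the
published power statement specifies no hazards, so it is exposed only
through the survival module with user-supplied assumptions rather than
reproduced.

## The retraining ensemble

The exploratory retraining asks whether the marker percentages add
anything to enumeration for predicting RP, among patients assessable for
RP with an average count of at least 5 (the only patients whose markers
were interpreted). The procedure, faithfully reproduced: split the
eligible records into training and validation sets (22/10 at the study's
size of 32, scaled proportionally otherwise); inflate the training set to
500 rows by resampling with replacement; fit one model — a classification
tree or a logistic fit — on the five predictors (average CTC, four marker
percentages); predict the matching validation set; repeat for 500
independently drawn pairs; average each patient's predicted probabilities
over the splits in which they fell into validation; and compute the ROC
curve and AUC from those means. "500 unique pairs" is read as 500
independently drawn pairs, not enforced-distinct partitions.

Tree hyperparameters are unstated in the plan, so defaults are explicit
choices: binary Gini splits, minimum leaf of 5 on the inflated scale,
effectively unlimited depth, all configurable. "Most important variable"
per tree is the largest total impurity decrease, tallied across trees.
Degenerate draws are handled explicitly: a single-class training multiset
yields the constant class-frequency predictor with a warning; a patient
never landing in validation is excluded from the ROC with a warning; an
all-one-class outcome makes the AUC an error rather than a number.
`univariate_logistic()` runs the follow-up single-predictor fits and
withholds Wald statistics under complete separation instead of reporting
meaningless ones.

## The synthetic cohort generator

The generator exists so every stage above is testable end to end without
patient data; its defaults are the study conditions the analyses assume.
Each of 120 patients is elevated at baseline with probability 0.36.
Elevated patients draw a mean count λ from 5 + lognormal(log 15, 1);
non-elevated patients are zero-inflated (probability 0.5 of λ = 0, else
uniform on (0, 1.5)), keeping a rounded four-aliquot average of ≥5
essentially impossible for them, as the elevation label requires. Aliquot
counts are conditionally Poisson(λ): with only four replicate counts per
draw, a two-level mixing model is as much dispersion structure as the
data could ever identify. A latent endocrine-resistance state (probability
0.7 given elevation, 0.2 otherwise) selects Beta priors for the marker
percentages, with marker-specific point mass at exactly 0% so the 0%
staining category actually occurs; the published record contains no
marker-percentage distributions, so these priors are free modeling
parameters, not estimates of any real cohort.

PFS is exponential with the median set by the patient's baseline index
category — 6.9, 8.5 and 2.8 months for low, intermediate and high, the
published category medians — via rate = ln 2 / median, censored at 12
months. The exponential is deliberately minimal: sufficient for
Kaplan–Meier and logrank machinery, silent about non-proportional
hazards. Elevation evolves across follow-up visits by a two-state Markov
chain (resistant patients retain elevation with probability 0.9,
sensitive with 0.45, non-elevated gain it with probability 0.02),
reproducing the declining elevated fraction under therapy seen in
monitoring data; marker percentages are redrawn per visit from the same
priors. Follow-up draws exist only strictly before the PFS endpoint
(patients reaching 12 months censored contribute the end-of-study draw)
and are thinned by per-visit missingness (5% at months 1–3, 45% at month
12). About 2% of draws carry a failure status (quantity not sufficient,
pre-analytic, or technical) and are unusable; 11% of patients lack the
3-month reimaging and are RP-unassessable. Fifteen percent of PFS events
are deaths, 80% of those due to the disease. Times are months throughout;
any day-scale input should be divided by 30.4375.

What passing tests on this cohort do and do not show: parameter-recovery
checks (baseline prevalence within binomial error at n = 5000, per-category
KM medians within 15% at n = 5000) demonstrate that the pipeline measures
what the generator planted, not that real cohorts satisfy the model; the
generator has no inter-laboratory variation, no staining-intensity
distributions behind the percentages, no dependence between missingness
and prognosis, and independent per-patient outcomes.

## Numerical choices and problem sizes

Half-up rounding is implemented as floor(x + 0.5) to avoid R's default
round-half-to-even. The logrank covariance inverts the (k − 1)-dimensional
submatrix, falling back to a generalized inverse when a degenerate
instance (e.g. a single event) makes it singular; no events at all gives
statistic 0 and p 1. Permutation p-values use the add-one estimator
(hits + 1)/(B + 1). Fisher r×c enumeration is delegated to the network
algorithm with a bounded workspace, and all-zero rows or columns are
collapsed first, preserving the p-value. The test suite exercises
simulation-based properties at sizes chosen to keep Monte-Carlo error
well inside the asserted margins while the full suite runs in well under
a minute: 5000 patients for parameter recovery, 2000 replicates for the
design power, a few hundred splits for ensemble properties, and exact
enumeration (70 relabelings, all margin-consistent tables at n ≤ 15)
wherever the instance is small enough for brute force.

## Known limitations

The Bio-Point defaults and the rounding rule are stand-ins for
unpublished protocol constants; conclusions that depend on the exact
point values should be re-run with the study's table via
`point_table()`/`read_point_table()`. The generator's marker priors are
free parameters, so ensemble AUC levels on synthetic cohorts say nothing
about real marker utility — only the machinery's correctness and its
qualitative behavior under planted signals are claimed. Cox models and
competing-risks analyses are out of scope (the analysis plan fits
neither), as are two-operator reconciliation, staining-image
interpretation, and inter-laboratory concordance.
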