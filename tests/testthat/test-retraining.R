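# Synthetic eligible cohorts with controlled outcome mechanisms.
make_eligible <- function(n, mechanism = c("null", "ki67", "ctc"), seed = 1) {
  mechanism <- match.arg(mechanism)
  set.seed(seed)
  df <- data.frame(
    patient_id = sprintf("E%03d", seq_len(n)),
    avg_ctc = 5 + stats::rlnorm(n, log(10), 1),
    pct_er = 100 * stats::rbeta(n, 2, 2),
    pct_bcl2 = 100 * stats::rbeta(n, 2, 2),
    pct_her2 = 100 * stats::rbeta(n, 2, 2),
    pct_ki67 = 100 * stats::rbeta(n, 2, 2))
  df$rp <- switch(mechanism,
    null = stats::runif(n) < 0.5,
    ki67 = stats::runif(n) < stats::plogis((df$pct_ki67 - 50) / 4),
    ctc  = stats::runif(n) < stats::plogis((df$avg_ctc - 15) / 2))
  df
}

test_that("split pairs have the configured sizes and are deterministic", {
  rec <- make_eligible(32)
  cfg <- retrain_config(n_splits = 500, train_n = 22, val_n = 10,
                        inflate_to = 500, seed = 5)
  sp <- make_splits(rec, cfg)
  expect_length(sp, 500)
  for (s in sp[c(1, 250, 500)]) {
    expect_length(s$train, 500)
    expect_length(s$val, 10)
    expect_length(unique(c(s$train, s$val)), 32)  # partition is exhaustive
    expect_length(intersect(unique(s$train), s$val), 0)
    expect_lte(length(unique(s$train)), 22)
  }
  expect_identical(sp, make_splits(rec, cfg))
  expect_error(make_splits(make_eligible(20), cfg), "train_n \\+ val_n")
})

test_that("a degenerate single split resamples the training set from itself", {
  rec <- make_eligible(12)
  cfg <- retrain_config(n_splits = 1, train_n = 8, val_n = 4, inflate_to = 8)
  sp <- make_splits(rec, cfg)[[1]]
  expect_length(sp$train, 8)
  expect_true(all(sp$train %in% setdiff(seq_len(12), sp$val)))
})

test_that("a tree separates a perfectly separable toy outcome", {
  rec <- make_eligible(60, seed = 3)
  rec$rp <- rec$pct_ki67 > 50
  mod <- fit_one_model(rec, retrain_config(model = "tree"))
  expect_equal(mod$kind, "tree")
  pred <- mod$predict(rec)
  expect_equal(as.logical(pred > 0.5), rec$rp)
  expect_equal(names(which.max(mod$importance)), "pct_ki67")
})

test_that("single-class training falls back to the constant predictor", {
  rec <- make_eligible(20)
  rec$rp <- TRUE
  expect_warning(mod <- fit_one_model(rec, retrain_config()), "single outcome class")
  expect_equal(mod$kind, "constant")
  expect_equal(mod$predict(rec[1:5, ]), rep(1, 5))
})

test_that("logistic fit recovers a null model on independent data", {
  rec <- make_eligible(600, "null", seed = 9)
  mod <- fit_one_model(rec, retrain_config(model = "logistic"))
  expect_equal(mod$kind, "logistic")
  fit <- suppressWarnings(stats::glm(
    rp ~ avg_ctc + pct_er + pct_bcl2 + pct_her2 + pct_ki67,
    data = rec, family = stats::binomial()))
  co <- summary(fit)$coefficients[-1, ]
  expect_true(all(abs(co[, "Estimate"]) < 4 * co[, "Std. Error"]))
})

test_that("ensemble AUC is near chance when the outcome is independent", {
  rec <- make_eligible(60, "null", seed = 13)
  cfg <- retrain_config(n_splits = 150, train_n = 40, val_n = 20, inflate_to = 200,
                        seed = 2)
  for (model in c("tree", "logistic")) {
    cfg$model <- model
    ens <- ensemble_validate(rec, cfg)
    expect_lt(abs(ens$auc - 0.5), 0.25)
  }
})

test_that("ensemble recovers a planted marker signal", {
  rec <- make_eligible(60, "ki67", seed = 4)
  cfg <- retrain_config(n_splits = 200, train_n = 40, val_n = 20, inflate_to = 200,
                        model = "tree", seed = 6)
  ens <- ensemble_validate(rec, cfg)
  expect_gt(ens$auc, 0.8)
  expect_equal(names(which.max(ens$importance_tally)), "pct_ki67")
})

test_that("ensemble bookkeeping is internally consistent and deterministic", {
  rec <- make_eligible(32, "ctc", seed = 8)
  cfg <- retrain_config(n_splits = 120, train_n = 22, val_n = 10, inflate_to = 150,
                        model = "tree", seed = 3)
  ens <- ensemble_validate(rec, cfg)
  expect_true(all(ens$probabilities$mean_prob >= 0 & ens$probabilities$mean_prob <= 1))
  expect_equal(ens$auc, auc_pairs_oracle(ens$probabilities$mean_prob,
                                         ens$probabilities$rp))
  expect_equal(sum(ens$importance_tally), 120)
  ens2 <- ensemble_validate(rec, cfg)
  expect_equal(ens$auc, ens2$auc)
  expect_identical(ens$probabilities, ens2$probabilities)
  # ROC endpoints and monotonicity
  expect_equal(ens$roc$fpr[1], 0)
  expect_equal(ens$roc$tpr[nrow(ens$roc)], 1)
  expect_true(all(diff(ens$roc$fpr) >= 0) && all(diff(ens$roc$tpr) >= 0))
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  for (i in 1:5) {
    scores <- c(stats::runif(20), stats::runif(15) + 0.3)
    labels <- rep(c(FALSE, TRUE), c(20, 15))
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_rank(scores, labels), ref, tolerance = 1e-10)
    expect_equal(auc_pairs_oracle(scores, labels), ref, tolerance = 1e-10)
  }
})

test_that("CTC-driven outcomes put CTC count on top of the importance tally", {
  rec <- make_eligible(40, "ctc", seed = 15)
  cfg <- retrain_config(n_splits = 150, train_n = 28, val_n = 12, inflate_to = 200,
                        model = "tree", seed = 5)
  ens <- ensemble_validate(rec, cfg)
  expect_equal(names(which.max(ens$importance_tally)), "avg_ctc")
})

test_that("degenerate outcomes make the ensemble AUC an error", {
  rec <- make_eligible(32)
  rec$rp <- FALSE
  expect_error(ensemble_validate(rec, retrain_config(train_n = 22, val_n = 10)),
               "undefined")
})

test_that("univariate logistic follow-up behaves under null and planted signal", {
  null_rec <- make_eligible(500, "null", seed = 21)
  un <- univariate_logistic(null_rec, "pct_er")
  expect_false(un$separation)
  expect_lt(abs(un$coefficient), 4 * un$se)

  sig <- make_eligible(400, "ki67", seed = 22)
  us <- univariate_logistic(sig, "pct_ki67")
  expect_gt(us$coefficient, 0)
  expect_lt(us$p, 0.05)

  cst <- make_eligible(30)
  cst$pct_er <- 50
  expect_error(univariate_logistic(cst, "pct_er"), "variation")
  expect_error(univariate_logistic(sig, "shoe_size"), "one of")
})

test_that("complete separation is flagged rather than reported", {
  rec <- make_eligible(40, seed = 30)
  rec$rp <- rec$pct_her2 > 50
  us <- univariate_logistic(rec, "pct_her2")
  expect_true(us$separation)
  expect_true(is.na(us$coefficient))
})
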