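#' Eligible records for index retraining
#'
#' The retraining cohort comprises patients assessable for rapid
#' progression whose four-aliquot average CTC count is >= 5/7.5 ml WB (so
#' the marker phenotyping was interpreted). Predictors are the average
#' count and the four percent-positive values; the outcome is RP.
#'
#' @param scored Cohort run through [score_cohort()].
#' @param visit Visit whose sample supplies the predictors (default `"BL"`).
#' @return Data frame with columns `patient_id`, `avg_ctc`, `pct_er`,
#'   `pct_bcl2`, `pct_her2`, `pct_ki67`, `rp` (logical).
#' @export
eligible_records <- function(scored, visit = "BL") {
  po <- cohort_rp_status(scored)
  rows <- scored[scored$visit == visit & scored$status == "ok", , drop = FALSE]
  rows <- merge(rows, po[, c("patient_id", "rp")], by = "patient_id")
  rows <- rows[rows$rp != "unassessable" & !is.na(rows$elevated) & rows$elevated &
                 rows$determined, , drop = FALSE]
  out <- data.frame(patient_id = rows$patient_id, avg_ctc = rows$avg_ctc,
                    pct_er = rows$pct_er, pct_bcl2 = rows$pct_bcl2,
                    pct_her2 = rows$pct_her2, pct_ki67 = rows$pct_ki67,
                    rp = rows$rp == "rp", stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Retraining ensemble configuration
#'
#' @param n_splits Number of train/validation split pairs (default 500).
#' @param train_n,val_n Training and validation set sizes (defaults 22 and
#'   10; they must sum to the eligible cohort size).
#' @param inflate_to Bootstrap-inflated training size (default 500): the
#'   training set is resampled with replacement up to this many rows to
#'   compensate for the small sample.
#' @param model `"tree"` or `"logistic"`.
#' @param min_leaf Minimum records per tree leaf, on the inflated scale
#'   (default 5).
#' @param max_depth Maximum tree depth (default 30, effectively unlimited).
#' @param seed Integer seed driving the whole ensemble.
#' @return Object of class `retrain_config`.
#' @export
retrain_config <- function(n_splits = 500, train_n = 22, val_n = 10,
                           inflate_to = 500, model = c("tree", "logistic"),
                           min_leaf = 5, max_depth = 30, seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_splits >= 1, train_n >= 2, val_n >= 1, inflate_to >= train_n)
  structure(list(n_splits = n_splits, train_n = train_n, val_n = val_n,
                 inflate_to = inflate_to, model = model, min_leaf = min_leaf,
                 max_depth = max_depth, seed = seed),
            class = "retrain_config")
}

retrain_predictors <- c("avg_ctc", "pct_er", "pct_bcl2", "pct_her2", "pct_ki67")

#' Draw the train/validation split pairs
#'
#' Each pair randomly partitions the eligible records into a training set of
#' `train_n` and a validation set of `val_n`, then resamples the training
#' set with replacement up to `inflate_to` rows. Pairs are drawn
#' independently; the sequence is deterministic given the seed.
#'
#' @param records [eligible_records()] output with `train_n + val_n` rows.
#' @param config A [retrain_config()].
#' @return List of `config$n_splits` elements, each with integer row
#'   indices `train` (length `inflate_to`, a multiset) and `val`.
#' @export
make_splits <- function(records, config = retrain_config()) {
  n <- nrow(records)
  if (n != config$train_n + config$val_n)
    stop(sprintf("records has %d rows; config requires train_n + val_n = %d",
                 n, config$train_n + config$val_n), call. = FALSE)
  set.seed(config$seed)
  lapply(seq_len(config$n_splits), function(s) {
    tr <- sample.int(n, config$train_n)
    list(train = sort(tr)[sample.int(config$train_n, config$inflate_to, replace = TRUE)],
         val = setdiff(seq_len(n), tr))
  })
}

#' Fit one model of the ensemble on one (inflated) training multiset
#'
#' A classification tree (binary recursive partitioning on the five
#' predictors, Gini splitting) or a maximum-likelihood logistic fit on the
#' same predictors. A single-class training draw cannot support either
#' model; the constant class-frequency predictor is returned with a
#' warning.
#'
#' @param training Data frame of training rows (already inflated).
#' @param config A [retrain_config()].
#' @return List with `predict(newdata)` returning RP probabilities, `kind`,
#'   and for trees `importance` (named total impurity decrease per
#'   predictor used).
#' @export
fit_one_model <- function(training, config = retrain_config()) {
  stopifnot(nrow(training) > 0)
  if (length(unique(training$rp)) < 2) {
    p0 <- mean(training$rp)
    warning("training draw contains a single outcome class; returning the constant predictor",
            call. = FALSE)
    return(list(predict = function(newdata) rep(p0, nrow(newdata)),
                kind = "constant", importance = NULL))
  }
  fml <- stats::as.formula(paste("rp ~", paste(retrain_predictors, collapse = " + ")))
  if (config$model == "tree") {
    fit <- rpart::rpart(
      fml, data = training, method = "class",
      control = rpart::rpart.control(minbucket = config$min_leaf,
                                     maxdepth = config$max_depth,
                                     cp = 0, xval = 0))
    imp <- fit$variable.importance
    list(predict = function(newdata)
      unname(stats::predict(fit, newdata = newdata, type = "prob")[, "TRUE"]),
      kind = "tree",
      importance = if (is.null(imp)) numeric(0) else imp)
  } else {
    fit <- suppressWarnings(stats::glm(fml, data = training, family = stats::binomial()))
    list(predict = function(newdata)
      unname(stats::predict(fit, newdata = newdata, type = "response")),
      kind = "logistic", importance = NULL)
  }
}

#' Area under the ROC curve from scores and binary labels
#'
#' Rank (Mann-Whitney) form with the tie correction: the probability a
#' random positive scores above a random negative, counting ties as one
#' half.
#'
#' @param scores Numeric predictions.
#' @param labels Logical outcomes.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("AUC is undefined when all outcomes are the same class", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points from scores and labels
#'
#' @param scores Numeric predictions.
#' @param labels Logical outcomes.
#' @return Data frame of `threshold`, `fpr`, `tpr`, one row per distinct
#'   score plus the two trivial endpoints.
#' @export
roc_points <- function(scores, labels) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  data.frame(
    threshold = th,
    fpr = vapply(th, function(t) mean(scores[!labels] >= t), numeric(1)),
    tpr = vapply(th, function(t) mean(scores[labels] >= t), numeric(1)))
}

#' Run the full retraining ensemble
#'
#' Draws the split pairs, fits one model per training multiset, collects
#' each patient's predicted RP probability from every split in which the
#' patient fell into validation, averages them per patient, and computes
#' the ROC curve and AUC from the averaged probabilities. For trees, the
#' most important variable of each fitted tree (largest total impurity
#' decrease) is tallied.
#'
#' @param records [eligible_records()] output.
#' @param config A [retrain_config()].
#' @return Object of class `ensemble_result`: list with `probabilities`
#'   (per-patient data frame: mean predicted probability, number of
#'   validation appearances, outcome), `roc`, `auc`, `importance_tally`
#'   (tree model; named counts summing to the number of fitted trees), and
#'   `config`.
#' @export
ensemble_validate <- function(records, config = retrain_config()) {
  if (length(unique(records$rp)) < 2)
    stop("AUC is undefined when all outcomes are the same class", call. = FALSE)
  splits <- make_splits(records, config)
  n <- nrow(records)
  prob_sum <- prob_n <- numeric(n)
  tally <- stats::setNames(numeric(length(retrain_predictors)), retrain_predictors)
  for (sp in splits) {
    mod <- suppressWarnings(fit_one_model(records[sp$train, , drop = FALSE], config))
    pv <- mod$predict(records[sp$val, , drop = FALSE])
    prob_sum[sp$val] <- prob_sum[sp$val] + pv
    prob_n[sp$val] <- prob_n[sp$val] + 1
    if (config$model == "tree" && mod$kind == "tree" && length(mod$importance))
      tally[names(which.max(mod$importance))] <-
        tally[names(which.max(mod$importance))] + 1
  }
  seen <- prob_n > 0
  if (!all(seen))
    warning(sum(!seen), " patient(s) never appeared in a validation set; excluded from ROC",
            call. = FALSE)
  probs <- data.frame(patient_id = records$patient_id[seen],
                      mean_prob = prob_sum[seen] / prob_n[seen],
                      n_validations = prob_n[seen], rp = records$rp[seen])
  structure(
    list(probabilities = probs,
         roc = roc_points(probs$mean_prob, probs$rp),
         auc = auc_rank(probs$mean_prob, probs$rp),
         importance_tally = if (config$model == "tree") tally else NULL,
         config = config),
    class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("Retraining ensemble (%s, %d splits): AUC %.3f over %d patients\n",
              x$config$model, x$config$n_splits, x$auc, nrow(x$probabilities)))
  if (!is.null(x$importance_tally)) {
    cat("  most-important-variable tally:\n")
    print(x$importance_tally)
  }
  invisible(x)
}

#' Univariate logistic follow-up of one predictor
#'
#' @param records [eligible_records()] output.
#' @param variable One of `avg_ctc`, `pct_er`, `pct_bcl2`, `pct_her2`,
#'   `pct_ki67`.
#' @return List with `coefficient`, `se`, `p`, and `separation` (TRUE when
#'   the fit is degenerate through complete separation, in which case the
#'   Wald numbers are withheld as `NA`).
#' @export
univariate_logistic <- function(records, variable) {
  if (!variable %in% retrain_predictors)
    stop("`variable` must be one of: ", paste(retrain_predictors, collapse = ", "),
         call. = FALSE)
  x <- records[[variable]]
  if (length(unique(x)) < 2)
    stop("predictor `", variable, "` has no variation", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm(records$rp ~ x, family = stats::binomial()))
  co <- summary(fit)$coefficients
  sep <- !fit$converged || abs(co["x", "Estimate"]) > 1e3 || co["x", "Std. Error"] > 1e3
  if (sep)
    return(list(coefficient = NA_real_, se = NA_real_, p = NA_real_,
                separation = TRUE))
  list(coefficient = co["x", "Estimate"], se = co["x", "Std. Error"],
       p = co["x", "Pr(>|z|)"], separation = FALSE)
}
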