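# Resampling protocols: repeated cross-validation for fitting PIN
# functions (stage A), application to test data, and double
# cross-validation for honest evaluation of the combined classifier
# (stage B).  All models share identical partitions within a run (paired
# design), and every source of randomness is derived from the single
# protocol seed.

#' Configure the cross-validation protocols
#'
#' @param n_folds number of folds per partition (default 10).
#' @param K number of repeated random partitions when fitting PIN
#'   functions (default 20; values of 20-50 are typical).
#' @param KK number of repeats of the full double-cross-validation pass
#'   (default 10).
#' @param seed integer master seed; partitioning, learner fits and
#'   tie-breaks all derive independent streams from it.
#' @param stratified stratify folds by class (default `TRUE`).  With
#'   classes as small as 8 instances, unstratified 10-fold splits can
#'   strand a class entirely outside a training fold; set `FALSE` to
#'   restore fully random partitions.
#' @return an object of class `cv_config`.
#' @export
cv_config <- function(n_folds = 10L, K = 20L, KK = 10L, seed = 1L,
                      stratified = TRUE) {
  stopifnot(n_folds >= 2, K >= 1, KK >= 1)
  structure(list(n_folds = as.integer(n_folds), K = as.integer(K),
                 KK = as.integer(KK), seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "cv_config")
}

# Random fold assignment (1..n_folds per instance), optionally stratified.
make_folds <- function(labels, n_folds, stratified, seed) {
  n <- length(labels)
  if (n < n_folds)
    stop("cannot make ", n_folds, " folds from ", n, " instances")
  with_seed(seed, {
    if (stratified) {
      fold <- integer(n)
      for (k in unique(labels)) {
        idx <- which(labels == k)
        fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
      fold
    } else {
      sample(rep_len(seq_len(n_folds), n))
    }
  })
}

# Row subset of a labeled dataset (keeps the full class vocabulary).
dataset_subset <- function(data, idx) {
  labeled_dataset(data$features[idx, , drop = FALSE],
                  data$labels[idx],
                  instance_ids = data$instance_ids[idx],
                  class_vocab = data$class_vocab)
}

#' Repeated cross-validated level-0 predictions
#'
#' Stage A1.1-A1.5: for each of `K` random partitions of the training
#' data into `n_folds` folds, every model is trained on the other folds
#' and predicts the held-out fold, yielding `K x n` prediction records
#' per model (with MaxP, predicted and true class, and repeat/fold
#' provenance).  All models see the identical partitions, so downstream
#' comparisons are paired.  Full posterior matrices are retained for the
#' stacking baselines.
#'
#' @param specs named list of [classifier_spec()] objects.
#' @param train a [labeled_dataset()].
#' @param cfg a [cv_config()]; `cfg$K` partitions are generated.
#' @return an object of class `cv_predictions`: per-model list with
#'   elements `records` (data frame of `K x n` rows) and `probs`
#'   (row-aligned posterior matrix), plus the vocabulary and config.
#' @export
cv_level0 <- function(specs, train, cfg = cv_config()) {
  stopifnot(inherits(train, "labeled_dataset"),
            inherits(cfg, "cv_config"))
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  mids <- vapply(specs, `[[`, "", "model_id")
  names(specs) <- mids
  counts <- table(train$labels)
  if (any(counts < 2))
    stop("class(es) with fewer than 2 instances: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  truth <- setNames(train$labels, train$instance_ids)
  acc_rec <- setNames(vector("list", length(specs)), mids)
  acc_prob <- setNames(vector("list", length(specs)), mids)
  for (k in seq_len(cfg$K)) {
    fold <- make_folds(train$labels, cfg$n_folds, cfg$stratified,
                       derive_seed(cfg$seed, "partition", k))
    for (f in sort(unique(fold))) {
      hold <- which(fold == f)
      sub <- dataset_subset(train, -hold)
      for (m in mids) {
        sp <- specs[[m]]
        sp$seed <- derive_seed(cfg$seed, m, "fit", k, f)
        P <- fit_predict_proba(sp, sub,
                               train$features[hold, , drop = FALSE],
                               eval_ids = train$instance_ids[hold])
        rec <- maxp_and_class(P, truth)
        rec$rep_idx <- k
        rec$fold <- f
        acc_rec[[m]] <- c(acc_rec[[m]], list(rec))
        acc_prob[[m]] <- c(acc_prob[[m]], list(P$probs))
      }
    }
  }
  models <- lapply(mids, function(m)
    list(records = do.call(rbind, acc_rec[[m]]),
         probs = do.call(rbind, acc_prob[[m]])))
  names(models) <- mids
  structure(list(models = models, class_vocab = train$class_vocab,
                 cfg = cfg, n = length(train$instance_ids)),
            class = "cv_predictions")
}

#' @export
print.cv_predictions <- function(x, ...) {
  cat("<cv_predictions> ", length(x$models), " models, ",
      nrow(x$models[[1]]$records), " records each (K = ", x$cfg$K,
      " x n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Fit PIN functions from cross-validated predictions (stage A1)
#'
#' Stage A1.6-A1.7: fits one PIN function per model on its pooled
#' `K x n` cross-validated records, attaches PIN values, and forms the
#' combined (maximum-PIN) training predictions.
#'
#' @param cv_sets a [cv_level0()] result.
#' @param seed tie-break seed for the combined predictions.
#' @return a list with `pin_functions` (named list), `records` (per-model
#'   data frames with `pin` set) and `combined` (the PINCom training
#'   predictions, confidence column `max_pin`).
#' @export
estimate_pins_A1 <- function(cv_sets, seed = 1L) {
  stopifnot(inherits(cv_sets, "cv_predictions"))
  pin_functions <- lapply(names(cv_sets$models), function(m)
    fit_pin(cv_sets$models[[m]]$records, model_id = m))
  names(pin_functions) <- names(cv_sets$models)
  records <- lapply(names(cv_sets$models), function(m)
    add_pin(cv_sets$models[[m]]$records, pin_functions[[m]]))
  names(records) <- names(cv_sets$models)
  combined <- if (length(records) >= 2L)
    combine_pin(records, seed = seed) else NULL
  list(pin_functions = pin_functions, records = records,
       combined = combined)
}

#' Apply trained models and PIN functions to test data (stage A2)
#'
#' Refits every model on the full training set, predicts the test
#' features, converts each model's MaxP to PIN through its
#' training-fitted PIN function (clamped outside the training knot
#' range), and forms the combined maximum-PIN prediction with seeded
#' random tie-breaks.
#'
#' @param specs named list of [classifier_spec()] objects.
#' @param train the full training [labeled_dataset()].
#' @param test_features numeric matrix with the training feature columns.
#' @param pin_functions named list of `pin_function`s from
#'   [estimate_pins_A1()] on the same training data.
#' @param seed tie-break seed.
#' @param test_ids optional test instance ids.
#' @param true_labels optional true test labels (named by id or aligned).
#' @return a list with `per_model` (record data frames with `pin`) and
#'   `combined` (PINCom test predictions).
#' @export
apply_A2 <- function(specs, train, test_features, pin_functions,
                     seed = 1L, test_ids = NULL, true_labels = NULL) {
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  mids <- vapply(specs, `[[`, "", "model_id")
  names(specs) <- mids
  miss <- setdiff(mids, names(pin_functions))
  if (length(miss))
    stop("no PIN function for model(s): ", paste(miss, collapse = ", "))
  test_features <- as.matrix(test_features)
  if (ncol(test_features) != ncol(train$features))
    stop("test features have ", ncol(test_features),
         " columns; training has ", ncol(train$features))
  if (is.null(test_ids))
    test_ids <- rownames(test_features) %||%
      paste0("t", seq_len(nrow(test_features)))
  per_model <- lapply(mids, function(m) {
    P <- fit_predict_proba(specs[[m]], train, test_features,
                           eval_ids = test_ids)
    add_pin(maxp_and_class(P, true_labels), pin_functions[[m]])
  })
  names(per_model) <- mids
  combined <- if (length(per_model) >= 2L)
    combine_pin(per_model, seed = derive_seed(seed, "A2-ties"))
  else per_model[[1]]
  list(per_model = per_model, combined = combined)
}

#' Double cross-validation of the combined classifier (stages B1-B2)
#'
#' The honest-evaluation protocol: in each of `KK` passes, the data are
#' partitioned into `n_folds` outer folds; for each outer fold, the
#' remaining data serve as a reduced training set on which an inner
#' `K`-repeat `n_folds`-fold cross-validation fits per-model PIN
#' functions (so roughly 81% of the data trains, 9% calibrates); the
#' outer-fold instances are then predicted by models trained on the
#' reduced set, their MaxP converted through the *inner* PIN functions,
#' and combined by maximum PIN.  No instance ever influences the
#' calibration applied to itself.
#'
#' @param specs named list of [classifier_spec()] objects.
#' @param train a [labeled_dataset()].
#' @param cfg a [cv_config()]; `cfg$K` inner repeats, `cfg$KK` passes.
#' @param max_fits soft cap on the number of level-0 model fits; a
#'   warning reports the estimated count when it exceeds the cap.
#' @return an object of class `double_cv`: `per_model` (named list of
#'   `KK x n`-row record data frames with `pin`), `combined` (the PINCom
#'   records, `KK x n` rows, confidence `max_pin`), and `audit`, a list
#'   per (pass, outer fold) recording the outer-fold ids and the ids
#'   whose records entered the inner PIN fits.
#' @export
double_cv <- function(specs, train, cfg = cv_config(), max_fits = 10000) {
  stopifnot(inherits(train, "labeled_dataset"),
            inherits(cfg, "cv_config"))
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  mids <- vapply(specs, `[[`, "", "model_id")
  names(specs) <- mids
  est_fits <- length(specs) * cfg$KK * cfg$n_folds *
    (cfg$K * cfg$n_folds + 1)
  if (est_fits > max_fits)
    warning("double_cv will perform about ", est_fits,
            " model fits (cap ", max_fits, "); consider lowering K, KK ",
            "or n_folds")
  truth <- setNames(train$labels, train$instance_ids)
  per_model <- setNames(rep(list(list()), length(mids)), mids)
  combined_acc <- list()
  audit <- list()
  for (kk in seq_len(cfg$KK)) {
    fold <- make_folds(train$labels, cfg$n_folds, cfg$stratified,
                       derive_seed(cfg$seed, "outer", kk))
    for (f in sort(unique(fold))) {
      hold <- which(fold == f)
      inner <- dataset_subset(train, -hold)
      inner_cfg <- cv_config(n_folds = cfg$n_folds, K = cfg$K, KK = 1L,
                             seed = derive_seed(cfg$seed, "inner", kk, f),
                             stratified = cfg$stratified)
      inner_cv <- cv_level0(specs, inner, inner_cfg)
      inner_pins <- lapply(names(inner_cv$models), function(m)
        fit_pin(inner_cv$models[[m]]$records, model_id = m))
      names(inner_pins) <- names(inner_cv$models)
      fold_records <- lapply(mids, function(m) {
        sp <- specs[[m]]
        sp$seed <- derive_seed(cfg$seed, m, "outer-fit", kk, f)
        P <- fit_predict_proba(sp, inner,
                               train$features[hold, , drop = FALSE],
                               eval_ids = train$instance_ids[hold])
        rec <- add_pin(maxp_and_class(P, truth), inner_pins[[m]])
        rec$pass <- kk
        rec$outer_fold <- f
        rec
      })
      names(fold_records) <- mids
      for (m in mids)
        per_model[[m]] <- c(per_model[[m]], list(fold_records[[m]]))
      comb <- if (length(fold_records) >= 2L) {
        combine_pin(fold_records,
                    seed = derive_seed(cfg$seed, "ties", kk, f))
      } else {
        r <- fold_records[[1]]
        data.frame(instance_id = r$instance_id,
                   winning_model_id = r$model_id,
                   predicted_class = r$predicted_class,
                   max_pin = r$pin, true_class = r$true_class,
                   stringsAsFactors = FALSE)
      }
      comb$pass <- kk
      comb$outer_fold <- f
      combined_acc <- c(combined_acc, list(comb))
      audit <- c(audit, list(list(
        pass = kk, outer_fold = f,
        outer_ids = train$instance_ids[hold],
        inner_ids = unique(inner_cv$models[[1]]$records$instance_id))))
    }
  }
  structure(
    list(per_model = lapply(per_model, function(l) do.call(rbind, l)),
         combined = do.call(rbind, combined_acc),
         audit = audit, cfg = cfg, n = length(train$instance_ids)),
    class = "double_cv")
}

#' @export
print.double_cv <- function(x, ...) {
  cat("<double_cv> ", length(x$per_model), " models + combined, ",
      nrow(x$combined), " records (KK = ", x$cfg$KK, " x n = ", x$n,
      ")\n", sep = "")
  invisible(x)
}

#' Estimate test-set precision and recall from double-CV precision
#'
#' For an unlabeled test set, the number of correct predictions in a
#' thresholded subset cannot be counted, but it can be estimated: the
#' subset `{score >= a}` of the test predictions is assumed to have the
#' precision `P_xv(a)` observed on the double-cross-validated training
#' predictions.  With `score = "pin"`, estimated correct =
#' `subset size x P_xv(a)`.  With `score = "pic"`, the estimate is
#' formed per predicted class `k` -- `#\{PIC >= a, predicted = k\}` times
#' the class-specific double-CV precision `P_k(a)` -- and summed over
#' classes.  `P(a)` divides the estimate by the subset size and `R(a)` by
#' the full test-set size.
#'
#' @param test_records test prediction records carrying the score column.
#' @param xv_records double-cross-validated training records with known
#'   `true_class` and the same score column.
#' @param thresholds numeric vector of thresholds `a`.
#' @param score `"pin"` (overall thresholding) or `"pic"`
#'   (class-specific thresholding); for combined-classifier records use
#'   `score_test` to point at the `max_pin` column.
#' @param score_test name of the score column in `test_records`
#'   (defaults to `score`).
#' @param score_xv name of the score column in `xv_records` (defaults to
#'   `score`).
#' @return a data frame with columns `a`, `subset_size`,
#'   `est_correct`, `P` and `R`; `P` is `NA` where the subset is empty.
#' @export
estimate_test_pr <- function(test_records, xv_records, thresholds,
                             score = c("pin", "pic"),
                             score_test = NULL, score_xv = NULL) {
  score <- match.arg(score)
  score_test <- score_test %||% score
  score_xv <- score_xv %||% score
  check_scored(test_records, score_test)
  check_scored(xv_records, score_xv, need_truth = TRUE)
  n_test <- nrow(test_records)
  s_test <- test_records[[score_test]]
  if (score == "pin") {
    curve <- rp_curve(xv_records, score_xv)
    out <- lapply(thresholds, function(a) {
      size <- sum(s_test >= a)
      if (size == 0L)
        return(data.frame(a = a, subset_size = 0L, est_correct = 0,
                          P = NA_real_, R = 0))
      p <- eval_curve(curve, a, "P")
      data.frame(a = a, subset_size = size, est_correct = size * p,
                 P = p, R = size * p / n_test)
    })
  } else {
    xv_classes <- unique(xv_records$predicted_class)
    class_curves <- lapply(xv_classes, function(k)
      class_rp_curve(xv_records, k, score_xv))
    names(class_curves) <- xv_classes
    overall <- rp_curve(xv_records, score_xv)
    out <- lapply(thresholds, function(a) {
      in_set <- s_test >= a
      size <- sum(in_set)
      if (size == 0L)
        return(data.frame(a = a, subset_size = 0L, est_correct = 0,
                          P = NA_real_, R = 0))
      est <- 0
      for (k in unique(test_records$predicted_class[in_set])) {
        nk <- sum(in_set & test_records$predicted_class == k)
        pk <- if (k %in% xv_classes)
          eval_curve(class_curves[[k]], a, "P")
        else eval_curve(overall, a, "P")
        est <- est + nk * pk
      }
      data.frame(a = a, subset_size = size, est_correct = est,
                 P = est / size, R = est / n_test)
    })
  }
  do.call(rbind, out)
}
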