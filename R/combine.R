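# Combining classifiers: the PIN-combined decision rule (PINCom) plus the
# majority-vote and stacking baselines, and the leave-one-classifier-out
# contribution analysis.

# Check that L record tables cover the same instances in the same order.
check_aligned <- function(per_model_records, need = "pin") {
  stopifnot(is.list(per_model_records), length(per_model_records) >= 1L)
  ref <- per_model_records[[1]]$instance_id
  for (r in per_model_records) {
    if (!identical(r$instance_id, ref))
      stop("per-model record tables are not aligned on the same ",
           "instances in the same order")
    miss <- setdiff(need, names(r))
    if (length(miss))
      stop("per-model records lack column(s): ",
           paste(miss, collapse = ", "))
  }
  invisible(ref)
}

model_ids_of <- function(per_model_records) {
  ids <- names(per_model_records)
  if (is.null(ids))
    ids <- vapply(per_model_records, function(r)
      unique(r$model_id)[1], "")
  ids
}

#' Combine classifiers by maximum precision index (PINCom)
#'
#' For each instance, the combined classifier adopts the predicted class
#' of whichever base model has the highest PIN; the maximum itself
#' (MaxPIN) is the combined classifier's confidence score.  Ties in PIN
#' are resolved by a uniform random choice among the tied models, using a
#' dedicated seeded stream so the combination is reproducible in
#' isolation.
#'
#' @param per_model_records list of `L >= 2` aligned prediction-record
#'   data frames (same instances, same order), each with `pin` and
#'   `predicted_class` set.
#' @param seed integer seed for the tie-break stream.
#' @return a data frame of combined predictions: `instance_id`,
#'   `winning_model_id`, `predicted_class`, `max_pin`, `true_class` (if
#'   present in the inputs), plus per-model `pin.<model>` and
#'   `class.<model>` columns.
#' @export
combine_pin <- function(per_model_records, seed = 1L) {
  if (length(per_model_records) < 2L)
    stop("combination needs >= 2 models")
  ids <- check_aligned(per_model_records, c("pin", "predicted_class"))
  mids <- model_ids_of(per_model_records)
  L <- length(per_model_records)
  n <- length(ids)
  pins <- vapply(per_model_records, `[[`, numeric(n), "pin")
  classes <- vapply(per_model_records, `[[`, character(n),
                    "predicted_class")
  if (n == 1L) { pins <- matrix(pins, 1); classes <- matrix(classes, 1) }
  best <- apply(pins, 1, max)
  winner <- with_seed(derive_seed(seed, "pin-ties"), {
    vapply(seq_len(n), function(i) {
      tied <- which(pins[i, ] == best[i])
      if (length(tied) == 1L) tied else tied[sample.int(length(tied), 1L)]
    }, integer(1))
  })
  out <- data.frame(
    instance_id = ids,
    winning_model_id = mids[winner],
    predicted_class = classes[cbind(seq_len(n), winner)],
    max_pin = best,
    stringsAsFactors = FALSE)
  if ("true_class" %in% names(per_model_records[[1]]))
    out$true_class <- per_model_records[[1]]$true_class
  for (m in seq_len(L)) {
    out[[paste0("pin.", mids[m])]] <- pins[, m]
    out[[paste0("class.", mids[m])]] <- classes[, m]
  }
  out
}

#' Combine classifiers by plurality vote
#'
#' Each instance is assigned the most frequently predicted class among
#' the base models; ties are broken by a seeded uniform random choice
#' among the tied classes.  With a single model the predictions are
#' returned unchanged.
#'
#' @param per_model_records list of aligned prediction-record data frames
#'   with `predicted_class` set.
#' @param seed integer seed for the tie-break stream.
#' @return a data frame with `instance_id`, `predicted_class` and
#'   `true_class` (if present).
#' @export
vote_combine <- function(per_model_records, seed = 1L) {
  ids <- check_aligned(per_model_records, "predicted_class")
  n <- length(ids)
  if (length(per_model_records) == 1L) {
    r <- per_model_records[[1]]
    keep <- intersect(c("instance_id", "predicted_class", "true_class"),
                      names(r))
    return(r[keep])
  }
  classes <- vapply(per_model_records, `[[`, character(n),
                    "predicted_class")
  if (n == 1L) classes <- matrix(classes, 1)
  pred <- with_seed(derive_seed(seed, "vote-ties"), {
    vapply(seq_len(n), function(i) {
      tab <- table(classes[i, ])
      top <- names(tab)[tab == max(tab)]
      if (length(top) == 1L) top else top[sample.int(length(top), 1L)]
    }, "")
  })
  out <- data.frame(instance_id = ids, predicted_class = pred,
                    stringsAsFactors = FALSE)
  if ("true_class" %in% names(per_model_records[[1]]))
    out$true_class <- per_model_records[[1]]$true_class
  out
}

# Assemble the L x C probability blocks into one design matrix.
stack_design <- function(prob_blocks) {
  stopifnot(is.list(prob_blocks), length(prob_blocks) >= 1L)
  nm <- names(prob_blocks) %||% paste0("m", seq_along(prob_blocks))
  blocks <- lapply(seq_along(prob_blocks), function(i) {
    b <- as.matrix(prob_blocks[[i]])
    colnames(b) <- paste(nm[i], colnames(b), sep = ".")
    b
  })
  do.call(cbind, blocks)
}

#' Fit the multi-response linear-regression stacker (Stack 1)
#'
#' Level-1 learning on the cross-validated class-probability outputs of
#' the level-0 models: one least-squares linear regression per class
#' against its 0/1 indicator, prediction by argmax of the fitted
#' responses.  Plain least squares (no regularization); a rank-deficient
#' design is fitted with the minimal-norm solution and a warning.
#'
#' @param prob_blocks named list of `L` numeric matrices (`n x C` each),
#'   the cross-validated class probabilities of the level-0 models, all
#'   row-aligned.
#' @param labels true class labels (length `n`).
#' @param class_vocab ordered class vocabulary; defaults to the sorted
#'   distinct labels.
#' @return an object of class `stack1_model`.
#' @export
stack1_fit <- function(prob_blocks, labels, class_vocab = NULL) {
  X <- stack_design(prob_blocks)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  if (is.null(class_vocab)) class_vocab <- sort(unique(labels))
  Y <- vapply(class_vocab, function(k) as.numeric(labels == k),
              numeric(length(labels)))
  Xi <- cbind(`(intercept)` = 1, X)
  sv <- svd(Xi)
  tol <- max(dim(Xi)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  if (sum(pos) < ncol(Xi))
    warning("rank-deficient level-1 design (rank ", sum(pos), " < ",
            ncol(Xi), "); using the minimal-norm least-squares solution")
  dinv <- ifelse(pos, 1 / sv$d, 0)
  B <- sv$v %*% (dinv * (t(sv$u) %*% Y))
  dimnames(B) <- list(colnames(Xi), class_vocab)
  structure(list(coefficients = B, class_vocab = class_vocab,
                 feature_names = colnames(X)),
            class = "stack1_model")
}

#' Predict with a Stack 1 model
#'
#' @param object a `stack1_model`.
#' @param prob_blocks list of probability blocks as in [stack1_fit()].
#' @param ... unused.
#' @return character vector of predicted classes (argmax of the fitted
#'   responses; ties to the lowest vocabulary index).
#' @export
predict.stack1_model <- function(object, prob_blocks, ...) {
  X <- stack_design(prob_blocks)
  if (!identical(colnames(X), object$feature_names))
    stop("level-1 feature columns do not match the fitted design")
  scores <- cbind(1, X) %*% object$coefficients
  object$class_vocab[max.col(scores, ties.method = "first")]
}

#' Fit the random-forest stacker (Stack 2)
#'
#' Level-1 learning on the cross-validated outputs of the level-0 models:
#' the design holds all `L x C` class probabilities plus the `L`
#' predicted-class columns (as categorical variables, which the forest
#' splits on directly), and a random forest is the level-1 classifier.
#'
#' @inheritParams stack1_fit
#' @param pred_classes named list of `L` character vectors, the level-0
#'   predicted classes, row-aligned with `prob_blocks`.
#' @param seed integer seed for the forest.
#' @param ntree number of trees.
#' @return an object of class `stack2_model`.
#' @export
stack2_fit <- function(prob_blocks, pred_classes, labels,
                       class_vocab = NULL, seed = 1L, ntree = 300) {
  X <- stack_design(prob_blocks)
  labels <- as.character(labels)
  if (is.null(class_vocab)) class_vocab <- sort(unique(labels))
  df <- as.data.frame(X)
  nm <- names(pred_classes) %||% paste0("m", seq_along(pred_classes))
  for (i in seq_along(pred_classes))
    df[[paste0("pred.", nm[i])]] <-
      factor(pred_classes[[i]], levels = class_vocab)
  y <- factor(labels, levels = class_vocab)
  fit <- with_seed(derive_seed(seed, "stack2"),
                   randomForest::randomForest(df, y, ntree = ntree))
  structure(list(forest = fit, class_vocab = class_vocab,
                 feature_names = names(df), model_names = nm),
            class = "stack2_model")
}

#' Predict with a Stack 2 model
#'
#' @param object a `stack2_model`.
#' @param prob_blocks,pred_classes level-1 inputs as in [stack2_fit()].
#' @param ... unused.
#' @return character vector of predicted classes.
#' @export
predict.stack2_model <- function(object, prob_blocks, pred_classes, ...) {
  X <- stack_design(prob_blocks)
  df <- as.data.frame(X)
  nm <- names(pred_classes) %||% object$model_names
  for (i in seq_along(pred_classes))
    df[[paste0("pred.", nm[i])]] <-
      factor(pred_classes[[i]], levels = object$class_vocab)
  if (!identical(names(df), object$feature_names))
    stop("level-1 feature columns do not match the fitted design")
  as.character(predict(object$forest, df))
}

#' Leave-one-classifier-out contribution analysis
#'
#' Quantifies what each base model adds to the combined classifier: for
#' each model `m` and each target precision `P0`, the recall of the full
#' `L`-model PINCom at `P0` minus the recall of the PINCom rebuilt from
#' the other `L - 1` models at the same `P0`.  Positive values mean the
#' model helps at that precision; negative values mean the combination
#' does better without it.  Entries where `P0` is unreachable by either
#' combination are `NA`.
#'
#' @param per_model_records list of `L >= 3` aligned prediction-record
#'   data frames with `pin`, `predicted_class` and `true_class`.
#' @param precisions numeric vector of target precision levels.
#' @param seed tie-break seed passed to [combine_pin()].
#' @return a data frame, one row per model, one column per precision
#'   level, entries = recall differences (full minus ablated).
#' @export
contribution_analysis <- function(per_model_records, precisions,
                                  seed = 1L) {
  if (length(per_model_records) < 3L)
    stop("contribution analysis needs >= 3 models (ablation must leave ",
         "a combination of >= 2)")
  mids <- model_ids_of(per_model_records)
  recall_at <- function(records, P0) {
    cv <- rp_curve(records, "max_pin")
    tryCatch(threshold_for_precision(cv, P0)$recall,
             error = function(e) NA_real_)
  }
  full <- combine_pin(per_model_records, seed = seed)
  full_rec <- vapply(precisions, function(p) recall_at(full, p),
                     numeric(1))
  out <- matrix(NA_real_, length(per_model_records), length(precisions),
                dimnames = list(mids, paste0("P", precisions)))
  for (m in seq_along(per_model_records)) {
    abl <- combine_pin(per_model_records[-m], seed = seed)
    abl_rec <- vapply(precisions, function(p) recall_at(abl, p),
                      numeric(1))
    out[m, ] <- full_rec - abl_rec
  }
  as.data.frame(out)
}
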