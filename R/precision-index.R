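# The precision index: calibrating MaxP onto an observed-precision scale.
#
# For a scored prediction set, Pindex(a) is the precision of the subset of
# predictions whose score is at least a.  Regressing the observed Pindex
# values isotonically on MaxP (one knot per distinct MaxP, weighted by tie
# multiplicity) and interpolating linearly yields PIN, a monotone
# non-decreasing calibration that is comparable across arbitrary
# classifiers.  PIC repeats the construction inside each predicted class,
# as a function of PIN.

#' Extract predicted classes and MaxP from a posterior matrix
#'
#' For each row, `predicted_class` is the argmax class (ties broken by the
#' lowest class-vocabulary index, deterministically) and `maxp` is the
#' maximum posterior probability -- the classifier's raw confidence.
#'
#' @param P a [posterior_matrix()].
#' @param true_labels optional vector of true class labels, either named
#'   by instance id or aligned with the rows of `P`.
#' @return a data frame of prediction records with columns `instance_id`,
#'   `model_id`, `predicted_class`, `true_class` (`NA` when unknown) and
#'   `maxp`.
#' @export
maxp_and_class <- function(P, true_labels = NULL) {
  stopifnot(inherits(P, "posterior_matrix"))
  probs <- P$probs
  if (nrow(probs) == 0L) {
    return(data.frame(instance_id = character(0), model_id = character(0),
                      predicted_class = character(0),
                      true_class = character(0), maxp = numeric(0),
                      stringsAsFactors = FALSE))
  }
  j <- max.col(probs, ties.method = "first")
  maxp <- probs[cbind(seq_len(nrow(probs)), j)]
  true_class <- rep(NA_character_, nrow(probs))
  if (!is.null(true_labels)) {
    if (!is.null(names(true_labels))) {
      true_class <- as.character(true_labels[P$instance_ids])
    } else {
      stopifnot(length(true_labels) == nrow(probs))
      true_class <- as.character(true_labels)
    }
  }
  data.frame(instance_id = P$instance_ids,
             model_id = P$model_id,
             predicted_class = colnames(probs)[j],
             true_class = true_class,
             maxp = maxp,
             stringsAsFactors = FALSE)
}

# Per-record tail precision: for each i, (# correct with score >= score_i) /
# (# with score >= score_i).  Records with equal scores share one value.
tail_precision <- function(score, correct) {
  n <- length(score)
  stopifnot(length(correct) == n, n >= 1L)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  prec <- cumsum(correct[ord]) / seq_len(n)
  r <- rle(s)
  last <- cumsum(r$lengths)
  out_sorted <- rep.int(prec[last], r$lengths)
  out <- numeric(n)
  out[ord] <- out_sorted
  out
}

#' Observed tail precision (Pindex) of scored predictions
#'
#' For each record `i`, returns
#' `Pindex(maxp_i) = #\{correct, maxp >= maxp_i\} / #\{maxp >= maxp_i\}`.
#' Records with equal `maxp` receive equal values: Pindex is a function of
#' the threshold, not of the record.
#'
#' @param records prediction-record data frame with columns `maxp`,
#'   `predicted_class` and `true_class` (all known).
#' @return numeric vector of tail precisions aligned with `records`.
#' @export
#' @examples
#' r <- data.frame(maxp = c(0.9, 0.8, 0.7, 0.6),
#'                 predicted_class = c("a", "a", "b", "a"),
#'                 true_class = c("a", "a", "a", "a"))
#' observed_pindex(r)  # 1, 1, 2/3, 3/4
observed_pindex <- function(records) {
  check_scored(records, "maxp", need_truth = TRUE)
  tail_precision(records$maxp,
                 records$predicted_class == records$true_class)
}

check_scored <- function(records, score_col, need_truth = FALSE) {
  stopifnot(is.data.frame(records))
  need <- c(score_col, "predicted_class", if (need_truth) "true_class")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack column(s): ", paste(miss, collapse = ", "))
  if (need_truth && anyNA(records$true_class))
    stop("all records must have a known true_class")
  invisible(records)
}

# Shared core: isotonic tail-precision curve of `correct` against `score`.
# One knot per distinct score, weight = multiplicity.
fit_precision_curve <- function(score, correct) {
  pind <- tail_precision(score, correct)
  ord <- order(score)
  s <- score[ord]; p <- pind[ord]
  r <- rle(s)
  first <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  knots <- r$values
  raw <- p[first]              # equal within a tie block
  w <- r$lengths
  list(knots = knots, raw = raw, weights = w,
       values = pava_fit(raw, w))
}

#' Fit the precision-index (PIN) function of one model
#'
#' Fits the monotone non-decreasing calibration of observed tail precision
#' (Pindex) on MaxP: one knot per distinct MaxP value, weighted isotonic
#' least squares (weight = number of tied records), evaluated between
#' knots by linear interpolation and outside the knot range by clamping to
#' the endpoint values.
#'
#' @param records prediction records with known `true_class` (typically
#'   pooled cross-validated predictions; at least 2).
#' @param model_id model identifier; defaults to the records' single
#'   `model_id`.
#' @return an object of class `pin_function` with elements `model_id`,
#'   `knots`, `values` and the raw (pre-smoothing) curve for diagnostics.
#' @seealso [predict.pin_function()], [fit_pic()]
#' @export
fit_pin <- function(records, model_id = NULL) {
  check_scored(records, "maxp", need_truth = TRUE)
  if (nrow(records) < 2L) stop("fit_pin needs at least 2 records")
  if (is.null(model_id)) {
    ids <- unique(records$model_id %||% "model")
    model_id <- if (length(ids) == 1L) ids else "pooled"
  }
  cur <- fit_precision_curve(records$maxp,
                             records$predicted_class == records$true_class)
  structure(
    list(model_id = model_id, knots = cur$knots, values = cur$values,
         raw = cur$raw, weights = cur$weights),
    class = "pin_function")
}

#' Evaluate a fitted PIN function
#'
#' Piecewise-linear evaluation of the calibration: linear interpolation
#' between knots, clamped to the endpoint values outside the observed MaxP
#' range.  Monotone non-decreasing in its argument.
#'
#' @param object a `pin_function` from [fit_pin()].
#' @param maxp numeric vector of MaxP values in `[0, 1]`.
#' @param ... unused.
#' @return numeric vector of PIN values in `[0, 1]`.
#' @export
predict.pin_function <- function(object, maxp, ...) {
  if (is.null(object$knots) || !length(object$knots))
    stop("pin_function has not been fitted")
  stopifnot(all(maxp >= 0 & maxp <= 1))
  if (length(object$knots) == 1L)
    return(rep(object$values, length(maxp)))
  approx(object$knots, object$values, xout = maxp, rule = 2,
         ties = "ordered")$y
}

#' @export
print.pin_function <- function(x, ...) {
  cat("<pin_function> model ", x$model_id, ": ", length(x$knots),
      " knots, PIN range [", format(min(x$values), digits = 4), ", ",
      format(max(x$values), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Attach PIN values to prediction records
#'
#' @param records prediction records with a `maxp` column.
#' @param pin_function a fitted `pin_function`.
#' @return `records` with a `pin` column added/replaced.
#' @export
add_pin <- function(records, pin_function) {
  check_scored(records, "maxp")
  records$pin <- predict(pin_function, records$maxp)
  records
}

#' Fit class-specific precision-index (PIC) functions
#'
#' For each predicted class `k`, restricts to the records predicted as `k`
#' and fits the class-specific tail precision over the threshold variable
#' `a = PIN` -- the same tail-count + isotonic + interpolation procedure
#' as [fit_pin()], with PIN as abscissa.  `PIC(x) = P_k(PIN(x))` for a
#' record predicted as `k`.  Classes with fewer than `min_support`
#' predictions get a constant PIC equal to the class precision (an
#' isotonic fit on 1-2 points is vacuous).
#'
#' @param records prediction records with known `true_class` and a `pin`
#'   column (see [add_pin()]).
#' @param model_id model identifier (defaulted as in [fit_pin()]).
#' @param min_support minimum number of predictions for a per-class
#'   isotonic fit (default 3).
#' @return an object of class `pic_function`: per-class curves plus the
#'   fallback policy for classes never predicted in the training records
#'   (evaluation then returns the record's PIN, with a warning).
#' @export
fit_pic <- function(records, model_id = NULL, min_support = 3L) {
  check_scored(records, "pin", need_truth = TRUE)
  if (is.null(model_id)) {
    ids <- unique(records$model_id %||% "model")
    model_id <- if (length(ids) == 1L) ids else "pooled"
  }
  curves <- list()
  for (k in sort(unique(records$predicted_class))) {
    sub <- records[records$predicted_class == k, , drop = FALSE]
    correct <- sub$predicted_class == sub$true_class
    if (nrow(sub) < min_support) {
      curves[[k]] <- list(constant = mean(correct))
    } else {
      cur <- fit_precision_curve(sub$pin, correct)
      curves[[k]] <- list(knots = cur$knots, values = cur$values,
                          raw = cur$raw, weights = cur$weights)
    }
  }
  structure(list(model_id = model_id, curves = curves),
            class = "pic_function")
}

#' Evaluate a fitted PIC function
#'
#' @param object a `pic_function` from [fit_pic()].
#' @param predicted_class character vector of predicted classes.
#' @param pin numeric vector of PIN values (recycled against
#'   `predicted_class`).
#' @param ... unused.
#' @return numeric vector of PIC values in `[0, 1]`.  For classes never
#'   seen among the training predictions the record's PIN is returned
#'   unchanged (a conservative fallback) with a warning.
#' @export
predict.pic_function <- function(object, predicted_class, pin, ...) {
  n <- max(length(predicted_class), length(pin))
  predicted_class <- rep_len(as.character(predicted_class), n)
  pin <- rep_len(pin, n)
  out <- numeric(n)
  unseen <- character(0)
  for (k in unique(predicted_class)) {
    idx <- which(predicted_class == k)
    cur <- object$curves[[k]]
    if (is.null(cur)) {
      unseen <- c(unseen, k)
      out[idx] <- pin[idx]
    } else if (!is.null(cur$constant)) {
      out[idx] <- cur$constant
    } else if (length(cur$knots) == 1L) {
      out[idx] <- cur$values
    } else {
      out[idx] <- approx(cur$knots, cur$values, xout = pin[idx],
                         rule = 2, ties = "ordered")$y
    }
  }
  if (length(unseen))
    warning("no training predictions for class(es) ",
            paste(unseen, collapse = ", "),
            "; falling back to the PIN value")
  out
}

#' Attach PIC values to prediction records
#'
#' @param records prediction records with `predicted_class` and `pin`.
#' @param pic_function a fitted `pic_function`.
#' @return `records` with a `pic` column added/replaced.
#' @export
add_pic <- function(records, pic_function) {
  check_scored(records, "pin")
  records$pic <- predict(pic_function, records$predicted_class,
                         records$pin)
  records
}
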