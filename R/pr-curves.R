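# Recall-precision curves over confidence-score thresholds, with monotone
# smoothing and threshold inversion.
#
# For a score s (MaxP, PIN, MaxPIN or PIC) and threshold a, the curve
# tracks P(a) = precision of {s >= a} and R(a) = (# correct in {s >= a}) /
# n_total.  P(0) and R(0) coincide: both are the overall precision of the
# full prediction set.  P is smoothed isotonically (non-decreasing) and R
# antitonically (non-increasing), each with one knot per distinct score
# weighted by multiplicity; raw step curves are retained for diagnostics.

#' Build a recall-precision curve from scored predictions
#'
#' @param records prediction records with known `true_class` and the
#'   column named by `score`.
#' @param score name of the score column (`"maxp"`, `"pin"`, `"max_pin"`,
#'   `"pic"`, ...).
#' @return an object of class `rp_curve`: a table of thresholds `a`
#'   (the distinct observed scores, with 0 prepended), raw and smoothed
#'   `P` and `R`, knot weights, and `n_total`.
#' @export
#' @examples
#' r <- data.frame(maxp = c(0.9, 0.8, 0.7),
#'                 predicted_class = c("a", "b", "a"),
#'                 true_class = c("a", "a", "a"))
#' cv <- rp_curve(r, "maxp")
#' cv$P_smooth[1]  # overall precision 2/3
rp_curve <- function(records, score = "pin") {
  check_scored(records, score, need_truth = TRUE)
  if (nrow(records) == 0L) stop("empty record set")
  s <- records[[score]]
  stopifnot(all(is.finite(s)), all(s >= 0 & s <= 1))
  correct <- records$predicted_class == records$true_class
  n_total <- length(s)
  ord <- order(s)
  ss <- s[ord]; cc <- correct[ord]
  r <- rle(ss)
  knots <- r$values
  w <- r$lengths
  # tail counts at each distinct score, from the right
  n_ge <- rev(cumsum(rev(w)))
  first <- cumsum(c(1L, w[-length(w)]))
  corr_at <- vapply(seq_along(knots), function(i)
    sum(cc[first[i]:(first[i] + w[i] - 1L)]), numeric(1))
  c_ge <- rev(cumsum(rev(corr_at)))
  P_raw <- c_ge / n_ge
  R_raw <- c_ge / n_total
  P_smooth <- pava_fit(P_raw, w)
  R_smooth <- antitonic_fit(R_raw, w)
  # prepend the zero threshold (full set; weightless duplicate of knot 1)
  if (knots[1] > 0) {
    knots <- c(0, knots); w <- c(0L, w)
    P_raw <- c(P_raw[1], P_raw); R_raw <- c(R_raw[1], R_raw)
    P_smooth <- c(P_smooth[1], P_smooth)
    R_smooth <- c(R_smooth[1], R_smooth)
  }
  structure(
    list(score_name = score,
         a = knots, P_raw = P_raw, R_raw = R_raw,
         P_smooth = P_smooth, R_smooth = R_smooth,
         weights = w, n_total = n_total),
    class = "rp_curve")
}

#' Class-specific recall-precision curve
#'
#' Restricts to the predictions assigned to class `k`:
#' `P_k(a)` is the precision of `{predicted = k, score >= a}` and
#' `R_k(a)` the number correct in that subset divided by the number of
#' instances whose *true* class is `k`.
#'
#' @inheritParams rp_curve
#' @param k class name.
#' @return an `rp_curve` (with `n_total` = count of true-`k` instances).
#' @export
class_rp_curve <- function(records, k, score = "pin") {
  check_scored(records, score, need_truth = TRUE)
  n_true_k <- sum(records$true_class == k)
  sub <- records[records$predicted_class == k, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no record predicted to class '", k, "'")
  if (n_true_k == 0L)
    stop("no record with true class '", k, "': recall undefined")
  s <- sub[[score]]
  correct <- sub$predicted_class == sub$true_class
  ord <- order(s)
  ss <- s[ord]; cc <- correct[ord]
  r <- rle(ss)
  knots <- r$values; w <- r$lengths
  n_ge <- rev(cumsum(rev(w)))
  first <- cumsum(c(1L, w[-length(w)]))
  corr_at <- vapply(seq_along(knots), function(i)
    sum(cc[first[i]:(first[i] + w[i] - 1L)]), numeric(1))
  c_ge <- rev(cumsum(rev(corr_at)))
  P_raw <- c_ge / n_ge
  R_raw <- c_ge / n_true_k
  P_smooth <- pava_fit(P_raw, w)
  R_smooth <- antitonic_fit(R_raw, w)
  if (knots[1] > 0) {
    knots <- c(0, knots); w <- c(0L, w)
    P_raw <- c(P_raw[1], P_raw); R_raw <- c(R_raw[1], R_raw)
    P_smooth <- c(P_smooth[1], P_smooth)
    R_smooth <- c(R_smooth[1], R_smooth)
  }
  structure(
    list(score_name = score, class = k,
         a = knots, P_raw = P_raw, R_raw = R_raw,
         P_smooth = P_smooth, R_smooth = R_smooth,
         weights = w, n_total = n_true_k),
    class = "rp_curve")
}

# Piecewise-linear evaluation of a smoothed curve component at thresholds x.
eval_curve <- function(curve, x, what = c("P", "R")) {
  what <- match.arg(what)
  yy <- if (what == "P") curve$P_smooth else curve$R_smooth
  if (length(curve$a) == 1L) return(rep(yy, length(x)))
  approx(curve$a, yy, xout = x, rule = 2, ties = "ordered")$y
}

#' Smallest threshold reaching a target precision
#'
#' Solves `P(a0) = P0` on the smoothed precision curve by inverse linear
#' interpolation, returning the *smallest* qualifying threshold -- i.e.
#' the largest prediction subset with precision at least `P0`.
#'
#' @param curve an [rp_curve()].
#' @param P0 target precision in `[0, 1]`.
#' @return a list with `threshold` (a0), `precision` (smoothed P(a0)),
#'   `recall` (smoothed R(a0)) and `subset_size` (number of predictions
#'   with score >= a0 among the curve's knot weights).
#' @export
threshold_for_precision <- function(curve, P0) {
  stopifnot(inherits(curve, "rp_curve"), P0 >= 0, P0 <= 1)
  P <- curve$P_smooth; a <- curve$a
  pmax_curve <- max(P)
  if (P0 > pmax_curve + 1e-12)
    stop("unreachable precision: target ", format(P0),
         " exceeds the achievable maximum ", format(pmax_curve))
  if (P0 <= P[1]) {
    a0 <- a[1]
  } else {
    i <- which(P >= P0)[1]          # first knot at/above target
    if (P[i - 1] >= P0 - 1e-15 || a[i] == a[i - 1]) {
      a0 <- a[i]
    } else {
      a0 <- a[i - 1] + (P0 - P[i - 1]) / (P[i] - P[i - 1]) *
        (a[i] - a[i - 1])
    }
  }
  list(threshold = a0,
       precision = eval_curve(curve, a0, "P"),
       recall = eval_curve(curve, a0, "R"),
       subset_size = sum(curve$weights[curve$a >= a0 - 1e-12]))
}

#' Largest threshold retaining a target recall
#'
#' Returns the largest `a0` with smoothed `R(a0) >= R0` -- the
#' highest-precision subset still delivering the requested recall.
#'
#' @param curve an [rp_curve()].
#' @param R0 target recall in `[0, R(0)]`.
#' @return a list with `threshold`, `precision` and `recall` at `a0`.
#' @export
threshold_for_recall <- function(curve, R0) {
  stopifnot(inherits(curve, "rp_curve"), R0 >= 0, R0 <= 1)
  R <- curve$R_smooth; a <- curve$a
  if (R0 > R[1] + 1e-12)
    stop("unreachable recall: target ", format(R0),
         " exceeds the overall recall ", format(R[1]))
  n <- length(a)
  if (R0 <= R[n]) {
    a0 <- a[n]
  } else {
    # R is non-increasing: find the segment where it crosses R0
    i <- max(which(R >= R0 - 1e-15))  # last knot still at/above target
    if (i == n || R[i] <= R0 + 1e-15) {
      a0 <- a[i]
    } else {
      a0 <- a[i] + (R[i] - R0) / (R[i] - R[i + 1]) * (a[i + 1] - a[i])
    }
  }
  list(threshold = a0,
       precision = eval_curve(curve, a0, "P"),
       recall = eval_curve(curve, a0, "R"))
}

#' @export
print.rp_curve <- function(x, ...) {
  cat("<rp_curve> score ", x$score_name,
      if (!is.null(x$class)) paste0(", class ", x$class),
      ": ", length(x$a), " thresholds, overall P(0) = R(0) = ",
      format(x$P_smooth[1], digits = 4),
      ", max smoothed precision ", format(max(x$P_smooth), digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.rp_curve <- function(x, ...) {
  data.frame(a = x$a, P_raw = x$P_raw, R_raw = x$R_raw,
             P_smooth = x$P_smooth, R_smooth = x$R_smooth)
}

#' Plot one or more recall-precision curves
#'
#' Draws recall (y) against precision (x) for the smoothed curves, one
#' line per model, the standard display for comparing classifiers'
#' ability to deliver large high-precision prediction sets.
#'
#' @param x an [rp_curve()].
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.rp_curve <- function(x, ...) {
  l <- list(x)
  names(l) <- x$score_name %||% "curve"
  plot_rp_curves(l, ...)
}

#' Overlay several recall-precision curves
#'
#' @param curves a named list of [rp_curve()] objects (one per model).
#' @param main plot title.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot_rp_curves <- function(curves, main = "Recall-Precision curves", ...) {
  if (inherits(curves, "rp_curve")) curves <- list(curve = curves)
  cols <- seq_along(curves)
  plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "Precision P(a)",
       ylab = "Recall R(a)", main = main, ...)
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    lines(cv$P_smooth, cv$R_smooth, col = cols[i], lwd = 2)
  }
  legend("topright", legend = names(curves), col = cols, lwd = 2,
         bty = "n")
  invisible(curves)
}
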