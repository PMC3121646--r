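# Weighted isotonic regression by pool-adjacent-violators.
#
# This is the numerical core of the precision-index calibration: observed
# tail precisions are regressed monotonically on the confidence score, with
# one knot per distinct score and weight equal to the number of tied
# records.  stats::isoreg is unweighted, so the weighted fit is implemented
# directly; with integer weights the two agree on replicated data, which
# the tests exploit as an independent cross-check.

#' Weighted isotonic (non-decreasing) least-squares fit
#'
#' Given responses `y` at increasing abscissae with positive weights `w`,
#' returns the monotone non-decreasing vector minimizing
#' `sum(w * (y - fit)^2)`, via the pool-adjacent-violators algorithm.
#' The fit preserves the weighted mean of `y` and, on each pooled block,
#' equals the block's weighted mean.
#'
#' @param y numeric responses, ordered by their abscissa.
#' @param w positive weights (default all 1).
#' @return numeric vector of fitted values, same length as `y`.
#' @export
#' @examples
#' pava_fit(c(0.75, 2 / 3, 1, 1))  # first two pool to their mean
pava_fit <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  stopifnot(length(w) == n, all(w > 0), all(is.finite(y)))
  if (n == 0L) return(numeric(0))
  val <- numeric(n); wt <- numeric(n); len <- integer(n)
  nb <- 0L
  for (i in seq_len(n)) {
    nb <- nb + 1L
    val[nb] <- y[i]; wt[nb] <- w[i]; len[nb] <- 1L
    while (nb > 1L && val[nb - 1L] > val[nb]) {
      pooled_w <- wt[nb - 1L] + wt[nb]
      val[nb - 1L] <- (wt[nb - 1L] * val[nb - 1L] + wt[nb] * val[nb]) /
        pooled_w
      wt[nb - 1L] <- pooled_w
      len[nb - 1L] <- len[nb - 1L] + len[nb]
      nb <- nb - 1L
    }
  }
  rep.int(val[seq_len(nb)], len[seq_len(nb)])
}

#' Weighted antitonic (non-increasing) least-squares fit
#'
#' The mirror image of [pava_fit()]: the monotone non-increasing vector
#' minimizing the weighted squared error.
#'
#' @inheritParams pava_fit
#' @return numeric vector of fitted values.
#' @export
antitonic_fit <- function(y, w = rep(1, length(y))) {
  -pava_fit(-y, w)
}
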