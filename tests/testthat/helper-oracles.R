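# Independent oracles used across the suite.  Each is a deliberately
# naive reference implementation (brute force or exhaustive enumeration)
# kept separate from the code paths it checks.

# O(n^2) tail precision: for each record i, count pairs directly.
brute_pindex <- function(maxp, correct) {
  vapply(seq_along(maxp), function(i) {
    idx <- maxp >= maxp[i]
    sum(correct[idx]) / sum(idx)
  }, numeric(1))
}

# Exhaustive weighted isotonic minimizer: enumerate every partition of
# the points into contiguous blocks, keep those with non-decreasing
# weighted block means, and return the fit with the smallest weighted
# squared error.  Feasible for n <= 12.
iso_exhaustive <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 1L) return(y)
  best <- NULL
  best_sse <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    bounds <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    starts <- c(1L, bounds + 1L)
    ends <- c(bounds, n)
    means <- mapply(function(s, e) sum(w[s:e] * y[s:e]) / sum(w[s:e]),
                    starts, ends)
    if (is.unsorted(means)) next
    fit <- rep(means, ends - starts + 1L)
    sse <- sum(w * (y - fit)^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}

# Random scored prediction records with known truth.
rand_records <- function(n, n_class = 3, seed = 1, model_id = "m") {
  set.seed(seed)
  cls <- paste0("k", seq_len(n_class))
  pred <- sample(cls, n, replace = TRUE)
  truth <- ifelse(runif(n) < 0.5, pred, sample(cls, n, replace = TRUE))
  data.frame(instance_id = paste0("i", seq_len(n)),
             model_id = model_id,
             predicted_class = pred,
             true_class = truth,
             maxp = runif(n, 1 / n_class, 1),
             stringsAsFactors = FALSE)
}

# Perfectly calibrated records: correctness ~ Bernoulli(maxp).
calibrated_records <- function(n, seed = 1, maxp_range = c(0.2, 1)) {
  set.seed(seed)
  maxp <- runif(n, maxp_range[1], maxp_range[2])
  correct <- rbinom(n, 1, maxp) == 1
  data.frame(instance_id = paste0("i", seq_len(n)),
             model_id = "cal",
             predicted_class = "a",
             true_class = ifelse(correct, "a", "b"),
             maxp = maxp,
             stringsAsFactors = FALSE)
}

# A tiny, fast, well-separated mixture for protocol tests.
small_mixture <- function(seed = 1, C = 3, per_class = 20, d = 4,
                          sigma = 1, separability = 2.5) {
  mixture_config(C = C, sizes = rep(per_class, C), d = d, sigma = sigma,
                 separability = separability, seed = seed)
}
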