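# Synthetic Gaussian-mixture benchmark with an exact Bayes-posterior oracle.
#
# The generator emulates the statistical setting the precision-index method
# assumes: many classes of very unequal size, moderate dimension, and
# heterogeneous separability so that no single classifier dominates every
# class.  A shared spherical covariance keeps the Bayes posterior in closed
# form, which the calibration tests use as a perfectly calibrated reference
# classifier.

# Default class sizes: 21 classes spanning 8..50 instances, 367 in total,
# mirroring a gene-function training set with small KEGG-style classes.
.default_sizes <- c(8L, 8L, 9L, 10L, 10L, 11L, 12L, 12L, 13L, 14L, 15L,
                    16L, 17L, 18L, 19L, 20L, 22L, 25L, 28L, 30L, 50L)

#' Configure a Gaussian-mixture population
#'
#' Defines a `C`-class mixture of spherical Gaussians
#' `N(mean_k, sigma^2 I_d)` with fixed per-class sample counts.  Class
#' means are placed on random directions (drawn once, deterministically
#' from `seed`) scaled by a per-class separability multiplier, so some
#' classes are easy and others hard -- the regime in which combining
#' heterogeneous classifiers pays off.
#'
#' Defaults emulate a gene-function classification setting: 21 classes
#' with sizes from 8 to 50 (367 instances in total) and 60 numeric
#' features.
#'
#' @param C number of classes.
#' @param sizes integer vector of per-class training counts (length `C`).
#' @param d feature dimension.
#' @param sigma shared within-class standard deviation (spherical).
#' @param separability per-class multiplier on the mean norm (length `C`
#'   or scalar); larger means an easier class.  Default ramps linearly
#'   from 1 to 3 across classes.
#' @param means optional `C x d` matrix of class means; if `NULL`, means
#'   are generated from `seed` as `separability[k] * u_k` with `u_k` a
#'   random unit vector.
#' @param seed integer seed; the configuration (including the means) and
#'   every draw from it are pure functions of the seed.
#' @return an object of class `mixture_config`.
#' @export
#' @examples
#' cfg <- mixture_config(C = 3, sizes = c(10, 20, 30), d = 4, seed = 1)
#' cfg$sizes
mixture_config <- function(C = 21L,
                           sizes = NULL,
                           d = 60L,
                           sigma = 1,
                           separability = NULL,
                           means = NULL,
                           seed = 1L) {
  C <- as.integer(C)
  if (is.null(sizes)) {
    sizes <- if (C == 21L) .default_sizes else rep(20L, C)
  }
  sizes <- as.integer(sizes)
  if (length(sizes) != C) stop("length(sizes) must equal C")
  if (any(sizes < 1L)) stop("all class sizes must be >= 1")
  if (sigma <= 0) stop("sigma must be > 0")
  if (is.null(separability)) {
    separability <- if (C > 1) seq(1, 3, length.out = C) else 2
  }
  if (length(separability) == 1L) separability <- rep(separability, C)
  if (length(separability) != C) stop("separability must have length C")
  classes <- paste0("class", formatC(seq_len(C), width = 2, flag = "0"))
  if (is.null(means)) {
    means <- with_seed(derive_seed(seed, "means"), {
      u <- matrix(rnorm(C * d), C, d)
      u <- u / sqrt(rowSums(u^2))
      u * separability
    })
  } else {
    means <- as.matrix(means)
    if (!identical(dim(means), c(C, as.integer(d))))
      stop("means must be a C x d matrix")
  }
  rownames(means) <- classes
  structure(
    list(C = C, sizes = sizes, d = as.integer(d), sigma = sigma,
         separability = separability, means = means,
         classes = classes, seed = as.integer(seed)),
    class = "mixture_config")
}

#' Draw a labeled dataset from a mixture configuration
#'
#' Samples exactly `cfg$sizes[k]` instances from class `k` (deterministic
#' per-class counts, not a multinomial draw, so bookkeeping is exact), each
#' from `N(mean_k, sigma^2 I)`.  A disjoint test draw of `n_test`
#' instances with class proportions matching `cfg$sizes` can be requested.
#'
#' @param cfg a [mixture_config()].
#' @param n_test optional total size of a held-out test draw (0 = none).
#' @param seed seed for this draw; defaults to `cfg$seed`.
#' @return a [labeled_dataset()]; when `n_test > 0`, a list with elements
#'   `train` and `test` (both [labeled_dataset()]).
#' @export
generate_mixture <- function(cfg, n_test = 0L, seed = cfg$seed) {
  stopifnot(inherits(cfg, "mixture_config"))
  draw <- function(sizes, prefix, sub) {
    with_seed(derive_seed(seed, "draw", sub), {
      n <- sum(sizes)
      x <- matrix(NA_real_, n, cfg$d)
      labs <- character(n)
      at <- 0L
      for (k in seq_len(cfg$C)) {
        nk <- sizes[k]
        if (nk == 0L) next
        rows <- at + seq_len(nk)
        x[rows, ] <- matrix(rnorm(nk * cfg$d, sd = cfg$sigma), nk, cfg$d) +
          matrix(cfg$means[k, ], nk, cfg$d, byrow = TRUE)
        labs[rows] <- cfg$classes[k]
        at <- at + nk
      }
      colnames(x) <- paste0("f", seq_len(cfg$d))
      labeled_dataset(x, labs,
                      instance_ids = paste0(prefix, seq_len(n)),
                      class_vocab = cfg$classes)
    })
  }
  train <- draw(cfg$sizes, "g", "train")
  if (n_test <= 0L) return(train)
  test_sizes <- pmax(1L, round(cfg$sizes / sum(cfg$sizes) * n_test))
  test <- draw(test_sizes, "t", "test")
  list(train = train, test = test)
}

#' Exact Bayes posterior of the mixture
#'
#' Computes `p(k | x)` proportional to `size_k * N(x; mean_k, sigma^2 I)`
#' for each row of `x`, using the mixture's own class prior (proportional
#' to `cfg$sizes`).  This is a perfectly calibrated reference classifier:
#' its maximum posterior equals the true probability that its prediction
#' is correct.
#'
#' @param cfg a [mixture_config()].
#' @param x numeric matrix of points (`m x d`) or a single vector.
#' @return an `m x C` matrix of posterior probabilities; rows sum to 1.
#' @export
bayes_posterior <- function(cfg, x) {
  stopifnot(inherits(cfg, "mixture_config"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != cfg$d) stop("x must have ", cfg$d, " columns")
  # log p(k) + log N(x; mean_k, sigma^2 I), constants dropped
  sq <- outer(rowSums(x^2), rep(1, cfg$C)) -
    2 * x %*% t(cfg$means) +
    outer(rep(1, nrow(x)), rowSums(cfg$means^2))
  loglik <- -sq / (2 * cfg$sigma^2)
  logpost <- sweep(loglik, 2, log(cfg$sizes / sum(cfg$sizes)), `+`)
  logpost <- logpost - apply(logpost, 1, max)
  p <- exp(logpost)
  p <- p / rowSums(p)
  colnames(p) <- cfg$classes
  p
}

#' Engineered complementary pseudo-classifiers
#'
#' Builds `L` synthetic posterior generators from a partition of the class
#' set into specialties.  Pseudo-model `m` returns the exact Bayes
#' posterior for instances whose true class lies in its specialty, and a
#' noise-degraded posterior (a convex blend of the Bayes posterior with a
#' random probability vector) elsewhere.  With disjoint specialties
#' covering all classes, no single pseudo-model is good everywhere while
#' every class is covered by some expert -- the scenario in which the
#' PIN-combined classifier must beat every individual model.
#'
#' @param cfg a [mixture_config()].
#' @param specialties list of `L` character vectors forming a partition of
#'   `cfg$classes`.
#' @param noise blend weight in `[0, 1]` toward the random vector on
#'   non-specialty instances; 0 makes every pseudo-model the Bayes oracle.
#' @param seed integer seed for the noise draws.
#' @return a named list of `L` generator functions; each takes a
#'   [labeled_dataset()] and returns a [posterior_matrix()].
#' @export
make_expert_models <- function(cfg, specialties, noise = 0.8, seed = 1L) {
  stopifnot(inherits(cfg, "mixture_config"))
  flat <- unlist(specialties, use.names = FALSE)
  if (anyDuplicated(flat) || !setequal(flat, cfg$classes))
    stop("specialties must form a partition of the mixture classes")
  if (noise < 0 || noise > 1) stop("noise must be in [0, 1]")
  model_ids <- names(specialties) %||% paste0("expert", seq_along(specialties))
  out <- vector("list", length(specialties))
  names(out) <- model_ids
  for (m in seq_along(specialties)) {
    local({
      mm <- m
      out[[mm]] <<- function(data) {
        stopifnot(inherits(data, "labeled_dataset"))
        p <- bayes_posterior(cfg, data$features)
        off <- !(data$labels %in% specialties[[mm]])
        if (any(off) && noise > 0) {
          r <- with_seed(derive_seed(seed, "expert", mm), {
            g <- matrix(rexp(sum(off) * cfg$C), sum(off), cfg$C)
            g / rowSums(g)
          })
          p[off, ] <- (1 - noise) * p[off, , drop = FALSE] + noise * r
        }
        posterior_matrix(model_ids[mm], data$instance_ids, p)
      }
    })
  }
  out
}
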