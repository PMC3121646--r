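# Uniform contract over heterogeneous base classifiers.
#
# Any learner that can emit class-membership probabilities can participate:
# a learner is a function (x, y, newx, params) -> probability matrix with
# one column per level of y, called under an already-set RNG seed.  The
# built-in registry covers the classical probabilistic learners (random
# forest, radial SVM, single-hidden-layer neural network, k-nearest
# neighbours with vote-fraction probabilities, linear discriminant
# analysis, multinomial logistic regression); oversampled variants are
# obtained through the `oversample` flag of the spec rather than separate
# learners.

.learner_registry <- new.env(parent = emptyenv())

#' Register a base learner
#'
#' @param kind string key for the learner.
#' @param fun function `(x, y, newx, params)` returning an
#'   `nrow(newx) x nlevels(y)` probability matrix with columns named by
#'   `levels(y)`; called with the RNG already seeded.
#' @param min_class_size smallest per-class training count the learner
#'   tolerates (used to raise an informative error naming the class).
#' @return `kind`, invisibly.
#' @export
register_learner <- function(kind, fun, min_class_size = 1L) {
  stopifnot(is.character(kind), length(kind) == 1L, is.function(fun))
  assign(kind, list(fun = fun, min_class_size = as.integer(min_class_size)),
         envir = .learner_registry)
  invisible(kind)
}

#' List registered learner kinds
#' @return character vector of learner keys.
#' @export
learner_kinds <- function() sort(ls(.learner_registry))

#' Specify a base classifier
#'
#' @param model_id string naming this model in all downstream tables.
#' @param kind learner key (see [learner_kinds()]).
#' @param params named list of learner hyperparameters.
#' @param oversample if `TRUE`, the training data are oversampled to the
#'   largest class size before every fit (the "oversampled" model
#'   variants).
#' @param n_runs number of averaged stochastic fits (e.g. 10 for neural
#'   networks, whose solutions depend on the random initial weights).
#' @param seed integer seed for this model's fits.
#' @return an object of class `classifier_spec`.
#' @export
#' @examples
#' classifier_spec("rfo", "rf", oversample = TRUE, seed = 7)
classifier_spec <- function(model_id, kind, params = list(),
                            oversample = FALSE, n_runs = 1L, seed = 1L) {
  if (!is.numeric(n_runs) || n_runs < 1) stop("n_runs must be >= 1")
  structure(
    list(model_id = as.character(model_id), kind = as.character(kind),
         params = params, oversample = isTRUE(oversample),
         n_runs = as.integer(n_runs), seed = as.integer(seed)),
    class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("<classifier_spec> ", x$model_id, " [", x$kind, "]",
      if (x$oversample) " oversampled",
      if (x$n_runs > 1) paste0(" x", x$n_runs, " runs"), "\n", sep = "")
  invisible(x)
}

#' Fit a classifier and predict class-membership probabilities
#'
#' The single entry point through which every base model is used: trains
#' the learner named by `spec` on `train` (after oversampling if
#' requested), predicts posterior probabilities for `eval_features`,
#' averages `spec$n_runs` independent stochastic fits, and floors/
#' renormalizes the rows so the result is strictly row-stochastic.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [classifier_spec()].
#' @param train a [labeled_dataset()].
#' @param eval_features numeric matrix with the same column count as
#'   `train$features`.
#' @param eval_ids optional ids for the evaluated rows.
#' @return a [posterior_matrix()] over `train$class_vocab`.
#' @export
fit_predict_proba <- function(spec, train, eval_features, eval_ids = NULL) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(train, "labeled_dataset"))
  eval_features <- as.matrix(eval_features)
  if (ncol(eval_features) != ncol(train$features))
    stop("eval_features has ", ncol(eval_features), " columns but the ",
         "training features have ", ncol(train$features))
  if (is.null(eval_ids))
    eval_ids <- rownames(eval_features) %||%
      paste0("e", seq_len(nrow(eval_features)))
  if (spec$oversample) train <- oversample(train)
  vocab <- train$class_vocab
  if (length(vocab) == 1L) {
    # degenerate vocabulary: probability 1 on the only class
    probs <- matrix(1, nrow(eval_features), 1,
                    dimnames = list(NULL, vocab))
    return(posterior_matrix(spec$model_id, eval_ids, probs))
  }
  if (!exists(spec$kind, envir = .learner_registry))
    stop("unknown learner kind '", spec$kind, "'; registered kinds: ",
         paste(learner_kinds(), collapse = ", "))
  entry <- get(spec$kind, envir = .learner_registry)
  counts <- table(factor(train$labels, levels = vocab))
  if (any(counts < entry$min_class_size)) {
    small <- names(counts)[counts < entry$min_class_size]
    stop("learner '", spec$kind, "' requires >= ", entry$min_class_size,
         " training instances per class; too small: ",
         paste(small, collapse = ", "))
  }
  y <- factor(train$labels, levels = vocab)
  runs <- lapply(seq_len(spec$n_runs), function(r) {
    probs <- with_seed(derive_seed(spec$seed, "fit", r),
                       entry$fun(train$features, y, eval_features,
                                 spec$params))
    probs <- as.matrix(probs)
    if (!setequal(colnames(probs), vocab))
      stop("learner '", spec$kind, "' returned columns not matching the ",
           "class vocabulary")
    posterior_matrix(spec$model_id, eval_ids,
                     probs[, vocab, drop = FALSE])
  })
  if (length(runs) == 1L) runs[[1]] else average_runs(runs)
}

# ---- built-in learners -----------------------------------------------------

.learn_rf <- function(x, y, newx, params) {
  fit <- randomForest::randomForest(
    x, y, ntree = params$ntree %||% 500,
    mtry = params$mtry %||% max(1L, floor(sqrt(ncol(x)))))
  predict(fit, newx, type = "prob")
}

.learn_svm <- function(x, y, newx, params) {
  fit <- e1071::svm(x, y, kernel = "radial", probability = TRUE,
                    gamma = params$gamma %||% (1 / ncol(x)),
                    cost = params$cost %||% 1)
  pr <- predict(fit, newx, probability = TRUE)
  attr(pr, "probabilities")
}

.learn_nn <- function(x, y, newx, params) {
  ymat <- nnet::class.ind(y)
  fit <- nnet::nnet(x, ymat, size = params$size %||% 5,
                    decay = params$decay %||% 0.01,
                    maxit = params$maxit %||% 200,
                    softmax = TRUE, trace = FALSE,
                    MaxNWts = params$MaxNWts %||% 20000)
  p <- predict(fit, newx)
  colnames(p) <- colnames(ymat)
  p
}

# k-nearest neighbours with probabilities = neighbour vote fractions
.learn_knn <- function(x, y, newx, params) {
  k <- params$k %||% 5L
  k <- min(k, nrow(x))
  lev <- levels(y)
  d2 <- outer(rowSums(newx^2), rep(1, nrow(x))) -
    2 * newx %*% t(x) + outer(rep(1, nrow(newx)), rowSums(x^2))
  p <- matrix(0, nrow(newx), length(lev), dimnames = list(NULL, lev))
  for (i in seq_len(nrow(newx))) {
    nb <- y[order(d2[i, ])[seq_len(k)]]
    p[i, ] <- tabulate(nb, nbins = length(lev)) / k
  }
  p
}

.learn_lda <- function(x, y, newx, params) {
  fit <- MASS::lda(x, grouping = y)
  post <- predict(fit, newx)$posterior
  # lda drops nothing here, but align defensively
  out <- matrix(0, nrow(newx), nlevels(y), dimnames = list(NULL, levels(y)))
  out[, colnames(post)] <- post
  out
}

.learn_multinom <- function(x, y, newx, params) {
  df <- data.frame(x)
  fit <- nnet::multinom(y ~ ., data = cbind(df, y = y), trace = FALSE,
                        decay = params$decay %||% 0,
                        maxit = params$maxit %||% 200,
                        MaxNWts = params$MaxNWts %||% 20000)
  p <- predict(fit, data.frame(newx), type = "probs")
  if (is.null(dim(p))) {  # two-class case returns a vector
    p <- cbind(1 - p, p)
    colnames(p) <- levels(y)
  }
  p
}

.register_builtin_learners <- function() {
  register_learner("rf", .learn_rf)
  register_learner("svm", .learn_svm, min_class_size = 2L)
  register_learner("nn", .learn_nn)
  register_learner("knn", .learn_knn)
  register_learner("lda", .learn_lda, min_class_size = 2L)
  register_learner("multinom", .learn_multinom)
}

.onLoad <- function(libname, pkgname) {
  .register_builtin_learners()
}
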