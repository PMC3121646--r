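# Core containers: labeled datasets and posterior-probability matrices.

#' Construct a labeled dataset
#'
#' Bundles a numeric feature matrix with one categorical class label per
#' instance.  This is the unit consumed by all classifiers and validation
#' protocols.
#'
#' @param features numeric matrix, instances in rows and features in
#'   columns.
#' @param labels character (or factor) vector of class labels, one per row
#'   of `features`.
#' @param instance_ids character vector of unique instance identifiers;
#'   defaults to the rownames of `features` or `"i1", "i2", ...`.
#' @param class_vocab ordered character vector of the distinct class names;
#'   defaults to the sorted distinct labels.  Every label must be a member,
#'   and every member must have at least one instance.
#' @return an object of class `labeled_dataset` with elements
#'   `instance_ids`, `features`, `labels`, `class_vocab`.
#' @export
#' @examples
#' d <- labeled_dataset(matrix(rnorm(20), 10, 2), rep(c("a", "b"), 5))
#' table(d$labels)
labeled_dataset <- function(features, labels,
                            instance_ids = NULL, class_vocab = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.character(labels)
  n <- nrow(features)
  if (length(labels) != n)
    stop("length(labels) [", length(labels),
         "] must equal nrow(features) [", n, "]")
  if (is.null(instance_ids)) {
    instance_ids <- rownames(features) %||% paste0("i", seq_len(n))
  }
  instance_ids <- as.character(instance_ids)
  if (length(instance_ids) != n)
    stop("length(instance_ids) must equal nrow(features)")
  if (anyDuplicated(instance_ids))
    stop("instance_ids must be unique")
  if (is.null(class_vocab)) class_vocab <- sort(unique(labels))
  class_vocab <- as.character(class_vocab)
  if (anyDuplicated(class_vocab)) stop("class_vocab must be distinct")
  missing_lab <- setdiff(labels, class_vocab)
  if (length(missing_lab))
    stop("labels not in class_vocab: ", paste(missing_lab, collapse = ", "))
  empty <- setdiff(class_vocab, labels)
  if (length(empty))
    stop("classes in class_vocab with no instance: ",
         paste(empty, collapse = ", "))
  rownames(features) <- instance_ids
  structure(
    list(instance_ids = instance_ids, features = features,
         labels = labels, class_vocab = class_vocab),
    class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", length(x$instance_ids), " instances, ",
      ncol(x$features), " features, ", length(x$class_vocab),
      " classes\n", sep = "")
  cs <- table(factor(x$labels, levels = x$class_vocab))
  cat("class sizes: ", paste(range(cs), collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Oversample a dataset so every class matches the largest class size
#'
#' Duplicates the instances of each smaller class until its count equals
#' the current maximum class count: whole copies of the class first, then a
#' top-up with the first `max_size %% class_size` instances of the class in
#' their original order.  Duplicated instances get suffixed ids
#' (`"<id>.dup1"`, ...) so the result remains a valid dataset.  Used to
#' up-weight small classes before training (the oversampled model
#' variants); the operation is idempotent.
#'
#' @param train a [labeled_dataset()].
#' @return a [labeled_dataset()] in which every class count equals the
#'   original maximum class count.
#' @export
#' @examples
#' d <- labeled_dataset(matrix(rnorm(10), 5, 2), c("a", "a", "a", "b", "b"))
#' table(oversample(d)$labels)
oversample <- function(train) {
  stopifnot(inherits(train, "labeled_dataset"))
  counts <- table(factor(train$labels, levels = train$class_vocab))
  size_max <- max(counts)
  keep <- seq_along(train$labels)
  extra <- integer(0)
  for (k in train$class_vocab) {
    idx <- which(train$labels == k)
    nk <- length(idx)
    if (nk == size_max) next
    n_full <- size_max %/% nk - 1L       # additional whole copies
    n_top <- size_max %% nk              # leading instances topping up
    extra <- c(extra, rep(idx, n_full), idx[seq_len(n_top)])
  }
  if (!length(extra)) return(train)
  all_idx <- c(keep, extra)
  ids <- train$instance_ids[all_idx]
  dup <- ave(seq_along(ids), ids, FUN = seq_along) - 1L
  ids <- ifelse(dup > 0L, paste0(ids, ".dup", dup), ids)
  labeled_dataset(train$features[all_idx, , drop = FALSE],
                  train$labels[all_idx],
                  instance_ids = ids,
                  class_vocab = train$class_vocab)
}

#' Construct a posterior-probability matrix
#'
#' Per-instance class-membership probabilities emitted by one classifier.
#' Rows are clipped to `[1e-12, 1]` and renormalized so that each row sums
#' to exactly 1, guarding against learners that emit exact zeros or small
#' negative values.
#'
#' @param model_id string identifying the emitting model.
#' @param instance_ids character vector of instance ids (rows).
#' @param probs numeric matrix, one column per class; column names are the
#'   class vocabulary.
#' @return an object of class `posterior_matrix`.
#' @export
posterior_matrix <- function(model_id, instance_ids, probs) {
  probs <- as.matrix(probs)
  if (is.null(colnames(probs)))
    stop("probs must carry class names as colnames")
  if (nrow(probs) != length(instance_ids))
    stop("nrow(probs) must equal length(instance_ids)")
  if (any(!is.finite(probs)))
    stop("non-finite probabilities from model ", model_id)
  probs <- pmin(pmax(probs, 1e-12), 1)
  probs <- probs / rowSums(probs)
  rownames(probs) <- as.character(instance_ids)
  structure(
    list(model_id = as.character(model_id),
         instance_ids = as.character(instance_ids),
         probs = probs),
    class = "posterior_matrix")
}

#' @export
print.posterior_matrix <- function(x, ...) {
  cat("<posterior_matrix> model ", x$model_id, ": ", nrow(x$probs),
      " instances x ", ncol(x$probs), " classes\n", sep = "")
  invisible(x)
}

#' Average the posterior matrices of repeated runs
#'
#' Element-wise mean of several posterior matrices from repeated stochastic
#' fits of the same model on the same instances (e.g. averaging neural
#' network runs started from different random weights).  All runs must
#' share the model id, instance order and class alignment.
#'
#' @param runs list of [posterior_matrix()] objects.
#' @return a single [posterior_matrix()].
#' @export
average_runs <- function(runs) {
  stopifnot(is.list(runs), length(runs) >= 1)
  ref <- runs[[1]]
  for (r in runs[-1]) {
    if (!identical(r$model_id, ref$model_id) ||
        !identical(r$instance_ids, ref$instance_ids) ||
        !identical(dim(r$probs), dim(ref$probs)) ||
        !identical(colnames(r$probs), colnames(ref$probs)))
      stop("runs are not aligned (model_id, instance order and class ",
           "vocabulary must match)")
  }
  acc <- Reduce(`+`, lapply(runs, `[[`, "probs")) / length(runs)
  posterior_matrix(ref$model_id, ref$instance_ids, acc)
}
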