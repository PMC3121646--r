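# File I/O: delimited feature/label tables, prediction-record TSVs, and
# JSON serialization of fitted PIN/PIC functions.  TSV is the canonical
# tabular format (diff-able, language-neutral); JSON carries fitted
# functions.  All numeric output is written at full precision.

#' Load a labeled dataset from delimited files
#'
#' Reads a feature table (header row = feature names, first column =
#' instance id) and a two-column label file (instance id, class), joins
#' them on instance id, and reports/excludes instances present in only
#' one file.  The class vocabulary is the sorted set of distinct labels.
#'
#' @param features_path path to the TSV/CSV feature table.
#' @param labels_path path to the TSV/CSV label table (columns: id,
#'   class).
#' @param sep field separator (default tab).
#' @return a [labeled_dataset()].
#' @export
load_dataset <- function(features_path, labels_path, sep = "\t") {
  feat <- read.delim(features_path, sep = sep, check.names = FALSE,
                     stringsAsFactors = FALSE)
  lab <- read.delim(labels_path, sep = sep, stringsAsFactors = FALSE)
  if (ncol(lab) < 2) stop("label file needs two columns: id, class")
  ids_f <- as.character(feat[[1]])
  ids_l <- as.character(lab[[1]])
  if (anyDuplicated(ids_f)) stop("duplicate instance ids in feature file")
  if (anyDuplicated(ids_l)) stop("duplicate instance ids in label file")
  common <- intersect(ids_f, ids_l)
  if (!length(common))
    stop("no instance id is shared between the feature and label files")
  dropped <- (length(ids_f) - length(common)) +
    (length(ids_l) - length(common))
  if (dropped > 0)
    message("excluding ", dropped,
            " instance(s) present in only one file")
  x <- as.matrix(feat[match(common, ids_f), -1, drop = FALSE])
  storage.mode(x) <- "double"
  labels <- as.character(lab[[2]][match(common, ids_l)])
  labeled_dataset(x, labels, instance_ids = common)
}

#' Write a labeled dataset to delimited files
#'
#' The inverse of [load_dataset()]: writes the feature table (id column
#' first) and the two-column label table.
#'
#' @param data a [labeled_dataset()].
#' @param features_path,labels_path output paths.
#' @param sep field separator.
#' @return the paths, invisibly.
#' @export
write_dataset <- function(data, features_path, labels_path, sep = "\t") {
  stopifnot(inherits(data, "labeled_dataset"))
  feat <- data.frame(instance_id = data$instance_ids,
                     data$features, check.names = FALSE)
  write.table(feat, features_path, sep = sep, quote = FALSE,
              row.names = FALSE)
  lab <- data.frame(instance_id = data$instance_ids,
                    class = data$labels)
  write.table(lab, labels_path, sep = sep, quote = FALSE,
              row.names = FALSE)
  invisible(c(features_path, labels_path))
}

#' Write prediction records to TSV
#'
#' @param records a prediction-record data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read prediction records from TSV
#'
#' @param path path written by [write_records()].
#' @return a data frame.
#' @export
read_records <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Serialize fitted PIN/PIC functions to JSON
#'
#' @param object a `pin_function` or `pic_function`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pin_json <- function(object, path) {
  if (inherits(object, "pin_function")) {
    payload <- list(type = "pin_function", model_id = object$model_id,
                    knots = object$knots, values = object$values)
  } else if (inherits(object, "pic_function")) {
    payload <- list(type = "pic_function", model_id = object$model_id,
                    curves = object$curves)
  } else stop("object must be a pin_function or pic_function")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a PIN/PIC function from JSON
#'
#' @param path path written by [write_pin_json()].
#' @return a `pin_function` or `pic_function`.
#' @export
read_pin_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(payload$type, "pin_function")) {
    structure(list(model_id = payload$model_id,
                   knots = as.numeric(payload$knots),
                   values = as.numeric(payload$values)),
              class = "pin_function")
  } else if (identical(payload$type, "pic_function")) {
    curves <- lapply(payload$curves, function(cur) {
      if (!is.null(cur$constant)) list(constant = as.numeric(cur$constant))
      else list(knots = as.numeric(cur$knots),
                values = as.numeric(cur$values))
    })
    structure(list(model_id = payload$model_id, curves = curves),
              class = "pic_function")
  } else stop("unrecognized JSON payload at ", path)
}

#' Export a recall-precision curve to TSV
#'
#' Writes the threshold grid with raw and smoothed precision and recall
#' (columns `a`, `P_raw`, `R_raw`, `P_smooth`, `R_smooth`).
#'
#' @param curve an [rp_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rp_curve <- function(curve, path) {
  stopifnot(inherits(curve, "rp_curve"))
  write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
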