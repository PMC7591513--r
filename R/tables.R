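#' Stimulus feature table
#'
#' Bundles a real-valued embedding matrix (one row per stimulus) with
#' ground-truth category labels. Any embedding source is acceptable: raw
#' pixels, HOG descriptors, CNN penultimate-layer activations, softmax
#' outputs, or synthetic Gaussian clusters.
#'
#' @param stimulus_id character vector of unique stimulus identifiers.
#' @param label integer vector of 0-based ground-truth category indices.
#' @param features numeric matrix, one row per stimulus.
#' @param n_categories number of categories; defaults to `max(label) + 1`.
#' @param representation_name free-text tag for the embedding source.
#' @return An object of class `feature_table` with elements `stimulus_id`,
#'   `label`, `features`, `n_categories`, `n_dims`, `representation_name`.
#' @export
feature_table <- function(stimulus_id, label, features,
                          n_categories = NULL,
                          representation_name = "unnamed") {
  stimulus_id <- as.character(stimulus_id)
  label <- as.integer(label)
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (anyDuplicated(stimulus_id))
    stop("duplicate stimulus_id: ", stimulus_id[duplicated(stimulus_id)][1L])
  if (length(stimulus_id) != nrow(features) || length(label) != nrow(features))
    stop("stimulus_id, label and feature rows must have equal length")
  if (is.null(n_categories)) n_categories <- max(label) + 1L
  n_categories <- as.integer(n_categories)
  if (any(label < 0L) || any(label >= n_categories))
    stop("labels must lie in 0..", n_categories - 1L)
  rownames(features) <- stimulus_id
  structure(
    list(stimulus_id = stimulus_id, label = label, features = features,
         n_categories = n_categories, n_dims = ncol(features),
         representation_name = representation_name),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d stimuli x %d dims, %d categories [%s]\n",
              length(x$stimulus_id), x$n_dims, x$n_categories,
              x$representation_name))
  invisible(x)
}

#' Human guess-count table
#'
#' Per-stimulus counts of human category choices: row s, column j holds the
#' number of raters who assigned stimulus s to category j.
#'
#' @param stimulus_id character vector of unique stimulus identifiers.
#' @param true_label integer vector of 0-based ground-truth categories.
#' @param counts non-negative integer matrix (stimuli x categories).
#' @return An object of class `guess_table`.
#' @export
guess_table <- function(stimulus_id, true_label, counts) {
  stimulus_id <- as.character(stimulus_id)
  true_label <- as.integer(true_label)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (anyDuplicated(stimulus_id))
    stop("duplicate stimulus_id: ", stimulus_id[duplicated(stimulus_id)][1L])
  if (length(stimulus_id) != nrow(counts) || length(true_label) != nrow(counts))
    stop("stimulus_id, true_label and count rows must have equal length")
  if (any(counts < 0)) {
    bad <- which(rowSums(counts < 0) > 0)[1L]
    stop("negative count for stimulus ", stimulus_id[bad])
  }
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("counts must be integers")
  if (any(rowSums(counts) < 1))
    stop("every stimulus needs at least one judgment")
  n_categories <- ncol(counts)
  if (any(true_label < 0L) || any(true_label >= n_categories))
    stop("true_label out of range 0..", n_categories - 1L)
  rownames(counts) <- stimulus_id
  structure(
    list(stimulus_id = stimulus_id, true_label = true_label,
         counts = counts, n_categories = n_categories),
    class = "guess_table")
}

#' @export
print.guess_table <- function(x, ...) {
  cat(sprintf("<guess_table> %d stimuli, %d categories, %d judgments\n",
              length(x$stimulus_id), x$n_categories, sum(x$counts)))
  invisible(x)
}

# Check that a guess table and feature table describe the same stimuli in the
# same order; used by every operation that consumes both.
check_aligned <- function(features, guesses) {
  stopifnot(inherits(features, "feature_table"), inherits(guesses, "guess_table"))
  if (!identical(features$stimulus_id, guesses$stimulus_id))
    stop("feature and guess tables are misaligned: stimulus ids differ")
  if (features$n_categories != guesses$n_categories)
    stop("feature and guess tables disagree on the number of categories")
  invisible(TRUE)
}
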