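#' Synthetic-dataset configuration
#'
#' Describes a synthetic analogue of a soft-label categorization dataset:
#' cluster-structured stimulus embeddings with controllable separability,
#' and per-stimulus guess counts sampled from a known ground-truth choice
#' model (~50 raters per stimulus by default). The defaults are chosen so
#' the generated data shares the qualitative signatures of large
#' crowd-sourced image-categorization datasets: a right-skewed guess-entropy
#' distribution (most stimuli near-unanimous, a tail of ambiguous ones) and
#' structured pairwise confusions.
#'
#' @param n_categories number of categories.
#' @param n_dims embedding dimensionality.
#' @param n_per_category stimuli per category.
#' @param separation mean pairwise Euclidean distance between category
#'   means; isotropically drawn means are rescaled so the realized mean
#'   distance equals this exactly.
#' @param spread within-category standard deviation per dimension.
#' @param confusion_pairs optional list of 0-based category index pairs
#'   whose means are pulled together, planting elevated confusion.
#' @param confusion_strength fraction of the inter-mean gap removed for
#'   planted pairs (0 = untouched, 1 = coincident means).
#' @param true_model list with elements `spec` ([model_spec()]) and
#'   parameter fields (`gamma`, `beta`, `attention`, `inv_variance`) for the
#'   rater model; defaults to a classic prototype rater with `gamma = 0.5`.
#' @param n_raters independent simulated raters per stimulus.
#' @param seed integer seed.
#' @return An object of class `synthesis_config`.
#' @export
synthesis_config <- function(n_categories = 10L, n_dims = 8L,
                             n_per_category = 100L,
                             separation = 5, spread = 1,
                             confusion_pairs = NULL,
                             confusion_strength = 0.5,
                             true_model = list(
                               spec = model_spec("classic_prototype"),
                               gamma = 0.5),
                             n_raters = 50L, seed = 1L) {
  stopifnot(n_categories >= 2, n_dims >= 1, n_per_category >= 1,
            separation >= 0, spread > 0, n_raters >= 1)
  structure(list(n_categories = as.integer(n_categories),
                 n_dims = as.integer(n_dims),
                 n_per_category = as.integer(n_per_category),
                 separation = separation, spread = spread,
                 confusion_pairs = confusion_pairs,
                 confusion_strength = confusion_strength,
                 true_model = true_model, n_raters = as.integer(n_raters),
                 seed = as.integer(seed)),
            class = "synthesis_config")
}

#' Generate a synthetic feature table
#'
#' Category means are placed isotropically at the configured expected
#' separation; stimuli are drawn Gaussian around their category mean with
#' the configured spread; planted confusion pairs have their means pulled
#' toward each other.
#'
#' @param config a [synthesis_config()].
#' @return a [feature_table()].
#' @export
generate_feature_table <- function(config) {
  set.seed(config$seed)
  n_c <- config$n_categories
  n_d <- config$n_dims
  means <- matrix(stats::rnorm(n_c * n_d), n_c, n_d)
  # rescale the drawn means so the realized mean pairwise distance equals
  # the configured separation exactly (not just in expectation)
  dbar <- mean(stats::dist(means))
  means <- means * (config$separation / dbar)
  for (pair in config$confusion_pairs) {
    i <- pair[1L] + 1L; j <- pair[2L] + 1L
    mid <- (means[i, ] + means[j, ]) / 2
    s <- 1 - config$confusion_strength
    means[i, ] <- mid + (means[i, ] - mid) * s
    means[j, ] <- mid + (means[j, ] - mid) * s
  }
  n <- n_c * config$n_per_category
  label <- rep(seq_len(n_c) - 1L, each = config$n_per_category)
  feats <- means[label + 1L, , drop = FALSE] +
    matrix(stats::rnorm(n * n_d, sd = config$spread), n, n_d)
  feature_table(sprintf("stim_%05d", seq_len(n)), label, feats,
                n_categories = n_c, representation_name = "synthetic")
}

# Build model_params for the configured rater model over a feature table.
true_model_params <- function(config, features) {
  tm <- config$true_model
  model_params(tm$spec, features,
               gamma = if (is.null(tm$gamma)) 1 else tm$gamma,
               beta = if (is.null(tm$beta)) 1 else tm$beta,
               attention = tm$attention,
               inv_variance = tm$inv_variance)
}

#' Generate guess counts from a known rater model
#'
#' Each stimulus receives `n_raters` independent category choices sampled
#' from the true model's Luce-Shepard choice probabilities (no rater-level
#' effects). Returns both the aggregated counts and the raw per-judgment
#' table.
#'
#' @param features a [feature_table()].
#' @param spec a [model_spec()] for the rater model.
#' @param params a [model_params()] for the rater model.
#' @param n_raters judgments per stimulus.
#' @param seed optional integer seed.
#' @return list with `guesses` (a [guess_table()]) and `raw` (a data frame
#'   with columns `stimulus_id`, `rater_id`, `chosen_label`, `true_label`,
#'   one row per judgment).
#' @export
generate_guess_table <- function(features, spec, params, n_raters = 50L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  probs <- predict_choice_probabilities(features, spec, params)
  n <- nrow(probs)
  counts <- t(vapply(seq_len(n), function(s)
    as.numeric(stats::rmultinom(1L, n_raters, probs[s, ])),
    numeric(ncol(probs))))
  guesses <- guess_table(features$stimulus_id, features$label, counts)
  raw <- do.call(rbind, lapply(seq_len(n), function(s) {
    chosen <- rep(seq_len(ncol(counts)) - 1L, times = counts[s, ])
    chosen <- sample(chosen)  # shuffle rater order within stimulus
    data.frame(stimulus_id = features$stimulus_id[s],
               rater_id = sprintf("r%03d", seq_len(n_raters)),
               chosen_label = chosen,
               true_label = features$label[s],
               stringsAsFactors = FALSE)
  }))
  list(guesses = guesses, raw = raw)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: features, true rater parameters, guess counts and
#' raw judgments from one configuration.
#'
#' @param config a [synthesis_config()].
#' @return list with `features`, `params` (the true rater parameters),
#'   `guesses` and `raw`.
#' @export
generate_dataset <- function(config = synthesis_config()) {
  features <- generate_feature_table(config)
  params <- true_model_params(config, features)
  gg <- generate_guess_table(features, config$true_model$spec, params,
                             n_raters = config$n_raters,
                             seed = config$seed + 1L)
  list(features = features, params = params,
       guesses = gg$guesses, raw = gg$raw)
}

# ---- on-disk formats --------------------------------------------------------

#' Write / read a guess table
#'
#' Three plain-text dialects are supported:
#' * `"wide"` — one CSV with header
#'   `stimulus_id,true_label,count_<cat0>,...`;
#' * `"matrix"` — a bare count matrix CSV (no header) plus a JSON sidecar
#'   (`<path>.json`) holding stimulus ids, true labels and the category
#'   order — the layout of deposited count releases;
#' * `"raw"` — a long CSV of individual judgments
#'   (`stimulus_id,rater_id,chosen_label,true_label`), aggregated to counts
#'   on reading.
#'
#' @param table a [guess_table()] (for `"raw"`, the raw judgment data
#'   frame from [generate_guess_table()]).
#' @param path file path; the `"matrix"` dialect writes `<path>.json` too.
#' @param dialect one of `"wide"`, `"matrix"`, `"raw"`.
#' @return `write_guess_table()` returns `path` invisibly;
#'   `read_guess_table()` returns a [guess_table()].
#' @export
write_guess_table <- function(table, path, dialect = c("wide", "matrix", "raw")) {
  dialect <- match.arg(dialect)
  if (dialect == "raw") {
    stopifnot(is.data.frame(table))
    utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  stopifnot(inherits(table, "guess_table"))
  n_c <- table$n_categories
  if (dialect == "wide") {
    df <- data.frame(stimulus_id = table$stimulus_id,
                     true_label = table$true_label)
    cnt <- as.data.frame(table$counts)
    names(cnt) <- paste0("count_", seq_len(n_c) - 1L)
    utils::write.csv(cbind(df, cnt), path, row.names = FALSE, quote = FALSE)
  } else {
    utils::write.table(table$counts, path, row.names = FALSE,
                       col.names = FALSE, sep = ",")
    sidecar <- list(stimulus_id = table$stimulus_id,
                    true_label = table$true_label,
                    categories = as.character(seq_len(n_c) - 1L))
    jsonlite::write_json(sidecar, paste0(path, ".json"))
  }
  invisible(path)
}

#' @rdname write_guess_table
#' @export
read_guess_table <- function(path, dialect = c("wide", "matrix", "raw")) {
  dialect <- match.arg(dialect)
  if (dialect == "wide") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    count_cols <- grep("^count_", names(df), value = TRUE)
    extra <- setdiff(names(df), c("stimulus_id", "true_label", count_cols))
    if (length(extra) > 0L)
      stop("unknown columns in guess file: ", paste(extra, collapse = ", "))
    counts <- as.matrix(df[count_cols])
    check_counts_file(counts, df$stimulus_id)
    return(guess_table(df$stimulus_id, df$true_label, counts))
  }
  if (dialect == "matrix") {
    counts <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
    sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    if (length(sidecar$stimulus_id) != nrow(counts))
      stop("sidecar lists ", length(sidecar$stimulus_id),
           " stimuli but the matrix has ", nrow(counts), " rows")
    check_counts_file(counts, sidecar$stimulus_id)
    return(guess_table(sidecar$stimulus_id, sidecar$true_label, counts))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  aggregate_raw_judgments(raw)
}

check_counts_file <- function(counts, ids) {
  if (anyNA(counts)) stop("ragged or non-numeric rows in counts file")
  if (any(counts < 0)) {
    bad <- which(rowSums(counts < 0) > 0)[1L]
    stop("negative count in row ", bad, " (stimulus ", ids[bad], ")")
  }
  invisible(TRUE)
}

#' Aggregate raw judgments to a guess table
#'
#' @param raw data frame with columns `stimulus_id`, `chosen_label`,
#'   `true_label` (one row per judgment).
#' @param n_categories number of categories; defaults to
#'   `max(chosen_label, true_label) + 1`.
#' @return a [guess_table()] with stimuli in first-appearance order.
#' @export
aggregate_raw_judgments <- function(raw, n_categories = NULL) {
  stopifnot(all(c("stimulus_id", "chosen_label", "true_label") %in% names(raw)))
  if (is.null(n_categories))
    n_categories <- max(raw$chosen_label, raw$true_label) + 1L
  ids <- unique(raw$stimulus_id)
  counts <- t(vapply(ids, function(id)
    tabulate(raw$chosen_label[raw$stimulus_id == id] + 1L, n_categories),
    numeric(n_categories)))
  true_label <- raw$true_label[match(ids, raw$stimulus_id)]
  guess_table(ids, true_label, counts)
}

#' Write / read a feature table
#'
#' The embedding matrix is written as a bare CSV (no header) with a JSON
#' sidecar (`<path>.json`) recording stimulus ids, labels, the number of
#' categories, dimensionality and the representation name. Row order in the
#' matrix is authoritative and mirrored in the sidecar.
#'
#' @param table a [feature_table()].
#' @param path matrix file path; `<path>.json` is written alongside.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a [feature_table()].
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  utils::write.table(table$features, path, row.names = FALSE,
                     col.names = FALSE, sep = ",")
  sidecar <- list(stimulus_id = table$stimulus_id, label = table$label,
                  n_categories = table$n_categories,
                  n_dims = table$n_dims,
                  representation_name = table$representation_name)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  feats <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (length(sidecar$stimulus_id) != nrow(feats))
    stop("index lists ", length(sidecar$stimulus_id),
         " stimuli but the matrix has ", nrow(feats), " rows")
  if (!is.null(sidecar$n_dims) && sidecar$n_dims != ncol(feats))
    stop("index records ", sidecar$n_dims, " dims but the matrix has ",
         ncol(feats), " columns")
  dimnames(feats) <- NULL
  feature_table(sidecar$stimulus_id, sidecar$label, feats,
                n_categories = sidecar$n_categories,
                representation_name = sidecar$representation_name)
}
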