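#' Evaluation configuration
#'
#' @param probability_floor model probabilities strictly below this value are
#'   rounded to zero before rank correlation with human proportions; default
#'   0.04, the resolution of ~50 raters (two guesses out of fifty).
#' @param entropy_bin_edges increasing interior edges (nats) splitting
#'   stimuli into low / medium / high guess-entropy bins.
#' @param smoothing pseudo-count per category for smoothed entropy.
#' @param noise_ceiling_splits random split-half repetitions per stimulus.
#' @return An object of class `evaluation_config`.
#' @export
evaluation_config <- function(probability_floor = 0.04,
                              entropy_bin_edges = c(0.64, 1.0),
                              smoothing = 1,
                              noise_ceiling_splits = 100L) {
  if (probability_floor < 0 || probability_floor >= 1)
    stop("probability_floor must lie in [0, 1)")
  if (is.unsorted(entropy_bin_edges, strictly = TRUE))
    stop("entropy_bin_edges must be strictly increasing")
  structure(list(probability_floor = probability_floor,
                 entropy_bin_edges = entropy_bin_edges,
                 smoothing = smoothing,
                 noise_ceiling_splits = as.integer(noise_ceiling_splits)),
            class = "evaluation_config")
}

#' Akaike information criterion
#'
#' `2k - 2 * logL`.
#'
#' @param log_likelihood maximized log likelihood.
#' @param k number of free parameters.
#' @return a scalar.
#' @export
aic <- function(log_likelihood, k) {
  stopifnot(is.finite(log_likelihood), k >= 0)
  2 * k - 2 * log_likelihood
}

#' Free-parameter count of a model variant
#'
#' Prototypes and exemplar sets are computed from ground truth and never
#' count as free parameters; gamma always does (one), as do the shared or
#' per-category inverse variances, the exemplar specificity and the
#' attention weights.
#'
#' @param spec a [model_spec()].
#' @param n_dims,n_categories dimensions of the feature space / label set.
#' @return integer count.
#' @export
parameter_count <- function(spec, n_dims, n_categories) {
  switch(spec$variant,
    classic_prototype = 1L,
    linear_prototype = n_dims + 1L,
    quadratic_prototype = n_categories * n_dims + 1L,
    exemplar_uniform = 2L,
    exemplar_attention = n_dims + 2L,
    baseline = if (spec$fit_gamma) 1L else 0L,
    stop("unknown variant ", spec$variant))
}

#' Entropy of a guess-count vector
#'
#' Shannon entropy (natural log) of the normalized guess distribution,
#' optionally after plus-one smoothing (one pseudo-count per category).
#'
#' @param counts non-negative count vector.
#' @param smoothed apply plus-one smoothing before normalizing?
#' @param smoothing pseudo-count added per category when `smoothed`.
#' @return entropy in nats.
#' @export
guess_entropy <- function(counts, smoothed = FALSE, smoothing = 1) {
  if (sum(counts) < 1) stop("counts must total at least 1")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (smoothed) counts <- counts + smoothing
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Entropy stratification of stimuli
#'
#' Assigns each stimulus to an entropy bin from the (unsmoothed) entropy of
#' its guess distribution: bin 1 (low) for `H <= edge1`, bin 2 (medium) for
#' `edge1 < H <= edge2`, and so on.
#'
#' @param guesses a [guess_table()].
#' @param config an [evaluation_config()].
#' @return integer vector of 1-based bin indices, one per stimulus, with the
#'   entropies as attribute `"entropy"`.
#' @export
stratify_by_entropy <- function(guesses, config = evaluation_config()) {
  h <- apply(guesses$counts, 1L, guess_entropy)
  # a stimulus sitting exactly on an edge belongs to the lower bin
  bin <- vapply(h, function(hi)
    sum(hi > config$entropy_bin_edges) + 1L, integer(1))
  attr(bin, "entropy") <- h
  bin
}

#' Rank correlation after flooring model probabilities
#'
#' Sets model probabilities strictly below the floor to zero (ranking noise
#' below the resolution of ~50 raters carries no signal) and computes
#' Spearman's rank correlation (average ranks for ties) against the human
#' proportion vector. If both vectors are constant, returns 1 when they have
#' identical ranks; any other undefined case returns `NA` (excluded from
#' averages).
#'
#' @param model_probs model probability vector over categories.
#' @param human_counts human guess-count vector of the same length.
#' @param floor probabilities strictly below this are zeroed.
#' @return correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
floored_spearman <- function(model_probs, human_counts, floor = 0.04) {
  if (length(model_probs) != length(human_counts))
    stop("model_probs and human_counts must have equal length")
  m <- ifelse(model_probs < floor, 0, model_probs)
  h <- human_counts / sum(human_counts)
  rm_ <- rank(m); rh <- rank(h)
  if (stats::sd(rm_) == 0 && stats::sd(rh) == 0)
    return(if (all(rm_ == rh)) 1 else NA_real_)
  if (stats::sd(rm_) == 0 || stats::sd(rh) == 0) return(NA_real_)
  stats::cor(rm_, rh)
}

# second-ranked category (0-based) of a vector; ties at the second position
# are all returned
second_ranked <- function(x) {
  ord <- order(x, decreasing = TRUE)
  top <- ord[1L]
  rest <- x[-top]
  second_val <- max(rest)
  which(x == second_val & seq_along(x) != top) - 1L
}

#' Second-best accuracy
#'
#' Fraction of stimuli for which the model's second most probable category
#' equals the humans' second most common choice. Stimuli whose human second
#' choice is tied count as correct when the model's second-ranked category
#' matches any tied label; stimuli with fewer than two categories receiving
#' guesses are excluded from the denominator.
#'
#' @param per_stimulus_predictions model probability matrix
#'   (stimuli x categories).
#' @param guesses an aligned [guess_table()].
#' @return the fraction, or `NA` when no stimulus qualifies.
#' @export
second_best_accuracy <- function(per_stimulus_predictions, guesses) {
  pred <- as.matrix(per_stimulus_predictions)
  counts <- guesses$counts
  if (nrow(pred) != nrow(counts) || ncol(pred) != ncol(counts))
    stop("predictions and guesses are misaligned")
  eligible <- rowSums(counts > 0) >= 2L
  if (!any(eligible)) return(NA_real_)
  hits <- vapply(which(eligible), function(s) {
    human_second <- second_ranked(counts[s, ])
    model_second <- second_ranked(pred[s, ])[1L]
    model_second %in% human_second
  }, logical(1))
  mean(hits)
}

#' Human confusion matrix
#'
#' Entry (i, j): proportion of all judgments on stimuli with true label i
#' that chose category j. Rows sum to one.
#'
#' @param guesses a [guess_table()].
#' @return an `n_categories x n_categories` proportion matrix.
#' @export
confusion_matrix <- function(guesses) {
  stopifnot(inherits(guesses, "guess_table"))
  n_c <- guesses$n_categories
  out <- matrix(0, n_c, n_c)
  for (j in seq_len(n_c) - 1L) {
    rows <- guesses$true_label == j
    if (any(rows)) {
      tot <- colSums(guesses$counts[rows, , drop = FALSE])
      out[j + 1L, ] <- tot / sum(tot)
    }
  }
  dimnames(out) <- list(true = seq_len(n_c) - 1L, guessed = seq_len(n_c) - 1L)
  out
}

#' Split-half noise ceiling
#'
#' Upper bound on how well any model can predict the per-stimulus human
#' guess distribution: per stimulus, the raw judgments are randomly split
#' into halves, the two halves' category proportion vectors are
#' Spearman-correlated, the correlation is Spearman-Brown corrected
#' (`2r / (1 + r)`), and the result is averaged over `n_splits` random
#' splits.
#'
#' @param raw_judgments a data frame with columns `stimulus_id` and
#'   `chosen_label` (0-based), one row per judgment (see
#'   [generate_guess_table()]).
#' @param n_categories number of categories.
#' @param n_splits random split repetitions.
#' @return list with `per_stimulus` (named vector of mean corrected
#'   correlations) and `mean` (their grand mean, `NA`s excluded).
#' @export
noise_ceiling <- function(raw_judgments, n_categories, n_splits = 100L) {
  stopifnot(all(c("stimulus_id", "chosen_label") %in% names(raw_judgments)))
  by_stim <- split(raw_judgments$chosen_label, raw_judgments$stimulus_id)
  short <- names(by_stim)[lengths(by_stim) < 4L]
  if (length(short) > 0L)
    stop("stimuli with fewer than 4 raw judgments: ", short[1L])
  per <- vapply(by_stim, function(labels) {
    n <- length(labels)
    nh <- n %/% 2L
    r <- vapply(seq_len(n_splits), function(i) {
      idx <- sample.int(n, nh)
      p1 <- tabulate(labels[idx] + 1L, n_categories)
      p2 <- tabulate(labels[-idx] + 1L, n_categories)
      rho <- suppressWarnings(
        stats::cor(rank(p1 / sum(p1)), rank(p2 / sum(p2))))
      if (is.na(rho)) return(NA_real_)
      2 * rho / (1 + rho)
    }, numeric(1))
    mean(r, na.rm = TRUE)
  }, numeric(1))
  list(per_stimulus = per, mean = mean(per, na.rm = TRUE))
}

#' Full model evaluation report
#'
#' Generates predictions for all stimuli from a fitted model (the averaged
#' cross-validated parameters) and assembles the comparison metrics: total
#' negative log likelihood, parameter count, AIC, mean floored rank
#' correlation per entropy bin, second-best accuracy and the human confusion
#' matrix.
#'
#' @param features a [feature_table()].
#' @param guesses an aligned [guess_table()].
#' @param fitted a `fitted_model` from [fit_model()], or a list with
#'   elements `spec` and `params` for hand-built models.
#' @param config an [evaluation_config()].
#' @return An object of class `evaluation_report` with fields `variant`,
#'   `nll`, `k`, `aic`, `spearman_by_bin`, `bin_sizes`, `sba`, `confusion`
#'   and `per_stimulus_predictions`.
#' @export
evaluate_model <- function(features, guesses, fitted,
                           config = evaluation_config()) {
  check_aligned(features, guesses)
  spec <- fitted$spec
  params <- fitted$params
  pred <- predict_choice_probabilities(features, spec, params)
  ll <- model_log_likelihood(features, guesses, spec, params)
  k <- parameter_count(spec, features$n_dims, features$n_categories)
  bins <- stratify_by_entropy(guesses, config)
  rho <- vapply(seq_len(nrow(pred)), function(s)
    floored_spearman(pred[s, ], guesses$counts[s, ],
                     floor = config$probability_floor), numeric(1))
  n_bins <- length(config$entropy_bin_edges) + 1L
  rho_by_bin <- vapply(seq_len(n_bins), function(b)
    mean(rho[bins == b], na.rm = TRUE), numeric(1))
  names(rho_by_bin) <- c("low", "medium", "high")[seq_len(n_bins)]
  structure(
    list(variant = spec$variant, nll = -ll, k = k, aic = aic(ll, k),
         spearman_by_bin = rho_by_bin,
         bin_sizes = tabulate(bins, n_bins),
         sba = second_best_accuracy(pred, guesses),
         confusion = confusion_matrix(guesses),
         per_stimulus_predictions = pred),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: NLL %.1f, k %d, AIC %.1f, SBA %s\n",
              x$variant, x$nll, x$k, x$aic,
              if (is.na(x$sba)) "NA" else sprintf("%.3f", x$sba)))
  cat("  Spearman by entropy bin:",
      paste(sprintf("%s %.3f", names(x$spearman_by_bin), x$spearman_by_bin),
            collapse = ", "), "\n")
  invisible(x)
}
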