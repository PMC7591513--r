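#' Model specification
#'
#' Picks one member of the unified prototype/exemplar family. All variants
#' share the Luce-Shepard choice rule and an exponentially decaying similarity
#' in squared (shape exponents q = r = 2) diagonal-Mahalanobis distance; they
#' differ in what the category summary is and which metric parameters are free:
#'
#' * `classic_prototype` — distance to the category mean under the identity
#'   metric; only the response-scaling exponent gamma is free.
#' * `linear_prototype` — one shared diagonal inverse covariance `c` across
#'   categories (linear decision boundaries).
#' * `quadratic_prototype` — a separate diagonal inverse covariance `c_i` per
#'   category (quadratic boundaries).
#' * `exemplar_uniform` — summed similarity to all stored category members with
#'   uniform attention weights and a free specificity beta.
#' * `exemplar_attention` — as above with free attention weights `w` (positive,
#'   summing to one).
#' * `baseline` — an external probability vector (e.g. a classifier softmax)
#'   used directly as the similarity.
#'
#' @param variant one of `"classic_prototype"`, `"linear_prototype"`,
#'   `"quadratic_prototype"`, `"exemplar_uniform"`, `"exemplar_attention"`,
#'   `"baseline"`.
#' @param fit_gamma should the response-scaling exponent be estimated?
#' @param exclude_self for exemplar variants: drop the query stimulus from its
#'   own category's exemplar sum when predicting for the training stimuli.
#'   Off by default (the stored category includes every ground-truth member).
#' @return An object of class `model_spec`. The shape exponents are fixed at
#'   `q = r = 2` (integral stimulus dimensions).
#' @export
model_spec <- function(variant = c("classic_prototype", "linear_prototype",
                                   "quadratic_prototype", "exemplar_uniform",
                                   "exemplar_attention", "baseline"),
                       fit_gamma = TRUE, exclude_self = FALSE) {
  variant <- match.arg(variant)
  structure(list(variant = variant, q = 2, r = 2,
                 fit_gamma = isTRUE(fit_gamma),
                 exclude_self = isTRUE(exclude_self)),
            class = "model_spec")
}

is_prototype_variant <- function(variant)
  variant %in% c("classic_prototype", "linear_prototype", "quadratic_prototype")

is_exemplar_variant <- function(variant)
  variant %in% c("exemplar_uniform", "exemplar_attention")

#' Empirical category prototypes
#'
#' The prototype of a category is the arithmetic mean of the feature vectors
#' of its ground-truth members.
#'
#' @param features a [feature_table()].
#' @return numeric matrix with one row per category (0-based category `j` in
#'   row `j + 1`).
#' @export
compute_prototypes <- function(features) {
  stopifnot(inherits(features, "feature_table"))
  n_c <- features$n_categories
  out <- matrix(NA_real_, n_c, features$n_dims)
  for (j in seq_len(n_c) - 1L) {
    rows <- features$label == j
    if (!any(rows))
      stop("category ", j, " has no members; cannot form a prototype")
    out[j + 1L, ] <- colMeans(features$features[rows, , drop = FALSE])
  }
  rownames(out) <- as.character(seq_len(n_c) - 1L)
  out
}

#' Squared diagonal Mahalanobis distance
#'
#' `sum(inv_diag * (y - z)^2)`. With `inv_diag` all ones this is the squared
#' Euclidean distance; entries act as inverse variances reweighting the
#' stimulus dimensions.
#'
#' @param y,z numeric vectors of equal length.
#' @param inv_diag non-negative diagonal of the inverse covariance matrix;
#'   defaults to the identity metric.
#' @return a non-negative scalar.
#' @export
mahalanobis_sq <- function(y, z, inv_diag = rep(1, length(y))) {
  if (length(y) != length(z) || length(inv_diag) != length(y))
    stop("y, z and inv_diag must have equal length")
  if (any(inv_diag < 0)) stop("inv_diag entries must be non-negative")
  sum(inv_diag * (y - z)^2)
}

#' Model parameters
#'
#' Collects the free and derived quantities of one model variant: the choice
#' exponent gamma, the exemplar specificity beta, attention weights, diagonal
#' inverse variances, the empirical prototypes, and (for exemplar variants) a
#' reference to the stored category members.
#'
#' @param spec a [model_spec()].
#' @param features the [feature_table()] whose ground-truth members define the
#'   prototypes and exemplar sets.
#' @param gamma positive response-scaling exponent.
#' @param beta positive specificity (exemplar variants).
#' @param attention length-`n_dims` non-negative weights summing to one
#'   (`exemplar_attention`); defaults to uniform.
#' @param inv_variance shared vector `c` (`linear_prototype`) or
#'   `n_categories x n_dims` matrix of `c_i` rows (`quadratic_prototype`);
#'   defaults to all ones.
#' @return An object of class `model_params`.
#' @export
model_params <- function(spec, features, gamma = 1, beta = 1,
                         attention = NULL, inv_variance = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(features, "feature_table"))
  if (gamma < 0) stop("gamma must be non-negative")
  n_d <- features$n_dims
  n_c <- features$n_categories
  variant <- spec$variant

  if (is_exemplar_variant(variant)) {
    if (beta <= 0) stop("beta must be positive")
    if (variant == "exemplar_uniform" || is.null(attention))
      attention <- rep(1 / n_d, n_d)
    if (length(attention) != n_d || any(attention < 0))
      stop("attention must be a non-negative vector of length n_dims")
    if (abs(sum(attention) - 1) > 1e-8)
      stop("attention weights must sum to 1")
  } else {
    attention <- NULL
    beta <- NULL
  }

  if (variant == "linear_prototype") {
    if (is.null(inv_variance)) inv_variance <- rep(1, n_d)
    if (!is.null(dim(inv_variance)) || length(inv_variance) != n_d)
      stop("linear_prototype needs a length-n_dims inv_variance vector")
  } else if (variant == "quadratic_prototype") {
    if (is.null(inv_variance)) inv_variance <- matrix(1, n_c, n_d)
    inv_variance <- as.matrix(inv_variance)
    if (!all(dim(inv_variance) == c(n_c, n_d)))
      stop("quadratic_prototype needs an n_categories x n_dims inv_variance matrix")
  } else {
    inv_variance <- NULL
  }
  if (!is.null(inv_variance) && any(inv_variance < 0))
    stop("inv_variance entries must be non-negative")

  prototypes <- if (is_prototype_variant(variant)) compute_prototypes(features)
                else NULL

  structure(
    list(variant = variant, gamma = gamma, beta = beta,
         attention = attention, inv_variance = inv_variance,
         prototypes = prototypes,
         exemplar_features = if (is_exemplar_variant(variant)) features$features,
         exemplar_label = if (is_exemplar_variant(variant)) features$label,
         n_categories = n_c, n_dims = n_d),
    class = "model_params")
}

# Diagonal inverse covariance used by a prototype variant for category j
# (0-based).
proto_inv_diag <- function(params, category) {
  switch(params$variant,
    classic_prototype = rep(1, params$n_dims),
    linear_prototype = params$inv_variance,
    quadratic_prototype = params$inv_variance[category + 1L, ],
    stop("no inv_variance for variant ", params$variant))
}

#' Prototype log similarity
#'
#' Log of the exponentially decaying similarity between a stimulus and one
#' category prototype: minus the squared diagonal-Mahalanobis distance to the
#' category mean, under the variant's metric (identity, shared `c`, or
#' per-category `c_i`).
#'
#' @param y numeric stimulus vector.
#' @param params a [model_params()] for a prototype variant.
#' @param category 0-based category index.
#' @return a scalar; `exp()` of it is the similarity.
#' @export
prototype_log_similarity <- function(y, params, category) {
  stopifnot(inherits(params, "model_params"))
  if (!is_prototype_variant(params$variant))
    stop("prototype_log_similarity requires a prototype variant")
  mu <- params$prototypes[category + 1L, ]
  -mahalanobis_sq(y, mu, proto_inv_diag(params, category))
}

#' Exemplar log similarity
#'
#' Log of the summed similarity between a stimulus and every stored member of
#' one category, `log sum_x exp(-beta * sum_k w_k (x_k - y_k)^2)`, evaluated
#' with a log-sum-exp so that large distances in high-dimensional spaces do
#' not underflow.
#'
#' @inheritParams prototype_log_similarity
#' @param params a [model_params()] for an exemplar variant.
#' @return a scalar; `exp()` of it is the summed similarity.
#' @export
exemplar_log_similarity <- function(y, params, category) {
  stopifnot(inherits(params, "model_params"))
  if (!is_exemplar_variant(params$variant))
    stop("exemplar_log_similarity requires an exemplar variant")
  if (params$beta <= 0) stop("beta must be positive")
  rows <- params$exemplar_label == category
  if (!any(rows)) stop("category ", category, " has no exemplars")
  x <- params$exemplar_features[rows, , drop = FALSE]
  d2 <- as.vector(x^2 %*% params$attention) -
    2 * as.vector(x %*% (params$attention * y)) +
    sum(params$attention * y^2)
  log_sum_exp(-params$beta * pmax(d2, 0))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Luce-Shepard choice rule in log space
#'
#' Converts per-category log similarities into log choice probabilities:
#' `gamma * logS_i - logsumexp_j(gamma * logS_j)`. Working on log similarities
#' keeps the rule stable when distances are large; as `gamma -> 0` responding
#' becomes uniform, and as `gamma -> Inf` it becomes deterministic at the
#' most similar category.
#'
#' @param log_similarities numeric vector of per-category log similarities.
#' @param gamma non-negative response-scaling exponent.
#' @return vector of log probabilities; `exp()` of it sums to one.
#' @export
choice_log_probabilities <- function(log_similarities, gamma) {
  if (anyNA(log_similarities) || is.na(gamma))
    stop("NaN/NA in choice rule inputs")
  if (gamma < 0) stop("gamma must be non-negative")
  g <- gamma * log_similarities
  g - log_sum_exp(g)
}

# Matrix of per-category log similarities for each row of `query` (a numeric
# matrix), under `params`. `self_index`: optional 1-based exemplar row index
# of each query row, used only when exclude_self is requested.
log_similarity_matrix <- function(query, params, exclude_self = FALSE,
                                  self_index = NULL) {
  n_c <- params$n_categories
  if (is_prototype_variant(params$variant)) {
    out <- matrix(NA_real_, nrow(query), n_c)
    for (j in seq_len(n_c) - 1L) {
      w <- proto_inv_diag(params, j)
      delta <- sweep(query, 2L, params$prototypes[j + 1L, ])
      out[, j + 1L] <- -as.vector(delta^2 %*% w)
    }
    return(out)
  }
  if (is_exemplar_variant(params$variant)) {
    x <- params$exemplar_features
    w <- params$attention
    # weighted squared distances query x exemplar via the expanded square
    qa <- query^2 %*% w               # n_query x 1
    xa <- x^2 %*% w                   # n_ex x 1
    cross <- query %*% t(sweep(x, 2L, w, `*`))
    d2 <- matrix(qa, nrow(query), nrow(x)) - 2 * cross +
      matrix(xa, nrow(query), nrow(x), byrow = TRUE)
    d2 <- pmax(d2, 0)
    e <- -params$beta * d2
    if (exclude_self && !is.null(self_index)) {
      e[cbind(seq_len(nrow(e)), self_index)] <- -Inf
    }
    out <- matrix(NA_real_, nrow(query), n_c)
    for (j in seq_len(n_c) - 1L) {
      cols <- params$exemplar_label == j
      if (!any(cols)) stop("category ", j, " has no exemplars")
      block <- e[, cols, drop = FALSE]
      m <- apply(block, 1L, max)
      out[, j + 1L] <- ifelse(is.finite(m),
                              m + log(rowSums(exp(block - m))), m)
    }
    return(out)
  }
  stop("log_similarity_matrix is undefined for variant ", params$variant)
}

#' Predicted choice probabilities for every stimulus
#'
#' Runs the variant's similarity computation and the Luce-Shepard choice rule
#' for each stimulus in a feature table.
#'
#' @param features a [feature_table()] of query stimuli.
#' @param spec a [model_spec()].
#' @param params a [model_params()] consistent with `spec`.
#' @param log should log probabilities be returned?
#' @return numeric matrix (stimuli x categories) of (log) probabilities.
#' @export
predict_choice_probabilities <- function(features, spec, params, log = FALSE) {
  stopifnot(inherits(features, "feature_table"))
  self_index <- NULL
  exclude_self <- FALSE
  if (is_exemplar_variant(params$variant) && isTRUE(spec$exclude_self)) {
    # self-exclusion only makes sense when the queries are the stored members
    ex_ids <- rownames(params$exemplar_features)
    self_index <- match(features$stimulus_id, ex_ids)
    exclude_self <- !anyNA(self_index)
  }
  ls <- log_similarity_matrix(features$features, params,
                              exclude_self = exclude_self,
                              self_index = self_index)
  lp <- t(apply(ls, 1L, choice_log_probabilities, gamma = params$gamma))
  rownames(lp) <- features$stimulus_id
  if (log) lp else exp(lp)
}

#' Log likelihood of human guesses under a model
#'
#' Sums `count * log p` over every stimulus and category, where `p` are the
#' model's Luce-Shepard choice probabilities. Equivalent to summing the log
#' probability of each individual human judgment.
#'
#' @param features a [feature_table()].
#' @param guesses a [guess_table()] aligned with `features`.
#' @param spec a [model_spec()].
#' @param params a [model_params()].
#' @return a scalar log likelihood (always `<= 0`).
#' @export
model_log_likelihood <- function(features, guesses, spec, params) {
  check_aligned(features, guesses)
  lp <- predict_choice_probabilities(features, spec, params, log = TRUE)
  ll_from_log_probs(lp, guesses$counts)
}

ll_from_log_probs <- function(log_probs, counts) {
  contrib <- counts * log_probs
  contrib[counts == 0] <- 0  # 0 * -Inf
  sum(contrib)
}

#' Baseline choice rule over external probabilities
#'
#' Treats each row of an external probability matrix (e.g. a CNN softmax) as
#' the per-category similarities and pushes it through the Luce-Shepard
#' choice rule. With `gamma = 1` the input distribution is returned
#' unchanged; `gamma = 0` gives uniform responding.
#'
#' @param softmax_outputs matrix whose rows are probability vectors.
#' @param gamma non-negative response-scaling exponent.
#' @param tol row-normalization tolerance.
#' @return matrix of log probabilities, same shape as the input.
#' @export
baseline_log_probabilities <- function(softmax_outputs, gamma, tol = 1e-6) {
  softmax_outputs <- as.matrix(softmax_outputs)
  rs <- rowSums(softmax_outputs)
  if (any(abs(rs - 1) > tol))
    stop("rows of softmax_outputs must sum to 1 (tolerance ", tol, ")")
  t(apply(log(softmax_outputs), 1L, choice_log_probabilities, gamma = gamma))
}
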