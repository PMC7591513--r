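#' Simulation configuration for the dimensionality study
#'
#' Defines the grid of the prototype-vs-exemplar simulation: category
#' complexity regimes, stimulus dimensionalities, per-category training-set
#' sizes, and the replicate structure. Each replicate draws a fresh pair of
#' categories, trains a zero-parameter nearest-prototype classifier and a
#' one-parameter exemplar classifier (only the specificity beta estimated by
#' cross-validated grid search, all other parameters fixed at 1), and
#' measures accuracy on unseen test stimuli.
#'
#' @param regimes subset of `"linear"`, `"simple"`, `"medium"`, `"complex"`,
#'   `"ill_conditioned"`.
#' @param dims_grid stimulus dimensionalities to sweep.
#' @param train_sizes training stimuli per category to sweep.
#' @param n_test_per_category unseen test stimuli per category.
#' @param n_replicates fresh category pairs per grid cell.
#' @param n_categories categories per problem (two, matching the paired
#'   component construction).
#' @param beta_grid candidate specificities for the exemplar grid search.
#' @param cv_folds folds for the beta cross-validation.
#' @param seed integer seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(regimes = c("linear", "simple", "medium",
                                          "complex", "ill_conditioned"),
                              dims_grid = c(2L, 32L, 256L),
                              train_sizes = c(16L, 512L),
                              n_test_per_category = 100L,
                              n_replicates = 300L,
                              n_categories = 2L,
                              beta_grid = 2^seq(-6, 6, by = 1),
                              cv_folds = 5L,
                              seed = 1L) {
  regimes <- match.arg(regimes, several.ok = TRUE)
  stopifnot(all(dims_grid >= 1), all(train_sizes >= 1),
            n_test_per_category >= 1, n_replicates >= 1)
  if (n_categories != 2L)
    stop("the paired-component construction defines two categories")
  structure(list(regimes = regimes, dims_grid = as.integer(dims_grid),
                 train_sizes = as.integer(train_sizes),
                 n_test_per_category = as.integer(n_test_per_category),
                 n_replicates = as.integer(n_replicates),
                 n_categories = 2L, beta_grid = sort(beta_grid),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "simulation_config")
}

#' Sample one Gaussian category component
#'
#' The mean is standard normal. The covariance is the identity in the
#' `linear` regime and otherwise a scaled Wishart draw `W / d` with
#' `W ~ Wishart(I, d)`, so the expected covariance is the identity and the
#' degrees of freedom `d` act purely as a conditioning knob: `d = n_dims +
#' 20` (simple/medium/complex) gives well-conditioned covariances, while
#' `d = n_dims` (ill_conditioned) concentrates variance in a few directions.
#'
#' @param n_dims dimensionality.
#' @param regime complexity regime name.
#' @return list with elements `mean` and `cov`.
#' @export
sample_component <- function(n_dims, regime) {
  stopifnot(n_dims >= 1)
  mean <- stats::rnorm(n_dims)
  if (regime == "linear") {
    cov <- diag(n_dims)
  } else {
    d <- if (regime == "ill_conditioned") n_dims else n_dims + 20L
    if (d < n_dims) stop("Wishart degrees of freedom below dimensionality")
    cov <- stats::rWishart(1L, df = d, Sigma = diag(n_dims))[, , 1L] / d
  }
  list(mean = mean, cov = cov)
}

#' Assemble sampled components into two categories
#'
#' `linear` and `simple` regimes pass one component per category through
#' (for `linear` the two means are first shifted apart along their
#' difference direction to a fixed separation, creating a linearly separable
#' problem). `medium` takes four components and groups the closest pair of
#' means (Euclidean) as category 1; `complex` and `ill_conditioned` pair the
#' four components uniformly at random. Mixture categories weight their two
#' components evenly.
#'
#' @param components list of components from [sample_component()] (two for
#'   single-Gaussian regimes, four for mixture regimes).
#' @param regime complexity regime name.
#' @param linear_separation distance to which the two `linear` means are
#'   pushed apart.
#' @return list of two `category_distribution` objects (fields `components`,
#'   each with `mean`, `cov`, `weight`, and `regime`).
#' @export
assemble_categories <- function(components, regime, linear_separation = 8) {
  single <- regime %in% c("linear", "simple")
  if (single) {
    if (length(components) != 2L)
      stop("single-Gaussian regimes need exactly 2 components")
    if (regime == "linear") {
      m1 <- components[[1L]]$mean; m2 <- components[[2L]]$mean
      diff <- m2 - m1
      nrm <- sqrt(sum(diff^2))
      u <- if (nrm < 1e-12) c(1, rep(0, length(m1) - 1L)) else diff / nrm
      mid <- (m1 + m2) / 2
      components[[1L]]$mean <- mid - u * linear_separation / 2
      components[[2L]]$mean <- mid + u * linear_separation / 2
    }
    return(lapply(components, function(co)
      structure(list(components = list(c(co, weight = 1)), regime = regime),
                class = "category_distribution")))
  }
  if (length(components) != 4L)
    stop("mixture regimes need exactly 4 components")
  if (regime == "medium") {
    means <- do.call(rbind, lapply(components, `[[`, "mean"))
    dd <- as.matrix(stats::dist(means))
    diag(dd) <- Inf
    pair <- which(dd == min(dd), arr.ind = TRUE)[1L, ]
    first <- sort(pair)
  } else {
    first <- sort(sample.int(4L, 2L))
  }
  second <- setdiff(1:4, first)
  make_cat <- function(idx)
    structure(list(components = lapply(components[idx],
                                       function(co) c(co, weight = 0.5)),
                   regime = regime),
              class = "category_distribution")
  list(make_cat(first), make_cat(second))
}

# Draw n stimuli from a (possibly mixture) category distribution.
sample_category <- function(dist, n) {
  k <- length(dist$components)
  w <- vapply(dist$components, `[[`, numeric(1), "weight")
  comp <- sample.int(k, n, replace = TRUE, prob = w)
  n_d <- length(dist$components[[1L]]$mean)
  out <- matrix(NA_real_, n, n_d)
  for (i in seq_len(k)) {
    rows <- which(comp == i)
    if (!length(rows)) next
    co <- dist$components[[i]]
    ch <- tryCatch(chol(co$cov), error = function(e) {
      eg <- eigen(co$cov, symmetric = TRUE)
      diag(sqrt(pmax(eg$values, 0))) %*% t(eg$vectors)
    })
    z <- matrix(stats::rnorm(length(rows) * n_d), length(rows), n_d)
    out[rows, ] <- sweep(z %*% ch, 2L, co$mean, `+`)
  }
  out
}

# Squared Euclidean distances between the rows of a and b.
sqed_matrix <- function(a, b) {
  d2 <- matrix(rowSums(a^2), nrow(a), nrow(b)) -
    2 * a %*% t(b) +
    matrix(rowSums(b^2), nrow(a), nrow(b), byrow = TRUE)
  pmax(d2, 0)
}

# Nearest-prototype classification: ties broken toward the lowest category.
classify_prototype <- function(test, prototypes) {
  d2 <- sqed_matrix(test, prototypes)
  max.col(-d2, ties.method = "first")
}

# Summed-similarity exemplar classification with fixed beta, from a
# precomputed squared-distance matrix (query x exemplar).
classify_exemplar <- function(d2, ex_label, beta, n_categories = 2L) {
  scores <- vapply(seq_len(n_categories), function(j) {
    block <- -beta * d2[, ex_label == j, drop = FALSE]
    m <- apply(block, 1L, max)
    m + log(rowSums(exp(block - m)))
  }, numeric(nrow(d2)))
  max.col(matrix(scores, nrow(d2)), ties.method = "first")
}

# Pick beta from the grid by cross-validated training classification
# accuracy (ties toward the smaller beta).
select_beta <- function(d2_train, train_label, beta_grid, cv_folds) {
  n <- nrow(d2_train)
  folds <- sample(rep_len(seq_len(min(cv_folds, n - 1L)), n))
  acc <- vapply(beta_grid, function(beta) {
    mean(vapply(unique(folds), function(f) {
      ho <- folds == f
      if (all(ho) || !any(ho)) return(NA_real_)
      pred <- classify_exemplar(d2_train[ho, !ho, drop = FALSE],
                                train_label[!ho], beta)
      mean(pred == train_label[ho])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  beta_grid[which.max(acc)]  # which.max takes the first (smallest) maximizer
}

#' Run one cell of the simulation grid
#'
#' Repeatedly samples a fresh category pair for the regime, draws training
#' and test stimuli, and scores the nearest-prototype classifier (empirical
#' means, squared Euclidean distance) and the one-parameter exemplar
#' classifier (beta selected by cross-validated grid search on training
#' accuracy) on the test stimuli.
#'
#' @param regime complexity regime name.
#' @param n_dims stimulus dimensionality.
#' @param n_train training stimuli per category.
#' @param config a [simulation_config()].
#' @param seed optional integer seed set before the replicate loop.
#' @return list with `prototype` and `exemplar` accuracy vectors (one entry
#'   per replicate) and their means.
#' @export
run_cell <- function(regime, n_dims, n_train, config = simulation_config(),
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_comp <- if (regime %in% c("linear", "simple")) 2L else 4L
  proto_acc <- ex_acc <- numeric(config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    cats <- assemble_categories(
      lapply(seq_len(n_comp), function(i) sample_component(n_dims, regime)),
      regime)
    train <- rbind(sample_category(cats[[1L]], n_train),
                   sample_category(cats[[2L]], n_train))
    train_label <- rep(1:2, each = n_train)
    test <- rbind(sample_category(cats[[1L]], config$n_test_per_category),
                  sample_category(cats[[2L]], config$n_test_per_category))
    test_label <- rep(1:2, each = config$n_test_per_category)

    prototypes <- rbind(colMeans(train[train_label == 1L, , drop = FALSE]),
                        colMeans(train[train_label == 2L, , drop = FALSE]))
    proto_acc[r] <- mean(classify_prototype(test, prototypes) == test_label)

    d2_train <- sqed_matrix(train, train)
    beta <- select_beta(d2_train, train_label, config$beta_grid,
                        config$cv_folds)
    d2_test <- sqed_matrix(test, train)
    ex_acc[r] <- mean(classify_exemplar(d2_test, train_label, beta) ==
                        test_label)
  }
  list(prototype = proto_acc, exemplar = ex_acc,
       prototype_mean = mean(proto_acc), exemplar_mean = mean(ex_acc))
}

#' Run the full simulation grid
#'
#' Sweeps every (regime, dimensionality, training size) cell with
#' [run_cell()], each cell seeded deterministically from the configuration
#' seed.
#'
#' @param config a [simulation_config()].
#' @return data frame with one row per cell: `regime`, `n_dims`, `n_train`,
#'   `prototype_acc`, `prototype_sd`, `exemplar_acc`, `exemplar_sd`,
#'   `difference` (prototype minus exemplar).
#' @export
run_grid <- function(config = simulation_config()) {
  cells <- expand.grid(regime = config$regimes, n_dims = config$dims_grid,
                       n_train = config$train_sizes,
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    res <- run_cell(cells$regime[i], cells$n_dims[i], cells$n_train[i],
                    config, seed = cell_seed(config$seed, i))
    data.frame(regime = cells$regime[i], n_dims = cells$n_dims[i],
               n_train = cells$n_train[i],
               prototype_acc = mean(res$prototype),
               prototype_sd = stats::sd(res$prototype),
               exemplar_acc = mean(res$exemplar),
               exemplar_sd = stats::sd(res$exemplar),
               difference = mean(res$prototype) - mean(res$exemplar))
  })
  do.call(rbind, rows)
}

#' Deterministic per-cell seed
#'
#' @param seed base seed.
#' @param index 1-based cell index.
#' @return an integer below 2^31.
#' @export
cell_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(index)) %% 2147483647)
}
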