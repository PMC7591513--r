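#' Fitting configuration
#'
#' Controls the mini-batch gradient estimation of model parameters:
#' stimuli are partitioned into `n_folds` cross-validation folds, parameters
#' are optimized on the training folds by Adam on the negative log likelihood,
#' and the training epoch minimizing the mean held-out negative log likelihood
#' across folds is selected (early stopping).
#'
#' @param n_folds number of cross-validation folds (>= 2).
#' @param batch_size stimuli per gradient step.
#' @param max_epochs upper bound on training epochs.
#' @param patience epochs without improvement of the mean held-out negative
#'   log likelihood before stopping.
#' @param learning_rate Adam step size.
#' @param decay learning-rate decay: step size at global step `t` is
#'   `learning_rate / (1 + decay * t)`.
#' @param grid named list with vectors `learning_rate` and `decay` defining
#'   the hyperparameter grid searched by [grid_search()].
#' @param seed integer seed controlling fold assignment and batch order.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_folds = 5L, batch_size = 256L, max_epochs = 100L,
                       patience = 10L, learning_rate = 0.05, decay = 0,
                       grid = list(learning_rate = c(1e-3, 1e-2, 1e-1),
                                   decay = c(0, 1e-4)),
                       seed = 1L) {
  if (n_folds < 2L) stop("n_folds must be at least 2")
  if (batch_size < 1L) stop("batch_size must be at least 1")
  structure(list(n_folds = as.integer(n_folds),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate, decay = decay,
                 grid = grid, seed = as.integer(seed)),
            class = "fit_config")
}

# ---- unconstrained parameterization -----------------------------------------
# gamma, beta and inverse variances are optimized as logs so positivity holds
# by construction; attention weights as softmax logits so they stay positive
# and sum to one.

theta_layout <- function(variant, n_dims, n_categories) {
  switch(variant,
    classic_prototype = c(log_gamma = 1L),
    linear_prototype = c(log_gamma = 1L, log_c = n_dims),
    quadratic_prototype = c(log_gamma = 1L, log_c = n_dims * n_categories),
    exemplar_uniform = c(log_gamma = 1L, log_beta = 1L),
    exemplar_attention = c(log_gamma = 1L, log_beta = 1L,
                           attn_logit = n_dims),
    stop("variant ", variant, " has no trainable parameterization"))
}

theta_split <- function(theta, variant, n_dims, n_categories) {
  lay <- theta_layout(variant, n_dims, n_categories)
  ends <- cumsum(lay)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- Map(function(s, e) theta[s:e], starts, ends)
  names(out) <- names(lay)
  out
}

theta_to_params <- function(theta, spec, features) {
  v <- spec$variant
  parts <- theta_split(theta, v, features$n_dims, features$n_categories)
  gamma <- exp(parts$log_gamma)
  beta <- if (!is.null(parts$log_beta)) exp(parts$log_beta)
  attention <- if (!is.null(parts$attn_logit)) {
    a <- parts$attn_logit
    exp(a - log_sum_exp(a))
  }
  inv_variance <- if (v == "linear_prototype") exp(parts$log_c)
    else if (v == "quadratic_prototype")
      matrix(exp(parts$log_c), features$n_categories, features$n_dims)
  model_params(spec, features, gamma = gamma,
               beta = if (is.null(beta)) 1 else beta,
               attention = attention, inv_variance = inv_variance)
}

params_to_theta <- function(params) {
  v <- params$variant
  switch(v,
    classic_prototype = c(log(params$gamma)),
    linear_prototype = c(log(params$gamma), log(params$inv_variance)),
    quadratic_prototype = c(log(params$gamma),
                            log(as.vector(params$inv_variance))),
    exemplar_uniform = c(log(params$gamma), log(params$beta)),
    exemplar_attention = c(log(params$gamma), log(params$beta),
                           log(params$attention)),
    stop("variant ", v, " has no trainable parameterization"))
}

# ---- precomputation ---------------------------------------------------------

precompute_fit <- function(features, spec) {
  v <- spec$variant
  y <- features$features
  n <- nrow(y)
  n_c <- features$n_categories
  n_d <- features$n_dims
  pre <- list(variant = v, n = n, n_c = n_c, n_d = n_d)
  if (is_prototype_variant(v)) {
    mu <- compute_prototypes(features)
    # flattened (stimulus, category) x dim matrix of squared differences;
    # row s + (j)*n holds stimulus s vs prototype j (0-based j)
    d2 <- matrix(NA_real_, n * n_c, n_d)
    for (j in seq_len(n_c) - 1L) {
      delta <- sweep(y, 2L, mu[j + 1L, ])
      d2[seq_len(n) + j * n, ] <- delta^2
    }
    pre$d2 <- d2
    if (v == "classic_prototype")
      pre$sqed <- matrix(rowSums(d2), n, n_c)
  } else if (is_exemplar_variant(v)) {
    pre$ex_label <- features$label
    if (v == "exemplar_uniform") {
      d <- matrix(0, n, n)
      for (k in seq_len(n_d)) d <- d + outer(y[, k], y[, k], `-`)^2
      pre$D <- d / n_d
    } else {
      pre$d2k <- lapply(seq_len(n_d),
                        function(k) outer(y[, k], y[, k], `-`)^2)
    }
    pre$cat_cols <- lapply(seq_len(n_c) - 1L,
                           function(j) which(features$label == j))
    if (any(lengths(pre$cat_cols) == 0L))
      stop("every category needs at least one exemplar")
  } else stop("cannot fit variant ", v)
  pre
}

# Negative log likelihood and gradient over the stimulus rows `rows`,
# in the unconstrained space. Returns list(nll, grad).
nll_and_grad <- function(theta, pre, counts, rows, spec, want_grad = TRUE) {
  v <- pre$variant
  parts <- theta_split(theta, v, pre$n_d, pre$n_c)
  gamma <- exp(parts$log_gamma)
  n_c <- pre$n_c
  B <- length(rows)

  if (is_prototype_variant(v)) {
    if (v == "classic_prototype") {
      ell <- -pre$sqed[rows, , drop = FALSE]
    } else if (v == "linear_prototype") {
      cvec <- exp(parts$log_c)
      idx <- as.vector(outer(rows, (seq_len(n_c) - 1L) * pre$n, `+`))
      ell <- -matrix(pre$d2[idx, , drop = FALSE] %*% cvec, B, n_c)
    } else {
      cmat <- matrix(exp(parts$log_c), n_c, pre$n_d)
      ell <- matrix(NA_real_, B, n_c)
      for (j in seq_len(n_c) - 1L)
        ell[, j + 1L] <- -as.vector(
          pre$d2[rows + j * pre$n, , drop = FALSE] %*% cmat[j + 1L, ])
    }
  } else {
    beta <- exp(parts$log_beta)
    if (v == "exemplar_uniform") {
      Dw <- pre$D[rows, , drop = FALSE]
    } else {
      w <- exp(parts$attn_logit - log_sum_exp(parts$attn_logit))
      Dw <- matrix(0, B, pre$n)
      for (k in seq_len(pre$n_d))
        Dw <- Dw + w[k] * pre$d2k[[k]][rows, , drop = FALSE]
    }
    E <- -beta * Dw
    ell <- matrix(NA_real_, B, n_c)
    for (j in seq_len(n_c)) {
      block <- E[, pre$cat_cols[[j]], drop = FALSE]
      m <- apply(block, 1L, max)
      ell[, j] <- m + log(rowSums(exp(block - m)))
    }
  }

  z <- gamma * ell
  m <- apply(z, 1L, max)
  lse <- m + log(rowSums(exp(z - m)))
  logp <- z - lse
  cnt <- counts[rows, , drop = FALSE]
  nll <- -ll_from_log_probs(logp, cnt)
  if (!want_grad) return(list(nll = nll))
  if (!is.finite(nll))
    stop("non-finite loss on a batch of ", B, " stimuli (rows ",
         rows[1L], "..); try a smaller learning rate")

  P <- exp(logp)
  Ns <- rowSums(cnt)
  G <- cnt - Ns * P                          # B x n_c
  grad <- numeric(length(theta))
  grad[1L] <- -sum(G * ell) * gamma          # d/d log_gamma

  if (v == "linear_prototype") {
    idx <- as.vector(outer(rows, (seq_len(n_c) - 1L) * pre$n, `+`))
    cvec <- exp(parts$log_c)
    gc <- gamma * as.vector(crossprod(pre$d2[idx, , drop = FALSE], as.vector(G)))
    grad[-1L] <- gc * cvec
  } else if (v == "quadratic_prototype") {
    cmat <- matrix(exp(parts$log_c), n_c, pre$n_d)
    gc <- matrix(NA_real_, n_c, pre$n_d)
    for (j in seq_len(n_c) - 1L)
      gc[j + 1L, ] <- gamma * as.vector(
        crossprod(pre$d2[rows + j * pre$n, , drop = FALSE], G[, j + 1L]))
    grad[-1L] <- as.vector(gc * cmat)
  } else if (is_exemplar_variant(v)) {
    # responsibilities of each exemplar within its category's log-sum-exp
    R <- exp(E - ell[, pre$ex_label + 1L, drop = FALSE])
    Gexp <- G[, pre$ex_label + 1L, drop = FALSE]   # B x n_exemplars
    GR <- Gexp * R
    grad_beta <- gamma * sum(GR * Dw)              # d/d beta
    grad[2L] <- grad_beta * beta                   # d/d log_beta
    if (v == "exemplar_attention") {
      gw <- vapply(seq_len(pre$n_d), function(k)
        gamma * beta * sum(GR * pre$d2k[[k]][rows, , drop = FALSE]),
        numeric(1))
      grad[-(1:2)] <- w * (gw - sum(w * gw))
    }
  }
  if (!spec$fit_gamma) grad[1L] <- 0
  list(nll = nll, grad = grad)
}

held_out_nll <- function(theta, pre, counts, rows, spec) {
  nll_and_grad(theta, pre, counts, rows, spec, want_grad = FALSE)$nll
}

#' Fit a categorization model
#'
#' Estimates the free parameters of a model variant against human guess
#' counts by mini-batch Adam on the negative log likelihood, with k-fold
#' cross-validation over stimuli and early stopping at the epoch minimizing
#' the mean held-out negative log likelihood across folds. The returned
#' parameters are the average (in the unconstrained space) of the per-fold
#' parameters at the selected epoch. For exemplar variants the stored
#' exemplar set is always the full set of ground-truth members of
#' `features`, regardless of the fold split.
#'
#' @param features a [feature_table()].
#' @param guesses an aligned [guess_table()].
#' @param spec a [model_spec()] for a trainable variant.
#' @param config a [fit_config()].
#' @return An object of class `fitted_model`: `spec`, `params`
#'   (fold-averaged), `fold_params` (per-fold snapshots at the selected
#'   epoch), `trace` (per-epoch mean held-out NLL per judgment),
#'   `selected_epoch`, `converged`, `init_nll` and `train_nll` (total
#'   training-fold NLL at initialization and at the selected epoch).
#' @export
fit_model <- function(features, guesses, spec, config = fit_config()) {
  check_aligned(features, guesses)
  if (spec$variant == "classic_prototype" && !spec$fit_gamma)
    stop("variant has no free parameters to fit")
  set.seed(config$seed)
  n <- length(features$stimulus_id)
  pre <- precompute_fit(features, spec)
  counts <- guesses$counts
  fold <- sample(rep_len(seq_len(config$n_folds), n))
  theta0 <- numeric(sum(theta_layout(spec$variant, pre$n_d, pre$n_c)))

  state <- lapply(seq_len(config$n_folds), function(f)
    list(theta = theta0, m = 0 * theta0, v = 0 * theta0, step = 0L))
  ho_judgments <- vapply(seq_len(config$n_folds),
                         function(f) sum(counts[fold == f, ]), numeric(1))

  trace <- numeric(0)
  snapshots <- list()
  best <- Inf; best_epoch <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

  for (epoch in seq_len(config$max_epochs)) {
    ho <- numeric(config$n_folds)
    for (f in seq_len(config$n_folds)) {
      train_rows <- which(fold != f)
      order_rows <- sample(train_rows)
      st <- state[[f]]
      nb <- ceiling(length(order_rows) / config$batch_size)
      for (b in seq_len(nb)) {
        rows <- order_rows[((b - 1L) * config$batch_size + 1L):
                             min(b * config$batch_size, length(order_rows))]
        gr <- nll_and_grad(st$theta, pre, counts, rows, spec)$grad
        st$step <- st$step + 1L
        lr <- config$learning_rate / (1 + config$decay * st$step)
        st$m <- b1 * st$m + (1 - b1) * gr
        st$v <- b2 * st$v + (1 - b2) * gr^2
        mhat <- st$m / (1 - b1^st$step)
        vhat <- st$v / (1 - b2^st$step)
        st$theta <- st$theta - lr * mhat / (sqrt(vhat) + eps)
      }
      state[[f]] <- st
      ho[f] <- held_out_nll(st$theta, pre, counts, which(fold == f), spec)
    }
    trace[epoch] <- sum(ho) / sum(ho_judgments)
    snapshots[[epoch]] <- lapply(state, `[[`, "theta")
    if (trace[epoch] < best - 1e-12) { best <- trace[epoch]; best_epoch <- epoch }
    if (epoch - best_epoch >= config$patience) break
  }

  # converged = the patience rule fired before max_epochs was exhausted;
  # otherwise the best epoch seen is returned with converged = FALSE
  converged <- length(trace) < config$max_epochs
  sel <- snapshots[[best_epoch]]
  theta_bar <- Reduce(`+`, sel) / length(sel)
  params <- theta_to_params(theta_bar, spec, features)

  init_nll <- sum(vapply(seq_len(config$n_folds), function(f)
    held_out_nll(theta0, pre, counts, which(fold != f), spec), numeric(1)))
  train_nll <- sum(vapply(seq_len(config$n_folds), function(f)
    held_out_nll(sel[[f]], pre, counts, which(fold != f), spec), numeric(1)))

  structure(
    list(spec = spec, params = params,
         fold_params = lapply(sel, theta_to_params, spec = spec,
                              features = features),
         trace = trace, selected_epoch = best_epoch,
         converged = converged, init_nll = init_nll, train_nll = train_nll,
         config = config, fold = fold),
    class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf(
    "<fitted_model> %s: epoch %d/%d, held-out NLL/judgment %.4f, gamma %.3f\n",
    x$spec$variant, x$selected_epoch, length(x$trace),
    min(x$trace), x$params$gamma))
  invisible(x)
}

#' Hyperparameter grid search
#'
#' Fits the model at every combination of learning rate and decay in
#' `config$grid` (each cell restarted from the same seed) and returns the
#' cell whose fit attains the lowest mean held-out negative log likelihood
#' at its early-stopping epoch. Cells whose optimization diverges to a
#' non-finite loss are discarded.
#'
#' @inheritParams fit_model
#' @return list with elements `config` (the winning [fit_config()] cell),
#'   `fit` (its [fit_model()] result) and `table` (per-cell summary).
#' @export
grid_search <- function(features, guesses, spec, config = fit_config()) {
  cells <- expand.grid(learning_rate = config$grid$learning_rate,
                       decay = config$grid$decay)
  if (nrow(cells) == 0L) stop("empty hyperparameter grid")
  best <- NULL; best_nll <- Inf; rows <- list()
  for (i in seq_len(nrow(cells))) {
    cfg <- config
    cfg$learning_rate <- cells$learning_rate[i]
    cfg$decay <- cells$decay[i]
    fit <- tryCatch(fit_model(features, guesses, spec, cfg),
                    error = function(e) e)
    diverged <- inherits(fit, "error")
    nll <- if (diverged) NA_real_ else min(fit$trace)
    rows[[i]] <- data.frame(learning_rate = cfg$learning_rate,
                            decay = cfg$decay, held_out_nll = nll,
                            diverged = diverged)
    if (!diverged && nll < best_nll) {
      best_nll <- nll; best <- list(config = cfg, fit = fit)
    }
  }
  if (is.null(best)) stop("every grid cell diverged")
  best$table <- do.call(rbind, rows)
  best
}

#' Average per-fold parameter snapshots
#'
#' Parameters are averaged elementwise in the unconstrained space (logs for
#' gamma, beta and inverse variances; logits for attention) and then
#' re-transformed, so positivity and the sum-to-one attention constraint hold
#' for the average by construction.
#'
#' @param snapshots list of [model_params()] of identical shape.
#' @param spec the [model_spec()] they were fitted under.
#' @param features the [feature_table()] defining prototypes/exemplars.
#' @return a single [model_params()].
#' @export
average_fold_parameters <- function(snapshots, spec, features) {
  if (length(snapshots) < 1L) stop("need at least one snapshot")
  thetas <- lapply(snapshots, params_to_theta)
  len <- unique(lengths(thetas))
  if (length(len) != 1L) stop("snapshot parameter shapes differ")
  theta_to_params(Reduce(`+`, thetas) / length(thetas), spec, features)
}
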