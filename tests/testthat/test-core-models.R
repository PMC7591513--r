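test_that("prototypes are the empirical category means", {
  # single member per category: prototype is that member
  ft1 <- feature_table(c("a", "b"), c(0L, 1L),
                       rbind(c(1, 2), c(3, 4)), n_categories = 2L)
  expect_equal(compute_prototypes(ft1), rbind(c(1, 2), c(3, 4)),
               ignore_attr = TRUE)
  # two members at (0,0) and (2,2): midpoint prototype
  ft2 <- feature_table(c("a", "b", "c"), c(0L, 0L, 1L),
                       rbind(c(0, 0), c(2, 2), c(5, 5)), n_categories = 2L)
  expect_equal(compute_prototypes(ft2)[1L, ], c(1, 1), ignore_attr = TRUE)
  # 50 random vectors per category match a loop-summation average
  set.seed(7)
  feats <- matrix(rnorm(100 * 6), 100, 6)
  label <- rep(0:1, each = 50L)
  ft3 <- feature_table(sprintf("s%03d", 1:100), label, feats)
  oracle <- matrix(0, 2, 6)
  for (i in 1:100) oracle[label[i] + 1L, ] <- oracle[label[i] + 1L, ] + feats[i, ]
  oracle <- oracle / 50
  expect_equal(compute_prototypes(ft3), oracle, ignore_attr = TRUE,
               tolerance = 1e-12)
  # empty category errors with its name
  expect_error(compute_prototypes(
    feature_table("a", 0L, matrix(1, 1, 2), n_categories = 2L)),
    "category 1")
})

test_that("squared Mahalanobis distance matches a scalar loop and its contract", {
  expect_identical(mahalanobis_sq(c(1, 2), c(1, 2)), 0)
  expect_identical(mahalanobis_sq(c(1, 1), c(0, 0)), 2)
  set.seed(11)
  for (i in 1:5) {
    y <- rnorm(16); z <- rnorm(16); w <- rexp(16)
    oracle <- 0
    for (k in 1:16) oracle <- oracle + w[k] * (y[k] - z[k])^2
    expect_equal(mahalanobis_sq(y, z, w), oracle, tolerance = 1e-12)
    expect_equal(mahalanobis_sq(z, y, w), mahalanobis_sq(y, z, w))
  }
  expect_error(mahalanobis_sq(1:3, 1:2), "equal length")
  expect_error(mahalanobis_sq(c(1, 2), c(0, 0), c(-1, 1)), "non-negative")
})

test_that("prototype log similarity follows the variant's metric", {
  ft <- tiny_features()
  classic <- model_params(model_spec("classic_prototype"), ft)
  mu0 <- classic$prototypes[1L, ]
  expect_equal(prototype_log_similarity(mu0, classic, 0L), 0)
  expect_equal(prototype_log_similarity(mu0 + c(1, 1, 0, 0), classic, 0L), -2)
  # quadratic variant matches a dense diagonal matrix-product evaluation
  set.seed(12)
  ci <- matrix(rexp(3 * 4), 3, 4)
  quad <- model_params(model_spec("quadratic_prototype"), ft,
                       inv_variance = ci)
  y <- rnorm(4)
  for (j in 0:2) {
    delta <- y - quad$prototypes[j + 1L, ]
    dense <- as.numeric(t(delta) %*% diag(ci[j + 1L, ]) %*% delta)
    expect_equal(prototype_log_similarity(y, quad, j), -dense,
                 tolerance = 1e-12)
  }
  expect_error(prototype_log_similarity(y, model_params(
    model_spec("exemplar_uniform"), ft), 0L), "prototype variant")
})

test_that("exemplar log similarity is a stable log-sum of similarities", {
  ft <- tiny_features()
  params <- model_params(model_spec("exemplar_uniform"), ft, beta = 1)
  x0 <- ft$features[1L, ]
  single <- feature_table("x", 0L, matrix(x0, 1), n_categories = 1L)
  p1 <- model_params(model_spec("exemplar_uniform"), single, beta = 1)
  expect_equal(exemplar_log_similarity(x0, p1, 0L), 0)
  # duplicating every exemplar adds log 2
  ft2 <- feature_table(c(ft$stimulus_id, paste0(ft$stimulus_id, "_dup")),
                       c(ft$label, ft$label),
                       rbind(ft$features, ft$features),
                       n_categories = ft$n_categories)
  p2 <- model_params(model_spec("exemplar_uniform"), ft2, beta = 1)
  y <- rnorm(4)
  expect_equal(exemplar_log_similarity(y, p2, 1L),
               exemplar_log_similarity(y, params, 1L) + log(2),
               tolerance = 1e-10)
  # 5 exemplars in 3 dims, beta = 0.7, random weights: direct-sum oracle
  set.seed(13)
  ex <- matrix(rnorm(15), 5, 3)
  w <- rexp(3); w <- w / sum(w)
  ft3 <- feature_table(paste0("e", 1:5), rep(0L, 5), ex, n_categories = 1L)
  p3 <- model_params(model_spec("exemplar_attention"), ft3, beta = 0.7,
                     attention = w)
  y3 <- rnorm(3)
  oracle <- 0
  for (i in 1:5) oracle <- oracle + exp(-0.7 * sum(w * (ex[i, ] - y3)^2))
  expect_equal(exemplar_log_similarity(y3, p3, 0L), log(oracle),
               tolerance = 1e-10)
  expect_error(model_params(model_spec("exemplar_uniform"), ft, beta = -1),
               "beta")
})

test_that("choice rule normalizes, hits its limits, and matches the direct form", {
  expect_equal(exp(choice_log_probabilities(rnorm(10), 0)), rep(0.1, 10),
               tolerance = 1e-12)
  expect_equal(exp(choice_log_probabilities(rep(-3.7, 6), 2.5)),
               rep(1 / 6, 6), tolerance = 1e-12)
  expect_equal(exp(choice_log_probabilities(log(c(1, 1, 2)), 1)),
               c(0.25, 0.25, 0.5), tolerance = 1e-12)
  set.seed(14)
  for (i in 1:20) {
    ls <- rnorm(10, sd = 3); g <- rexp(1)
    lp <- choice_log_probabilities(ls, g)
    expect_lt(abs(sum(exp(lp)) - 1), 1e-12)
    direct <- exp(ls)^g / sum(exp(ls)^g)   # similarity-power form
    expect_equal(exp(lp), direct, tolerance = 1e-10)
  }
  # monotone toward one-hot at the argmax as gamma grows
  ls <- c(-1, 0.5, 0)
  p_small <- exp(choice_log_probabilities(ls, 1))[2L]
  p_big <- exp(choice_log_probabilities(ls, 20))[2L]
  expect_gt(p_big, p_small)
  expect_gt(p_big, 0.999)
  expect_error(choice_log_probabilities(c(1, NA), 1), "NaN/NA")
})

test_that("model log likelihood equals the per-judgment sum", {
  ft <- tiny_features(n_per = 5L)
  gt <- tiny_guesses(ft, n_raters = 10L)
  spec <- model_spec("classic_prototype")
  # gamma = 0: uniform responding, closed form N log(1/n_c)
  p0 <- model_params(spec, ft, gamma = 0)
  expect_equal(model_log_likelihood(ft, gt, spec, p0),
               sum(gt$counts) * log(1 / ft$n_categories), tolerance = 1e-10)
  # unrolled per-guess oracle
  params <- model_params(spec, ft, gamma = 0.8)
  lp <- predict_choice_probabilities(ft, spec, params, log = TRUE)
  oracle <- 0
  for (s in seq_along(gt$stimulus_id))
    for (j in seq_len(gt$n_categories))
      if (gt$counts[s, j] > 0)
        oracle <- oracle + gt$counts[s, j] * lp[s, j]
  expect_equal(model_log_likelihood(ft, gt, spec, params), unname(oracle),
               tolerance = 1e-8)
  expect_lte(model_log_likelihood(ft, gt, spec, params), 0)
  # deterministic limit: concentrated guesses, huge gamma -> likelihood -> 0
  hard <- model_params(spec, ft, gamma = 200)
  det_guesses <- generate_guess_table(ft, spec, hard, n_raters = 10L,
                                      seed = 3L)$guesses
  expect_gt(model_log_likelihood(ft, det_guesses, spec, hard), -1e-3)
  # misaligned ids error
  gt2 <- gt; gt2$stimulus_id <- rev(gt2$stimulus_id)
  expect_error(model_log_likelihood(ft, gt2, spec, params), "misaligned")
})

test_that("baseline choice rule transforms external probabilities", {
  p <- rbind(c(0.5, 0.25, 0.25), c(0.2, 0.3, 0.5))
  expect_equal(exp(baseline_log_probabilities(p, 1)), p, tolerance = 1e-12)
  expect_equal(exp(baseline_log_probabilities(p, 0)),
               matrix(1 / 3, 2, 3), tolerance = 1e-12)
  expect_equal(exp(baseline_log_probabilities(p[1, , drop = FALSE], 2)),
               matrix(c(4, 1, 1) / 6, 1), tolerance = 1e-12)
  expect_error(baseline_log_probabilities(rbind(c(0.9, 0.3)), 1), "sum to 1")
})

test_that("exclude_self drops the query from its own exemplar sum", {
  ft <- tiny_features(n_per = 4L)
  spec_in <- model_spec("exemplar_uniform")
  spec_ex <- model_spec("exemplar_uniform", exclude_self = TRUE)
  params <- model_params(spec_in, ft, gamma = 1, beta = 1)
  p_in <- predict_choice_probabilities(ft, spec_in, params)
  p_ex <- predict_choice_probabilities(ft, spec_ex, params)
  # removing the self-exemplar (distance 0, similarity 1) lowers the own
  # category's similarity, so the own-label probability cannot increase
  own <- cbind(seq_len(12), ft$label + 1L)
  expect_true(all(p_ex[own] <= p_in[own] + 1e-12))
  expect_false(isTRUE(all.equal(p_in, p_ex)))
})
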