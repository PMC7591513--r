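test_that("AIC and parameter counts follow their definitions", {
  expect_equal(aic(0, 0), 0)
  expect_equal(aic(-100, 1), 202)
  expect_equal(aic(-55.5, 7) - aic(-55.5, 6), 2)
  expect_equal(parameter_count(model_spec("classic_prototype"), 64, 10), 1L)
  expect_equal(parameter_count(model_spec("linear_prototype"), 64, 10), 65L)
  expect_equal(parameter_count(model_spec("quadratic_prototype"), 64, 10), 641L)
  expect_equal(parameter_count(model_spec("exemplar_uniform"), 64, 10), 2L)
  expect_equal(parameter_count(model_spec("exemplar_attention"), 3, 10), 5L)
})

test_that("guess entropy handles smoothing and degenerate inputs", {
  onehot <- c(50, rep(0, 9))
  expect_equal(guess_entropy(onehot), 0)
  expect_equal(guess_entropy(rep(5, 10)), log(10), tolerance = 1e-12)
  # plus-one smoothing of a one-hot 50-rater vector, direct expression
  expected <- -(51 / 60) * log(51 / 60) - 9 * (1 / 60) * log(1 / 60)
  expect_equal(guess_entropy(onehot, smoothed = TRUE), expected,
               tolerance = 1e-12)
  expect_error(guess_entropy(rep(0, 10)), "at least 1")
})

test_that("entropy stratification uses the printed bin edges", {
  # construct counts whose unsmoothed entropies fall in known bins
  mk <- function(p, n = 1000) round(p * n)
  counts <- rbind(
    mk(c(0.9, 0.1, rep(0, 8))),          # H ~ 0.33 -> low
    mk(c(0.75, 0.25, rep(0, 8))),        # H ~ 0.56 -> low
    mk(c(0.6, 0.3, 0.1, rep(0, 7))),     # H ~ 0.90 -> medium
    mk(c(0.4, 0.3, 0.2, 0.1, rep(0, 6))),# H ~ 1.28 -> high
    c(1000, rep(0, 9)))                  # one-hot -> low
  gt <- guess_table(paste0("s", 1:5), rep(0L, 5), counts)
  bins <- stratify_by_entropy(gt)
  expect_equal(as.integer(bins), c(1L, 1L, 2L, 3L, 1L))
  # sort-and-threshold oracle on random counts
  set.seed(5)
  counts2 <- t(rmultinom(40, 50, prob = c(0.5, 0.3, 0.1, 0.05, 0.05)))
  gt2 <- guess_table(paste0("r", 1:40), rep(0L, 40), counts2)
  bins2 <- stratify_by_entropy(gt2)
  h <- apply(counts2, 1, function(cnt) {
    p <- cnt[cnt > 0] / sum(cnt); -sum(p * log(p))
  })
  oracle <- ifelse(h <= 0.64, 1L, ifelse(h <= 1, 2L, 3L))
  expect_equal(as.integer(bins2), oracle)
})

# independent average-rank Spearman: explicit ranking with midranks
rank_corr_oracle <- function(a, b) {
  # midrank of each value: average position of its ties in the sorted vector
  midrank <- function(x)
    vapply(x, function(xi) mean(which(sort(x) == xi)), numeric(1))
  ra <- midrank(a); rb <- midrank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

test_that("floored Spearman zeroes sub-resolution probabilities", {
  h <- c(45, 5, rep(0, 8))
  expect_equal(floored_spearman(h / 50, h), 1)
  # probabilities below 0.04 are floored before ranking: the model's tiny
  # preferences among never-chosen categories must not hurt the correlation
  m <- c(0.95, 0.039, 0.011, rep(0, 7))
  h2 <- c(50, rep(0, 9))
  floored <- ifelse(m < 0.04, 0, m)
  expect_equal(floored_spearman(m, h2),
               rank_corr_oracle(floored, h2 / 50))
  expect_equal(floored_spearman(m, h2), 1)  # after flooring, ranks agree
  # exactly 0.04 is kept (strict "below the resolution")
  m3 <- c(0.92, 0.04, 0.04, rep(0, 7))
  h3 <- c(46, 2, 2, rep(0, 7))
  expect_equal(floored_spearman(m3, h3), 1)
  # random vectors match the explicit-rank oracle
  set.seed(6)
  for (i in 1:10) {
    mp <- as.vector(rmultinom(1, 100, rexp(10))) / 100
    hc <- as.vector(rmultinom(1, 50, rexp(10)))
    expect_equal(floored_spearman(mp, hc),
                 rank_corr_oracle(ifelse(mp < 0.04, 0, mp), hc / 50),
                 tolerance = 1e-12)
  }
  # invariance to a monotone rescaling that preserves the floor set
  mp <- c(0.5, 0.3, 0.1, 0.06, 0.04, rep(0, 5))
  hc <- c(20, 15, 10, 3, 2, rep(0, 5))
  mp_resc <- mp^0.8 / sum(mp^0.8)  # order-preserving, all entries stay >= 0.04
  expect_true(all((mp_resc < 0.04) == (mp < 0.04)))
  expect_equal(floored_spearman(mp, hc), floored_spearman(mp_resc, hc))
  # both constant and identical -> 1; undefined single-sided -> NA
  expect_equal(floored_spearman(rep(0.1, 10), rep(5, 10)), 1)
  expect_true(is.na(floored_spearman(rep(0.1, 10), c(10, rep(0, 9)))))
})

test_that("second-best accuracy counts matches, ties and exclusions", {
  # 4-stimulus toy set with hand-built orderings
  pred <- rbind(c(0.6, 0.3, 0.1),   # second = cat 1
                c(0.5, 0.2, 0.3),   # second = cat 2
                c(0.7, 0.2, 0.1),   # second = cat 1
                c(0.8, 0.15, 0.05)) # second = cat 1
  counts <- rbind(c(30, 15, 5),     # human second = cat 1 -> hit
                  c(25, 20, 5),     # human second = cat 1 -> miss
                  c(20, 15, 15),    # human second tied {1,2} -> hit
                  c(50, 0, 0))      # single category -> excluded
  gt <- guess_table(paste0("s", 1:4), rep(0L, 4), counts)
  expect_equal(second_best_accuracy(pred, gt), 2 / 3)
  # model identical to human proportions with strict ordering counts correct
  gt1 <- guess_table("a", 0L, rbind(c(30, 15, 5)))
  expect_equal(second_best_accuracy(rbind(c(0.6, 0.3, 0.1)), gt1), 1)
  # only one-hot humans: empty denominator
  gt2 <- guess_table(c("a", "b"), c(0L, 1L), rbind(c(10, 0), c(0, 10)))
  expect_true(is.na(second_best_accuracy(rbind(c(0.9, 0.1), c(0.2, 0.8)), gt2)))
})

test_that("confusion matrix aggregates guesses by true category", {
  # perfect raters give the identity
  counts <- diag(10) * 50
  gt <- guess_table(paste0("s", 1:10), 0:9, counts)
  expect_equal(unname(confusion_matrix(gt)), diag(10))
  # rows always sum to one
  set.seed(8)
  counts2 <- t(rmultinom(30, 50, rep(0.1, 10)))
  gt2 <- guess_table(paste0("r", 1:30), rep(0:9, each = 3), counts2)
  expect_equal(unname(rowSums(confusion_matrix(gt2))), rep(1, 10))
  # planted cat<->dog style confusion surfaces as the largest off-diagonals
  cfg <- synthesis_config(n_per_category = 40L, confusion_pairs = list(c(3L, 5L)),
                          confusion_strength = 0.8, seed = 17L)
  ds <- generate_dataset(cfg)
  cm <- confusion_matrix(ds$guesses)
  off <- cm; diag(off) <- 0
  peak <- which(off == max(off), arr.ind = TRUE)[1L, ]
  expect_true(all(sort(unname(peak)) == c(4L, 6L)))  # rows 4,6 = categories 3,5
})

test_that("noise ceiling behaves like a split-half reliability", {
  set.seed(9)
  # informative two-category stimulus: high ceiling
  raw <- data.frame(stimulus_id = "s1",
                    chosen_label = rep(c(0L, 1L), c(30, 20)))
  nc <- noise_ceiling(raw, n_categories = 10L, n_splits = 50L)
  expect_true(all(nc$per_stimulus >= -1 & nc$per_stimulus <= 1, na.rm = TRUE))
  expect_gt(nc$mean, 0.8)
  # mean ceiling increases with rater count (iid raters, fixed distribution)
  p <- c(0.5, 0.3, 0.2, rep(0, 7))
  gen <- function(n_raters) {
    do.call(rbind, lapply(1:40, function(s)
      data.frame(stimulus_id = sprintf("t%02d", s),
                 chosen_label = sample(0:9, n_raters, TRUE, p))))
  }
  nc_small <- noise_ceiling(gen(8L), 10L, n_splits = 30L)
  nc_big <- noise_ceiling(gen(48L), 10L, n_splits = 30L)
  expect_gt(nc_big$mean, nc_small$mean)
  expect_error(noise_ceiling(
    data.frame(stimulus_id = "x", chosen_label = 0L), 10L), "fewer than 4")
})

test_that("evaluate_model assembles an internally consistent report", {
  ft <- tiny_features(n_per = 8L, n_c = 4L)
  gt <- tiny_guesses(ft, n_raters = 20L, gamma = 0.8)
  spec <- model_spec("classic_prototype")
  # uniform gamma = 0 model: closed-form NLL and AIC
  rep0 <- evaluate_model(ft, gt, list(spec = spec,
                                      params = model_params(spec, ft, gamma = 0)))
  expect_equal(rep0$nll, sum(gt$counts) * log(4), tolerance = 1e-8)
  expect_equal(rep0$aic, 2 * rep0$k + 2 * rep0$nll, tolerance = 1e-10)
  # the generating model scores a lower NLL than a gamma-perturbed copy
  gen <- evaluate_model(ft, gt, list(spec = spec,
                                     params = model_params(spec, ft, gamma = 0.8)))
  off <- evaluate_model(ft, gt, list(spec = spec,
                                     params = model_params(spec, ft, gamma = 2.4)))
  expect_lt(gen$nll, off$nll)
  expect_equal(gen$aic, 2 * gen$k + 2 * gen$nll, tolerance = 1e-10)
  expect_equal(sum(gen$bin_sizes), length(ft$stimulus_id))
  expect_equal(dim(gen$per_stimulus_predictions),
               c(length(ft$stimulus_id), 4L))
})
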