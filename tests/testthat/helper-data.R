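# Small in-code fixtures shared across test files.

# A tiny hand-sized feature table: n_c categories on a simplex-like layout.
tiny_features <- function(n_per = 3L, n_c = 3L, n_d = 4L, sep = 3,
                          spread = 0.5, seed = 42L) {
  set.seed(seed)
  means <- matrix(rnorm(n_c * n_d, sd = sep / sqrt(2 * n_d)), n_c, n_d)
  label <- rep(seq_len(n_c) - 1L, each = n_per)
  feats <- means[label + 1L, , drop = FALSE] +
    matrix(rnorm(n_per * n_c * n_d, sd = spread), n_per * n_c, n_d)
  feature_table(sprintf("s%02d", seq_along(label)), label, feats,
                n_categories = n_c)
}

# A guess table with known counts for the tiny features.
tiny_guesses <- function(features, n_raters = 10L, gamma = 1, seed = 43L) {
  spec <- model_spec("classic_prototype")
  params <- model_params(spec, features, gamma = gamma)
  generate_guess_table(features, spec, params, n_raters = n_raters,
                       seed = seed)$guesses
}

# Moderately ambiguous synthetic dataset used by recovery-style tests:
# separation 2.5 keeps the guess distributions informative about the
# choice-rule parameters (saturated near-one-hot responses carry almost no
# information about gamma or beta).
recovery_config <- function(variant, n_per = 100L, n_d = 8L, seed = 1L,
                            gamma = 1, beta = 1, attention = NULL,
                            inv_variance = NULL) {
  synthesis_config(
    n_categories = 10L, n_dims = n_d, n_per_category = n_per,
    separation = 2.5, spread = 1,
    true_model = list(spec = model_spec(variant), gamma = gamma, beta = beta,
                      attention = attention, inv_variance = inv_variance),
    n_raters = 50L, seed = seed)
}

expect_equal_tol <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
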