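# Small in-code fixtures shared across test files.

# Tiny adulteration dataset: 16 groups x n samples, fast to generate.
tiny_dataset <- function(n_per_group = 5, seed = 1, ...) {
  generate_dataset(generator_config(n_per_group = n_per_group,
                                    rng_seed = seed, ...))
}

# Small planted-signal benchmark for selector tests.
tiny_planted <- function(n_per_class = 15, seed = 1) {
  generate_planted_dataset(n_per_class = n_per_class, n_classes = 3,
                           rng_seed = seed)
}

# Brute-force per-window polynomial fit: independent oracle for SG.
sg_oracle <- function(x, window, polyorder) {
  n <- length(x)
  h <- (window - 1) %/% 2
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - h):min(n, i + h)
    t <- idx - i
    fit <- stats::lm(x[idx] ~ stats::poly(t, degree = polyorder, raw = TRUE))
    unname(stats::predict(fit, data.frame(t = 0)))
  }, numeric(1))
}

# Independent loop-based confusion-count oracle.
confusion_oracle <- function(true, pred, classes) {
  m <- matrix(0L, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (i in seq_along(true)) {
    m[true[i], pred[i]] <- m[true[i], pred[i]] + 1L
  }
  m
}
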