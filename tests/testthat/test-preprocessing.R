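test_that("SG smoothing reproduces low-order polynomials, edges included", {
  x <- seq(0, 1, length.out = 41)
  for (coefs in list(c(2, 0, 0), c(1, -3, 0), c(0.5, 2, -4))) {
    y <- coefs[1] + coefs[2] * x + coefs[3] * x^2
    expect_equal(sg_smooth(y, window = 11, polyorder = 2), y,
                 tolerance = 1e-9)
  }
  expect_equal(sg_smooth(rep(3.2, 20), 5, 2), rep(3.2, 20),
               tolerance = 1e-12)
  expect_error(sg_smooth(x, window = 4, polyorder = 2), "odd")
  expect_error(sg_smooth(x, window = 5, polyorder = 5), "polyorder")
})

test_that("SG equals an independent per-window polynomial fit", {
  set.seed(42)
  y <- cumsum(rnorm(11))
  expect_equal(sg_smooth(y, window = 5, polyorder = 2),
               sg_oracle(y, 5, 2), tolerance = 1e-8)
  y2 <- rnorm(30)
  expect_equal(sg_smooth(y2, window = 7, polyorder = 3),
               sg_oracle(y2, 7, 3), tolerance = 1e-8)
})

test_that("SG is linear and works row-wise on matrices", {
  set.seed(7)
  x <- rnorm(25); y <- rnorm(25)
  a <- 2.5; b <- -1.25
  expect_equal(sg_smooth(a * x + b * y, 7, 2),
               a * sg_smooth(x, 7, 2) + b * sg_smooth(y, 7, 2),
               tolerance = 1e-10)
  m <- rbind(x, y)
  sm <- sg_smooth(m, 7, 2)
  expect_equal(sm[1, ], sg_smooth(x, 7, 2), ignore_attr = TRUE)
  expect_equal(sm[2, ], sg_smooth(y, 7, 2), ignore_attr = TRUE)
})

test_that("SNV standardizes, is affine-invariant and idempotent", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(8)
  x <- rnorm(228, mean = 0.5, sd = 0.1)
  out <- snv(x)
  expect_lt(abs(mean(out)), 1e-10)
  expect_lt(abs(stats::sd(out) - 1), 1e-10)
  expect_equal(snv(3.7 * x + 0.9), out, tolerance = 1e-10)
  expect_equal(snv(out), out, tolerance = 1e-10)
  expect_error(snv(rep(1, 10)), "zero-variance")
  expect_error(snv(1), "2 points")
})

test_that("MSC inverts affine scatter against the reference", {
  set.seed(9)
  ref <- endmember_spectrum("coffee")
  expect_equal(msc(ref, ref), ref, tolerance = 1e-10)
  expect_equal(msc(2 * ref + 1, ref), ref, tolerance = 1e-10)
  # 3-point toy: a, b from hand-solved normal equations
  r3 <- c(1, 2, 4)
  x3 <- c(3, 5, 9)  # exactly 2*ref + 1
  b <- sum((r3 - mean(r3)) * (x3 - mean(x3))) / sum((r3 - mean(r3))^2)
  a <- mean(x3) - b * mean(r3)
  expect_equal(c(a, b), c(1, 2), tolerance = 1e-12)
  expect_equal(msc(x3, r3), (x3 - a) / b, tolerance = 1e-12)
  expect_error(msc(x3, rep(1, 3)), "constant")
  expect_error(msc(rbind(x3, c(5, 5, 5)), r3), "row")
})

test_that("MSC-corrected spectra refit against the reference with a~0, b~1", {
  set.seed(10)
  ref <- endmember_spectrum("soybean")
  n <- 12
  X <- t(sapply(seq_len(n), function(i) {
    (1 + rnorm(1, 0, 0.2)) * ref + rnorm(1, 0, 0.1) + rnorm(228, 0, 0.002)
  }))
  corrected <- msc(X, ref)
  for (i in seq_len(n)) {
    fit <- stats::coef(stats::lm(corrected[i, ] ~ ref))
    expect_lt(abs(fit[1]), 0.02)
    expect_lt(abs(fit[2] - 1), 0.05)
  }
})

test_that("preprocessing chains honour train/test separation and order", {
  d <- tiny_dataset(n_per_group = 4, seed = 12,
                    scatter_slope_sd = 0.15, scatter_offset_sd = 0.05)
  sp <- split_dataset(d, split_spec(rng_seed = 13))
  raw <- apply_preprocessing(sp$train, sp$prediction, preprocess_spec("RAW"))
  expect_identical(raw$train$reflectance, sp$train$reflectance)
  expect_identical(raw$test$reflectance, sp$prediction$reflectance)

  # SG-SNV: every output spectrum standardized
  sgsnv <- apply_preprocessing(sp$train, sp$prediction,
                               preprocess_spec("SG-SNV"))
  rm_ <- rowMeans(sgsnv$test$reflectance)
  rs <- apply(sgsnv$test$reflectance, 1, stats::sd)
  expect_true(all(abs(rm_) < 1e-10))
  expect_true(all(abs(rs - 1) < 1e-10))

  # SG-MSC shrinks within-group spread on scatter-corrupted data
  spread <- function(mat) {
    mean(stats::dist(mat))
  }
  grp <- class_labels(sp$train) == class_labels(sp$train)[1]
  sgmsc <- apply_preprocessing(sp$train, sp$prediction,
                               preprocess_spec("SG-MSC"))
  expect_lt(spread(sgmsc$train$reflectance[grp, ]),
            spread(sp$train$reflectance[grp, ]))

  # SG-MSC equals SG then MSC with the SG'd train mean as reference
  manual_tr <- sg_smooth(sp$train$reflectance, 11, 2)
  manual_te <- sg_smooth(sp$prediction$reflectance, 11, 2)
  ref <- colMeans(manual_tr)
  expect_equal(unname(sgmsc$train$reflectance), unname(msc(manual_tr, ref)),
               tolerance = 1e-10)
  expect_equal(unname(sgmsc$test$reflectance), unname(msc(manual_te, ref)),
               tolerance = 1e-10)

  expect_error(preprocess_spec("SG-RAW"))
  expect_error(preprocess_spec("SG", sg_window = 8), "odd")
})
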