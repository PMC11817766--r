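test_that("endmember spectra have configured minima and obey the library", {
  wl <- default_wavelengths()
  lib <- endmember_library()
  coffee <- endmember_spectrum("coffee", wl, lib)
  # each configured coffee band center is a local dip of the
  # continuum-removed spectrum (the raw curve also slopes downwards)
  frac <- (wl - 900) / 800
  residual <- coffee - (0.52 + (0.42 - 0.52) * frac)
  for (ctr in lib$materials$coffee$bands$center) {
    i <- which.min(abs(wl - ctr))
    window <- residual[max(1, i - 15):min(length(wl), i + 15)]
    expect_lte(residual[i], min(window) + 1e-9)
  }
  # the strong 1462 nm band is a local minimum of the raw curve too
  # (within one grid step: the center falls between grid points)
  i <- which.min(abs(wl - 1462))
  expect_lte(abs(which.min(coffee[(i - 10):(i + 10)]) - 11), 1)
  expect_error(endmember_spectrum("tea", wl, lib), "tea")

  # zero band depths are rejected by the library; a flat continuum comes
  # from a depth-scale of 0 instead
  flat <- endmember_spectrum("coffee", wl, lib, depth_scale = 1e-12)
  frac <- (wl - 900) / 800
  continuum <- 0.52 + (0.42 - 0.52) * frac
  expect_equal(flat, continuum, tolerance = 1e-9)
})

test_that("soybean band depth matches the Gaussian band formula", {
  wl <- default_wavelengths()
  lib <- endmember_library()
  s <- endmember_spectrum("soybean", wl, lib)
  b <- lib$materials$soybean$bands
  # evaluate the band model directly at the 1210 nm center vs one step off
  k <- which(b$center == 1210)
  i <- which.min(abs(wl - 1210))
  frac <- (wl - 900) / 800
  cont <- 0.74 + (0.62 - 0.74) * frac
  expected <- cont - rowSums(sapply(seq_len(nrow(b)), function(j) {
    b$depth[j] * exp(-(wl - b$center[j])^2 / (2 * b$width[j]^2))
  }))
  expect_equal(s, expected, tolerance = 1e-12)
  # at the center the dip is approximately the configured depth relative
  # to the local continuum
  expect_equal(cont[i] - s[i], b$depth[k], tolerance = 0.02)
})

test_that("mix_spectrum is a convex combination in absorbance space", {
  cvec <- c(0.5, 0.4, 0.6)
  avec <- c(0.7, 0.6, 0.5)
  expect_identical(mix_spectrum(cvec, avec, 0), cvec)
  expect_identical(mix_spectrum(cvec, avec, 1), avec)
  # brute-force per point: -log10, mix, back-transform
  f <- 0.4
  expected <- vapply(1:3, function(i) {
    10^-((1 - f) * -log10(cvec[i]) + f * -log10(avec[i]))
  }, numeric(1))
  expect_equal(mix_spectrum(cvec, avec, f), expected, tolerance = 1e-12)
  expect_error(mix_spectrum(cvec, avec, 1.2), "fraction")
  expect_error(mix_spectrum(cvec, avec[1:2], 0.5), "length")
})

test_that("measurement effects match their stated noise model", {
  wl <- default_wavelengths()
  clean <- endmember_spectrum("coffee", wl)
  zero <- generator_config(noise_sd = 0, scatter_slope_sd = 0,
                           scatter_offset_sd = 0, baseline_amplitude = 0,
                           fraction_jitter_sd = 0, component_variability = 0)
  set.seed(1)
  expect_identical(apply_measurement_effects(clean, zero, wl), clean)

  # scatter only: exact affine transform of the input
  scatter <- generator_config(noise_sd = 0, baseline_amplitude = 0,
                              scatter_slope_sd = 0.1,
                              scatter_offset_sd = 0.05)
  set.seed(7)
  out <- apply_measurement_effects(clean, scatter, wl)
  fit <- stats::lm(out ~ clean)
  expect_equal(unname(stats::predict(fit)), out, tolerance = 1e-10)

  # noise only: variance of (output - input) near noise_sd^2, within 3 SE
  noisy <- generator_config(noise_sd = 0.01, scatter_slope_sd = 0,
                            scatter_offset_sd = 0, baseline_amplitude = 0)
  set.seed(11)
  resid <- apply_measurement_effects(clean, noisy, wl) - clean
  v <- stats::var(resid)
  se <- 0.01^2 * sqrt(2 / (length(wl) - 1))
  expect_lt(abs(v - 0.01^2), 3 * se)
})

test_that("generated dataset matches the study design and is seeded", {
  d <- tiny_dataset(n_per_group = 1, seed = 3)
  expect_equal(n_samples(d), 16)
  expect_equal(length(unique(class_labels(d))), 16)
  expect_equal(n_wavelengths(d), 228)

  d1 <- tiny_dataset(n_per_group = 4, seed = 5)
  d2 <- tiny_dataset(n_per_group = 4, seed = 5)
  expect_identical(d1, d2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_spectra(d1, f1); write_spectra(d2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  rt <- read_spectra(f1)
  expect_equal(rt$wavelengths, d1$wavelengths, tolerance = 1e-6)
  expect_equal(unname(rt$reflectance), unname(d1$reflectance),
               tolerance = 1e-6)
  expect_identical(rt$adulterant, d1$adulterant)
})

test_that("blank dataset labels level 0 exactly for coffee", {
  b <- generate_materials_dataset(generator_config(rng_seed = 2),
                                  n_per_material = 3)
  expect_equal(n_samples(b), 15)
  expect_identical(b$level == 0, b$adulterant == "coffee")
})

test_that("clean spectra separate the five materials almost perfectly", {
  cfg <- generator_config(noise_sd = 0.002, scatter_slope_sd = 0,
                          scatter_offset_sd = 0, baseline_amplitude = 0,
                          fraction_jitter_sd = 0,
                          component_variability = 0, rng_seed = 9)
  b <- generate_materials_dataset(cfg, n_per_material = 20)
  sp <- split_dataset(b, split_spec(rng_seed = 10),
                      labels = class_labels(b, "material"))
  m <- train_classifier(sp$train,
                        model_spec(svm_C_grid = 10, svm_gamma_grid = 0.01,
                                   rng_seed = 11),
                        labels = class_labels(sp$train, "material"))
  rep <- metrics(confusion(class_labels(sp$prediction, "material"),
                           predict(m, sp$prediction)))
  expect_gt(rep$accuracy, 95)
})

test_that("absorbance at a coffee band center falls monotonically with adulteration", {
  wl <- default_wavelengths()
  i <- which.min(abs(wl - 1462))
  cfg <- generator_config(n_per_group = 30, rng_seed = 13)
  d <- generate_dataset(cfg)
  blanks <- generate_materials_dataset(cfg, n_per_material = 120)
  coffee_rows <- blanks$reflectance[blanks$adulterant == "coffee", i]
  means <- mean(-log10(coffee_rows))  # fraction 0 = pure coffee blanks
  for (f in c(0.1, 0.2, 0.3, 0.4)) {
    means <- c(means, mean(-log10(d$reflectance[d$level == f, i])))
  }
  expect_true(all(diff(means) < 0))
})
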