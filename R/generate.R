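#' Generator configuration
#'
#' Settings for the synthetic adulterated-coffee dataset.  The defaults
#' reproduce the study design: 4 adulterants x 4 levels (10-40%) x 50
#' samples per group = 800 samples on the 228-point 900--1700 nm grid.
#'
#' Noise and scatter defaults describe a portable diffuse-reflectance
#' instrument: per-wavelength repeatability noise of 0.005 reflectance
#' units after scan averaging, multiplicative scatter with ~5% slope and
#' 0.02 offset spread from particle-size and packing variation, and a
#' quadratic baseline drift of up to 0.02.  `fraction_jitter_sd` and
#' `component_variability` emulate within-group sample variability
#' (mixing inhomogeneity of the scanned spot; natural variation in the
#' absorbing constituents); the study design does not pin these down, so
#' they are fixed package defaults, not fitted quantities.
#'
#' @param n_per_group Samples per adulterant-by-level group (design: 50).
#' @param adulterants Adulterant names; must exist in `library`.
#' @param levels Adulteration mass fractions (design: 0.1, 0.2, 0.3, 0.4).
#' @param noise_sd Additive i.i.d. noise sd, reflectance units.
#' @param scatter_slope_sd Sd of the multiplicative slope around 1.
#' @param scatter_offset_sd Sd of the additive offset.
#' @param baseline_amplitude Max amplitude of the quadratic baseline drift.
#' @param fraction_jitter_sd Sd of per-sample jitter on the nominal mass
#'   fraction (absolute units).
#' @param component_variability Sd of the per-sample multiplicative factor
#'   on band depths.
#' @param rng_seed Integer seed; all stochastic draws flow from it.
#' @param library An [endmember_library()].
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_per_group = 50L,
                             adulterants = c("soybean", "barley",
                                             "chicory", "corn"),
                             levels = c(0.1, 0.2, 0.3, 0.4),
                             noise_sd = 0.005,
                             scatter_slope_sd = 0.05,
                             scatter_offset_sd = 0.02,
                             baseline_amplitude = 0.02,
                             fraction_jitter_sd = 0.015,
                             component_variability = 0.04,
                             rng_seed = 1L,
                             library = endmember_library()) {
  stopifnot(n_per_group >= 1,
            noise_sd >= 0, scatter_slope_sd >= 0, scatter_offset_sd >= 0,
            baseline_amplitude >= 0, fraction_jitter_sd >= 0,
            component_variability >= 0,
            all(levels > 0), all(levels <= 1))
  structure(list(n_per_group = as.integer(n_per_group),
                 adulterants = adulterants, levels = levels,
                 noise_sd = noise_sd,
                 scatter_slope_sd = scatter_slope_sd,
                 scatter_offset_sd = scatter_offset_sd,
                 baseline_amplitude = baseline_amplitude,
                 fraction_jitter_sd = fraction_jitter_sd,
                 component_variability = component_variability,
                 rng_seed = as.integer(rng_seed),
                 library = library),
            class = "generator_config")
}

#' Mix a coffee spectrum with an adulterant spectrum
#'
#' Mixing is done in absorbance-like space: reflectance is mapped through
#' `A = -log10(R)`, the two absorbance curves are combined as the convex
#' combination `(1 - fraction) * coffee + fraction * adulterant`
#' (Beer-Lambert-like additivity of the absorbing constituents), and the
#' result is mapped back with `R = 10^-A`.  Fractions 0 and 1 return the
#' respective pure spectrum exactly.
#'
#' @param coffee Reflectance vector of the pure coffee endmember.
#' @param adulterant Reflectance vector of the adulterant, same length.
#' @param fraction Adulterant mass fraction in `[0, 1]`.
#' @return Mixed reflectance vector.
#' @export
mix_spectrum <- function(coffee, adulterant, fraction) {
  if (length(coffee) != length(adulterant)) {
    stop("coffee and adulterant spectra must have equal length")
  }
  if (fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1], got ", fraction)
  }
  a <- (1 - fraction) * (-log10(coffee)) + fraction * (-log10(adulterant))
  10^(-a)
}

#' Corrupt a clean spectrum with instrument measurement effects
#'
#' Applies the artifacts the preprocessing chain is meant to remove:
#' multiplicative scatter (`slope ~ 1 + N(0, scatter_slope_sd)`), an
#' additive offset (`N(0, scatter_offset_sd)`), a random quadratic
#' baseline with amplitude at most `baseline_amplitude`, and i.i.d.
#' Gaussian noise (`noise_sd`).  The result is clipped below at 1e-4 so
#' reflectance stays strictly positive.  With an all-zero config the
#' input is returned unchanged.
#'
#' Draws come from R's current RNG stream: seed control is the caller's
#' job (the generator seeds once from `rng_seed`).
#'
#' @param clean Reflectance vector.
#' @param config A [generator_config()].
#' @param wavelengths Wavelength grid matching `clean` (used to shape the
#'   baseline polynomial).
#' @return Corrupted reflectance vector of the same length.
#' @export
apply_measurement_effects <- function(clean, config,
                                      wavelengths = default_wavelengths()) {
  slope  <- 1 + stats::rnorm(1, 0, config$scatter_slope_sd)
  offset <- stats::rnorm(1, 0, config$scatter_offset_sd)
  u <- (wavelengths - min(wavelengths)) /
       (max(wavelengths) - min(wavelengths)) * 2 - 1
  coefs <- stats::runif(3, -1, 1)
  poly <- coefs[1] + coefs[2] * u + coefs[3] * u^2
  m <- max(abs(poly))
  baseline <- if (m > 0) config$baseline_amplitude * poly / m else poly * 0
  eps <- stats::rnorm(length(clean), 0, config$noise_sd)
  out <- slope * clean + offset + baseline + eps
  if (config$scatter_slope_sd == 0 && config$scatter_offset_sd == 0 &&
      config$baseline_amplitude == 0 && config$noise_sd == 0) {
    return(clean)
  }
  pmax(out, 1e-4)
}

#' Generate the adulterated-coffee dataset
#'
#' For each adulterant x level group, `n_per_group` samples are built by
#' mixing the coffee endmember with the adulterant endmember at the
#' nominal fraction (plus per-sample jitter), with per-sample band-depth
#' variability, then corrupted with [apply_measurement_effects()].  Fully
#' reproducible from `config$rng_seed`.
#'
#' @param config A [generator_config()].
#' @param clean If `TRUE`, skip measurement effects and within-group
#'   variability: each group is its noiseless mixture spectrum.
#' @return A [spectra_set()]; with the default design 800 samples and 16
#'   distinct type-by-level classes.
#' @export
generate_dataset <- function(config = generator_config(), clean = FALSE) {
  wl <- default_wavelengths()
  set.seed(config$rng_seed)
  rows <- list(); type <- character(0); lev <- numeric(0)
  for (ad in config$adulterants) {
    for (f in config$levels) {
      for (i in seq_len(config$n_per_group)) {
        if (clean) {
          cf <- endmember_spectrum("coffee", wl, config$library)
          as <- endmember_spectrum(ad, wl, config$library)
          x <- mix_spectrum(cf, as, f)
        } else {
          dsc <- 1 + stats::rnorm(1, 0, config$component_variability)
          dsa <- 1 + stats::rnorm(1, 0, config$component_variability)
          cf <- endmember_spectrum("coffee", wl, config$library,
                                   depth_scale = max(dsc, 0.2))
          as <- endmember_spectrum(ad, wl, config$library,
                                   depth_scale = max(dsa, 0.2))
          fi <- min(max(f + stats::rnorm(1, 0, config$fraction_jitter_sd),
                        0), 1)
          x <- apply_measurement_effects(mix_spectrum(cf, as, fi),
                                         config, wl)
        }
        rows[[length(rows) + 1L]] <- x
        type <- c(type, ad); lev <- c(lev, f)
      }
    }
  }
  spectra_set(wl, do.call(rbind, rows), type, lev)
}

#' Generate the blank (pure-material) dataset
#'
#' Emulates the blank study arm: `n_per_material` unadulterated samples
#' of each of the five ground powders (coffee plus the four adulterants),
#' for 5-class material identification.  Coffee blanks carry level 0;
#' pure adulterant blanks carry level 1 (they are 100% adulterant).
#'
#' @param config A [generator_config()]; `n_per_material` defaults to 20
#'   (100 blanks in total).
#' @param n_per_material Samples per material.
#' @param clean As in [generate_dataset()].
#' @return A [spectra_set()].
#' @export
generate_materials_dataset <- function(config = generator_config(),
                                       n_per_material = 20L,
                                       clean = FALSE) {
  wl <- default_wavelengths()
  set.seed(config$rng_seed + 1L)
  mats <- c("coffee", config$adulterants)
  rows <- list(); type <- character(0); lev <- numeric(0)
  for (m in mats) {
    for (i in seq_len(n_per_material)) {
      if (clean) {
        x <- endmember_spectrum(m, wl, config$library)
      } else {
        ds <- max(1 + stats::rnorm(1, 0, config$component_variability), 0.2)
        x <- apply_measurement_effects(
          endmember_spectrum(m, wl, config$library, depth_scale = ds),
          config, wl)
      }
      rows[[length(rows) + 1L]] <- x
      type <- c(type, m)
      lev <- c(lev, if (m == "coffee") 0 else 1)
    }
  }
  spectra_set(wl, do.call(rbind, rows), type, lev)
}

#' Benchmark dataset with planted informative wavelengths
#'
#' A selector benchmark where ground truth is known by construction: only
#' `n_informative` wavelength channels carry class signal (class-specific
#' mean offsets); every other channel is pure noise around a flat 0.5
#' reflectance.  Used to measure how well a wavelength selector recovers
#' the informative set.
#'
#' @param n_per_class Samples per class.
#' @param n_classes Number of classes.
#' @param n_informative Number of signal-bearing channels.
#' @param effect_sd Sd of the class-specific mean offsets on informative
#'   channels (reflectance units).
#' @param noise_sd Per-channel noise sd.
#' @param rng_seed Integer seed.
#' @return A [spectra_set()] with attribute `informative` holding the
#'   planted channel indices.
#' @export
generate_planted_dataset <- function(n_per_class = 40L, n_classes = 5L,
                                     n_informative = 10L,
                                     effect_sd = 0.10, noise_sd = 0.03,
                                     rng_seed = 1L) {
  wl <- default_wavelengths()
  p <- length(wl)
  set.seed(rng_seed)
  informative <- sort(sample.int(p, n_informative))
  offsets <- matrix(stats::rnorm(n_classes * n_informative, 0, effect_sd),
                    n_classes, n_informative)
  n <- n_per_class * n_classes
  refl <- matrix(0.5 + stats::rnorm(n * p, 0, noise_sd), n, p)
  cls <- rep(seq_len(n_classes), each = n_per_class)
  refl[, informative] <- refl[, informative] + offsets[cls, ]
  refl <- pmax(refl, 1e-4)
  out <- spectra_set(wl, refl, paste0("class", cls),
                     rep(0.1, n))  # dummy nonzero level, unused
  attr(out, "informative") <- informative
  out
}
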