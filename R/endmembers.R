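#' Parametric pure-material reflectance library
#'
#' Each material (coffee and the four common adulterants: soybean, barley,
#' chicory, corn) is modelled as a smooth linear continuum minus a set of
#' Gaussian absorption bands.  Band centres sit at the wavelengths where
#' the mean curves of the five ground powders differ most in the
#' 900--1700 nm window (920, 945, 1070, 1210, 1257, 1462, 1660, 1686 nm),
#' and every material carries a broad O-H water band in the 1400--1650 nm
#' region.  Roasted coffee is the strongest absorber (caffeine,
#' chlorogenic acid, oils), so its continuum is the lowest; the starch- and
#' protein-dominated adulterants reflect more.
#'
#' Band depths and widths are this package's own choices: the field's
#' published curves fix only where the discriminating bands lie, not their
#' shapes, so defaults are set to echo the qualitative ordering of the
#' materials without being calibrated to any measured curve.
#'
#' @param materials Optional named list to override/extend the defaults.
#'   Each element needs `continuum` (reflectance at 900 and 1700 nm) and
#'   `bands` (data.frame with `center` nm, `width` nm, `depth` reflectance
#'   units).
#' @return An object of class `endmember_library`.
#' @export
endmember_library <- function(materials = NULL) {
  band <- function(center, width, depth) {
    data.frame(center = center, width = width, depth = depth)
  }
  defaults <- list(
    coffee = list(
      continuum = c(0.52, 0.42),
      bands = band(c(920, 1210, 1462, 1660),
                   c(16, 24, 42, 20),
                   c(0.040, 0.070, 0.110, 0.060))),
    soybean = list(
      continuum = c(0.74, 0.62),
      bands = band(c(1210, 1450, 1686),
                   c(26, 55, 22),
                   c(0.095, 0.070, 0.055))),
    barley = list(
      continuum = c(0.76, 0.66),
      bands = band(c(945, 1257, 1445),
                   c(18, 26, 55),
                   c(0.045, 0.065, 0.060))),
    chicory = list(
      continuum = c(0.66, 0.56),
      bands = band(c(1070, 1455, 1660),
                   c(22, 55, 20),
                   c(0.075, 0.075, 0.045))),
    corn = list(
      continuum = c(0.72, 0.60),
      bands = band(c(945, 1210, 1257, 1440),
                   c(18, 24, 24, 55),
                   c(0.055, 0.050, 0.045, 0.055))))
  lib <- defaults
  if (!is.null(materials)) lib[names(materials)] <- materials
  obj <- structure(list(materials = lib,
                        water_region = c(1400, 1650)),
                   class = "endmember_library")
  validate_endmember_library(obj)
  obj
}

validate_endmember_library <- function(lib) {
  step <- diff(default_wavelengths())[1]
  for (m in names(lib$materials)) {
    b <- lib$materials[[m]]$bands
    if (any(b$center < 900 | b$center > 1700)) {
      stop("band centers for ", m, " must lie in [900, 1700] nm")
    }
    if (any(b$depth <= 0) || any(b$width <= 0)) {
      stop("band depths and widths for ", m, " must be positive")
    }
  }
  coffee <- lib$materials$coffee$bands$center
  for (m in setdiff(names(lib$materials), "coffee")) {
    other <- lib$materials[[m]]$bands$center
    sep <- vapply(coffee, function(c0) min(abs(c0 - other)), numeric(1))
    if (max(sep) <= 2 * step) {
      stop("coffee band set is not distinguishable from ", m,
           ": no band center differs by more than 2 grid steps")
    }
  }
  invisible(lib)
}

#' Evaluate a pure-material reflectance spectrum
#'
#' Continuum minus the sum of the material's Gaussian absorption bands,
#' evaluated on the given wavelength grid.  Deterministic for a fixed
#' library.
#'
#' @param material Material name present in `library`.
#' @param wavelengths Numeric grid in nm, within `[900, 1700]`.
#' @param library An [endmember_library()].
#' @param depth_scale Optional multiplier (scalar or one per band) on band
#'   depths; used by the generator to emulate sample-to-sample
#'   compositional variability.
#' @return Reflectance vector, one value per wavelength.
#' @export
endmember_spectrum <- function(material, wavelengths = default_wavelengths(),
                               library = endmember_library(),
                               depth_scale = 1) {
  if (!material %in% names(library$materials)) {
    stop("unknown material: '", material, "'")
  }
  if (any(wavelengths < 900 | wavelengths > 1700)) {
    stop("wavelengths must lie within [900, 1700] nm")
  }
  spec <- library$materials[[material]]
  frac <- (wavelengths - 900) / 800
  r <- spec$continuum[1] + (spec$continuum[2] - spec$continuum[1]) * frac
  b <- spec$bands
  depth <- b$depth * depth_scale
  for (k in seq_len(nrow(b))) {
    r <- r - depth[k] * exp(-(wavelengths - b$center[k])^2 / (2 * b$width[k]^2))
  }
  r
}
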