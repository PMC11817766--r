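#' Default portable-instrument wavelength grid
#'
#' The acquisition grid of the portable NIR reflectance instrument the
#' analysis targets: 228 equally spaced wavelength points covering
#' 900--1700 nm (a step of about 3.52 nm).
#'
#' @return Numeric vector of 228 wavelengths in nm.
#' @export
default_wavelengths <- function() {
  seq(900, 1700, length.out = 228L)
}

#' Construct a spectra set
#'
#' A `spectra_set` bundles a wavelength grid, a reflectance matrix
#' (samples in rows, wavelengths in columns) and per-sample labels:
#' the material or adulterant name and the adulteration mass fraction.
#' For adulterated samples a combined type-by-level class label
#' (`class16` in the full 4 adulterant x 4 level design) is derived.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param reflectance Numeric matrix, `n_samples x length(wavelengths)`,
#'   finite and strictly positive.
#' @param adulterant Character vector of material names, one per sample.
#' @param level Numeric vector of adulteration mass fractions in `[0, 1]`,
#'   one per sample.
#' @param sample_id Optional character vector of sample identifiers;
#'   defaults to `s0001, s0002, ...`.
#' @param check_positive Require strictly positive values (`TRUE` for raw
#'   reflectance; preprocessed spectra such as SNV output may be negative
#'   and are rebuilt with `FALSE`).
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(wavelengths, reflectance, adulterant, level,
                        sample_id = NULL, check_positive = TRUE) {
  wavelengths <- as.numeric(wavelengths)
  reflectance <- as.matrix(reflectance)
  if (ncol(reflectance) != length(wavelengths)) {
    stop("reflectance has ", ncol(reflectance), " columns but ",
         length(wavelengths), " wavelengths were given")
  }
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing")
  }
  if (!all(is.finite(reflectance))) stop("reflectance must be finite")
  if (check_positive && any(reflectance <= 0)) {
    stop("reflectance must be strictly positive")
  }
  n <- nrow(reflectance)
  adulterant <- as.character(adulterant)
  level <- as.numeric(level)
  if (length(adulterant) != n || length(level) != n) {
    stop("labels must have one entry per sample")
  }
  if (any(level < 0 | level > 1)) stop("level must lie in [0, 1]")
  if (is.null(sample_id)) sample_id <- sprintf("s%04d", seq_len(n))
  dimnames(reflectance) <- list(sample_id, sprintf("%.3f", wavelengths))
  structure(
    list(wavelengths = wavelengths,
         reflectance = reflectance,
         adulterant  = adulterant,
         level       = level,
         sample_id   = as.character(sample_id)),
    class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$reflectance), " samples x ",
      length(x$wavelengths), " wavelengths (",
      format(min(x$wavelengths)), "-", format(max(x$wavelengths)),
      " nm)\n", sep = "")
  tab <- table(class_labels(x, "class16"))
  cat("  classes: ", length(tab), " (",
      paste(utils::head(names(tab), 4), collapse = ", "),
      if (length(tab) > 4) ", ..." else "", ")\n", sep = "")
  invisible(x)
}

#' Number of samples / wavelengths in a spectra set
#' @param x A `spectra_set`.
#' @return Integer count.
#' @export
n_samples <- function(x) nrow(x$reflectance)

#' @rdname n_samples
#' @export
n_wavelengths <- function(x) length(x$wavelengths)

#' Per-sample class labels for a detection task
#'
#' `"qualitative4"` labels samples by adulterant type only (the 4-class
#' qualitative task); `"class16"` (alias `"quantitative16"`) crosses type
#' with adulteration level, e.g. `"soybean_20"`; `"material"` returns the
#' raw material name (used by the 5-material blank dataset).
#'
#' @param x A `spectra_set`.
#' @param task One of `"qualitative4"`, `"class16"`, `"quantitative16"`,
#'   `"material"`.
#' @return Character vector of labels, one per sample.
#' @export
class_labels <- function(x, task = c("class16", "quantitative16",
                                     "qualitative4", "material")) {
  task <- match.arg(task)
  switch(task,
    qualitative4 = ,
    material     = x$adulterant,
    class16      = ,
    quantitative16 = ifelse(
      x$level > 0,
      paste0(x$adulterant, "_", round(100 * x$level)),
      x$adulterant))
}

#' Subset a spectra set by sample index
#' @param x A `spectra_set`.
#' @param i Integer or logical sample index.
#' @return A `spectra_set` with the selected samples.
#' @export
subset_samples <- function(x, i) {
  spectra_set(x$wavelengths, x$reflectance[i, , drop = FALSE],
              x$adulterant[i], x$level[i], x$sample_id[i],
              check_positive = FALSE)
}

#' Keep only the wavelengths flagged by a binary mask
#'
#' Applies a wavelength-selection mask: columns where `mask == 1` are
#' retained and the wavelength grid is subset accordingly.
#'
#' @param x A `spectra_set`.
#' @param mask Integer/logical vector, one entry per wavelength.
#' @return A `spectra_set` with `sum(mask)` wavelength columns.
#' @export
apply_mask <- function(x, mask) {
  mask <- as.logical(mask)
  if (length(mask) != n_wavelengths(x)) {
    stop("mask length ", length(mask), " does not match ",
         n_wavelengths(x), " wavelengths")
  }
  if (!any(mask)) stop("mask selects no wavelengths")
  spectra_set(x$wavelengths[mask], x$reflectance[, mask, drop = FALSE],
              x$adulterant, x$level, x$sample_id, check_positive = FALSE)
}

#' Write / read a spectra set as CSV
#'
#' Layout: `sample_id`, `adulterant`, `level`, then one column per
#' wavelength named by its value in nm with 3 decimals. UTF-8, dot
#' decimal separator.
#'
#' @param x A `spectra_set`.
#' @param path File path.
#' @return `write_spectra` returns `path` invisibly; `read_spectra`
#'   returns a `spectra_set`.
#' @export
write_spectra <- function(x, path) {
  dt <- data.table::data.table(
    sample_id = x$sample_id,
    adulterant = x$adulterant,
    level = x$level)
  refl <- data.table::as.data.table(x$reflectance)
  data.table::setnames(refl, sprintf("%.3f", x$wavelengths))
  data.table::fwrite(cbind(dt, refl), path, sep = ",", dec = ".",
                     quote = FALSE, eol = "\n", scipen = 50)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  dt <- data.table::fread(path, sep = ",", dec = ".", header = TRUE,
                          data.table = TRUE)
  wl <- as.numeric(names(dt)[-(1:3)])
  spectra_set(wl, as.matrix(dt[, -(1:3)]), dt$adulterant, dt$level,
              dt$sample_id)
}

#' Mean spectra per class, for quick diagnostics
#'
#' @param x A `spectra_set`.
#' @param task Label set to group by, see [class_labels()].
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the matrix of class-mean spectra.
#' @export
plot_mean_spectra <- function(x, task = "material", ...) {
  lab <- class_labels(x, task)
  means <- t(vapply(split(seq_along(lab), lab),
                    function(i) colMeans(x$reflectance[i, , drop = FALSE]),
                    numeric(n_wavelengths(x))))
  graphics::matplot(x$wavelengths, t(means), type = "l", lty = 1,
                    xlab = "wavelength (nm)", ylab = "reflectance", ...)
  graphics::legend("topright", legend = rownames(means),
                   col = seq_len(nrow(means)), lty = 1, cex = 0.7)
  invisible(means)
}
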