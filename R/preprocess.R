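#' Preprocessing specification
#'
#' @param method One of `"RAW"`, `"SG"`, `"SNV"`, `"MSC"`, `"SG-MSC"`,
#'   `"SG-SNV"`.  Chained methods are applied left to right.
#' @param sg_window Odd Savitzky-Golay window length (points), >= 3.
#' @param sg_polyorder Polynomial order, `< sg_window`.
#' @param msc_reference Either `"train_mean"` (reference = mean spectrum of
#'   the training set, computed after any preceding step) or an explicit
#'   numeric reference spectrum.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(method = c("RAW", "SG", "SNV", "MSC",
                                       "SG-MSC", "SG-SNV"),
                            sg_window = 11L, sg_polyorder = 2L,
                            msc_reference = "train_mean") {
  method <- match.arg(method)
  sg_window <- as.integer(sg_window)
  sg_polyorder <- as.integer(sg_polyorder)
  if (sg_window < 3L || sg_window %% 2L == 0L) {
    stop("sg_window must be an odd integer >= 3")
  }
  if (sg_polyorder >= sg_window) stop("sg_polyorder must be < sg_window")
  structure(list(method = method, sg_window = sg_window,
                 sg_polyorder = sg_polyorder,
                 msc_reference = msc_reference),
            class = "preprocess_spec")
}

# Banded smoothing matrix for SG: row i holds the least-squares weights of
# the window around point i.  Interior rows share the classical symmetric
# convolution weights; within half a window of either boundary the
# polynomial is refit on the truncated window (asymmetric support), which
# keeps the filter exact on polynomials up to the fit order at the edges.
sg_matrix <- function(n, window, polyorder) {
  h <- (window - 1L) %/% 2L
  S <- matrix(0, n, n)
  weights_for <- function(t) {
    X <- outer(t, 0:polyorder, `^`)
    e <- c(1, rep(0, polyorder))  # value of the fit at offset 0
    drop(e %*% solve(crossprod(X), t(X)))
  }
  interior <- weights_for(seq(-h, h))
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    idx <- lo:hi
    if (lo == i - h && hi == i + h) {
      S[i, idx] <- interior
    } else {
      S[i, idx] <- weights_for(idx - i)
    }
  }
  S
}

#' Savitzky-Golay smoothing
#'
#' Each point is replaced by the value at the window centre of a
#' least-squares polynomial fit over a sliding window.  Near the
#' boundaries the window is truncated rather than padded, and the
#' polynomial refit on the available points, so polynomials of degree
#' up to `polyorder` pass through unchanged everywhere.
#'
#' @param x A numeric vector (one spectrum) or a matrix with spectra in
#'   rows.
#' @param window Odd window length, `<=` spectrum length.
#' @param polyorder Polynomial order `< window`.
#' @return Smoothed vector or matrix, same shape as `x`.
#' @export
sg_smooth <- function(x, window = 11L, polyorder = 2L) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  n <- if (is.matrix(x)) ncol(x) else length(x)
  if (n < window) stop("spectrum length must be >= window")
  S <- sg_matrix(n, window, polyorder)
  if (is.matrix(x)) x %*% t(S) else drop(S %*% x)
}

#' Standard normal variate transform
#'
#' Centres and scales each spectrum to mean 0 and (sample, n-1
#' denominator) standard deviation 1, removing per-spectrum offset and
#' multiplicative scatter.
#'
#' @param x A numeric vector or matrix with spectra in rows.
#' @return Transformed vector/matrix.
#' @export
snv <- function(x) {
  one <- function(v) {
    if (length(v) < 2) stop("snv needs at least 2 points")
    s <- stats::sd(v)
    if (s == 0) stop("snv undefined for a zero-variance spectrum")
    (v - mean(v)) / s
  }
  if (is.matrix(x)) t(apply(x, 1, one)) else one(x)
}

#' Multiplicative scatter correction
#'
#' Each spectrum `x` is regressed on the reference spectrum by ordinary
#' least squares, `x ~ a + b * reference`, and the scatter inverted as
#' `(x - a) / b`.
#'
#' @param x A matrix with spectra in rows (or a single vector).
#' @param reference Reference spectrum, same length as a row; must not be
#'   constant.
#' @return Corrected matrix/vector.
#' @export
msc <- function(x, reference) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(reference)) {
    stop("reference length does not match spectra")
  }
  rc <- reference - mean(reference)
  den <- sum(rc^2)
  if (den == 0) stop("reference spectrum is constant")
  xm <- rowMeans(x)
  b <- drop((x - xm) %*% rc) / den
  bad <- which(abs(b) < 1e-12)
  if (length(bad)) {
    stop("MSC slope numerically zero for row(s): ",
         paste(bad, collapse = ", "))
  }
  a <- xm - b * mean(reference)
  out <- (x - a) / b
  if (vec) drop(out) else out
}

#' Apply a preprocessing chain to train and test spectra
#'
#' Chained methods are applied left to right (`"SG-MSC"` = SG then MSC).
#' The MSC reference is computed from the training set only (after any
#' preceding step) and reused for the test set, so no information leaks
#' from test to train.  `"RAW"` is the identity.
#'
#' @param train A [spectra_set()].
#' @param test Optional [spectra_set()] on the identical wavelength grid.
#' @param spec A [preprocess_spec()].
#' @return A list with elements `train` and `test` (the latter `NULL` if
#'   not supplied).
#' @export
apply_preprocessing <- function(train, test = NULL,
                                spec = preprocess_spec("RAW")) {
  if (!is.null(test) &&
      !isTRUE(all.equal(train$wavelengths, test$wavelengths))) {
    stop("train and test wavelength grids differ")
  }
  steps <- strsplit(spec$method, "-", fixed = TRUE)[[1]]
  tr <- train$reflectance
  te <- if (!is.null(test)) test$reflectance else NULL
  for (s in steps) {
    if (s == "RAW") next
    if (s == "SG") {
      tr <- sg_smooth(tr, spec$sg_window, spec$sg_polyorder)
      if (!is.null(te)) te <- sg_smooth(te, spec$sg_window, spec$sg_polyorder)
    } else if (s == "SNV") {
      tr <- snv(tr)
      if (!is.null(te)) te <- snv(te)
    } else if (s == "MSC") {
      ref <- if (identical(spec$msc_reference, "train_mean")) {
        colMeans(tr)
      } else {
        as.numeric(spec$msc_reference)
      }
      tr <- msc(tr, ref)
      if (!is.null(te)) te <- msc(te, ref)
    } else {
      stop("unknown preprocessing method: '", s, "'")
    }
  }
  rebuild <- function(orig, mat) {
    out <- orig
    dimnames(mat) <- dimnames(orig$reflectance)
    out$reflectance <- mat
    out
  }
  list(train = rebuild(train, tr),
       test = if (!is.null(test)) rebuild(test, te) else NULL)
}
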