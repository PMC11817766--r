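#' Invasive weed optimization configuration
#'
#' Canonical (Mehrabian-Lucas) IWO adapted to wavelength subset
#' selection: candidates live in `[0,1]^p`; a coordinate above
#' `threshold` selects that wavelength.  The study ran 10 iterations with
#' 15% of the training data as the wrapper's validation set; population
#' and dispersal defaults are the canonical small-population settings.
#'
#' @param n_initial Initial population size.
#' @param n_max_population Population cap after competitive exclusion.
#' @param seeds_min,seeds_max Seed counts for the worst/best candidate.
#' @param sigma_initial,sigma_final Dispersal standard deviations at the
#'   first and last iteration.
#' @param modulation_n Nonlinear modulation exponent of the sigma
#'   schedule.
#' @param n_iterations Number of iterations.
#' @param validation_fraction Fraction of the training set held out as
#'   the wrapper's validation split.
#' @param threshold Binarization threshold in (0, 1).
#' @param rng_seed Integer seed.
#' @return An object of class `iwo_config`.
#' @export
iwo_config <- function(n_initial = 10L, n_max_population = 30L,
                       seeds_min = 0L, seeds_max = 5L,
                       sigma_initial = 0.5, sigma_final = 0.01,
                       modulation_n = 3, n_iterations = 10L,
                       validation_fraction = 0.15, threshold = 0.5,
                       rng_seed = 1L) {
  stopifnot(seeds_min <= seeds_max, sigma_final <= sigma_initial,
            n_iterations >= 1, threshold > 0, threshold < 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(n_initial = as.integer(n_initial),
                 n_max_population = as.integer(n_max_population),
                 seeds_min = as.integer(seeds_min),
                 seeds_max = as.integer(seeds_max),
                 sigma_initial = sigma_initial, sigma_final = sigma_final,
                 modulation_n = modulation_n,
                 n_iterations = as.integer(n_iterations),
                 validation_fraction = validation_fraction,
                 threshold = threshold, rng_seed = as.integer(rng_seed)),
            class = "iwo_config")
}

#' Binary chimp optimization configuration
#'
#' The chimp optimizer divides its population into four role groups
#' (attacker, barrier, chaser, driver -- the hunt's attack, blockade,
#' pursuit and breakthrough roles) whose dynamic coefficient `f` decays
#' from `f_initial` to 0 on four distinct schedules.  Positions are
#' binarized through an S-shaped (logistic) transfer function.  The study
#' ran 100 iterations with 20% of the training data as the wrapper's
#' validation set.
#'
#' @param n_chimps Population size (>= 4, one per role group).
#' @param n_iterations Number of iterations.
#' @param validation_fraction Wrapper validation fraction.
#' @param f_initial Initial value of the dynamic coefficient.
#' @param rng_seed Integer seed.
#' @return An object of class `bchoa_config`.
#' @export
bchoa_config <- function(n_chimps = 12L, n_iterations = 100L,
                         validation_fraction = 0.20, f_initial = 2.5,
                         rng_seed = 1L) {
  stopifnot(n_chimps >= 4, n_iterations >= 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(n_chimps = as.integer(n_chimps),
                 n_iterations = as.integer(n_iterations),
                 validation_fraction = validation_fraction,
                 f_initial = f_initial, rng_seed = as.integer(rng_seed)),
            class = "bchoa_config")
}

#' Classification error rate of a wavelength mask
#'
#' The wrapper fitness: the training set is split (stratified by class)
#' into an inner training part and a validation part, a fixed-
#' hyperparameter RBF SVM is fit on the masked wavelengths of the inner
#' part, and the misclassified fraction on the validation part is
#' returned.  An empty mask is not an error: it scores the worst possible
#' fitness, 1.0.
#'
#' @param mask Binary vector over wavelengths.
#' @param train A [spectra_set()].
#' @param labels Class labels (default: type-by-level).
#' @param validation_fraction Held-out fraction for the inner split.
#' @param split Optional list with `inner` and `val` index vectors; when
#'   the selectors evaluate many candidates they draw this split once so
#'   all fitness values share a validation set.
#' @param cost SVM cost parameter of the wrapper classifier.
#' @return CER in `[0, 1]`.
#' @export
cer_fitness <- function(mask, train, labels = class_labels(train),
                        validation_fraction = 0.15, split = NULL,
                        cost = 10) {
  mask <- as.logical(mask)
  if (!any(mask)) {
    message("empty wavelength mask: assigning worst fitness 1.0")
    return(1.0)
  }
  if (is.null(split)) {
    split <- draw_inner_split(labels, validation_fraction)
  }
  X <- train$reflectance[, mask, drop = FALSE]
  y <- factor(labels)
  fit <- e1071::svm(X[split$inner, , drop = FALSE], y[split$inner],
                    kernel = "radial", cost = cost, scale = TRUE)
  pr <- stats::predict(fit, X[split$val, , drop = FALSE])
  mean(pr != y[split$val])
}

# One stratified inner/validation split, drawn from the current RNG state.
draw_inner_split <- function(labels, validation_fraction) {
  val <- sort(stratified_indices(labels, validation_fraction))
  list(inner = setdiff(seq_along(labels), val), val = val)
}

#' IWO dispersal standard deviation schedule
#'
#' `sigma(t) = ((T - t) / T)^n * (sigma_initial - sigma_final) +
#' sigma_final` with `T = n_iterations` and `n = modulation_n`: the
#' dispersal radius shrinks nonlinearly from global exploration to local
#' refinement.
#'
#' @param iteration Iteration index in `0..n_iterations`.
#' @param config An [iwo_config()].
#' @return Dispersal sd at that iteration.
#' @export
iwo_sigma <- function(iteration, config) {
  T_ <- config$n_iterations
  ((T_ - iteration) / T_)^config$modulation_n *
    (config$sigma_initial - config$sigma_final) + config$sigma_final
}

#' Seeds allocated to a weed given its fitness
#'
#' Linear interpolation between `seeds_max` (best fitness, i.e. lowest
#' CER) and `seeds_min` (worst), floored to an integer.  When all
#' candidates tie, everyone gets `seeds_max`.
#'
#' @param fitness Candidate CER.
#' @param best_fitness,worst_fitness Population extremes (CER: lower is
#'   better, so `best_fitness <= worst_fitness`).
#' @param config An [iwo_config()].
#' @return Integer seed count.
#' @export
iwo_seed_count <- function(fitness, best_fitness, worst_fitness, config) {
  if (worst_fitness == best_fitness) return(config$seeds_max)
  frac <- (worst_fitness - fitness) / (worst_fitness - best_fitness)
  as.integer(floor(config$seeds_min +
                     frac * (config$seeds_max - config$seeds_min)))
}

new_selection_result <- function(position, mask, wavelengths, trajectory,
                                 method) {
  structure(list(method = method,
                 mask = as.integer(mask),
                 selected_wavelengths = wavelengths[as.logical(mask)],
                 cer_trajectory = trajectory,
                 n_selected = sum(mask),
                 position = position),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", x$method, ": ", x$n_selected,
      " wavelengths selected, final CER ",
      format(min(x$cer_trajectory), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Plot the best-so-far CER trajectory of a selection run
#' @param x A `selection_result`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.selection_result <- function(x, ...) {
  graphics::plot(seq_along(x$cer_trajectory) - 1L, x$cer_trajectory,
                 type = "s", xlab = "iteration", ylab = "best CER",
                 main = x$method, ...)
  invisible(x)
}

check_selectable <- function(labels) {
  if (length(unique(labels)) < 2) {
    stop("wavelength selection needs >= 2 classes in the training data")
  }
}

#' Wavelength selection by invasive weed optimization
#'
#' Candidates are continuous positions in `[0,1]^p`, binarized at
#' `config$threshold` and scored by [cer_fitness()].  Each iteration every
#' weed produces seeds in proportion to its fitness rank (best gets
#' `seeds_max`, worst `seeds_min`), each offspring being the parent
#' position plus coordinate-wise Gaussian noise with the shrinking
#' [iwo_sigma()] radius, clipped to `[0,1]`; parents and offspring then
#' compete and only the best `n_max_population` survive.  The best
#' candidate ever evaluated is returned.
#'
#' The wrapper's validation split is drawn once per run, so all fitness
#' comparisons share the same validation set.
#'
#' @param train A [spectra_set()] (preprocessed training data).
#' @param config An [iwo_config()].
#' @param labels Class labels (default: type-by-level).
#' @return A `selection_result`: binary `mask`, `selected_wavelengths`
#'   (nm), best-so-far `cer_trajectory` (one entry per iteration; the
#'   first iteration evaluates the initial population) and `n_selected`.
#' @export
iwo_select <- function(train, config = iwo_config(),
                       labels = class_labels(train)) {
  check_selectable(labels)
  p <- n_wavelengths(train)
  set.seed(config$rng_seed)
  split <- draw_inner_split(labels, config$validation_fraction)
  evaluate <- function(pos) {
    cer_fitness(pos > config$threshold, train, labels,
                split = split)
  }
  # iteration 1 evaluates the initial population; reproduction starts at
  # iteration 2, dispersing with sigma(t - 2) so the first reproduction
  # uses sigma_initial
  pos <- matrix(stats::runif(config$n_initial * p), config$n_initial, p)
  fit <- apply(pos, 1, evaluate)
  best_i <- which.min(fit)
  best <- list(position = pos[best_i, ], fitness = fit[best_i])
  trajectory <- best$fitness
  for (t in seq_len(config$n_iterations)[-1]) {
    sigma <- iwo_sigma(t - 2L, config)
    o_best <- min(fit); o_worst <- max(fit)
    children <- list()
    for (i in seq_len(nrow(pos))) {
      n_seeds <- iwo_seed_count(fit[i], o_best, o_worst, config)
      for (s in seq_len(n_seeds)) {
        child <- pos[i, ] + stats::rnorm(p, 0, sigma)
        children[[length(children) + 1L]] <- pmin(pmax(child, 0), 1)
      }
    }
    if (length(children)) {
      cpos <- do.call(rbind, children)
      cfit <- apply(cpos, 1, evaluate)
      pos <- rbind(pos, cpos)
      fit <- c(fit, cfit)
    }
    if (nrow(pos) > config$n_max_population) {
      keep <- order(fit)[seq_len(config$n_max_population)]
      pos <- pos[keep, , drop = FALSE]
      fit <- fit[keep]
    }
    if (min(fit) < best$fitness) {
      i <- which.min(fit)
      best <- list(position = pos[i, ], fitness = fit[i])
    }
    trajectory <- c(trajectory, best$fitness)
  }
  mask <- as.integer(best$position > config$threshold)
  new_selection_result(best$position, mask, train$wavelengths,
                       trajectory, "IWO")
}

#' S-shaped transfer function
#'
#' Logistic map from the centered continuous update term to a selection
#' probability: `1 / (1 + exp(-x))`, so 0 maps to probability 0.5 and
#' large positive/negative updates saturate at 1/0.
#'
#' @param x Centered update term (any real value).
#' @return Selection probability in (0, 1).
#' @export
bchoa_transfer <- function(x) {
  1 / (1 + exp(-x))
}

# Dynamic coefficient schedules, one per role group, all decaying
# f_initial -> 0 over the run on distinct curves.
bchoa_f <- function(t, n_iterations, f_initial) {
  u <- t / n_iterations
  f_initial * c(attacker = 1 - u,
                barrier  = (1 - u)^2,
                chaser   = sqrt(1 - u),
                driver   = (1 - u)^3)
}

#' Wavelength selection by binary chimp optimization
#'
#' Binary candidate masks are scored by [cer_fitness()].  The four best
#' candidates take the attacker, barrier, chaser and driver roles; every
#' chimp's continuous update is the average of the four role-driven terms
#' `X_role - a * |c * X_role - m * X_i|` with `a = 2 f r1 - f`,
#' `c = 2 r2`, the chaotic factor `m` a uniform draw, and the role-wise
#' dynamic coefficient `f` decaying from `config$f_initial` to 0 on four
#' distinct schedules.  The update is centered and passed through the
#' S-shaped [bchoa_transfer()]; each coordinate becomes 1 when a uniform
#' draw falls below the transfer probability.  The best mask ever
#' evaluated is returned.
#'
#' @param train A [spectra_set()] (preprocessed training data).
#' @param config A [bchoa_config()].
#' @param labels Class labels (default: type-by-level).
#' @return A `selection_result`, as for [iwo_select()].
#' @export
bchoa_select <- function(train, config = bchoa_config(),
                         labels = class_labels(train)) {
  check_selectable(labels)
  p <- n_wavelengths(train)
  set.seed(config$rng_seed)
  split <- draw_inner_split(labels, config$validation_fraction)
  evaluate <- function(mask) {
    cer_fitness(mask, train, labels, split = split)
  }
  # iteration 1 evaluates the initial random masks; position updates start
  # at iteration 2, with the role-wise f schedule starting at f_initial
  pos <- matrix(as.integer(stats::runif(config$n_chimps * p) > 0.5),
                config$n_chimps, p)
  fit <- apply(pos, 1, evaluate)
  i <- which.min(fit)
  best <- list(mask = pos[i, ], fitness = fit[i])
  trajectory <- best$fitness
  for (t in seq_len(config$n_iterations)[-1]) {
    f_role <- bchoa_f(t - 2L, config$n_iterations, config$f_initial)
    leaders <- pos[order(fit)[1:4], , drop = FALSE]  # attacker..driver
    new_pos <- pos
    for (i in seq_len(config$n_chimps)) {
      upd <- numeric(p)
      for (g in 1:4) {
        f <- f_role[g]
        r1 <- stats::runif(p); r2 <- stats::runif(p)
        m <- stats::runif(p)  # chaotic factor stand-in
        a <- 2 * f * r1 - f
        cc <- 2 * r2
        d <- abs(cc * leaders[g, ] - m * pos[i, ])
        upd <- upd + (leaders[g, ] - a * d)
      }
      upd <- upd / 4
      prob <- bchoa_transfer(upd - 0.5)
      new_pos[i, ] <- as.integer(stats::runif(p) < prob)
    }
    pos <- new_pos
    fit <- apply(pos, 1, evaluate)
    if (min(fit) < best$fitness) {
      i <- which.min(fit)
      best <- list(mask = pos[i, ], fitness = fit[i])
    }
    trajectory <- c(trajectory, best$fitness)
  }
  new_selection_result(as.numeric(best$mask), best$mask,
                       train$wavelengths, trajectory, "BChOA")
}
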