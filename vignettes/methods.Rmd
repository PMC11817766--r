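---
title: "Methods: synthetic NIR mixtures, preprocessing and wrapper wavelength selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic NIR mixtures, preprocessing and wrapper wavelength selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nircoffee)
```

# The detection problem

Ground roasted coffee is routinely adulterated with cheaper roasted and
ground materials — soybean, barley, chicory, corn — that are visually
indistinguishable from coffee powder after sieving. Portable near-infrared
(NIR) reflectance spectroscopy separates the materials chemically: C-H,
O-H and N-H bond overtones absorb at material-specific wavelengths in the
900–1700 nm window, so coffee (rich in caffeine, chlorogenic acid and
oils, a strong NIR absorber) reflects differently from the
carbohydrate-dominated adulterants.

The package implements the full detection workflow on this premise:

1. **qualitative detection** — which adulterant is present (4 classes);
2. **qualitative + quantitative detection** — which adulterant *and* at
   which mass fraction, 10/20/30/40% (4 × 4 = 16 classes).

Spectra are classified with a grid-searched RBF support vector machine
(SVM), after preprocessing, optionally on a subset of wavelengths chosen
by one of two wrapper metaheuristics.

# Synthetic spectra generator

No public spectra exist for this exact design, so the package ships a
generator that reproduces its statistical structure: 16 groups of 50
samples (800 total) plus 100 blanks, on a 228-point uniform grid from
900 to 1700 nm.

**Endmembers.** Each pure material is a linear continuum minus Gaussian
absorption bands. Band centres sit at the wavelengths where the five
materials' mean curves differ most (920, 945, 1070, 1210, 1257, 1462,
1660, 1686 nm), and every material carries a broad O-H water band in the
1400–1650 nm region. Only the *centres* are anchored in published
observations; depths and widths are package choices set so coffee is the
strongest absorber and each adulterant has at least one band displaced
from every coffee band by more than two grid steps (a library invariant,
checked at construction).

**Mixing.** Adulteration at mass fraction $f$ mixes endmember reflectance
in absorbance space:
$$R_{mix} = 10^{-\left[(1-f)\,A_{coffee} + f\,A_{adulterant}\right]},
\qquad A = -\log_{10} R,$$
i.e. Beer–Lambert-like additivity of the absorbing constituents. Mixing
in absorbance rather than raw reflectance keeps the quantity linear in
composition, which is what both the band logic and the preprocessing
reason about. At a coffee-specific band the mean absorbance therefore
falls monotonically as the adulterant fraction rises — a tested
invariant.

**Measurement effects.** Each clean mixture is corrupted with exactly the
artifacts the preprocessing chain is designed to remove:
$$x(\lambda) = s\,r(\lambda) + o + b(\lambda) + \varepsilon(\lambda),$$
with multiplicative scatter $s \sim 1 + N(0, 0.05)$, offset
$o \sim N(0, 0.02)$, a random quadratic baseline $b$ with amplitude at
most 0.02 (order 2 is the mildest drift MSC/SNV are expected to
correct), and i.i.d. noise $\varepsilon \sim N(0, 0.005)$ (reflectance
units, ~1% of signal — plausible repeatability for a portable instrument
after scan averaging). Output is clipped below at $10^{-4}$ so
reflectance stays positive.

**Within-group variability.** The study design says nothing about how
much replicate samples of a group vary, yet some variation must exist
(no two 10 g scoops of a powder mix are identical). Two placeholder
knobs provide it: per-sample jitter on the nominal fraction
($\sigma = 0.015$ absolute) and a per-sample multiplicative factor on
band depths ($\sigma = 0.04$). Both were fixed once on these plausibility
grounds; they are not calibrated to any measurement.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: instrument line-shape and wavelength-
registration error, detector nonlinearity, temperature drifts,
wavelength-correlated noise, and, importantly, any *localized sparse*
discriminative structure (see "A negative result" below). All stochastic
draws flow from one `rng_seed`; identical seeds give byte-identical
datasets, which the determinism tests assert.

A second generator, `generate_planted_dataset()`, builds a benchmark
where ground truth is known by construction: 10 of 228 channels carry
class-specific mean offsets ($\sigma = 0.10$) over a flat noisy
background ($\sigma = 0.03$); it exists to measure selector recall.

# Preprocessing

Five transforms (and the identity) are available, chained left to right:

* **SG** — Savitzky–Golay smoothing: each point replaced by the centre
  value of a least-squares polynomial fit over a sliding window. Window
  11 points, order 2 by default — a common chemometrics choice for a
  ~3.5 nm step; both are exposed in `preprocess_spec()`. Edges refit the
  polynomial on the truncated window rather than padding, so the filter
  reproduces polynomials up to the fit order exactly everywhere (tested
  against an independent per-window `lm` oracle, edges included).
* **SNV** — per-spectrum standardization to mean 0, sd 1 (sample sd,
  $n-1$ denominator). A zero-variance spectrum is an error, not silent
  zeros.
* **MSC** — each spectrum regressed on a reference by OLS,
  $x \approx a + b\,\mathrm{ref}$, then corrected as $(x - a)/b$. The
  reference is the *training-set* mean spectrum (computed after any
  preceding step) and reused unchanged on the test set — no test
  information reaches the training transform. $|b| < 10^{-12}$ is an
  error naming the offending row.
* **SG-MSC**, **SG-SNV** — the chains used in the comparison tables.

# Wrapper wavelength selection

Both selectors optimize the same fitness: the **classification error
rate (CER)** of an RBF SVM trained on the masked wavelengths of an inner
training split and evaluated on an inner validation split (stratified;
15% for IWO, 20% for BChOA). The inner split is drawn once per run so
every candidate is scored against the same validation set (less fitness
noise between candidates). The wrapper SVM uses fixed hyperparameters
(C = 10, gamma = 1/p) for tractability; the final model on the returned
mask is the fully grid-searched SVM. An empty mask is assigned the worst
fitness 1.0 rather than repaired, leaving the search space untouched.

**Invasive weed optimization (IWO)**, canonical Mehrabian–Lucas form:
candidates are continuous positions in $[0,1]^{228}$, binarized at 0.5.
Each iteration, every weed produces 0–5 seeds by linear interpolation
between the population's best and worst CER (floored; all get the
maximum on a tie), each offspring dispersing by coordinate-wise Gaussian
noise whose sd shrinks as
$$\sigma_t = \left(\frac{T-t}{T}\right)^{3}(\sigma_0 - \sigma_T) +
\sigma_T, \quad \sigma_0 = 0.5,\ \sigma_T = 0.01,$$
followed by competitive exclusion to the 30 best. Defaults: 10 initial
weeds, 10 iterations. The first iteration evaluates the initial
population; reproduction starts at the second, so a one-iteration run
returns the best initial candidate.

**Binary chimp optimization (BChOA)**: binary masks updated by the four
best candidates in the attacker/barrier/chaser/driver roles (the hunt's
attack, blockade, pursuit and breakthrough). Each role's dynamic
coefficient $f$ decays from 2.5 to 0 on its own curve (linear,
quadratic, square-root, cubic — the published description names four
groups but no schedules, so these are package choices), the chaotic
factor is replaced by a uniform draw, and the averaged continuous update
is centered and passed through the S-shaped logistic transfer
$1/(1+e^{-x})$; a coordinate becomes 1 when a uniform draw falls below
that probability. Defaults: 12 chimps, 100 iterations.

Both selectors track the best candidate ever evaluated; the reported CER
trajectory is best-so-far per iteration and is non-increasing by
construction (tested). Identical seeds give identical `selection_result`
objects.

# Modeling and evaluation

The 8:2 train/prediction split is stratified by the task's classes
(800 → 640/160 in the full design; unstratified splits floor toward the
training set). The SVM grid is C ∈ {1, 10, 100, 1000} ×
gamma ∈ {0.001, 0.01, 0.1, 1}, scored by 5-fold cross-validated accuracy
(folds stratified and seeded; ties broken by grid order) and refit on the
whole training set. The kernel is not stated in the source material for
this design; RBF is assumed, as standard with a gamma grid. Features are
standardized with training-set statistics before SVM and BP (kernels and
gradients are scale-sensitive), not before RF. The BP baseline is a
single 64-unit hidden layer trained with L2 weight decay ($10^{-3}$) and
an iteration cap; the RF baseline uses 500 trees. Both are baselines,
not the analysis's selected model.

Evaluation reduces the K×K confusion matrix one-vs-rest per class:
$TP_k = C_{kk}$, $FP_k$, $FN_k$ the off-diagonal column/row sums,
$TN_k$ the remainder; accuracy $= 100\,\mathrm{tr}(C)/n$, and precision
$TP/(TP+FP)$ and specificity $TN/(TN+FP)$ are **macro** (unweighted)
means over classes — the averaging rule is not stated where these
metrics are reported as single numbers, and macro is the natural choice
for balanced designs. A class never predicted is excluded from the
precision mean with a message. Percentages are reported to 2 decimals
with half-up rounding. Accuracy improvement of a selected model over the
full spectrum is reported **relative** ($100(a_{sel}-a_{full})/a_{full}$)
rather than absolute, because the relative form reproduces the published
comparison arithmetic exactly; the absolute difference is also returned.

# Problem sizes

The analysis scripts and acceptance checks use three scales, chosen as
the package's replicate-study sizes:

* design-count checks and the single-run comparison tables: the full
  800-sample design (`n_per_group = 50`);
* the 5-seed selector replicate studies: `n_per_group = 20`
  (320 samples), so five full wrapper runs plus grid-searched SVMs
  complete in minutes on one core;
* the planted-wavelength benchmark: 5 classes × 40 samples.

# A negative result worth knowing

On the planted benchmark the wrappers do what wrappers should: IWO
recovers ≥ 70% and BChOA ≥ 60% of the planted channels in most seeds,
and label-shuffled data drops recall to the size-implied chance level
(a tested sanity check against selection bias in the benchmark itself).

On the *adulteration* generator, however, selection does **not**
reliably beat the full spectrum: across seeds the selected-wavelength
SVM ties or trails it by a few points. The reason is structural, not a
search failure — after SG-MSC the 16-class level signal is spread
smoothly over the whole collinear grid, so even an oracle mask covering
every configured band only ties the full spectrum; there is little
channel-specific noise for selection to remove. Real spectra evidently
concentrate discriminative information more sparsely than this
generator's smooth Gaussian bands do. The corresponding acceptance
check is asserted as specified and documents this limitation when it
fails; treat the generator's selection experiments as a test of the
machinery, not as evidence about real-data benefit.

# Known limitations

* Endmember band shapes are Gaussian with invented depths/widths;
  nothing is calibrated to measured curves.
* Within-group variability is a placeholder (see above).
* The wrapper's inner CER is coarse on small validation sets
  (granularity 1/n-validation), which flattens the fitness landscape at
  small problem sizes.
* `nnet` provides no validation-based early stopping; the BP baseline
  regularizes with weight decay instead.
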