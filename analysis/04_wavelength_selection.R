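#!/usr/bin/env Rscript
# Wrapper wavelength selection on the 16-class task: IWO and BChOA with
# CER fitness on SG-MSC preprocessed training data, compared against the
# full spectrum (dimensionality reduction, relative accuracy change).
#
# Runs at the replicate-study scale (20 samples per group) so the whole
# script finishes in a few minutes on one core.

library(nircoffee)

seed <- 20260924
dir.create("results", showWarnings = FALSE)

gen <- generator_config(n_per_group = 20, rng_seed = seed)
data <- generate_dataset(gen)

cfg <- pipeline_config(generator = gen, task = "quantitative16",
                       preprocess = preprocess_spec("SG-MSC"),
                       output_dir = "results/selection", rng_seed = seed)
tab <- compare_selectors(cfg, data = data)
print(tab)

for (sel in c("IWO", "BChOA")) {
  row <- tab[tab$selector == sel, ]
  cat(sprintf(
    "%s: %d wavelengths kept (%.2f%% reduction), accuracy %+0.2f%% relative to full spectrum\n",
    sel, row$n_wavelengths, row$reduction_pct,
    row$accuracy_improvement_pct))
}
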