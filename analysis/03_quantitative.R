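#!/usr/bin/env Rscript
# Qualitative + quantitative detection: adulterant type AND level
# (16 classes).  Compares SVM, BP and RF across the six preprocessing
# variants on a shared 8:2 split.

library(nircoffee)

seed <- 20260924
dir.create("results", showWarnings = FALSE)

gen <- generator_config(n_per_group = 50, rng_seed = seed)
data <- if (file.exists("results/data/adulterated_800.csv")) {
  read_spectra("results/data/adulterated_800.csv")
} else {
  generate_dataset(gen)
}

cfg <- pipeline_config(generator = gen, task = "quantitative16",
                       selector = "none",
                       output_dir = "results/quantitative",
                       rng_seed = seed)
tab <- compare_preprocessing(cfg, data = data,
                             models = c("SVM", "BP", "RF"))
print(tab)

best <- tab[which.max(tab$prediction_accuracy), ]
cat(sprintf("\nbest combination: %s + %s (prediction accuracy %.2f%%)\n",
            best$preprocessing, best$model, best$prediction_accuracy))
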