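#!/usr/bin/env Rscript
# Qualitative detection: which adulterant is present? (4 classes)
# Compares the six preprocessing variants with the grid-searched SVM on
# a shared 8:2 split and writes the comparison table.

library(nircoffee)

seed <- 20260924
dir.create("results", showWarnings = FALSE)

gen <- generator_config(n_per_group = 50, rng_seed = seed)
data <- if (file.exists("results/data/adulterated_800.csv")) {
  read_spectra("results/data/adulterated_800.csv")
} else {
  generate_dataset(gen)
}

cfg <- pipeline_config(generator = gen, task = "qualitative4",
                       selector = "none", output_dir = "results/qualitative",
                       rng_seed = seed)
tab <- compare_preprocessing(cfg, data = data)
print(tab)

best <- tab[which.max(tab$prediction_accuracy), ]
cat(sprintf("\nbest preprocessing: %s (prediction accuracy %.2f%%)\n",
            best$preprocessing, best$prediction_accuracy))

# full artifact dump for the best method
cfg$preprocess <- preprocess_spec(best$preprocessing)
res <- run_experiment(cfg, data = data)
print(res$report_prediction)
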