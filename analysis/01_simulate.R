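#!/usr/bin/env Rscript
# Generate the synthetic study datasets and write them (plus the mean
# spectra of the five pure materials) under results/data/.
#
# Emulated design: 4 adulterants (soybean, barley, chicory, corn) x 4
# adulteration levels (10-40%) x 50 samples = 800 adulterated samples,
# plus 100 blanks (20 per material), on the 228-point 900-1700 nm grid.

library(nircoffee)

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(n_per_group = 50, rng_seed = 20260924)
adulterated <- generate_dataset(cfg)
blanks <- generate_materials_dataset(cfg, n_per_material = 20)

write_spectra(adulterated, file.path(out_dir, "adulterated_800.csv"))
write_spectra(blanks, file.path(out_dir, "blanks_100.csv"))

cat("adulterated:", n_samples(adulterated), "samples,",
    length(unique(class_labels(adulterated))), "classes\n")
cat("blanks:", n_samples(blanks), "samples,",
    length(unique(blanks$adulterant)), "materials\n")

# mean endmember curves, for eyeballing the material ordering
wl <- default_wavelengths()
mats <- c("coffee", "soybean", "barley", "chicory", "corn")
curves <- sapply(mats, endmember_spectrum, wavelengths = wl)
utils::write.csv(
  data.frame(wavelength_nm = sprintf("%.3f", wl), round(curves, 6)),
  file.path(out_dir, "endmember_means.csv"), row.names = FALSE,
  quote = FALSE)
cat("wrote", file.path(out_dir, "endmember_means.csv"), "\n")
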