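#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# 120 passion fruits over six storage batches: NIR diffuse-reflectance
# spectra (10,000-4000 cm-1), six puncture curves per fruit, and the planted
# F1/F2 epicarp hardness. Everything downstream re-derives from the same
# master seed, so deleting results/ and re-running reproduces every file.

suppressMessages(library(epinir))
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_config(seed = 42)
dataset <- generate_spectra(cfg, curves = TRUE)

message(sprintf(
  "simulated %d fruits x %d wavenumbers across %d batches",
  cfg$n_samples, length(dataset$spectra$wavenumbers), cfg$n_batches
))

write_hardness(dataset$hardness, "results/hardness_planted.csv")
# working spectra at 4 cm-1 spacing (the acquisition resolution)
write_spectra(decimate_spectra(dataset$spectra, 4), "results/spectra.csv")
# a handful of example puncture curves for inspection
write_puncture_curves(dataset$curves[1:3], "results/example_curves")

message("wrote results/spectra.csv, results/hardness_planted.csv, results/example_curves/")
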