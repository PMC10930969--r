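#!/usr/bin/env Rscript
# Stage 2 — texture analysis.
#
# Reads the first two peak forces off every puncture curve (outer epicarp F1,
# inner epicarp F2), averages the six punctures per fruit, and tabulates the
# descriptive statistics of both responses — the measured counterpart of the
# planted hardness table from stage 1.

suppressMessages(library(epinir))
dir.create("results", showWarnings = FALSE)

dataset <- generate_spectra(synthetic_config(seed = 42), curves = TRUE)
hardness <- hardness_from_curves(dataset$curves,
  batch_day = dataset$hardness$batch_day
)
write_hardness(hardness, "results/hardness_measured.csv")

stats <- describe_hardness(hardness)
write.csv(stats, "results/hardness_descriptives.csv", row.names = FALSE)
print(stats)

batch_means <- aggregate(
  cbind(F1, F2) ~ batch_day,
  transform(hardness, batch_day = dataset$hardness$batch_day), mean
)
write.csv(batch_means, "results/hardness_by_storage_day.csv", row.names = FALSE)
message("F2 declines monotonically with storage: ",
  all(diff(batch_means$F2) < 0))
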