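#!/usr/bin/env Rscript
# Stage 5 — model comparison.
#
# Crosses preprocessing (none/MA/MC) x selection (full/CARS/SPA/UVE) x model
# (grid-searched RF, GA-tuned SVR) x response (F1/F2) — 48 fits — and writes
# the ranked comparison table. Problem sizes are scaled for a workstation
# run (751-point grid, compact RF grid, short GA); expect ~10 minutes.

suppressMessages(library(epinir))

cfg <- run_config(
  synthetic = synthetic_config(seed = 42),
  decimate = 8L, # 751-point working grid
  seed = 42,
  output_dir = "results/experiment",
  rf = list(ntree_grid = c(100, 300)),
  ga = list(population_size = 15, n_generations = 12)
)
res <- run_experiment(cfg)

message(sprintf(
  "\n%d evaluations, %d failures; best rows:",
  length(res$reports), length(res$failures)
))
print(res$comparison[res$comparison$best, c(
  "response", "model", "preprocessing", "selection",
  "R2_C", "RMSE_C", "R2_P", "RMSE_P", "RPD"
)])
message("full table: results/experiment/comparison.csv")
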