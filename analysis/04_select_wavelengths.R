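#!/usr/bin/env Rscript
# Stage 4 — feature-wavelength selection.
#
# Runs CARS, SPA and UVE on the mean-centred calibration spectra of each
# response and summarises subset sizes and how many of the planted
# water/cellulose/pectin absorption bands each subset hits (a band counts as
# hit when a selected wavenumber lies within 50 cm-1 of its centre).

suppressMessages(library(epinir))
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_config(seed = 42)
dataset <- generate_spectra(cfg, curves = TRUE)
hardness <- hardness_from_curves(dataset$curves,
  batch_day = dataset$hardness$batch_day
)
spectra <- decimate_spectra(dataset$spectra, 4)
water <- c(8403, 6896, 5154)

rows <- list()
for (resp in c("F1", "F2")) {
  y <- hardness[[resp]]
  names(y) <- hardness$sample_id
  split <- spxy_split(spectra, y, 0.75)
  state <- preprocess_fit("MC", spectra[split$calibration_ids, ])
  Xc <- preprocess_apply(state, spectra[split$calibration_ids, ])$absorbance
  yc <- y[split$calibration_ids]

  sels <- list(
    CARS = cars_select(Xc, yc,
      seed = derive_seed(42, paste0("cars/", resp)),
      wavenumbers = spectra$wavenumbers
    ),
    SPA = spa_select(Xc, yc, wavenumbers = spectra$wavenumbers),
    UVE = suppressWarnings(uve_select(Xc, yc,
      seed = derive_seed(42, paste0("uve/", resp)),
      wavenumbers = spectra$wavenumbers
    ))
  )
  for (m in names(sels)) {
    write_selection(sels[[m]], sprintf("results/selection_%s_%s.json", m, resp))
    rows[[paste(resp, m)]] <- data.frame(
      response = resp, method = m,
      n_selected = length(sels[[m]]$selected),
      water_bands_hit = band_coverage(sels[[m]]$wavenumbers, water),
      all_bands_hit = band_coverage(sels[[m]]$wavenumbers, cfg$band_centers)
    )
  }
}
tab <- do.call(rbind, rows)
rownames(tab) <- NULL
write.csv(tab, "results/selection_summary.csv", row.names = FALSE)
print(tab)
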