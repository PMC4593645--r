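## Presence-only habitat suitability model on the ARS locations: build the
## predictor stack (SST, CHL, BAT, their window gradients, wind, distance to
## colony), balance presences per bird, fit the maximum-entropy model, and
## evaluate it with 50 replicate 70/30 splits.

source("analysis/00_config.R")

locs <- read.csv(file.path(RESULTS, "ars_locations.csv"))
locs <- locs[locs$individual_id != "bird_nested", ]

## study-extent 0.12-degree grid covering all ARS locations
pad <- 0.4
grid <- list(
  lon = seq(min(locs$lon) - pad, max(locs$lon) + pad, by = 0.12),
  lat = seq(min(locs$lat) - pad, max(locs$lat) + pad, by = 0.12))
rasters <- local({
  sst <- simulate_raster(grid, "front",
                         list(angle_deg = 90, width_deg = 0.6, low = 17,
                              high = 25, noise_sd = 0.2),
                         seed = SEED + 1, name = "SST")
  chl <- simulate_raster(grid, "front",
                         list(angle_deg = 270, width_deg = 0.8, low = 0.2,
                              high = 2, noise_sd = 0.05),
                         seed = SEED + 2, name = "CHL")
  bat <- simulate_raster(grid, "seamount",
                         list(base = 4000, height = -3500, radius_deg = 0.6,
                              noise_sd = 50),
                         seed = SEED + 3, name = "BAT")
  wspd <- simulate_raster(grid, "front",
                          list(angle_deg = 45, width_deg = 1.5, low = 4,
                               high = 8, noise_sd = 0.3),
                          seed = SEED + 4, name = "WSPD")
  list(SST = sst, CHL = chl, BAT = bat,
       SSTG = window_gradient(sst), CHLG = window_gradient(chl),
       BATG = window_gradient(bat), WSPD = wspd,
       DCOL = distance_to_colony(grid, COLONY))
})
for (nm in names(rasters))
  write_ascii_grid(rasters[[nm]],
                   file.path(RESULTS, paste0("raster_", nm, ".asc")))

## equal number of ARS locations per bird (bootstrap balancing)
by_bird <- split(locs[, c("lon", "lat")], locs$individual_id)
by_bird <- by_bird[vapply(by_bird, nrow, integer(1)) > 0]
pres <- balanced_subsample(by_bird, seed = SEED + 5)
cat(sprintf("balanced presences: %d birds x %d locations = %d\n",
            length(unique(pres$bird)), nrow(pres) / length(unique(pres$bird)),
            nrow(pres)))

ev <- evaluate_habitat_model(pres[, c("lon", "lat")], rasters,
                             replicates = 50, seed = SEED + 6)
cat(sprintf("mean test AUC over %d replicates: %.3f (%s)\n",
            ev$replicates_used, ev$mean_auc, ev$auc_category))
ctab <- data.frame(variable = names(ev$pct_contribution),
                   pct_contribution = round(as.numeric(ev$pct_contribution), 2),
                   permutation_contribution =
                     round(as.numeric(ev$permutation_contribution), 2))
print(ctab[order(-ctab$pct_contribution), ], row.names = FALSE)
write.csv(ctab, file.path(RESULTS, "habitat_contributions.csv"),
          row.names = FALSE)
write_ascii_grid(ev$mean_prediction,
                 file.path(RESULTS, "suitability_mean.asc"))
write_ascii_grid(ev$cv_prediction, file.path(RESULTS, "suitability_cv.asc"))
jsonlite::write_json(
  list(mean_auc = ev$mean_auc, category = ev$auc_category, auc = ev$auc,
       jackknife = ev$jackknife),
  file.path(RESULTS, "habitat_evaluation.json"),
  auto_unbox = TRUE, digits = NA)
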