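## Kernel utilization distributions on the ARS locations: LSCV bandwidth,
## 50% (core foraging region, FR) and 95% (home range, HR) contours, UD
## overlap between bird groups, and percentage overlap of the FR with a
## synthetic marine-protection layer.

source("analysis/00_config.R")

locs <- read.csv(file.path(RESULTS, "ars_locations.csv"))
locs <- locs[locs$individual_id != "bird_nested", ]
pts <- locs[, c("lon", "lat")]

h <- suppressWarnings(lscv_bandwidth(pts, center = COLONY))
cat(sprintf("LSCV bandwidth: %.2f km over %d ARS locations\n", h, nrow(pts)))

ud <- kernel_ud(pts, h, center = COLONY)
fr <- ud_contour(ud, 0.50)
hr <- ud_contour(ud, 0.95)
cat(sprintf("FR (50%% UD): %.0f km2;  HR (95%% UD): %.0f km2\n",
            fr$area_km2, hr$area_km2))
write_ascii_grid(env_raster("ud", ud$lon, ud$lat, ud$z),
                 file.path(RESULTS, "ud.asc"))
write_geojson_polygons(contour_to_polyset(fr),
                       file.path(RESULTS, "fr_50.geojson"),
                       properties = list(level = 0.5, area_km2 = fr$area_km2))
write_geojson_polygons(contour_to_polyset(hr),
                       file.path(RESULTS, "hr_95.geojson"),
                       properties = list(level = 0.95, area_km2 = hr$area_km2))

## between-phase overlap on the shared grid (one bandwidth reused across
## datasets, mirroring the reference-bandwidth convention) and within-phase
## overlap between the two chick-rearing birds
phase <- bird_phase(locs$individual_id)
grid <- list(lon = ud$lon, lat = ud$lat)
ud_of <- function(sel) kernel_ud(locs[sel, c("lon", "lat")], h, grid, COLONY)
vi_phase <- ud_overlap_vi(ud_of(phase == "incubation"),
                          ud_of(phase == "chick_rearing"))
vi_within <- ud_overlap_vi(ud_of(locs$individual_id == "bird03"),
                           ud_of(locs$individual_id == "bird04"))
cat(sprintf("UD overlap (VI) between phases: %.2f; between chick-rearing birds: %.2f\n",
            vi_phase, vi_within))
write.csv(data.frame(comparison = c("incubation_vs_chick_rearing",
                                    "bird03_vs_bird04"),
                     vi = c(vi_phase, vi_within)),
          file.path(RESULTS, "ud_overlap.csv"), row.names = FALSE)

## synthetic conservation layer: a rectangle over the eastern half of the FR
## extent, standing in for an mIBA polygon
bb_lon <- range(ud$lon[colSums(fr$include) > 0])
bb_lat <- range(ud$lat[rowSums(fr$include) > 0])
layer <- cbind(lon = c(mean(bb_lon), bb_lon[2] + 1, bb_lon[2] + 1,
                       mean(bb_lon), mean(bb_lon)),
               lat = c(bb_lat[1] - 1, bb_lat[1] - 1, bb_lat[2] + 1,
                       bb_lat[2] + 1, bb_lat[1] - 1))
write_geojson_polygons(list(layer),
                       file.path(RESULTS, "synthetic_mpa.geojson"),
                       properties = list(name = "synthetic protection layer"))
pct <- polygon_overlap_pct(fr, list(layer))
cat(sprintf("FR overlap with synthetic protection layer: %.1f%%\n", pct))
write.csv(data.frame(focal = "FR_50", layer = "synthetic_mpa",
                     overlap_pct = pct),
          file.path(RESULTS, "conservation_overlap.csv"), row.names = FALSE)
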