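## Shared settings for the analysis scripts. Everything downstream is a pure
## function of these values.

library(foragescape)

SEED <- 42
COLONY <- c(-24.5877, 16.6113)      # breeding colony, Cape Verde archipelago
RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

## Study design: four birds emulating the two breeding phases.
##  - birds 1-2 ("incubation-like"): one long excursion each to a distant
##    (~540 km) productive patch, 48 h of foraging -> trips > 3 days
##  - birds 3-4 ("chick-rearing-like"): two short excursions each to nearby
##    (~75 km) patches, 12 h of foraging -> trips < 3 days
## Patch centres differ between birds so space use overlaps only partially.
BIRDS <- list(
  bird01 = list(phase = "incubation", n_exc = 1, forage_h = 48,
                patch = list(center_km = c(430, 330), radius_km = 20)),
  bird02 = list(phase = "incubation", n_exc = 1, forage_h = 48,
                patch = list(center_km = c(470, 270), radius_km = 20)),
  bird03 = list(phase = "chick_rearing", n_exc = 2, forage_h = 12,
                patch = list(center_km = c(45, 35), radius_km = 10)),
  bird04 = list(phase = "chick_rearing", n_exc = 2, forage_h = 12,
                patch = list(center_km = c(70, -10), radius_km = 10)))

bird_config <- function(id) {
  b <- BIRDS[[id]]
  traj_config(seed = SEED * 100 + match(id, names(BIRDS)),
              colony = COLONY, n_excursions = b$n_exc,
              forage_time_h = b$forage_h,
              rest_rate_per_h = 0.3, rest_mean_min = 45,
              patches = list(c(b$patch, list(level = "meso",
                                             speed_mult = 0.45,
                                             turn_sd_deg = 80))))
}
bird_phase <- function(ids) {
  vapply(BIRDS[ids], `[[`, character(1), "phase")
}
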