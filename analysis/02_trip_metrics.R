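## Segment the simulated tracks into foraging trips and compute the trip
## metrics (duration, distance, range, flight hours, short/long class).

source("analysis/00_config.R")

trajs <- read_tracks(file.path(RESULTS, "tracks.csv"), COLONY)
trips <- list()
for (tr in trajs) {
  tr <- classify_behaviour(tr)
  trips <- c(trips, suppressMessages(segment_trips(tr)))
}
tab <- trips_table(trips)
write.csv(tab, file.path(RESULTS, "trips.csv"), row.names = FALSE)

fmt <- function(x) sprintf("%.1f +/- %.1f", mean(x), sd(x))
cat(sprintf("%d trips from %d individuals\n", nrow(tab),
            length(unique(tab$individual_id))))
cat("  trip duration (days):      ", fmt(tab$duration_days), "\n")
cat("  total distance (km):       ", fmt(tab$total_distance_km), "\n")
cat("  max distance colony (km):  ", fmt(tab$max_distance_colony_km), "\n")
cat("  flight hours per day (h):  ", fmt(tab$flight_hours_per_day), "\n")
cat(sprintf("  dual strategy: %d short, %d long trips\n",
            sum(tab$duration_class == "short"),
            sum(tab$duration_class == "long")))
cat("wrote", file.path(RESULTS, "trips.csv"), "\n")
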