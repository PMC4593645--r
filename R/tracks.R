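#' Read GPS tracks into per-individual trajectories
#'
#' Parses a delimited track table with columns `individual_id`, `timestamp`
#' (ISO 8601, UTC), `lon`, `lat` and returns one trajectory per individual,
#' time-sorted and validated.
#'
#' @param path CSV file path, or a data frame already holding the columns.
#' @param colony Numeric `c(lon, lat)` of the breeding colony.
#' @return A list of `trajectory` objects (data frames with attributes
#'   `individual_id` and `colony`).
#' @export
read_tracks <- function(path, colony) {
  df <- if (is.data.frame(path)) path else read.csv(path, stringsAsFactors = FALSE)
  needed <- c("individual_id", "timestamp", "lon", "lat")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("track table is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!inherits(df$timestamp, "POSIXct"))
    df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                               tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(df$timestamp)) stop("unparseable timestamp in track table")
  bad <- abs(df$lat) > 90 | abs(df$lon) > 180
  if (any(bad)) stop("coordinates out of range at row(s) ", paste(which(bad), collapse = ", "))
  out <- lapply(split(df, df$individual_id), function(d) {
    d <- d[order(d$timestamp), , drop = FALSE]
    dup <- duplicated(d$timestamp)
    if (any(dup))
      stop("duplicate timestamp for individual ", d$individual_id[1],
           " at row ", which(dup)[1])
    new_trajectory(d[, needed], individual_id = d$individual_id[1], colony = colony)
  })
  unname(out)
}

new_trajectory <- function(df, individual_id, colony) {
  structure(df, class = c("trajectory", "data.frame"),
            individual_id = individual_id, colony = as.numeric(colony))
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> individual", attr(x, "individual_id"), "-", nrow(x), "fixes,",
      format(min(x$timestamp)), "to", format(max(x$timestamp)), "\n")
  invisible(x)
}

#' Classify fixes as flight or rest by speed
#'
#' Each fix is labelled by its incoming speed (distance from the previous fix
#' divided by the elapsed time, assigned to the later fix): `rest` when the
#' speed is strictly below `threshold`, `flight` otherwise. The first fix
#' inherits the label of the second. The 3 km/h default separates birds
#' sitting on the water (drift) from travelling flight.
#'
#' @param traj A `trajectory`.
#' @param threshold Speed threshold in km/h; strict `<` means rest.
#' @return The trajectory with `speed_kmh` and `behaviour` columns.
#' @export
classify_behaviour <- function(traj, threshold = 3) {
  if (nrow(traj) < 2) stop("cannot classify behaviour on a single-fix trajectory")
  p <- cbind(traj$lon, traj$lat)
  d <- great_circle_km(p[-nrow(p), , drop = FALSE], p[-1, , drop = FALSE])
  dt <- as.numeric(diff(traj$timestamp), units = "hours")
  if (any(dt <= 0)) stop("non-increasing timestamps")
  sp <- c(NA, d / dt)
  lab <- ifelse(sp < threshold, "rest", "flight")
  lab[1] <- lab[2]
  sp[1] <- sp[2]
  traj$speed_kmh <- sp
  traj$behaviour <- lab
  traj
}

#' Segment a trajectory into central-place foraging trips
#'
#' A trip is a maximal run of consecutive fixes farther than `buffer_km` from
#' the colony, kept when it lasts at least `min_duration_h` hours and contains
#' at least `min_fixes` fixes. Gaps longer than 60 min inside a trip are
#' reported via `message()` but do not split the trip.
#'
#' @param traj A `trajectory` (behaviour labels optional but carried through).
#' @param buffer_km Colony buffer radius in km.
#' @param min_duration_h Minimum trip duration in hours.
#' @param min_fixes Minimum number of fixes per trip.
#' @return A list of `trip` objects, disjoint and in time order; empty when
#'   the trajectory never leaves the buffer.
#' @export
segment_trips <- function(traj, buffer_km = 2, min_duration_h = 1, min_fixes = 5) {
  colony <- attr(traj, "colony")
  if (is.null(colony)) stop("trajectory has no colony set")
  d <- great_circle_km(cbind(traj$lon, traj$lat), colony)
  away <- d > buffer_km
  if (!any(away)) return(list())
  r <- rle(away)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  trips <- list()
  k <- 0
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    idx <- starts[i]:ends[i]
    dur_h <- as.numeric(difftime(traj$timestamp[idx[length(idx)]],
                                 traj$timestamp[idx[1]], units = "hours"))
    if (dur_h < min_duration_h || length(idx) < min_fixes) next
    gaps <- as.numeric(diff(traj$timestamp[idx]), units = "mins")
    if (any(gaps > 60))
      message("trip for ", attr(traj, "individual_id"), ": ",
              sum(gaps > 60), " gap(s) > 60 min retained")
    k <- k + 1
    tr <- traj[idx, , drop = FALSE]
    rownames(tr) <- NULL
    trips[[k]] <- structure(tr, class = c("trip", "data.frame"),
                            individual_id = attr(traj, "individual_id"),
                            colony = colony, trip_id = k)
  }
  trips
}

#' @export
print.trip <- function(x, ...) {
  cat("<trip>", attr(x, "individual_id"), "#", attr(x, "trip_id"), "-",
      nrow(x), "fixes\n")
  invisible(x)
}

#' Per-trip foraging metrics
#'
#' Duration (days), total distance covered (km, sum of consecutive
#' great-circle legs), maximum distance from the colony (km), flight hours
#' per day, and the short/long duration class (long when duration exceeds
#' 3 days, the dual-foraging-strategy threshold). Time is attributed to a fix
#' as half the gap to each neighbour, so flight hours are unbiased for
#' regular sampling with occasional dropouts.
#'
#' @param trip A `trip` with behaviour labels.
#' @return One-row data frame of metrics.
#' @export
trip_metrics <- function(trip) {
  colony <- attr(trip, "colony")
  n <- nrow(trip)
  p <- cbind(trip$lon, trip$lat)
  legs <- if (n > 1) great_circle_km(p[-n, , drop = FALSE], p[-1, , drop = FALSE]) else 0
  duration_days <- as.numeric(difftime(trip$timestamp[n], trip$timestamp[1],
                                       units = "days"))
  if (duration_days <= 0) stop("trip duration must be positive")
  gaps_h <- as.numeric(diff(trip$timestamp), units = "hours")
  # trapezoidal attribution: each fix owns half of each adjacent gap
  fix_hours <- (c(0, gaps_h) + c(gaps_h, 0)) / 2
  flight_h <- if ("behaviour" %in% names(trip))
    sum(fix_hours[trip$behaviour == "flight"]) else NA_real_
  data.frame(
    individual_id = attr(trip, "individual_id"),
    trip_id = attr(trip, "trip_id"),
    n_fixes = n,
    duration_days = duration_days,
    total_distance_km = sum(legs),
    max_distance_colony_km = max(great_circle_km(p, colony)),
    flight_hours_per_day = flight_h / duration_days,
    duration_class = if (duration_days > 3) "long" else "short",
    stringsAsFactors = FALSE
  )
}

#' Metrics table for a list of trips
#' @param trips List of `trip` objects.
#' @return Data frame, one row per trip.
#' @export
trips_table <- function(trips) {
  do.call(rbind, lapply(trips, trip_metrics))
}
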