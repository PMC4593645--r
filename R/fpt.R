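#' Interpolate a trip to equal along-path spacing for FPT analysis
#'
#' Rest bouts (maximal runs of rest-labelled fixes, i.e. drift on the water)
#' are removed and the flight path reconnected before interpolation, because
#' sub-100-m drift creates spurious small-scale variance in first-passage
#' time. The bridging leg across a removed bout keeps the elapsed time minus
#' the bout's internal duration, so vertex times measure flight time.
#' Vertices are then placed every `step_km` along the rectified path (the
#' last segment may be shorter); vertex times are linearly interpolated
#' within each leg.
#'
#' @param trip A behaviour-labelled `trip`.
#' @param step_km Along-path vertex spacing in km.
#' @return An `fpt_path`: list with `x`, `y` (km, azimuthal-equidistant about
#'   the colony), `lon`, `lat`, `t_h` (flight hours since departure),
#'   `step_km`, `total_km`, `colony`, `t0` (departure timestamp).
#' @export
interpolate_path <- function(trip, step_km) {
  if (!"behaviour" %in% names(trip))
    stop("trip must be behaviour-labelled (see classify_behaviour)")
  colony <- attr(trip, "colony")
  keep <- trip$behaviour == "flight"
  if (sum(keep) < 2) stop("trip has fewer than 2 flight fixes")

  ts <- as.numeric(trip$timestamp)            # seconds
  kept_idx <- which(keep)
  t_adj <- numeric(length(kept_idx))
  for (k in seq_along(kept_idx)[-1]) {
    i_prev <- kept_idx[k - 1]; i_cur <- kept_idx[k]
    dt <- ts[i_cur] - ts[i_prev]
    if (i_cur - i_prev > 1) {                 # a rest bout was removed
      bout <- (i_prev + 1):(i_cur - 1)
      dt <- dt - (ts[bout[length(bout)]] - ts[bout[1]])
    }
    t_adj[k] <- t_adj[k - 1] + dt / 3600
  }

  xy <- aeqd_project(trip$lon[kept_idx], trip$lat[kept_idx], colony)
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= step_km) stop("rectified path shorter than one step")
  # collapse zero-length legs so approx() sees strictly increasing abscissae
  ok <- !duplicated(s)
  s_u <- s[ok]; x_u <- xy[ok, 1]; y_u <- xy[ok, 2]; t_u <- t_adj[ok]

  sv <- seq(0, total, by = step_km)
  if (sv[length(sv)] < total - 1e-9) sv <- c(sv, total)
  px <- approx(s_u, x_u, xout = sv)$y
  py <- approx(s_u, y_u, xout = sv)$y
  pt <- approx(s_u, t_u, xout = sv)$y
  ll <- aeqd_inverse(px, py, colony)
  structure(list(x = px, y = py, lon = ll[, 1], lat = ll[, 2], t_h = pt,
                 step_km = step_km, total_km = total, colony = colony,
                 t0 = trip$timestamp[kept_idx[1]]),
            class = "fpt_path")
}

#' @export
print.fpt_path <- function(x, ...) {
  cat("<fpt_path>", length(x$x), "vertices, step", x$step_km, "km, length",
      round(x$total_km, 1), "km\n")
  invisible(x)
}

#' First-passage time along an interpolated path
#'
#' FPT at a vertex is the time the animal takes to pass through the circle of
#' radius `radius_km` centred there: the backward time to first exit plus the
#' forward time to first exit. Exits are located by exact segment-circle
#' intersection with the crossing time prorated linearly within the segment.
#' Vertices whose circle is never exited before either path end are `NA`.
#'
#' @param path An `fpt_path`.
#' @param radius_km Circle radius in km (> 0).
#' @return Numeric vector of hours, one per vertex, `NA` where undefined.
#' @export
first_passage_time <- function(path, radius_km) {
  stopifnot(inherits(path, "fpt_path"), radius_km > 0)
  .fpt_cpp(path$x, path$y, path$t_h, radius_km)
}

#' Variance of log FPT across radii
#'
#' The log transform makes the variance independent of the magnitude of the
#' mean FPT, so profiles are comparable across radii; the radius maximizing
#' the variance is the candidate area-restricted-search scale.
#'
#' @param path An `fpt_path`.
#' @param radii Vector of radii in km (>= 2 values).
#' @return An `fpt_profile`: list with `radii`, `var_log_fpt`, `n_defined`
#'   and the vertex-by-radius `fpt` matrix (hours).
#' @export
variance_profile <- function(path, radii) {
  stopifnot(length(radii) >= 2)
  fpt <- vapply(radii, function(r) first_passage_time(path, r),
                numeric(length(path$x)))
  v <- apply(fpt, 2, function(col) {
    col <- col[is.finite(col) & col > 0]
    if (length(col) < 2) NA_real_ else var(log(col))
  })
  structure(list(radii = radii, var_log_fpt = v,
                 n_defined = colSums(is.finite(fpt)), fpt = fpt),
            class = "fpt_profile")
}

#' Detect the ARS scale from a variance profile
#'
#' The ARS scale is the radius of the global maximum of `var_log_fpt`,
#' accepted only when it is an interior local maximum; a maximum sitting on
#' the radius-range boundary is rejected (no peak resolved). Ties break
#' toward the smaller radius.
#'
#' @param profile An `fpt_profile` with at least 3 radii.
#' @return The scale in km, or `NA_real_` when no interior peak exists.
#' @export
detect_ars_scale <- function(profile) {
  v <- profile$var_log_fpt
  ok <- which(is.finite(v))
  if (length(ok) < 3) return(NA_real_)
  i <- ok[which.max(v[ok])]          # first max = smaller radius on ties
  if (i == ok[1] || i == ok[length(ok)]) return(NA_real_)
  profile$radii[i]
}

#' Delineate ARS zones at a detected scale
#'
#' Zones are maximal contiguous vertex runs whose FPT at the detected scale
#' exceeds the `q`-quantile of the trip's defined FPT values at that scale.
#' Runs separated by less than `r_star` / (mean flight speed) hours are
#' merged, since the bird has not left the scale's neighbourhood in between.
#'
#' @param path An `fpt_path`.
#' @param r_star Detected ARS scale in km.
#' @param q Threshold quantile of the defined FPT values (default 0.75).
#' @param fpt Optional precomputed FPT vector at `r_star` (saves recomputation).
#' @return Data frame of zones: `scale_km`, `lon`, `lat` (time-weighted
#'   centroid), `max_fpt_h`, `entry_time`, `residence_h`, `dist_colony_km`,
#'   ordered by entry time. Zero rows when no vertex exceeds the threshold.
#' @export
delineate_ars_zones <- function(path, r_star, q = 0.75, fpt = NULL) {
  if (is.null(fpt)) fpt <- first_passage_time(path, r_star)
  def <- is.finite(fpt)
  empty <- data.frame(scale_km = numeric(0), lon = numeric(0), lat = numeric(0),
                      max_fpt_h = numeric(0), entry_time = as.POSIXct(character(0), tz = "UTC"),
                      residence_h = numeric(0), dist_colony_km = numeric(0))
  if (!any(def)) return(empty)
  thr <- quantile(fpt[def], q, names = FALSE)
  # strict threshold with a numeric guard so a homogeneous path (all FPT
  # equal up to rounding) yields no zones
  above <- def & (fpt - thr) > 1e-9 * max(abs(thr), 1)
  if (!any(above)) return(empty)

  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])

  mean_speed <- path$total_km / max(path$t_h[length(path$t_h)], 1e-9)
  merge_gap_h <- r_star / mean_speed
  merged <- list(runs[1, ])
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    last <- merged[[length(merged)]]
    gap <- path$t_h[runs[i, 1]] - path$t_h[last[2]]
    if (gap < merge_gap_h) merged[[length(merged)]] <- c(last[1], runs[i, 2])
    else merged[[length(merged) + 1]] <- runs[i, ]
  }

  zones <- lapply(merged, function(rn) {
    idx <- rn[1]:rn[2]
    t_loc <- path$t_h[idx]
    # time weight per vertex: half the gap to each neighbour within the run
    w <- if (length(idx) > 1)
      (c(0, diff(t_loc)) + c(diff(t_loc), 0)) / 2 else 1
    w <- w / sum(w)
    cx <- sum(w * path$x[idx]); cy <- sum(w * path$y[idx])
    ll <- aeqd_inverse(cx, cy, path$colony)
    data.frame(
      scale_km = r_star, lon = ll[1, 1], lat = ll[1, 2],
      max_fpt_h = max(fpt[idx], na.rm = TRUE),
      entry_time = path$t0 + t_loc[1] * 3600,
      residence_h = max(t_loc[length(t_loc)] - t_loc[1], path$step_km / mean_speed),
      dist_colony_km = great_circle_km(ll[1, , drop = FALSE], path$colony))
  })
  out <- do.call(rbind, zones)
  out[order(out$entry_time), , drop = FALSE]
}

#' Two-stage ARS analysis of a foraging trip
#'
#' Stage 1 (meso scale) interpolates the flight path every 1 km and scans
#' radii 1 to 50 km in 1-km steps; stage 2 (coarse/fine scale) interpolates
#' every 0.1 km and scans 0.1 to 10 km in 0.1-km steps. Each stage detects
#' its own variance peak and delineates zones at that scale.
#'
#' @param trip A behaviour-labelled `trip`.
#' @param q Zone threshold quantile passed to [delineate_ars_zones()].
#' @param meso_step,meso_radii,coarse_step,coarse_radii Stage geometry
#'   (defaults are the standard two-step scheme above).
#' @return List with `meso` and `coarse` elements, each holding `scale_km`,
#'   `zones`, and `profile` (`NULL` profile and empty zones when the stage
#'   cannot resolve, e.g. the path is too short).
#' @export
two_stage_ars <- function(trip, q = 0.75,
                          meso_step = 1, meso_radii = seq(1, 50, by = 1),
                          coarse_step = 0.1, coarse_radii = seq(0.1, 10, by = 0.1)) {
  run_stage <- function(step, radii) {
    res <- list(scale_km = NA_real_,
                zones = delineate_ars_zones_empty(), profile = NULL)
    path <- tryCatch(interpolate_path(trip, step), error = function(e) NULL)
    if (is.null(path)) return(res)
    prof <- variance_profile(path, radii)
    res$profile <- prof
    r_star <- detect_ars_scale(prof)
    res$scale_km <- r_star
    if (is.finite(r_star)) {
      j <- which.min(abs(prof$radii - r_star))
      res$zones <- delineate_ars_zones(path, r_star, q, fpt = prof$fpt[, j])
    }
    res
  }
  list(meso = run_stage(meso_step, meso_radii),
       coarse = run_stage(coarse_step, coarse_radii))
}

delineate_ars_zones_empty <- function() {
  data.frame(scale_km = numeric(0), lon = numeric(0), lat = numeric(0),
             max_fpt_h = numeric(0),
             entry_time = as.POSIXct(character(0), tz = "UTC"),
             residence_h = numeric(0), dist_colony_km = numeric(0))
}
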