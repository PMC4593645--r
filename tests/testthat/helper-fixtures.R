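## Shared fixture builders. Everything is generated in code; no data files.

EQ_KM_PER_DEG <- 6371.0088 * pi / 180   # km per degree of arc on the sphere

## track table for one individual moving along given lon/lat at fixed cadence
make_track_df <- function(lon, lat, start = "2014-03-01 00:00:00",
                          by_min = 5, id = "b1") {
  data.frame(
    individual_id = id,
    timestamp = format(
      as.POSIXct(start, tz = "UTC") + (seq_along(lon) - 1) * by_min * 60,
      "%Y-%m-%dT%H:%M:%SZ"),
    lon = lon, lat = lat, stringsAsFactors = FALSE)
}

## trajectory moving east along the equator at constant speed (km/h)
make_east_traj <- function(speed_kmh, n_fixes, by_min = 5, colony = c(0, 0),
                           lat = 0) {
  step_deg <- speed_kmh * (by_min / 60) / EQ_KM_PER_DEG
  df <- make_track_df(lon = (seq_len(n_fixes) - 1) * step_deg,
                      lat = rep(lat, n_fixes), by_min = by_min)
  read_tracks(df, colony)[[1]]
}

## hand-built interpolated path in the km plane (bypasses trip machinery);
## speeds in km/h, vertices every step_km along a straight east line
make_straight_path <- function(length_km, step_km, speed_kmh,
                               colony = c(0, 0)) {
  x <- seq(0, length_km, by = step_km)
  ll <- foragescape:::aeqd_inverse(x, rep(0, length(x)), colony)
  structure(list(x = x, y = rep(0, length(x)), lon = ll[, 1], lat = ll[, 2],
                 t_h = x / speed_kmh, step_km = step_km,
                 total_km = length_km, colony = colony,
                 t0 = as.POSIXct("2014-03-01 00:00:00", tz = "UTC")),
            class = "fpt_path")
}

## random CRW path object in the km plane for oracle comparisons
make_random_path <- function(n, seed, step_sd = 0.5) {
  set.seed(seed)
  ang <- cumsum(rnorm(n - 1, 0, 0.6))
  sp <- pmax(abs(rnorm(n - 1, 1, step_sd)), 0.05)
  x <- c(0, cumsum(sp * cos(ang)))
  y <- c(0, cumsum(sp * sin(ang)))
  dt <- abs(rnorm(n - 1, 0.1, 0.02)) + 0.01
  structure(list(x = x, y = y, lon = x, lat = y, t_h = c(0, cumsum(dt)),
                 step_km = NA_real_, total_km = sum(sp), colony = c(0, 0),
                 t0 = as.POSIXct("2014-03-01 00:00:00", tz = "UTC")),
            class = "fpt_path")
}

## independent brute-force FPT oracle: walks every step and locates the
## circle crossing by bisection on the segment (no closed-form quadratic)
fpt_oracle <- function(path, r) {
  x <- path$x; y <- path$y; tt <- path$t_h
  n <- length(x)
  one_dir <- function(i0, dir) {
    cx <- x[i0]; cy <- y[i0]
    i <- i0
    repeat {
      j <- i + dir
      if (j < 1 || j > n) return(NA_real_)
      if (sqrt((x[j] - cx)^2 + (y[j] - cy)^2) > r) {
        f <- function(s) {
          px <- x[i] + s * (x[j] - x[i]); py <- y[i] + s * (y[j] - y[i])
          sqrt((px - cx)^2 + (py - cy)^2) - r
        }
        lo <- 0; hi <- 1
        for (k in 1:60) {                     # bisection to ~1e-18
          mid <- (lo + hi) / 2
          if (f(mid) > 0) hi <- mid else lo <- mid
        }
        s <- (lo + hi) / 2
        return(abs(tt[i] + s * (tt[j] - tt[i]) - tt[i0]))
      }
      i <- j
    }
  }
  vapply(seq_len(n), function(i) {
    fwd <- one_dir(i, 1L)
    if (is.na(fwd)) return(NA_real_)
    bwd <- one_dir(i, -1L)
    if (is.na(bwd)) return(NA_real_)
    fwd + bwd
  }, numeric(1))
}

## construct a sample whose *sample* covariance is exactly S (and mean mu)
exact_cov_sample <- function(n, S, mu = c(0, 0), seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(2 * n), ncol = 2)
  z <- sweep(z, 2, colMeans(z))
  z <- z %*% solve(chol(cov(z)))         # whiten to unit sample covariance
  m <- z %*% chol(S)
  data.frame(d13C = m[, 1] + mu[1], d15N = m[, 2] + mu[2])
}

## small aligned raster stack on a given grid for habitat tests
make_test_grid <- function(n = 30, cell = 0.12, lon0 = -26, lat0 = 15) {
  list(lon = lon0 + cell * (seq_len(n) - 0.5),
       lat = lat0 + cell * (seq_len(n) - 0.5))
}
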