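test_that("interpolation spaces vertices and preserves endpoints and times", {
  # straight 1-km leg at 12 km/h: 11 vertices at 0.1 km
  n <- 11
  lon <- (seq_len(n) - 1) * 0.1 / EQ_KM_PER_DEG
  tr <- classify_behaviour(read_tracks(
    make_track_df(lon = lon, lat = rep(0, n), by_min = 0.5),
    c(-0.05, 0))[[1]])
  # bypass trip segmentation: label directly and interpolate a trip-like frame
  trip <- structure(as.data.frame(tr), class = c("trip", "data.frame"),
                    individual_id = "b1", colony = c(-0.05, 0), trip_id = 1L)
  path <- interpolate_path(trip, 0.1)
  expect_equal(length(path$x), 11)
  expect_equal(path$lon[1], lon[1], tolerance = 1e-9)
  expect_equal(path$lon[length(path$lon)], lon[n], tolerance = 1e-9)
  # constant speed: vertex times equally spaced
  expect_equal(diff(path$t_h), rep(diff(path$t_h)[1], 10), tolerance = 1e-9)
})

test_that("rest bouts are removed and their duration excluded", {
  # east at 12 km/h, with a 30-min drift bout in the middle
  step <- 12 * (5 / 60) / EQ_KM_PER_DEG
  drift <- 0.5 * (5 / 60) / EQ_KM_PER_DEG
  lon <- cumsum(c(0, rep(step, 6), rep(drift, 6), rep(step, 6)))
  tr <- read_tracks(make_track_df(lon = lon, lat = rep(0, length(lon))),
                    c(-1, 0))[[1]]
  tr <- classify_behaviour(tr)
  expect_equal(sum(tr$behaviour == "rest"), 6)
  trip <- structure(as.data.frame(tr), class = c("trip", "data.frame"),
                    individual_id = "b1", colony = c(-1, 0), trip_id = 1L)
  path <- interpolate_path(trip, 0.1)
  # flight time: 12 legs at 5 min plus the bridging leg net of the bout's
  # internal duration (30 - 25 min removed)
  expect_lt(max(path$t_h), 12 * 5 / 60 + 10 / 60 + 1e-6)
})

test_that("FPT matches the straight-path closed form", {
  path <- make_straight_path(30, 0.1, 10)
  f <- first_passage_time(path, 5)
  interior <- path$x > 5 & path$x < 25
  expect_true(all(is.finite(f[interior])))
  expect_equal(f[interior], rep(1, sum(interior)), tolerance = 1e-9)
  # vertices within r of either end are undefined
  expect_true(all(is.na(f[path$x < 5 - 1e-9 | path$x > 25 + 1e-9])))
})

test_that("FPT equals the brute-force crossing oracle on random paths", {
  for (s in 1:5) {
    path <- make_random_path(150, seed = s)
    for (r in c(1.5, 4)) {
      got <- first_passage_time(path, r)
      want <- fpt_oracle(path, r)
      expect_equal(is.na(got), is.na(want))
      ok <- !is.na(got)
      expect_equal(got[ok], want[ok], tolerance = 1e-9)
    }
  }
})

test_that("FPT is invariant to path reversal", {
  path <- make_random_path(200, seed = 9)
  rev_path <- path
  rev_path$x <- rev(path$x); rev_path$y <- rev(path$y)
  rev_path$t_h <- max(path$t_h) - rev(path$t_h)
  f1 <- first_passage_time(path, 3)
  f2 <- rev(first_passage_time(rev_path, 3))
  expect_equal(is.na(f1), is.na(f2))
  ok <- !is.na(f1)
  expect_equal(f1[ok], f2[ok], tolerance = 1e-9)
})

test_that("variance profile is ~0 on homogeneous paths and speed-invariant", {
  path <- make_straight_path(40, 0.5, 10)
  prof <- variance_profile(path, c(2, 5, 8))
  expect_true(all(prof$var_log_fpt < 1e-12))

  # rescaling all speeds shifts log FPT by a constant: variance unchanged
  path2 <- make_random_path(300, seed = 3)
  fast <- path2; fast$t_h <- path2$t_h / 3
  p1 <- variance_profile(path2, c(2, 5))
  p2 <- variance_profile(fast, c(2, 5))
  expect_equal(p1$var_log_fpt, p2$var_log_fpt, tolerance = 1e-9)

  # a radius larger than the whole path is flagged missing
  p3 <- variance_profile(path, c(2, 100))
  expect_true(is.na(p3$var_log_fpt[2]))
})

test_that("variance profile equals a direct recomputation", {
  path <- make_random_path(400, seed = 5)
  radii <- c(1, 2, 4, 8)
  prof <- variance_profile(path, radii)
  for (i in seq_along(radii)) {
    f <- fpt_oracle(path, radii[i])
    f <- f[is.finite(f) & f > 0]
    if (length(f) >= 2)
      expect_equal(prof$var_log_fpt[i], var(log(f)), tolerance = 1e-9)
  }
})

test_that("scale detection takes the interior global maximum", {
  mk_prof <- function(radii, v)
    structure(list(radii = radii, var_log_fpt = v), class = "fpt_profile")
  expect_equal(detect_ars_scale(mk_prof(c(10, 20, 30), c(0.1, 0.9, 0.2))), 20)
  # monotone profile: boundary maximum rejected
  expect_true(is.na(detect_ars_scale(mk_prof(1:5, 1:5 / 10))))
  expect_true(is.na(detect_ars_scale(mk_prof(1:5, 5:1 / 10))))
  # ties break toward the smaller radius
  expect_equal(detect_ars_scale(mk_prof(c(3, 5, 7, 9, 11),
                                        c(0.1, 0.8, 0.3, 0.8, 0.1))), 5)
})

test_that("zone delineation finds embedded slow sections in order", {
  # straight geometry with two slow (high residence) sections
  x <- seq(0, 60, by = 0.2)
  speed <- rep(30, length(x))
  speed[x > 15 & x < 20] <- 4
  speed[x > 40 & x < 46] <- 4
  t_h <- c(0, cumsum(0.2 / speed[-1]))
  path <- structure(list(x = x, y = rep(0, length(x)),
                         lon = x / EQ_KM_PER_DEG, lat = rep(0, length(x)),
                         t_h = t_h, step_km = 0.2, total_km = 60,
                         colony = c(0, 0),
                         t0 = as.POSIXct("2014-03-01", tz = "UTC")),
                    class = "fpt_path")
  zones <- delineate_ars_zones(path, r_star = 3)
  expect_equal(nrow(zones), 2)
  expect_true(all(diff(as.numeric(zones$entry_time)) > 0))
  # centroids sit inside the slow sections
  cx <- zones$lon * EQ_KM_PER_DEG
  expect_true(cx[1] > 14 && cx[1] < 21)
  expect_true(cx[2] > 39 && cx[2] < 47)
  expect_true(all(zones$residence_h > 0))
  expect_true(all(zones$max_fpt_h >= 0))

  # homogeneous straight path: no zones
  flat <- make_straight_path(40, 0.2, 20)
  expect_equal(nrow(delineate_ars_zones(flat, 3)), 0)
})

test_that("zone centroid lands inside the true simulated patch", {
  hits <- 0
  for (s in 1:3) {
    cfg <- traj_config(seed = s)
    sim <- simulate_trajectory(cfg)
    tr <- classify_behaviour(sim$trajectory)
    trip <- segment_trips(tr)[[1]]
    path <- interpolate_path(trip, 1)
    prof <- variance_profile(path, 1:50)
    r_star <- detect_ars_scale(prof)
    if (!is.finite(r_star)) next
    zones <- delineate_ars_zones(path, r_star)
    expect_gte(nrow(zones), 1)
    top <- zones[which.max(zones$residence_h), ]
    true_ctr <- foragescape:::aeqd_inverse(
      cfg$patches[[1]]$center_km[1], cfg$patches[[1]]$center_km[2],
      cfg$colony)
    d <- great_circle_km(c(top$lon, top$lat), true_ctr)
    if (d <= cfg$patches[[1]]$radius_km) hits <- hits + 1
  }
  expect_gte(hits, 2)
})

test_that("two-stage analysis uses the standard radii schemes", {
  sim <- simulate_trajectory(traj_config(seed = 4, forage_time_h = 6))
  trip <- segment_trips(classify_behaviour(sim$trajectory))[[1]]
  res <- two_stage_ars(trip)
  expect_length(res$meso$profile$radii, 50)
  expect_length(res$coarse$profile$radii, 100)
  expect_equal(res$meso$profile$radii, seq(1, 50, by = 1))
  expect_equal(res$coarse$profile$radii, seq(0.1, 10, by = 0.1),
               tolerance = 1e-12)
})

test_that("degenerately short trips yield no stage-1 scale", {
  # a 0.8-km rectified excursion cannot support 1-km interpolation
  out <- seq(0, 0.4, by = 0.05) / EQ_KM_PER_DEG
  lon <- c(out, rev(out)[-1])
  tr <- classify_behaviour(read_tracks(
    make_track_df(lon = lon, lat = rep(0, length(lon)), by_min = 0.5),
    c(0, 0))[[1]])
  trips <- segment_trips(tr, buffer_km = 0.1, min_duration_h = 0.05,
                         min_fixes = 3)
  expect_length(trips, 1)
  res <- two_stage_ars(trips[[1]])
  expect_true(is.na(res$meso$scale_km))
  expect_equal(nrow(res$meso$zones), 0)
})
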