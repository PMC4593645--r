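## predictor stack fixtures (one narrow front, one broad thermal ramp)
make_stack <- function(grid, colony, seed = 1, broad_sst = FALSE) {
  rs <- foragescape:::pipeline_rasters(grid, colony, seed)
  if (broad_sst) {
    sst <- simulate_raster(grid, "front",
                           list(angle_deg = 90, width_deg = 1.5, low = 10,
                                high = 26, noise_sd = 0.2),
                           seed = seed + 10, name = "SST")
    rs$SST <- sst
    rs$SSTG <- window_gradient(sst)
  }
  rs
}

test_that("window gradient matches the printed formula and edge contract", {
  cst <- env_raster("X", 1:5, 1:4, matrix(7, 4, 5))
  g <- window_gradient(cst)
  expect_true(all(g$z == 0))

  z <- matrix(5, 3, 3); z[2, 2] <- 10
  r <- env_raster("X", 1:3, 1:3, z)
  expect_equal(window_gradient(r)$z[2, 2], (10 - 5) * 100 / 10)

  # corner cell sees only its 4 in-bounds neighbours
  z2 <- matrix(c(1, 2, 100, 4, 5, 100, 100, 100, 100), 3, 3, byrow = TRUE)
  g2 <- window_gradient(env_raster("X", 1:3, 1:3, z2))
  expect_equal(g2$z[1, 1], (5 - 1) * 100 / 5)

  # division guard: all-zero window leaves the cell missing
  z3 <- matrix(0, 3, 3)
  expect_true(all(is.na(window_gradient(env_raster("X", 1:3, 1:3, z3))$z)))
})

test_that("window gradient equals a brute-force recomputation exactly", {
  set.seed(8)
  for (k in 1:20) {
    z <- matrix(runif(400, 1, 10), 20, 20)
    z[sample(400, 10)] <- NA
    r <- env_raster("X", 1:20, 1:20, z)
    g <- window_gradient(r)$z
    want <- matrix(NA_real_, 20, 20)
    for (i in 1:20) for (j in 1:20) {
      nb <- z[max(1, i - 1):min(20, i + 1), max(1, j - 1):min(20, j + 1)]
      nb <- nb[!is.na(nb)]
      if (length(nb) && max(nb) != 0)
        want[i, j] <- (max(nb) - min(nb)) * 100 / max(nb)
    }
    expect_identical(g, want)
  }
})

test_that("distance-to-colony raster is exact and symmetric", {
  grid <- list(lon = seq(-2, 2, by = 0.5), lat = seq(-1, 1, by = 0.5))
  d <- distance_to_colony(grid, colony = c(0, 0))
  i0 <- which(d$lat == 0); j0 <- which(d$lon == 0)
  expect_equal(d$z[i0, j0], 0)
  j1 <- which(d$lon == 1)
  expect_equal(d$z[i0, j1], 6371.0088 * pi / 180, tolerance = 1e-10)
  # east/west symmetry at equal offsets
  expect_equal(d$z[, which(d$lon == 1)], d$z[, which(d$lon == -1)])
})

test_that("balanced subsampling equalizes birds deterministically", {
  zones <- list(
    a = data.frame(lon = runif(5), lat = runif(5)),
    b = data.frame(lon = runif(8), lat = runif(8)),
    c = data.frame(lon = runif(12), lat = runif(12)))
  s1 <- balanced_subsample(zones, seed = 7)
  expect_equal(nrow(s1), 15)
  expect_equal(as.integer(table(s1$bird)), rep(5L, 3))
  expect_identical(balanced_subsample(zones, seed = 7), s1)
  diffs <- vapply(1:10, function(s)
    !identical(balanced_subsample(zones, seed = s), s1), logical(1))
  expect_true(any(diffs))
  expect_error(balanced_subsample(list()), "no birds")
  expect_error(balanced_subsample(list(a = zones$a[0, ])), "at least one")
})

test_that("uniform presences give a near-flat model", {
  grid <- make_test_grid(30)
  colony <- c(grid$lon[1], grid$lat[1])
  rs <- make_stack(grid, colony, seed = 2)
  flat <- env_raster("u", grid$lon, grid$lat,
                     matrix(1, length(grid$lat), length(grid$lon)))
  acc <- 0
  for (s in 1:5) {
    pres <- simulate_presences(flat, 120, seed = s)$points
    m <- fit_maxent(pres[, c("lon", "lat")], rs)
    pred <- predict(m, rs)
    expect_true(all(pred$z > 0 & pred$z < 1, na.rm = TRUE))
    # per-seed the surface is flat on average; sampling noise can push a few
    # cells slightly further out
    expect_lt(mean(abs(pred$z - 0.5), na.rm = TRUE), 0.05)
    acc <- acc + pred$z
  }
  # averaged over the 5 null simulations the surface is 0.5 within 0.1
  expect_lt(max(abs(acc / 5 - 0.5), na.rm = TRUE), 0.1)
})

test_that("a thermal-driver model recovers the driver", {
  grid <- make_test_grid(30)
  colony <- c(grid$lon[1], grid$lat[1])
  rs <- make_stack(grid, colony, seed = 3)
  sst <- rs$SST
  x <- (sst$z - min(sst$z)) / diff(range(sst$z))
  suit <- env_raster("truth", sst$lon, sst$lat, exp(2 * x))
  pres <- simulate_presences(suit, 150, seed = 4)$points
  m <- fit_maxent(pres[, c("lon", "lat")], rs)
  expect_gt(m$lambda[which(m$feature_names == "SST.l")], 0)
  expect_equal(names(which.max(m$var_gain)), "SST")
})

test_that("fitted model satisfies the regularized moment conditions", {
  grid <- make_test_grid(25)
  colony <- c(grid$lon[1], grid$lat[1])
  rs <- make_stack(grid, colony, seed = 5)
  sst <- rs$SST
  suit <- env_raster("t", sst$lon, sst$lat, exp(2 * (sst$z - 17) / 8))
  pres <- simulate_presences(suit, 120, seed = 6)$points
  m <- fit_maxent(pres[, c("lon", "lat")], rs)
  # KKT: |E_q[f] - mean_presence[f]| <= beta_j (+ small numeric slack)
  sv <- foragescape:::stack_values(rs)
  okbg <- rowSums(!is.finite(sv$values)) == 0
  scale01 <- function(v) sweep(sweep(v, 2, m$rng[1, ]), 2, m$span, "/")
  f_bg <- foragescape:::build_features(scale01(sv$values[okbg, , drop = FALSE]))
  f_pr <- foragescape:::build_features(
    scale01(sv$values[m$presence_cells, , drop = FALSE]))
  gap <- abs(colMeans(f_pr) - as.vector(t(f_bg) %*% m$q_bg))
  expect_true(all(gap <= m$beta + 1e-3))
})

test_that("maxent errors on bad presences", {
  grid <- make_test_grid(20)
  colony <- c(grid$lon[1], grid$lat[1])
  rs <- make_stack(grid, colony, seed = 6)
  rs$SST$z[5, 5] <- NA   # hole in one layer
  hole <- c(rs$SST$lon[5], rs$SST$lat[5])
  pres <- cbind(lon = rep(hole[1], 12) + rnorm(12, 0, 1e-4),
                lat = rep(hole[2], 12) + rnorm(12, 0, 1e-4))
  expect_error(fit_maxent(pres, rs), "non-finite predictor")
  expect_error(fit_maxent(cbind(lon = 99, lat = 99), rs), "outside")
})

test_that("AUC helper matches rank logic and the category bands", {
  expect_equal(auc_presence_background(c(2, 3), c(0, 1)), 1)
  expect_equal(auc_presence_background(c(0, 1), c(2, 3)), 0)
  expect_equal(auc_presence_background(1, 1), 0.5)
  expect_equal(foragescape:::auc_category(0.95), "excellent")
  expect_equal(foragescape:::auc_category(0.85), "good")
  expect_equal(foragescape:::auc_category(0.75), "acceptable")
  expect_equal(foragescape:::auc_category(0.65), "bad")
  expect_equal(foragescape:::auc_category(0.55), "invalid")
})

test_that("replicated evaluation is reproducible and well-normalized", {
  grid <- make_test_grid(25)
  colony <- c(grid$lon[1], grid$lat[1])
  rs <- make_stack(grid, colony, seed = 7, broad_sst = TRUE)
  suit <- env_raster("t", rs$SST$lon, rs$SST$lat, exp(2 * rs$SST$z))
  pres <- simulate_presences(suit, 100, seed = 8)$points
  ev1 <- evaluate_habitat_model(pres[, c("lon", "lat")], rs, replicates = 8,
                                seed = 9)
  ev2 <- evaluate_habitat_model(pres[, c("lon", "lat")], rs, replicates = 8,
                                seed = 9)
  expect_identical(ev1$auc, ev2$auc)
  expect_identical(ev1$pct_contribution, ev2$pct_contribution)
  expect_identical(ev1$mean_prediction$z, ev2$mean_prediction$z)

  expect_lt(abs(sum(ev1$pct_contribution) - 100), 0.1)
  expect_lt(abs(sum(ev1$permutation_contribution) - 100), 0.1)
  expect_equal(ev1$replicates_used, 8)
  expect_true(all(ev1$auc >= 0 & ev1$auc <= 1))

  # jackknife table covers every variable with finite gains
  expect_setequal(ev1$jackknife$variable, names(rs))
  expect_true(all(is.finite(ev1$jackknife$gain_alone)))
})

test_that("the true generating surface upper-bounds the fitted AUC", {
  grid <- make_test_grid(25)
  colony <- c(grid$lon[1], grid$lat[1])
  rs <- make_stack(grid, colony, seed = 10, broad_sst = TRUE)
  suit <- env_raster("t", rs$SST$lon, rs$SST$lat, exp(2 * rs$SST$z))
  pres <- simulate_presences(suit, 150, seed = 11)$points
  m <- fit_maxent(pres[, c("lon", "lat")], rs)
  pred <- predict(m, rs)
  sv <- foragescape:::stack_values(rs)
  ci <- foragescape:::cell_index(sv$grid, pres$lon, pres$lat)
  pv <- as.vector(t(pred$z)); tv <- as.vector(t(suit$z))
  auc_fit <- auc_presence_background(pv[ci], pv[!is.na(pv)])
  auc_true <- auc_presence_background(tv[ci], tv[!is.na(tv)])
  expect_lte(auc_fit, auc_true + 0.02)   # Monte-Carlo slack
})
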