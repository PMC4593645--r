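## analytic Gaussian UD on a grid centred at `ctr` with SD sigma_km
gaussian_ud <- function(ctr, sigma_km, span_deg = 6, cell = 0.12,
                        origin = c(0, 0)) {
  lon <- seq(origin[1] - span_deg, origin[1] + span_deg, by = cell)
  lat <- seq(origin[2] - span_deg, origin[2] + span_deg, by = cell)
  gg <- expand.grid(lon = lon, lat = lat)
  xy <- foragescape:::aeqd_project(gg$lon, gg$lat, origin)
  d2 <- (xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2
  z <- matrix(exp(-d2 / (2 * sigma_km^2)), nrow = length(lat),
              ncol = length(lon), byrow = TRUE)
  ud_grid(lon, lat, z, center = origin)
}

test_that("LSCV bandwidth is positive and near the Gaussian-optimal rate", {
  set.seed(1)
  n <- 2000; sigma <- 40                       # km
  xy <- cbind(rnorm(n, 0, sigma), rnorm(n, 0, sigma))
  pts <- foragescape:::aeqd_inverse(xy[, 1], xy[, 2], c(0, 0))
  h <- lscv_bandwidth(pts, center = c(0, 0))
  expect_gt(h, 0)
  h_opt <- sigma * n^(-1 / 6)                  # bivariate Gaussian reference
  expect_gt(h / h_opt, 0.5)
  expect_lt(h / h_opt, 2)

  # duplicating every point must not change the selected bandwidth
  h2 <- lscv_bandwidth(rbind(pts, pts), center = c(0, 0))
  expect_equal(h2, h)

  expect_error(lscv_bandwidth(pts[rep(1, 20), ]), "at least 10 distinct")
})

test_that("kernel UD conserves mass and peaks at the data", {
  set.seed(2)
  pts <- foragescape:::aeqd_inverse(rnorm(200, 0, 30), rnorm(200, 0, 30),
                                    c(0, 0))
  ud <- kernel_ud(pts, h_km = 15, center = c(0, 0))
  expect_lt(abs(sum(ud$z * ud$area_km2) - 1), 1e-6)
  expect_true(all(ud$z >= 0))

  # single point: density maximum at that point's cell
  one <- kernel_ud(matrix(c(1.3, 0.7), 1), h_km = 20, center = c(0, 0))
  idx <- which(one$z == max(one$z), arr.ind = TRUE)
  expect_lt(abs(one$lon[idx[2]] - 1.3), one$cell_deg)
  expect_lt(abs(one$lat[idx[1]] - 0.7), one$cell_deg)

  expect_error(kernel_ud(matrix(numeric(0), 0, 2), 10), "empty")
})

test_that("contours enclose the requested mass and nest", {
  set.seed(3)
  pts <- foragescape:::aeqd_inverse(rnorm(1e4, 0, 40), rnorm(1e4, 0, 40),
                                    c(0, 0))
  ud <- kernel_ud(pts, h_km = 10, center = c(0, 0))
  c50 <- ud_contour(ud, 0.5)
  c95 <- ud_contour(ud, 0.95)
  expect_gte(c95$area_km2, c50$area_km2)
  expect_true(all(c95$include[c50$include]))   # 50% cells inside 95% set
  # mass inside the 95% contour of a Gaussian sample
  expect_gte(c95$mass, 0.94)
  expect_lte(c95$mass, 0.96)
})

test_that("Gaussian contour areas follow the log-level ratio", {
  ud <- gaussian_ud(c(0, 0), sigma_km = 60)
  a50 <- ud_contour(ud, 0.5)$area_km2
  a95 <- ud_contour(ud, 0.95)$area_km2
  expect_equal(a95 / a50, log(0.05) / log(0.5), tolerance = 0.05)
})

test_that("a bimodal UD yields a two-part contour", {
  ud1 <- gaussian_ud(c(-150, 0), 25, span_deg = 5)
  ud2 <- gaussian_ud(c(150, 0), 25, span_deg = 5)
  mix <- ud_grid(ud1$lon, ud1$lat, ud1$z + ud2$z, center = c(0, 0))
  ctr <- ud_contour(mix, 0.5)
  # both modes contribute cells, separated by an empty middle column
  gg_lon <- which(colSums(ctr$include) > 0)
  expect_true(any(mix$lon[gg_lon] < -0.5) && any(mix$lon[gg_lon] > 0.5))
  mid <- which.min(abs(mix$lon))
  expect_equal(sum(ctr$include[, mid]), 0)
})

test_that("VI overlap matches identity, disjointness and the closed form", {
  a <- gaussian_ud(c(0, 0), 50)
  expect_gte(ud_overlap_vi(a, a), 0.999)

  b_far <- gaussian_ud(c(450, 0), 50)          # ~9 sigma away
  expect_lte(ud_overlap_vi(a, b_far), 0.01)

  # two isotropic unit-sigma Gaussians separated by d = 2 sigma:
  # VI = 2 * pnorm(-1)
  b <- gaussian_ud(c(100, 0), 50)
  expect_equal(ud_overlap_vi(a, b), 2 * pnorm(-1), tolerance = 0.01)

  # symmetry and range on a seeded random pair
  set.seed(4)
  z1 <- matrix(runif(length(a$lat) * length(a$lon)), length(a$lat))
  z2 <- matrix(runif(length(a$lat) * length(a$lon)), length(a$lat))
  u1 <- ud_grid(a$lon, a$lat, z1, c(0, 0))
  u2 <- ud_grid(a$lon, a$lat, z2, c(0, 0))
  expect_equal(ud_overlap_vi(u1, u2), ud_overlap_vi(u2, u1))
  expect_gte(ud_overlap_vi(u1, u2), 0)
  expect_lte(ud_overlap_vi(u1, u2), 1)

  bad <- gaussian_ud(c(0, 0), 50, span_deg = 5)
  expect_error(ud_overlap_vi(a, bad), "different grids")
})

test_that("polygon overlap percentages follow constructed geometry", {
  # focal contour: rectangular block of cells straddling the equator
  # (grid offset so no cell centre sits exactly on the splitting meridians)
  lon <- seq(-2.94, 3, by = 0.12); lat <- seq(-2.94, 3, by = 0.12)
  include <- matrix(FALSE, length(lat), length(lon))
  rows <- which(abs(lat) < 1); cols <- which(abs(lon) < 2)
  include[rows, cols] <- TRUE
  focal <- structure(list(level = 0.5, include = include,
                          area_km2 = NA, mass = NA, lon = lon, lat = lat,
                          cell_deg = 0.12), class = "ud_contour")
  big <- cbind(lon = c(-10, 10, 10, -10, -10), lat = c(-10, -10, 10, 10, -10))
  expect_equal(polygon_overlap_pct(focal, list(big)), 100)

  far <- big; far[, "lon"] <- far[, "lon"] + 50
  expect_equal(polygon_overlap_pct(focal, list(far)), 0)

  # half-plane lon > 0 covers exactly half the block (east/west symmetry)
  half <- cbind(lon = c(0, 10, 10, 0, 0), lat = c(-10, -10, 10, 10, -10))
  expect_equal(polygon_overlap_pct(focal, list(half)), 50, tolerance = 1e-9)

  # invariant to layer order and to splitting the layer into pieces
  south <- cbind(lon = c(-10, 10, 10, -10, -10), lat = c(-10, -10, 0, 0, -10))
  north <- cbind(lon = c(-10, 10, 10, -10, -10), lat = c(0, 0, 10, 10, 0))
  expect_equal(polygon_overlap_pct(focal, list(north, south)),
               polygon_overlap_pct(focal, list(south, north)))
  expect_equal(polygon_overlap_pct(focal, list(north, south)), 100,
               tolerance = 1e-9)

  empty <- structure(list(level = 0.5,
                          include = matrix(FALSE, length(lat), length(lon)),
                          lon = lon, lat = lat, cell_deg = 0.12),
                     class = "ud_contour")
  expect_error(polygon_overlap_pct(empty, list(big)), "empty focal")
})

test_that("GeoJSON polygons round-trip through write and read", {
  ring <- cbind(lon = c(0, 1, 1, 0, 0), lat = c(0, 0, 1, 1, 0))
  f <- tempfile(fileext = ".geojson")
  write_geojson_polygons(list(ring), f, properties = list(level = 0.5))
  back <- read_geojson_polygons(f)
  expect_length(back, 1)
  expect_equal(back[[1]][, 1], ring[, 1])
  expect_equal(back[[1]][, 2], ring[, 2])
  unlink(f)
})
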