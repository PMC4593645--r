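## Utilization distributions on a geographic grid.
##
## Estimation is metric: points and cell centres are projected to an
## azimuthal-equidistant plane (km) about `center`, the Gaussian kernel and
## its bandwidth live in km, and the result is reported on the 0.12-degree
## geographic grid that the environmental predictors share. This avoids the
## lon/lat anisotropy a degree-unit kernel would have at these latitudes.

#' Construct a utilization-distribution grid
#'
#' @param lon,lat Vectors of cell-centre coordinates (regular spacing).
#' @param z Density matrix, `length(lat)` rows by `length(lon)` columns;
#'   renormalized so that the density integrates to 1 over the grid.
#' @param center `c(lon, lat)` projection centre used for metric operations.
#' @param h_km Bandwidth used to build the surface, if any.
#' @return A `ud_grid` object.
#' @export
ud_grid <- function(lon, lat, z, center, h_km = NA_real_) {
  stopifnot(nrow(z) == length(lat), ncol(z) == length(lon), all(z >= 0))
  area <- cell_areas_km2(lon, lat)
  tot <- sum(z * area)
  if (tot <= 0) stop("density surface has no mass")
  structure(list(lon = lon, lat = lat, z = z / tot, area_km2 = area,
                 cell_deg = if (length(lon) > 1) diff(lon[1:2]) else NA_real_,
                 center = as.numeric(center), h_km = h_km),
            class = "ud_grid")
}

## exact spherical cell areas (km^2); matrix matching z
cell_areas_km2 <- function(lon, lat) {
  dlon <- if (length(lon) > 1) abs(diff(lon[1:2])) else stop("need >= 2 lon cells")
  dlat <- if (length(lat) > 1) abs(diff(lat[1:2])) else stop("need >= 2 lat cells")
  band <- EARTH_RADIUS_KM^2 * (dlon * pi / 180) *
    (sin((lat + dlat / 2) * pi / 180) - sin((lat - dlat / 2) * pi / 180))
  matrix(band, nrow = length(lat), ncol = length(lon))
}

#' @export
print.ud_grid <- function(x, ...) {
  cat("<ud_grid>", length(x$lat), "x", length(x$lon), "cells of",
      x$cell_deg, "deg; h =", round(x$h_km, 3), "km\n")
  invisible(x)
}

#' Least-squares cross-validation bandwidth
#'
#' Minimizes the LSCV score of an isotropic bivariate Gaussian kernel over a
#' log-spaced grid spanning 0.05 to 2 times the Gaussian reference bandwidth
#' (Silverman's rule in two dimensions). Duplicate points are removed first:
#' exact duplicates make the leave-one-out term degenerate and drive the
#' bandwidth to zero. When the minimum lands on a grid boundary the reference
#' bandwidth is returned with a warning.
#'
#' @param points Two-column matrix or data frame of lon/lat.
#' @param center Projection centre; defaults to the point centroid.
#' @param n_grid Number of candidate bandwidths.
#' @return Bandwidth in km.
#' @export
lscv_bandwidth <- function(points, center = NULL, n_grid = 30) {
  pts <- unique(as.matrix(points)[, 1:2, drop = FALSE])
  n <- nrow(pts)
  if (n < 10) stop("need at least 10 distinct points")
  if (is.null(center)) center <- colMeans(pts)
  xy <- aeqd_project(pts[, 1], pts[, 2], center)
  sdev <- sqrt((var(xy[, 1]) + var(xy[, 2])) / 2)
  if (sdev == 0) stop("all points identical")
  h_ref <- sdev * n^(-1 / 6)
  d2 <- dist(xy)^2                      # pairwise squared distances (i < j)
  hs <- exp(seq(log(0.05 * h_ref), log(2 * h_ref), length.out = n_grid))
  score <- vapply(hs, function(h) {
    # integral of fhat^2: (1/n^2) sum_ij N(d; 2h^2), diagonal included
    int_f2 <- (n + 2 * sum(exp(-d2 / (4 * h^2)))) / (4 * pi * h^2 * n^2)
    loo <- 2 * sum(exp(-d2 / (2 * h^2))) / (2 * pi * h^2 * n * (n - 1))
    int_f2 - 2 * loo
  }, numeric(1))
  i <- which.min(score)
  if (i == 1L || i == n_grid) {
    warning("LSCV minimum on grid boundary; falling back to reference bandwidth")
    return(h_ref)
  }
  hs[i]
}

#' Kernel utilization distribution
#'
#' Bivariate Gaussian kernel density of the points, evaluated at the centres
#' of a regular geographic grid (default cell 0.12 degrees, matching the
#' coarsest environmental predictor) and renormalized to unit mass.
#'
#' @param points Two-column matrix or data frame of lon/lat.
#' @param h_km Bandwidth in km (> 0), e.g. from [lscv_bandwidth()].
#' @param grid Optional list with `lon` and `lat` cell-centre vectors; by
#'   default built from the padded point extent at `cell_deg` resolution.
#' @param center Projection centre; defaults to the point centroid.
#' @param cell_deg Grid cell size in degrees.
#' @return A `ud_grid`.
#' @export
kernel_ud <- function(points, h_km, grid = NULL, center = NULL, cell_deg = 0.12) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(pts) == 0) stop("empty point set")
  stopifnot(h_km > 0)
  if (is.null(center)) center <- colMeans(pts)
  if (is.null(grid)) {
    pad <- 4 * h_km / 111.195          # ~4 bandwidths of margin, in degrees
    grid <- list(
      lon = seq(min(pts[, 1]) - pad, max(pts[, 1]) + pad + cell_deg, by = cell_deg),
      lat = seq(min(pts[, 2]) - pad, max(pts[, 2]) + pad + cell_deg, by = cell_deg))
  }
  gg <- expand.grid(lon = grid$lon, lat = grid$lat)
  pxy <- aeqd_project(pts[, 1], pts[, 2], center)
  gxy <- aeqd_project(gg$lon, gg$lat, center)
  dens <- .kde_cpp(pxy[, 1], pxy[, 2], gxy[, 1], gxy[, 2], h_km)
  z <- matrix(dens, nrow = length(grid$lat), ncol = length(grid$lon), byrow = TRUE)
  ud_grid(grid$lon, grid$lat, z, center, h_km = h_km)
}

#' Probability contour of a utilization distribution
#'
#' Cells are accumulated in order of decreasing density until the enclosed
#' probability mass reaches `level` (the standard UD volume convention); the
#' 50% contour is the core foraging region (FR) and the 95% contour the home
#' range (HR).
#'
#' @param ud A `ud_grid`.
#' @param level Probability level in (0, 1).
#' @return A `ud_contour`: the included-cell mask, its area (km2), the mass
#'   actually enclosed, and the grid geometry.
#' @export
ud_contour <- function(ud, level) {
  stopifnot(level > 0, level < 1)
  mass <- ud$z * ud$area_km2
  o <- order(ud$z, decreasing = TRUE)
  cum <- cumsum(mass[o])
  k <- which(cum >= level)[1]
  if (is.na(k)) k <- length(o)
  include <- matrix(FALSE, nrow(ud$z), ncol(ud$z))
  include[o[seq_len(k)]] <- TRUE
  structure(list(level = level, include = include,
                 area_km2 = sum(ud$area_km2[include]),
                 mass = cum[k], lon = ud$lon, lat = ud$lat,
                 cell_deg = ud$cell_deg),
            class = "ud_contour")
}

#' @export
print.ud_contour <- function(x, ...) {
  cat("<ud_contour>", x$level * 100, "% level:", sum(x$include), "cells,",
      round(x$area_km2), "km2 (mass", round(x$mass, 4), ")\n")
  invisible(x)
}

#' Utilization-distribution overlap (volume intersection index)
#'
#' VI is the integral of the pointwise minimum of the two densities:
#' 0 for disjoint space use, 1 for identical distributions.
#'
#' @param ud1,ud2 `ud_grid` objects on the same grid.
#' @return Overlap fraction in \[0, 1\].
#' @export
ud_overlap_vi <- function(ud1, ud2) {
  if (!isTRUE(all.equal(ud1$lon, ud2$lon)) || !isTRUE(all.equal(ud1$lat, ud2$lat)))
    stop("utilization distributions are on different grids")
  sum(pmin(ud1$z, ud2$z) * ud1$area_km2)
}

#' Percentage overlap of a foraging-region contour with a polygon layer
#'
#' Reports 100 * area(focal intersect layer) / area(focal), with areas taken
#' on the sphere (equal-area by construction of the cell areas). The layer is
#' a set of polygons treated as a union; the focal region is a UD contour.
#'
#' @param focal A `ud_contour`.
#' @param layer A list of polygon rings (two-column lon/lat matrices), e.g.
#'   from [read_geojson_polygons()].
#' @return Percentage in \[0, 100\].
#' @export
polygon_overlap_pct <- function(focal, layer) {
  if (!any(focal$include)) stop("empty focal polygon")
  if (is.matrix(layer)) layer <- list(layer)
  gg <- expand.grid(lon = focal$lon, lat = focal$lat)
  # expand.grid varies lon fastest; include is [lat, lon] so transpose
  inc <- as.vector(t(focal$include))
  area <- as.vector(t(cell_areas_km2(focal$lon, focal$lat)))
  idx <- which(inc)
  inside <- point_in_polyset(gg$lon[idx], gg$lat[idx], layer)
  100 * sum(area[idx][inside]) / sum(area[idx])
}

#' Contour cells as polygon rings
#'
#' Each included cell becomes its bounding rectangle; useful for GeoJSON
#' export of FR/HR outlines.
#' @param contour A `ud_contour`.
#' @return List of closed rings (lon/lat matrices).
#' @export
contour_to_polyset <- function(contour) {
  half <- contour$cell_deg / 2
  idx <- which(contour$include, arr.ind = TRUE)
  lapply(seq_len(nrow(idx)), function(i) {
    lo <- contour$lon[idx[i, 2]]; la <- contour$lat[idx[i, 1]]
    cbind(lon = c(lo - half, lo + half, lo + half, lo - half, lo - half),
          lat = c(la - half, la - half, la + half, la + half, la - half))
  })
}

#' Read polygons from a GeoJSON file
#'
#' Supports Polygon and MultiPolygon geometries in a FeatureCollection,
#' Feature, or bare geometry; outer rings only (holes are ignored).
#' @param path GeoJSON file.
#' @return List of rings (two-column lon/lat matrices).
#' @export
read_geojson_polygons <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geoms <- switch(g$type,
    FeatureCollection = lapply(g$features, function(f) f$geometry),
    Feature = list(g$geometry),
    list(g))
  rings <- list()
  for (gm in geoms) {
    if (is.null(gm)) next
    if (gm$type == "Polygon") {
      rings[[length(rings) + 1]] <- ring_to_matrix(gm$coordinates[[1]])
    } else if (gm$type == "MultiPolygon") {
      for (poly in gm$coordinates)
        rings[[length(rings) + 1]] <- ring_to_matrix(poly[[1]])
    }
  }
  rings
}

ring_to_matrix <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  colnames(m) <- c("lon", "lat")
  m
}

#' Write polygons to a GeoJSON file
#' @param polyset List of rings (lon/lat matrices) forming one MultiPolygon.
#' @param path Output file.
#' @param properties Optional named list written as feature properties.
#' @export
write_geojson_polygons <- function(polyset, path, properties = NULL) {
  close_ring <- function(r) {
    if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
    lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
  }
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature",
    properties = if (is.null(properties)) setNames(list(), character(0)) else properties,
    geometry = list(type = "MultiPolygon",
                    coordinates = lapply(polyset, function(r) list(close_ring(r)))))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
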