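#' Great-circle distance between two points
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the mean Earth
#' radius). At foraging-trip scales (tens to hundreds of km) the spherical
#' approximation is within 0.5% of the ellipsoidal distance.
#'
#' @param a,b Numeric length-2 vectors `c(lon, lat)` in decimal degrees, or
#'   two-column matrices of such points (recycled against each other).
#' @return Distance(s) in km.
#' @examples
#' great_circle_km(c(0, 0), c(1, 0))  # one degree of longitude at the equator
#' @export
great_circle_km <- function(a, b) {
  geosphere::distHaversine(a, b, r = EARTH_RADIUS_KM)
}

## Azimuthal-equidistant projection about `center` = c(lon, lat), on the same
## sphere as great_circle_km(). Returns km east/north. Used internally so that
## path geometry, kernel smoothing and FPT circles are metric, while lon/lat
## stays the exchange format.
aeqd_project <- function(lon, lat, center) {
  lam <- lon * pi / 180; phi <- lat * pi / 180
  lam0 <- center[1] * pi / 180; phi0 <- center[2] * pi / 180
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- EARTH_RADIUS_KM * k * cos(phi) * sin(lam - lam0)
  y <- EARTH_RADIUS_KM * k *
    (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  cbind(x = x, y = y)
}

aeqd_inverse <- function(x, y, center) {
  lam0 <- center[1] * pi / 180; phi0 <- center[2] * pi / 180
  rho <- sqrt(x^2 + y^2)
  c_ang <- rho / EARTH_RADIUS_KM
  phi <- ifelse(rho < 1e-12, phi0,
                asin(cos(c_ang) * sin(phi0) + y * sin(c_ang) * cos(phi0) / rho))
  lam <- lam0 + atan2(x * sin(c_ang),
                      rho * cos(phi0) * cos(c_ang) - y * sin(phi0) * sin(c_ang))
  cbind(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

## shoelace area of a closed or open ring given as two columns
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

## ray-casting point-in-polygon; ring is a two-column matrix, open or closed.
## Vectorized over the query points.
point_in_ring <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  if (abs(x[1] - x[n]) < 1e-12 && abs(y[1] - y[n]) < 1e-12) {
    x <- x[-n]; y <- y[-n]; n <- n - 1
  }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py)) &
      (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

## membership in a polygon set (list of rings treated as a union; holes are
## not modelled -- conservation layers here are simple outer rings)
point_in_polyset <- function(px, py, polyset) {
  inside <- rep(FALSE, length(px))
  for (ring in polyset) inside <- inside | point_in_ring(px, py, ring)
  inside
}
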