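# Geometry helpers: cylindrical equal-area projection, haversine distances,
# ray-casting point-in-polygon. Earth radius pinned to 6371 km so that MST
# lengths are reproducible across platforms.

EARTH_RADIUS_KM <- 6371

# Lambert cylindrical equal-area projection (standard parallel lat_ts, central
# meridian lon0). Returns km. Area-preserving, so polygon translation in the
# projected plane conserves sampling area exactly.
cea_project <- function(lon, lat, lon0 = 0, lat_ts = 0) {
  k <- cos(lat_ts * pi / 180)
  list(x = EARTH_RADIUS_KM * ((lon - lon0) * pi / 180) * k,
       y = EARTH_RADIUS_KM * sin(lat * pi / 180) / k)
}

cea_unproject <- function(x, y, lon0 = 0, lat_ts = 0) {
  k <- cos(lat_ts * pi / 180)
  s <- y * k / EARTH_RADIUS_KM
  if (any(abs(s) > 1 + 1e-12)) {
    stop("projected point lies beyond a pole; reduce the drift or move the ",
         "base polygon away from high latitudes", call. = FALSE)
  }
  list(lon = x / (EARTH_RADIUS_KM * k) * 180 / pi + lon0,
       lat = asin(pmin(1, pmax(-1, s))) * 180 / pi)
}

# Great-circle distance in km (haversine, radius 6371 km), vectorised.
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM)
}

# Full pairwise haversine distance matrix over points (lon, lat).
haversine_matrix <- function(lon, lat) {
  n <- length(lon)
  m <- matrix(0, n, n)
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d <- haversine_km(lon[i], lat[i], lon[j], lat[j])
    m[i, j] <- d
    m[j, i] <- d
  }
  m
}

# Shoelace area of a polygon given coordinate vectors (projected units).
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Ray-casting point-in-polygon, boundary-inclusive: points exactly on an edge
# or vertex count as inside. px, py vectors; polygon as x/y vectors (open or
# closed ring).
point_in_polygon <- function(px, py, vx, vy, tol = 1e-9) {
  n <- length(vx)
  if (vx[1] == vx[n] && vy[1] == vy[n]) {
    vx <- vx[-n]; vy <- vy[-n]; n <- n - 1
  }
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # collinear and within segment bounding box -> on boundary
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seg <- abs(cross) <= tol * (abs(x2 - x1) + abs(y2 - y1) + 1) &
      px >= pmin(x1, x2) - tol & px <= pmax(x1, x2) + tol &
      py >= pmin(y1, y2) - tol & py <= pmax(y1, y2) + tol
    on_edge <- on_edge | seg
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}
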