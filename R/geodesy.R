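# Great-circle geometry on the sphere R = 6371 km. All distances in km.

EARTH_RADIUS_KM <- 6371
KM_PER_DEG <- EARTH_RADIUS_KM * pi / 180  # 111.1949 km per degree of arc

#' Haversine great-circle distance
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in degrees; vectors are recycled.
#' @return Distance in km on the sphere R = 6371 km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  k <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  geosphere::distHaversine(
    cbind(rep_len(lon1, k), rep_len(lat1, k)),
    cbind(rep_len(lon2, k), rep_len(lat2, k)),
    r = EARTH_RADIUS_KM * 1000) / 1000
}

# unit vectors on the sphere, rows = points
latlon_to_unit <- function(lat, lon) {
  la <- lat * pi / 180; lo <- lon * pi / 180
  cbind(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
}

unit_to_latlon <- function(v) {
  cbind(lat = asin(pmax(-1, pmin(1, v[, 3]))) * 180 / pi,
        lon = atan2(v[, 2], v[, 1]) * 180 / pi)
}

# angle between unit vectors via the numerically stable chord formula
# (pmin/pmax take attributes from their first argument, so keep the
# matrix-valued expression first to preserve dim)
chord_angle <- function(dot) 2 * asin(pmin(sqrt(pmax((1 - dot) / 2, 0)), 1))

#' Minimum great-circle distance from point(s) to a polyline
#'
#' Exact point-to-arc distance: per segment, the cross-track distance when the
#' great-circle foot of the point falls inside the arc, otherwise the nearer
#' vertex distance. Spherical model, R = 6371 km.
#'
#' @param lat,lon Query point coordinates in degrees (vectors allowed).
#' @param polyline A data frame with `lat` and `lon` columns (an [isoline] is
#'   one), vertices in path order; a `segment` column, if present, breaks the
#'   path into separate polylines.
#' @return Numeric vector of distances in km, one per query point.
#' @export
dist_point_to_polyline <- function(lat, lon, polyline) {
  stopifnot(is.data.frame(polyline), all(c("lat", "lon") %in% names(polyline)))
  if (nrow(polyline) == 0) stop("empty polyline", call. = FALSE)
  P <- latlon_to_unit(lat, lon)
  k <- nrow(P)
  seg <- if ("segment" %in% names(polyline)) polyline$segment else rep(1L, nrow(polyline))
  V <- latlon_to_unit(polyline$lat, polyline$lon)
  # edges within each segment
  n <- nrow(V)
  keep <- seq_len(n - 1)
  keep <- keep[seg[keep] == seg[keep + 1]]
  best <- rep(Inf, k)
  # vertex distances first (covers single-vertex segments too)
  dotPV <- P %*% t(V)                          # k x n
  best <- pmin(best, apply(chord_angle(dotPV), 1, min))
  if (length(keep) > 0) {
    A <- V[keep, , drop = FALSE]; B <- V[keep + 1, , drop = FALSE]
    e <- nrow(A)
    cr <- cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
                A[, 3] * B[, 1] - A[, 1] * B[, 3],
                A[, 1] * B[, 2] - A[, 2] * B[, 1])
    crn <- sqrt(rowSums(cr^2))
    ok <- crn > 1e-12                          # degenerate edges fall back to vertices
    if (any(ok)) {
      A <- A[ok, , drop = FALSE]; B <- B[ok, , drop = FALSE]
      Nh <- cr[ok, , drop = FALSE] / crn[ok]
      e <- nrow(A)
      angAB <- chord_angle(rowSums(A * B))
      S <- P %*% t(Nh)                         # k x e, sine of cross-track
      # foot of each point on each edge's great circle
      Fx <- outer(P[, 1], rep(1, e)) - S * matrix(Nh[, 1], k, e, byrow = TRUE)
      Fy <- outer(P[, 2], rep(1, e)) - S * matrix(Nh[, 2], k, e, byrow = TRUE)
      Fz <- outer(P[, 3], rep(1, e)) - S * matrix(Nh[, 3], k, e, byrow = TRUE)
      nrm <- sqrt(Fx^2 + Fy^2 + Fz^2)
      Fx <- Fx / nrm; Fy <- Fy / nrm; Fz <- Fz / nrm
      dotFA <- Fx * matrix(A[, 1], k, e, byrow = TRUE) +
        Fy * matrix(A[, 2], k, e, byrow = TRUE) +
        Fz * matrix(A[, 3], k, e, byrow = TRUE)
      dotFB <- Fx * matrix(B[, 1], k, e, byrow = TRUE) +
        Fy * matrix(B[, 2], k, e, byrow = TRUE) +
        Fz * matrix(B[, 3], k, e, byrow = TRUE)
      inside <- chord_angle(dotFA) + chord_angle(dotFB) <=
        matrix(angAB, k, e, byrow = TRUE) + 1e-9
      dct <- asin(pmin(abs(S), 1))
      dct[!inside] <- Inf
      best <- pmin(best, apply(dct, 1, min))
    }
  }
  best * EARTH_RADIUS_KM
}

# destination point given start, bearing (deg clockwise from north), arc km
move_geodesic <- function(lat, lon, bearing_deg, dist_km) {
  d <- dist_km / EARTH_RADIUS_KM
  br <- bearing_deg * pi / 180
  la1 <- lat * pi / 180; lo1 <- lon * pi / 180
  la2 <- asin(sin(la1) * cos(d) + cos(la1) * sin(d) * cos(br))
  lo2 <- lo1 + atan2(sin(br) * sin(d) * cos(la1),
                     cos(d) - sin(la1) * sin(la2))
  cbind(lat = la2 * 180 / pi, lon = norm_lon(lo2 * 180 / pi))
}
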