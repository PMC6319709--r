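#' Great-circle distance matrix between populations
#'
#' Haversine distances on a sphere of radius 6371.0088 km (IUGG mean earth
#' radius).  Coordinates are decimal-degree WGS84 treated as spherical; at
#' regional scales the difference from ellipsoidal geodesics is well below
#' 1 percent.
#'
#' @param meta data frame with columns `population_id`, `latitude`,
#'   `longitude` (decimal degrees).
#' @return symmetric, zero-diagonal matrix of distances in km, with
#'   population ids as dimnames.  Populations with missing coordinates are
#'   dropped with a warning.
#' @examples
#' m <- data.frame(population_id = c("a", "b"),
#'                 latitude = c(0, 0), longitude = c(0, 1))
#' geodesic_distance_matrix(m)  # ~111.195 km
#' @export
geodesic_distance_matrix <- function(meta) {
  req <- c("population_id", "latitude", "longitude")
  if (!all(req %in% names(meta)))
    stop("meta must have columns ", paste(req, collapse = ", "))
  ok <- stats::complete.cases(meta[, c("latitude", "longitude")])
  if (!all(ok)) {
    warning("dropping populations with missing coordinates: ",
            paste(meta$population_id[!ok], collapse = ", "), call. = FALSE)
    meta <- meta[ok, , drop = FALSE]
  }
  if (any(abs(meta$latitude) > 90) || any(abs(meta$longitude) > 180))
    stop("coordinates out of range")
  n <- nrow(meta)
  pts <- cbind(meta$longitude, meta$latitude)
  d <- matrix(0, n, n, dimnames = list(meta$population_id, meta$population_id))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      dij <- geosphere::distHaversine(pts[i, , drop = FALSE],
                                      pts[j, , drop = FALSE],
                                      r = 6371008.8) / 1000
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  d
}

#' Aggregate point-sampled soil variables to populations
#'
#' Averages soil survey point records within a fixed radius of each
#' population (closed ball: points at exactly the radius contribute).
#'
#' @param points data frame of point records with `latitude`, `longitude`
#'   and numeric soil variable columns.
#' @param meta data frame with `population_id`, `latitude`, `longitude`.
#' @param radius_km search radius in km (default 15).
#' @return data frame: one row per population with the mean of each soil
#'   variable over contributing points and an `n_points` count.  Populations
#'   with no point in range get `NA` soil values and a warning.
#' @export
aggregate_soil <- function(points, meta, radius_km = 15) {
  vars <- setdiff(names(points), c("latitude", "longitude"))
  vars <- vars[vapply(points[vars], is.numeric, logical(1))]
  if (!length(vars)) stop("no numeric soil variables in points")
  out <- data.frame(population_id = meta$population_id,
                    stringsAsFactors = FALSE)
  out[vars] <- NA_real_
  out$n_points <- 0L
  ppts <- cbind(points$longitude, points$latitude)
  for (i in seq_len(nrow(meta))) {
    d <- geosphere::distHaversine(c(meta$longitude[i], meta$latitude[i]),
                                  ppts, r = 6371008.8) / 1000
    inside <- d <= radius_km
    out$n_points[i] <- sum(inside)
    if (any(inside)) {
      out[i, vars] <- colMeans(points[inside, vars, drop = FALSE],
                               na.rm = TRUE)
    }
  }
  empty <- out$n_points == 0L
  if (any(empty))
    warning("no soil points within ", radius_km, " km of: ",
            paste(meta$population_id[empty], collapse = ", "), call. = FALSE)
  out
}
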