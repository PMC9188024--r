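#' Great-circle distance between coordinates
#'
#' Haversine distance on a sphere of radius 6371 km; used for movement
#' distances between consecutive tracking fixes.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (vectorized).
#' @return distance(s) in kilometres.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  check_coords(lon1, lat1)
  check_coords(lon2, lat2)
  r <- 6371.0
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

check_coords <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)) ||
      any(lon < -180 | lon > 180) || any(lat < -90 | lat > 90))
    fc_stop("coordinates must satisfy lon in [-180,180], lat in [-90,90]")
  invisible(NULL)
}

#' Minimum convex polygon of tracking points
#'
#' Convex hull of point locations in geographic (degree) space, the basis
#' of seasonal range delineation.
#'
#' @param points tibble/data frame with `lon` and `lat` columns.
#' @return tibble of hull vertices (`lon`, `lat`) in counter-clockwise
#'   order, class `fc_polygon`; errors for < 3 distinct points or collinear
#'   input.
#' @export
minimum_convex_polygon <- function(points) {
  pts <- unique(tibble::tibble(lon = points$lon, lat = points$lat))
  check_coords(pts$lon, pts$lat)
  if (nrow(pts) < 3) fc_stop("need >= 3 distinct points")
  idx <- grDevices::chull(pts$lon, pts$lat)
  if (length(idx) < 3) fc_stop("points are collinear; polygon undefined")
  hull <- pts[rev(idx), ]  # chull returns clockwise; reverse to CCW
  structure(hull, class = c("fc_polygon", class(hull)))
}

# signed polygon area (shoelace); positive for CCW vertex order
polygon_area <- function(poly) {
  x <- poly$lon; y <- poly$lat
  n <- length(x)
  i2 <- c(2:n, 1)
  sum(x * y[i2] - x[i2] * y) / 2
}

#' Buffer a convex polygon in degree space
#'
#' Rounded-corner (Minkowski-sum) buffer of a convex polygon: each edge is
#' offset outward by `radius` degrees and vertices are joined by circular
#' arcs. Buffering is done in geographic degree space, matching the
#' convention of delineating ranges with a fixed-degree buffer; the result
#' is approximate near the poles.
#'
#' @param poly an `fc_polygon` (CCW convex vertices).
#' @param radius buffer radius in degrees (default 0.5).
#' @param n_arc arc segments per vertex.
#' @return buffered polygon as an `fc_polygon` tibble.
#' @export
buffer_degrees <- function(poly, radius = 0.5, n_arc = 24) {
  if (radius < 0) fc_stop("radius must be >= 0")
  if (radius == 0) return(poly)
  x <- poly$lon; y <- poly$lat
  n <- length(x)
  if (polygon_area(poly) < 0) {
    x <- rev(x); y <- rev(y)
  }
  out_x <- out_y <- numeric(0)
  for (i in seq_len(n)) {
    ip <- if (i == 1) n else i - 1
    inx <- if (i == n) 1 else i + 1
    # outward normals of the two edges adjacent to vertex i (CCW polygon)
    e_in <- c(x[i] - x[ip], y[i] - y[ip])
    e_out <- c(x[inx] - x[i], y[inx] - y[i])
    nrm <- function(e) {
      v <- c(e[2], -e[1])
      v / sqrt(sum(v^2))
    }
    a1 <- atan2(nrm(e_in)[2], nrm(e_in)[1])
    a2 <- atan2(nrm(e_out)[2], nrm(e_out)[1])
    if (a2 < a1) a2 <- a2 + 2 * pi  # CCW polygon: normals rotate CCW
    ang <- seq(a1, a2, length.out = n_arc + 1)
    out_x <- c(out_x, x[i] + radius * cos(ang))
    out_y <- c(out_y, y[i] + radius * sin(ang))
  }
  structure(tibble::tibble(lon = out_x, lat = out_y),
            class = c("fc_polygon", class(tibble::tibble())))
}

#' Point-in-polygon test
#'
#' Ray-casting test in degree space, boundary-inclusive up to numerical
#' tolerance.
#'
#' @param poly an `fc_polygon`.
#' @param lon,lat point coordinates (vectorized).
#' @return logical vector.
#' @export
point_in_polygon <- function(poly, lon, lat) {
  px <- poly$lon; py <- poly$lat
  n <- length(px)
  vapply(seq_along(lon), function(q) {
    x <- lon[q]; y <- lat[q]
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      on_seg <- abs((py[j] - py[i]) * (x - px[i]) -
                      (y - py[i]) * (px[j] - px[i])) < 1e-12 &&
        x >= min(px[i], px[j]) - 1e-12 && x <= max(px[i], px[j]) + 1e-12 &&
        y >= min(py[i], py[j]) - 1e-12 && y <= max(py[i], py[j]) + 1e-12
      if (on_seg) return(TRUE)
      if ((py[i] > y) != (py[j] > y) &&
          x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
        inside <- !inside
      j <- i
    }
    inside
  }, logical(1))
}

#' Polygon as well-known text
#'
#' @param poly an `fc_polygon`.
#' @return `POLYGON ((...))` WKT string (ring closed).
#' @export
polygon_wkt <- function(poly) {
  lon <- c(poly$lon, poly$lon[1])
  lat <- c(poly$lat, poly$lat[1])
  sprintf("POLYGON ((%s))",
          paste(sprintf("%.6f %.6f", lon, lat), collapse = ", "))
}

#' Assign tracking fixes to molt / winter seasons
#'
#' Molting window: Aug 1 to Oct 15; wintering window: Oct 16 to Mar 31.
#' Fixes outside both windows get `NA`.
#'
#' @param date a `Date` vector.
#' @return character vector `"molt"`, `"winter"` or `NA`.
#' @export
assign_season <- function(date) {
  md <- as.integer(format(date, "%m")) * 100 + as.integer(format(date, "%d"))
  dplyr::case_when(
    md >= 801 & md <= 1015 ~ "molt",
    md >= 1016 | md <= 331 ~ "winter",
    TRUE ~ NA_character_
  )
}

#' Movement distances between consecutive fixes
#'
#' Great-circle distances between successive fixes per bird, labelled by
#' season transition (within-season vs between-season), shaped like a
#' tracking-movement summary table.
#'
#' @param track tibble: `bird_id`, `lon`, `lat`, `date`.
#' @param min_km report only movements larger than this (default 1 km).
#' @return tibble: `bird_id`, `from_date`, `to_date`, `from_season`,
#'   `to_season`, `leg` and `distance_km`.
#' @export
movement_distances <- function(track, min_km = 1) {
  track <- dplyr::arrange(track, .data$bird_id, .data$date)
  track$season <- assign_season(track$date)
  out <- track |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::mutate(
      distance_km = c(NA, haversine_km(head(.data$lon, -1), head(.data$lat, -1),
                                       tail(.data$lon, -1), tail(.data$lat, -1))),
      from_date = dplyr::lag(.data$date),
      from_season = dplyr::lag(.data$season)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$distance_km), .data$distance_km > min_km) |>
    dplyr::mutate(
      leg = dplyr::case_when(
        is.na(.data$from_season) | is.na(.data$season) ~ "transition",
        .data$from_season == .data$season ~ paste0("within_", .data$season),
        TRUE ~ paste0(.data$from_season, "_to_", .data$season)
      )
    ) |>
    dplyr::select("bird_id", "from_date", to_date = "date",
                  "from_season", to_season = "season", "leg", "distance_km")
  out
}
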