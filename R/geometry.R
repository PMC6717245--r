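#' Survey geometry for a shore-based whale survey
#'
#' Bundles the fixed geometry of the observation site: observer and camera
#' positions and heights, the infrared camera's field of view and image
#' dimensions, the horizon calibration row, the true bearings of the image
#' edges, the hydrophone array, and the mean distance a whale travels through
#' the array.
#'
#' @param observer_position numeric length-2 (lat, lon) in decimal degrees.
#' @param observer_height_m observer eye height above sea level, metres.
#' @param camera_position numeric length-2 (lat, lon) in decimal degrees.
#' @param camera_height_m camera lens height above sea level, metres.
#' @param camera_hfov_deg horizontal field of view, degrees.
#' @param camera_vfov_deg vertical field of view, degrees.
#' @param image_width_px,image_height_px image dimensions in pixels.
#' @param horizon_row_px calibrated pixel row of the sea horizon (row 0 is
#'   the image top); a per-deployment calibration input.
#' @param camera_edge_azimuths_deg true bearings (degrees, clockwise from
#'   north) of the left and right image edges; their span must equal
#'   \code{camera_hfov_deg}.
#' @param hydrophone_positions 4 x 2 matrix of (lat, lon) hydrophone
#'   positions.
#' @param array_transit_distance_m mean along-track distance through the
#'   hydrophone array, metres.
#' @param earth_radius_m earth radius, metres. An effective-radius
#'   multiplier larger than 1 can stand in for atmospheric refraction.
#' @param refraction_multiplier multiplier applied to the earth radius for
#'   ray-bending; default 1 (no refraction correction).
#' @return an object of class \code{survey_geometry}.
#' @export
survey_geometry <- function(observer_position = c(36.43989, -121.92237),
                            observer_height_m = 22.3,
                            camera_position = c(36.44017, -121.92206),
                            camera_height_m = 28.1,
                            camera_hfov_deg = 6.2,
                            camera_vfov_deg = 5,
                            image_width_px = 640L,
                            image_height_px = 480L,
                            horizon_row_px = 40,
                            camera_edge_azimuths_deg = c(240, 246.2),
                            hydrophone_positions = default_hydrophones(),
                            array_transit_distance_m = 2280,
                            earth_radius_m = 6371000,
                            refraction_multiplier = 1) {
  check_number(observer_height_m, "observer_height_m", 0, strict_lower = TRUE)
  check_number(camera_height_m, "camera_height_m", 0, strict_lower = TRUE)
  check_number(camera_hfov_deg, "camera_hfov_deg", 0, strict_lower = TRUE)
  check_number(camera_vfov_deg, "camera_vfov_deg", 0, strict_lower = TRUE)
  check_number(array_transit_distance_m, "array_transit_distance_m", 0,
               strict_lower = TRUE)
  check_number(refraction_multiplier, "refraction_multiplier", 0,
               strict_lower = TRUE)
  hp <- as.matrix(hydrophone_positions)
  if (nrow(hp) != 4L || ncol(hp) != 2L)
    stop_cfg("'hydrophone_positions' must be a 4 x 2 (lat, lon) matrix")
  span <- abs(diff(camera_edge_azimuths_deg)) %% 360
  if (abs(span - camera_hfov_deg) > 1e-6)
    stop_cfg("edge azimuth span (%g) must equal the horizontal FOV (%g)",
             span, camera_hfov_deg)
  structure(list(
    observer_position = as.numeric(observer_position),
    observer_height_m = observer_height_m,
    camera_position = as.numeric(camera_position),
    camera_height_m = camera_height_m,
    camera_hfov_deg = camera_hfov_deg,
    camera_vfov_deg = camera_vfov_deg,
    image_width_px = as.integer(image_width_px),
    image_height_px = as.integer(image_height_px),
    horizon_row_px = horizon_row_px,
    camera_edge_azimuths_deg = as.numeric(camera_edge_azimuths_deg),
    hydrophone_positions = hp,
    array_transit_distance_m = array_transit_distance_m,
    earth_radius_m = earth_radius_m * refraction_multiplier
  ), class = "survey_geometry")
}

# Hydrophone array corners offshore of the survey site (shore-relative layout
# spanning roughly 1.5-3.6 km from shore); synthetic stand-ins used only to
# carry array shape in simulations.
default_hydrophones <- function() {
  matrix(c(36.425, -121.940,
           36.445, -121.950,
           36.455, -121.930,
           36.435, -121.920), ncol = 2, byrow = TRUE,
         dimnames = list(c("SE", "SW", "NW", "NE"), c("lat", "lon")))
}

#' Convert an image pixel row to a range from the camera
#'
#' The depression angle of the target below the sea horizon is obtained by
#' linear interpolation of the vertical field of view; adding the horizon dip
#' \eqn{\arccos(R/(R+h))} gives the total depression below the camera's local
#' horizontal, and the surface (great-circle) distance follows from spherical
#' single-camera photogrammetry: the central angle \eqn{\gamma} solves
#' \deqn{\tan\beta = \frac{(R+h) - R\cos\gamma}{R\sin\gamma}.}
#'
#' @param row_px pixel row(s) of the target, below the horizon row (row 0 at
#'   the image top, integer pixel centres).
#' @param geom a \code{\link{survey_geometry}}.
#' @return range(s) from the camera along the sea surface, metres.
#' @export
pixel_to_range <- function(row_px, geom) {
  stopifnot(inherits(geom, "survey_geometry"))
  R <- geom$earth_radius_m
  h <- geom$camera_height_m
  dip <- acos(R / (R + h))
  delta <- (row_px - geom$horizon_row_px) *
    (geom$camera_vfov_deg * pi / 180) / geom$image_height_px
  if (any(delta <= 0))
    stop_cfg("pixel row at or above the horizon row: no sea-surface intersection")
  if (any(delta > geom$camera_vfov_deg * pi / 180))
    stop_cfg("depression angle exceeds the vertical field of view")
  beta <- delta + dip
  gamma_h <- acos(R / (R + h))  # central angle to the horizon point
  vapply(beta, function(b) {
    f <- function(g) tan(b) - ((R + h) - R * cos(g)) / (R * sin(g))
    # f is decreasing in gamma; the root on (0, gamma_h] is unique
    R * stats::uniroot(f, c(1e-12, gamma_h), tol = 1e-13)$root
  }, numeric(1))
}

#' Convert an image pixel column to a true azimuth
#'
#' Linear interpolation between the calibrated true bearings of the left and
#' right image edges.
#'
#' @param col_px pixel column(s), 0 to width - 1 (0 at the left edge).
#' @param geom a \code{\link{survey_geometry}}.
#' @return bearing(s) in degrees true.
#' @export
pixel_to_azimuth <- function(col_px, geom) {
  stopifnot(inherits(geom, "survey_geometry"))
  if (any(col_px < 0 | col_px >= geom$image_width_px))
    stop_cfg("pixel column outside the image")
  e <- geom$camera_edge_azimuths_deg
  e[1] + col_px / (geom$image_width_px - 1L) * (e[2] - e[1])
}

#' Project a range and bearing from an origin to a geographic position
#'
#' Great-circle forward solution on a spherical earth, matching the
#' bearing/distance convention of the shore-based sighting records.
#'
#' @param origin numeric length-2 (lat, lon), decimal degrees.
#' @param range_m surface distance, metres (>= 0).
#' @param bearing_deg true bearing, degrees clockwise from north.
#' @param earth_radius_m earth radius, metres.
#' @return numeric length-2 (lat, lon) or a matrix for vector input.
#' @export
range_bearing_to_position <- function(origin, range_m, bearing_deg,
                                      earth_radius_m = 6371000) {
  if (any(range_m < 0)) stop_cfg("range must be >= 0")
  # geosphere works lon-first
  p <- geosphere::destPoint(c(origin[2], origin[1]), bearing_deg, range_m,
                            r = earth_radius_m)
  out <- cbind(lat = p[, 2], lon = p[, 1])
  if (nrow(out) == 1L) out[1, ] else out
}

#' Recover range and bearing between two positions (spherical earth)
#'
#' Inverse of \code{\link{range_bearing_to_position}}.
#'
#' @param origin,target numeric length-2 (lat, lon), decimal degrees.
#' @param earth_radius_m earth radius, metres.
#' @return list with \code{range_m} and \code{bearing_deg}.
#' @export
position_to_range_bearing <- function(origin, target,
                                      earth_radius_m = 6371000) {
  o <- c(origin[2], origin[1]); t <- c(target[2], target[1])
  list(range_m = geosphere::distCosine(o, t, r = earth_radius_m),
       bearing_deg = (geosphere::bearing(o, t) + 360) %% 360)
}

#' Mean transit time through the camera field of view
#'
#' The search area of a narrow-angle camera is a wedge; a whale crossing it at
#' range \eqn{r} travels the arc length \eqn{2\pi r \cdot \mathrm{hfov}/360}.
#' Averaging over the offshore distribution of sighted whales gives
#' \deqn{\bar t_{SA} = 2\pi\frac{\mathrm{hfov}}{360}
#'   \sum_j \frac{n_W(r_j)}{\sum_j n_W(r_j)} \frac{r_j}{s}.}
#'
#' @param dist an \code{\link{offshore_distribution}} (or any list with
#'   \code{ranges_m} and \code{weights}).
#' @param speed_mps swimming speed, m/s (> 0).
#' @param hfov_deg horizontal field of view, degrees.
#' @return a \code{transit_time} object (minutes; see
#'   \code{\link{transit_time}}).
#' @export
camera_transit_time <- function(dist, speed_mps = 1.6, hfov_deg = 6.2) {
  if (length(dist$ranges_m) == 0L || sum(dist$weights) <= 0)
    stop_cfg("offshore distribution is empty")
  check_number(speed_mps, "speed_mps", 0, strict_lower = TRUE)
  w <- dist$weights / sum(dist$weights)
  secs <- 2 * pi * (hfov_deg / 360) * sum(w * dist$ranges_m / speed_mps)
  transit_time(secs / 60, "camera")
}

#' Mean transit time through the hydrophone array
#'
#' Distance through the array divided by the mean swimming speed.
#'
#' @param geom a \code{\link{survey_geometry}}, or a number taken as the
#'   transit distance in metres.
#' @param speed_mps swimming speed, m/s (> 0).
#' @return a \code{transit_time} object (minutes).
#' @export
acoustic_transit_time <- function(geom, speed_mps = 1.6) {
  d <- if (inherits(geom, "survey_geometry")) geom$array_transit_distance_m
       else as.numeric(geom)
  check_number(speed_mps, "speed_mps", 0, strict_lower = TRUE)
  if (d < 0) stop_cfg("transit distance must be >= 0")
  transit_time(d / speed_mps / 60, "acoustic")
}

#' Transit time through a sensor search area
#'
#' @param value_minutes transit time in minutes.
#' @param search_area_label \code{"acoustic"} or \code{"camera"}.
#' @return a \code{transit_time} object.
#' @export
transit_time <- function(value_minutes, search_area_label) {
  search_area_label <- match.arg(search_area_label, c("acoustic", "camera"))
  structure(list(value_minutes = value_minutes,
                 search_area_label = search_area_label),
            class = "transit_time")
}

#' @export
print.transit_time <- function(x, ...) {
  cat(sprintf("Transit time (%s search area): %.3f min\n",
              x$search_area_label, x$value_minutes))
  invisible(x)
}

# transit time in an arbitrary unit
transit_in_unit <- function(t_sa, unit = c("day", "hour", "minute")) {
  unit <- match.arg(unit)
  m <- if (inherits(t_sa, "transit_time")) t_sa$value_minutes
       else as.numeric(t_sa)
  switch(unit, day = m / 1440, hour = m / 60, minute = m)
}
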