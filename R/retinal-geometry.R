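# Hemispherical retinal coordinates. The flattened retina is modelled as an
# azimuthal-equidistant projection of a hemisphere: latitude is linear in
# the normalised radial distance from the optic nerve head (ONH, latitude
# -pi/2) out to the rim (latitude 0); longitude is measured so that the
# dorsal direction is always pi/2, with 0 temporal for left eyes and nasal
# for right eyes. Right-eye coordinates can be mirrored into a common
# left-eye space.
#
# Planar inputs use image conventions: x right, y down, angles measured
# from +x toward +y (clockwise on screen).

#' Map a planar flat-mount position to retinal geographic coordinates
#'
#' @param xy_um planar position `(x, y)` in micrometres (y-down image
#'   frame).
#' @param onh_um ONH position in the same frame.
#' @param rim_um distance from ONH to the retinal rim (um).
#' @param dorsal_deg planar direction of dorsal, degrees from +x toward +y.
#' @param eye `"left"` or `"right"`.
#' @param phi0_deg rim angle of the hemisphere used during dissection
#'   reconstruction; carried for provenance, unused by the simplified
#'   azimuthal-equidistant model.
#' @return a `retinal_coordinate`: list `lat_rad` in `[-pi/2, 0]`,
#'   `lon_rad` in `[0, 2*pi)`, `eye`, `source_um`.
#' @export
map_to_sphere <- function(xy_um, onh_um, rim_um, dorsal_deg = 90,
                          eye = c("left", "right"), phi0_deg = 22) {
  eye <- match.arg(eye)
  stopifnot(rim_um > 0)
  rel <- c(xy_um[1] - onh_um[1], xy_um[2] - onh_um[2])
  r <- sqrt(sum(rel^2))
  if (r > rim_um * (1 + 1e-9)) stop("point beyond rim")
  lat <- (r / rim_um - 1) * pi / 2
  alpha <- atan2(rel[2], rel[1])
  ad <- dorsal_deg * pi / 180
  lon <- if (eye == "left") pi / 2 - (alpha - ad) else pi / 2 + (alpha - ad)
  if (r == 0) lon <- 0  # longitude undefined at the pole
  structure(list(lat_rad = lat, lon_rad = lon %% (2 * pi), eye = eye,
                 source_um = c(x = xy_um[1], y = xy_um[2])),
            class = "retinal_coordinate")
}

#' Inverse of [map_to_sphere()] (planar position from coordinates)
#' @param coord a `retinal_coordinate`.
#' @inheritParams map_to_sphere
#' @return planar `(x, y)` in micrometres.
#' @export
map_from_sphere <- function(coord, onh_um, rim_um, dorsal_deg = 90) {
  r <- (coord$lat_rad / (pi / 2) + 1) * rim_um
  ad <- dorsal_deg * pi / 180
  alpha <- if (coord$eye == "left") ad - (coord$lon_rad - pi / 2) else
    ad + (coord$lon_rad - pi / 2)
  c(onh_um[1] + r * cos(alpha), onh_um[2] + r * sin(alpha))
}

#' Mirror a right-eye coordinate into the common left-eye space
#'
#' Longitude is reflected about the dorsal-ventral axis
#' (`lambda -> pi - lambda`), which fixes dorsal (pi/2) and maps right-eye
#' nasal (0) onto left-eye nasal (pi); latitude is unchanged. Left-eye
#' coordinates pass through untouched. Applying the right-eye mirror twice
#' returns the original longitude.
#'
#' @param coord a `retinal_coordinate`.
#' @return a `retinal_coordinate` in left-eye space (`eye = "left"` for
#'   mirrored inputs).
#' @export
harmonize_eye <- function(coord) {
  if (identical(coord$eye, "left")) return(coord)
  out <- coord
  out$lon_rad <- (pi - coord$lon_rad) %% (2 * pi)
  out$eye <- "left"
  out
}

#' @export
print.retinal_coordinate <- function(x, ...) {
  cat(sprintf("retinal_coordinate: lat %.4f rad (%.1f deg), lon %.4f rad (%.1f deg), %s eye\n",
              x$lat_rad, x$lat_rad * 180 / pi, x$lon_rad,
              x$lon_rad * 180 / pi, x$eye))
  invisible(x)
}

#' Map a table of cell positions to retinal coordinates
#'
#' Vectorised convenience over [map_to_sphere()] and [harmonize_eye()]:
#' takes a data.frame with columns `cell_id, x_um, y_um, eye, onh_x, onh_y,
#' rim_dist_um, dorsal_angle_deg` and appends `lat_rad`, `lon_rad`
#' (harmonised to left-eye space).
#'
#' @param df input data.frame.
#' @param harmonize mirror right eyes into left-eye space (default TRUE).
#' @return the data.frame with `lat_rad`, `lon_rad` appended.
#' @export
map_cell_table <- function(df, harmonize = TRUE) {
  need <- c("cell_id", "x_um", "y_um", "eye", "onh_x", "onh_y",
            "rim_dist_um", "dorsal_angle_deg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  lat <- lon <- numeric(nrow(df))
  for (i in seq_len(nrow(df))) {
    co <- map_to_sphere(c(df$x_um[i], df$y_um[i]),
                        c(df$onh_x[i], df$onh_y[i]),
                        df$rim_dist_um[i], df$dorsal_angle_deg[i],
                        df$eye[i])
    if (harmonize) co <- harmonize_eye(co)
    lat[i] <- co$lat_rad; lon[i] <- co$lon_rad
  }
  df$lat_rad <- lat; df$lon_rad <- lon
  df
}

#' Quadratic eccentricity trend of a morphology parameter
#'
#' Ordinary least-squares fit of `value ~ a * lat^2 + b * lat + c`. The
#' curvature sign reports "negative" (mid-retina maximum), "positive"
#' (mid-retina minimum) or "flat" when `|a|` falls below a tolerance scaled
#' to the data.
#'
#' @param values numeric vector.
#' @param latitudes numeric vector (radians), >= 3 distinct values.
#' @param flat_tol curvature magnitude treated as flat, as a multiple of
#'   `sd(values)` (default 1e-6).
#' @return a `trend_fit`: list `a`, `b`, `c`, `curvature`, `residual_sd`,
#'   `n`.
#' @export
eccentricity_trend <- function(values, latitudes, flat_tol = 1e-6) {
  stopifnot(length(values) == length(latitudes))
  keep <- is.finite(values) & is.finite(latitudes)
  values <- values[keep]; latitudes <- latitudes[keep]
  if (length(unique(latitudes)) < 3) {
    stop("rank-deficient design: need >= 3 distinct latitudes")
  }
  fit <- stats::lm(values ~ latitudes + I(latitudes^2))
  cf <- stats::coef(fit)
  a <- unname(cf[3]); b <- unname(cf[2]); cc <- unname(cf[1])
  scale <- max(stats::sd(values), .Machine$double.eps)
  curv <- if (abs(a) < flat_tol * scale) "flat" else
    if (a < 0) "negative" else "positive"
  structure(list(a = a, b = b, c = cc, curvature = curv,
                 residual_sd = stats::sd(stats::residuals(fit)),
                 n = length(values)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("trend_fit: value = %.4g*lat^2 + %.4g*lat + %.4g (%s curvature, n=%d)\n",
              x$a, x$b, x$c, x$curvature, x$n))
  invisible(x)
}
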