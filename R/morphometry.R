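# Per-cell shape descriptors over the full outline (FO) and its convex hull
# (CVH), plus marker-coverage and soma-displacement measurements.
#
# Measurement conventions (shared with the supersampled ground truth of the
# synthetic generator; see the methods vignette):
#   area       : pixel count (crack-boundary area, exact in pixels)
#   perimeter  : traced 8-chain boundary polygon after one corner-cut pass,
#                diagonal steps at Euclidean weight; holes included
#   Feret/hull : convex hull of boundary-pixel corners (centre +- 0.5 px)
#   solidity   : pixel count of region / pixel count of rasterised hull
#   ellipse    : second central moments (with the 1/12 px^2 cover term),
#                axes scaled so the ellipse area matches the region area

#' Boundary-pixel corner points of an outline
#' @keywords internal
boundary_corners <- function(poly) {
  rbind(cbind(poly[, 1] - 0.5, poly[, 2] - 0.5),
        cbind(poly[, 1] + 0.5, poly[, 2] - 0.5),
        cbind(poly[, 1] - 0.5, poly[, 2] + 0.5),
        cbind(poly[, 1] + 0.5, poly[, 2] + 0.5))
}

#' Maximum and minimum Feret diameter of a cell outline
#'
#' Maximum Feret is the largest caliper distance across the outline,
#' computed by rotating calipers on the convex hull of the boundary-pixel
#' corners; minimum Feret is the smallest projection width over
#' orientations.
#'
#' @param outline a [cell_outline()], a logical mask matrix (then `px_um`
#'   must be given), or a two-column point matrix in pixel units.
#' @param px_um pixel size when `outline` is a mask or points.
#' @return list `max_um`, `min_um`, `angle_deg`.
#' @export
feret_diameter <- function(outline, px_um = NULL) {
  if (inherits(outline, "cell_outline")) {
    pts <- boundary_corners(outline$outer)
    px <- outline$px_um
  } else if (is.matrix(outline) && is.logical(outline)) {
    if (is.null(px_um)) stop("px_um required for a mask input")
    pts <- boundary_corners(trace_boundary(outline))
    px <- px_um
  } else {
    pts <- as.matrix(outline)
    if (nrow(pts) < 2) {
      px <- px_um %||% 1
      return(list(max_um = sqrt(2) * px, min_um = sqrt(2) * px, angle_deg = 45))
    }
    px <- px_um %||% 1
  }
  f <- feret_calipers(convex_hull(pts))
  list(max_um = f$max * px, min_um = f$min * px, angle_deg = f$angle_deg)
}

#' Moment-matched ellipse fit of a region
#'
#' Returns the axes of the ellipse sharing the region's second central
#' moments, rescaled so the ellipse area equals the region area, in the
#' convention of standard particle analysis.
#'
#' @param outline a [cell_outline()] or logical mask.
#' @param px_um pixel size when a mask is supplied.
#' @return list `major_um`, `minor_um`, `angle_deg` (y-up convention).
#' @export
fit_ellipse <- function(outline, px_um = NULL) {
  if (inherits(outline, "cell_outline")) {
    mask <- outline$mask; px <- outline$px_um
  } else {
    mask <- outline; px <- px_um %||% 1
  }
  xy <- idx_to_xy(which(mask), nrow(mask))
  n <- nrow(xy)
  if (n == 0) stop("zero-area outline")
  mx <- mean(xy[, 1]); my <- mean(xy[, 2])
  # raw point moments detect collinear regions before the pixel-cover term
  rxx <- sum((xy[, 1] - mx)^2) / n
  ryy <- sum((xy[, 2] - my)^2) / n
  cxy <- sum((xy[, 1] - mx) * (xy[, 2] - my)) / n
  if (rxx * ryy - cxy^2 <= .Machine$double.eps * max(rxx, ryy, 1)) {
    warning("collinear region: minor axis is zero")
    major <- 4 * sqrt(max(rxx + ryy, 0))
    return(list(major_um = major * px, minor_um = 0,
                angle_deg = -0.5 * atan2(2 * cxy, rxx - ryy) * 180 / pi))
  }
  # central moments with the 1/12 term for the unit-square pixel footprint
  cxx <- rxx + 1 / 12
  cyy <- ryy + 1 / 12
  tr <- cxx + cyy
  det <- cxx * cyy - cxy^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  major <- 4 * sqrt(max(l1, 0)); minor <- 4 * sqrt(max(l2, 0))
  # scale so pi/4 * major * minor equals the pixel area
  if (minor > 0) {
    s <- sqrt(n / (pi / 4 * major * minor))
    major <- major * s; minor <- minor * s
  }
  ang <- if (abs(cxy) < 1e-12 && cxx >= cyy) 0
         else 0.5 * atan2(2 * cxy, cxx - cyy) * 180 / pi
  list(major_um = major * px, minor_um = minor * px, angle_deg = -ang)
}

#' Rasterised convex hull (pixel-centre hull) of an outline
#'
#' The hull is taken over boundary-pixel centres; a frame pixel belongs to
#' the rasterised hull if its centre falls inside the hull polygon or if it
#' belongs to the (hole-filled) region itself, which guarantees
#' `CVH area >= FO area` and keeps the estimator unbiased across
#' resolutions.
#' @keywords internal
hull_raster_count <- function(outline) {
  hull <- convex_hull(outline$outer)
  hull_loc <- cbind(hull[, 1] - outline$offset[1], hull[, 2] - outline$offset[2])
  ny <- nrow(outline$mask); nx <- ncol(outline$mask)
  gx <- rep(seq_len(nx), each = ny)
  gy <- rep(seq_len(ny), times = nx)
  ins <- matrix(FALSE, ny, nx)
  ins[cbind(gy, gx)] <- points_in_polygon(gx, gy, hull_loc)
  filled <- outline$mask | (hole_components(outline$mask) > 0)
  sum(ins | filled)
}

#' Full shape-descriptor set for one cell
#'
#' Computes the full-outline (FO) and convex-hull (CVH) measurement set:
#' areas, perimeters, fitted-ellipse axes, circularity
#' (`4 pi area / perimeter^2`), roundness (`4 area / (pi major^2)`),
#' solidity (`area / CVH area`), maximum Feret diameter, geometric CVH
#' centroid, intensity-weighted centre of mass, their separation, and the
#' percentage of the outline covered by a marker mask.
#'
#' @param outline a [cell_outline()].
#' @param intensity optional full-frame intensity matrix (projected
#'   membrane channel) used for the centre of mass; geometric centroid is
#'   used when absent.
#' @param marker optional full-frame logical mask (e.g. binarised GFAP);
#'   coverage is measured inside the outline.
#' @return one-row `data.frame` with the fields of the shape-metric set, in
#'   micrometre units.
#' @export
shape_metrics <- function(outline, intensity = NULL, marker = NULL) {
  stopifnot(inherits(outline, "cell_outline"))
  px <- outline$px_um
  npx <- sum(outline$mask)
  if (npx == 0) stop("zero-area outline")
  fo_area <- npx * px^2
  per_px <- polygon_length(smooth_closed_polygon(outline$outer))
  for (h in outline$holes) per_px <- per_px + polygon_length(smooth_closed_polygon(h))
  fo_perim <- per_px * px

  ell <- fit_ellipse(outline)
  fer <- feret_diameter(outline)

  hull <- convex_hull(outline$outer)
  cvh_px <- hull_raster_count(outline)
  cvh_area <- cvh_px * px^2
  cvh_perim <- polygon_length(hull) * px
  cvh_centroid <- polygon_centroid(hull) * px

  circ <- min(4 * pi * fo_area / fo_perim^2, 1)
  roundness <- if (ell$major_um > 0) min(4 * fo_area / (pi * ell$major_um^2), 1) else NA_real_
  solidity <- min(npx / cvh_px, 1)

  xy <- idx_to_xy(which(outline$mask), nrow(outline$mask))
  xy_abs <- cbind(xy[, 1] + outline$offset[1], xy[, 2] + outline$offset[2])
  if (is.null(intensity)) {
    com <- colMeans(xy_abs) * px
  } else {
    w <- intensity[xy_to_idx(xy_abs[, 1], xy_abs[, 2], nrow(intensity))]
    if (sum(w) <= 0) w <- rep(1, length(w))
    com <- c(sum(xy_abs[, 1] * w), sum(xy_abs[, 2] * w)) / sum(w) * px
  }
  d_com <- pt_dist(cvh_centroid, com)

  pct_marker <- NA_real_
  if (!is.null(marker)) {
    inm <- marker[xy_to_idx(xy_abs[, 1], xy_abs[, 2], nrow(marker))]
    pct_marker <- 100 * sum(inm) / npx
  }

  data.frame(
    fo_area_um2 = fo_area, fo_perimeter_um = fo_perim,
    fo_major_axis_um = ell$major_um, fo_minor_axis_um = ell$minor_um,
    fo_circularity = circ, fo_feret_um = fer$max_um,
    fo_roundness = roundness, fo_solidity = solidity,
    cvh_area_um2 = cvh_area, cvh_perimeter_um = cvh_perim,
    cvh_feret_um = fer$max_um,
    cvh_centroid_x_um = cvh_centroid[1], cvh_centroid_y_um = cvh_centroid[2],
    com_x_um = com[1], com_y_um = com[2],
    dist_centroid_com_um = d_com,
    pct_marker = pct_marker
  )
}

#' Displacement between the soma and the convex-hull centroid
#'
#' @param outline a [cell_outline()].
#' @param soma_um soma centroid `(x, y)` in micrometres (frame coordinates).
#' @param frame_dim optional frame dimensions `c(ny, nx)` in pixels used to
#'   validate that the soma lies inside the image.
#' @return list `soma_um`, `cvh_centroid_um`, `distance_um`.
#' @export
soma_displacement <- function(outline, soma_um, frame_dim = NULL) {
  stopifnot(inherits(outline, "cell_outline"))
  px <- outline$px_um
  if (!is.null(frame_dim)) {
    sp <- soma_um / px
    if (sp[1] < 0.5 || sp[2] < 0.5 || sp[1] > frame_dim[2] + 0.5 ||
        sp[2] > frame_dim[1] + 0.5) {
      stop("soma centroid lies outside the image")
    }
  }
  hull <- convex_hull(outline$outer)
  cen <- polygon_centroid(hull) * px
  list(soma_um = soma_um, cvh_centroid_um = cen,
       distance_um = pt_dist(cen, soma_um))
}
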