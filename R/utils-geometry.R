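# Planar geometry primitives shared across modules.
#
# Conventions: a polygon is a two-column matrix (x, y) of vertices, implicitly
# closed. Pixel centres sit at integer coordinates, x = column, y = row,
# y increasing downward (image convention).

#' Signed area of a closed polygon (shoelace formula)
#'
#' Positive for counter-clockwise vertex order in a y-up frame; callers that
#' only need magnitude should take `abs()`.
#'
#' @param xy two-column matrix of vertices.
#' @return signed area (units of the coordinates squared).
#' @keywords internal
shoelace_area <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Perimeter of a (closed) polygon
#' @param xy two-column vertex matrix.
#' @param closed close the ring (default TRUE).
#' @keywords internal
polygon_length <- function(xy, closed = TRUE) {
  n <- nrow(xy)
  if (is.null(n) || n < 2) return(0)
  if (closed) xy <- rbind(xy, xy[1, , drop = FALSE])
  sqrt(rowSums(diff(xy)^2)) |> sum()
}

#' Centroid of a simple closed polygon
#' @keywords internal
polygon_centroid <- function(xy) {
  n <- nrow(xy)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(xy))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

#' One corner-cutting (midpoint) pass over a closed polygon
#'
#' Replaces the ring by the midpoints of consecutive vertices. Applied to a
#' traced 8-connected pixel-centre chain this removes most of the staircase
#' length bias while keeping diagonal steps at their Euclidean (sqrt 2) weight.
#' @keywords internal
smooth_closed_polygon <- function(xy, passes = 1) {
  for (i in seq_len(passes)) {
    n <- nrow(xy)
    if (n < 3) return(xy)
    xy <- (xy + xy[c(2:n, 1), , drop = FALSE]) / 2
  }
  xy
}

#' Convex hull of a point set, counter-clockwise vertex order
#'
#' Wraps [grDevices::chull()]; vertices are returned in counter-clockwise
#' order in a y-up frame (clockwise on screen with y-down).
#' @keywords internal
convex_hull <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) <= 2) return(xy)
  idx <- grDevices::chull(xy[, 1], xy[, 2])
  h <- xy[idx, , drop = FALSE]
  if (shoelace_area(h) < 0) h <- h[rev(seq_len(nrow(h))), , drop = FALSE]
  h
}

#' Maximum and minimum Feret diameter of a convex polygon
#'
#' Maximum caliper distance via the rotating-calipers antipodal-pair walk;
#' minimum Feret as the smallest width over directions normal to hull edges.
#'
#' @param hull counter-clockwise convex polygon (two-column matrix).
#' @return list with `max`, `min`, `angle_deg` (orientation of the maximum
#'   caliper, degrees in (-90, 90], measured y-up).
#' @keywords internal
feret_calipers <- function(hull) {
  m <- nrow(hull)
  if (m == 1) return(list(max = 0, min = 0, angle_deg = 0))
  if (m == 2) {
    d <- hull[2, ] - hull[1, ]
    return(list(max = sqrt(sum(d^2)), min = 0,
                angle_deg = atan2(-d[2], d[1]) * 180 / pi))
  }
  nxt <- function(i) i %% m + 1L
  cross2 <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  # area of triangle (i, nxt(i), j) is unimodal in j: advance antipodal point
  best <- 0; best_pair <- c(1L, 1L)
  j <- 2L
  for (i in seq_len(m)) {
    i2 <- nxt(i)
    repeat {
      j2 <- nxt(j)
      if (abs(cross2(hull[i, ], hull[i2, ], hull[j2, ])) >
          abs(cross2(hull[i, ], hull[i2, ], hull[j, ]))) j <- j2 else break
    }
    for (cand in c(i, i2)) {
      d2 <- sum((hull[cand, ] - hull[j, ])^2)
      if (d2 > best) { best <- d2; best_pair <- c(cand, j) }
    }
  }
  dvec <- hull[best_pair[2], ] - hull[best_pair[1], ]
  # minimum width: for each edge, the farthest vertex distance to its line
  wmin <- Inf
  for (i in seq_len(m)) {
    e <- hull[nxt(i), ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < .Machine$double.eps) next
    nrm <- c(-e[2], e[1]) / len
    d <- abs((hull[, 1] - hull[i, 1]) * nrm[1] + (hull[, 2] - hull[i, 2]) * nrm[2])
    wmin <- min(wmin, max(d))
  }
  ang <- atan2(-dvec[2], dvec[1]) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  list(max = sqrt(best), min = wmin, angle_deg = ang)
}

#' Test points against a (possibly non-convex) polygon, even-odd rule
#'
#' Vectorised over points; boundary points count as inside (within `eps`).
#' @keywords internal
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, seq_len(n - 1))
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    jj <- j[k]
    yk <- y[k]; yj <- y[jj]; xk <- x[k]; xj <- x[jj]
    crosses <- ((yk > py) != (yj > py))
    if (any(crosses)) {
      xint <- xk + (py[crosses] - yk) * (xj - xk) / (yj - yk)
      flip <- xint > px[crosses]
      inside[crosses] <- xor(inside[crosses], flip)
    }
  }
  inside
}

#' Rasterise polygons onto a pixel grid
#'
#' @param polys list of two-column matrices (outer rings).
#' @param holes list of two-column matrices subtracted from the union.
#' @param nx,ny grid size in pixels.
#' @param scale multiply coordinates by this factor before rasterising
#'   (supersampling uses `scale > 1` together with a proportionally larger
#'   grid).
#' @return logical matrix `[ny, nx]`, `m[y, x]`.
#' @keywords internal
rasterize_polygons <- function(polys, holes = list(), nx, ny, scale = 1) {
  if (!is.list(polys)) polys <- list(polys)
  m <- matrix(FALSE, ny, nx)
  fill_one <- function(poly) {
    poly <- poly * scale
    xr <- range(poly[, 1]); yr <- range(poly[, 2])
    x0 <- max(1L, floor(xr[1])); x1 <- min(nx, ceiling(xr[2]))
    y0 <- max(1L, floor(yr[1])); y1 <- min(ny, ceiling(yr[2]))
    if (x0 > x1 || y0 > y1) return(NULL)
    gx <- rep(x0:x1, times = y1 - y0 + 1)
    gy <- rep(y0:y1, each = x1 - x0 + 1)
    ins <- points_in_polygon(gx, gy, poly)
    list(x = gx[ins], y = gy[ins])
  }
  for (p in polys) {
    f <- fill_one(p)
    if (!is.null(f) && length(f$x)) m[cbind(f$y, f$x)] <- TRUE
  }
  for (h in holes) {
    f <- fill_one(h)
    if (!is.null(f) && length(f$x)) m[cbind(f$y, f$x)] <- FALSE
  }
  m
}

#' Euclidean distance between two points given as length-2 vectors
#' @keywords internal
pt_dist <- function(a, b) sqrt(sum((a - b)^2))
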