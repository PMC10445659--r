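# Outline extraction: standard-deviation projection, global and Phansalkar
# local thresholding, particle filtering, and XOR composition of complex cell
# outlines with holes.

#' Standard-deviation Z-projection
#'
#' Collapses a Z-stack to a 2D image whose pixels hold the sample standard
#' deviation (n-1 denominator) of the voxel column. Membrane-label stacks
#' projected this way show labelled structure as positive values and empty
#' space as zero.
#'
#' @param stack an `astro_stack` (see [render_flatmount()]) or a 3D numeric
#'   array `[y, x, z]`.
#' @param channel channel name when `stack` is an `astro_stack`.
#' @return a `projected_image`: list with `data` (matrix), `px_um`,
#'   `channel`, `method`.
#' @export
project_std <- function(stack, channel = NULL) {
  if (inherits(stack, "astro_stack")) {
    if (is.null(channel)) stop("channel must be named for an astro_stack")
    arr <- stack$channels[[channel]]
    if (is.null(arr)) stop("no such channel: ", channel)
    px <- stack$px_um
  } else {
    arr <- stack
    px <- attr(stack, "px_um") %||% NA_real_
  }
  if (length(dim(arr)) != 3 || dim(arr)[3] < 2) {
    stop("projection requires >=2 planes")
  }
  nz <- dim(arr)[3]
  s1 <- rowSums(arr, dims = 2)
  s2 <- rowSums(arr^2, dims = 2)
  v <- (s2 - s1^2 / nz) / (nz - 1)
  out <- list(data = sqrt(pmax(v, 0)), px_um = px,
              channel = channel %||% NA_character_, method = "sd")
  class(out) <- "projected_image"
  out
}

#' @export
print.projected_image <- function(x, ...) {
  cat(sprintf("projected_image [%d x %d] channel=%s method=%s px=%s um\n",
              nrow(x$data), ncol(x$data), x$channel, x$method,
              format(x$px_um)))
  invisible(x)
}

img_data <- function(image) {
  if (inherits(image, "projected_image")) image$data else as.matrix(image)
}

#' Global automatic threshold
#'
#' Binarises an image with a histogram-based global threshold. The default
#' method is Otsu's criterion on a 256-bin histogram of the min-max
#' normalised image.
#'
#' @param image `projected_image` or numeric matrix.
#' @param method `"otsu"` (default) or `"mean"`.
#' @return logical matrix; foreground is `TRUE`. The threshold used (on the
#'   normalised scale) is attached as attribute `"threshold"`.
#' @export
threshold_global <- function(image, method = c("otsu", "mean")) {
  method <- match.arg(method)
  m <- img_data(image)
  rg <- range(m)
  if (diff(rg) <= 0) stop("degenerate histogram: image is constant")
  norm <- (m - rg[1]) / diff(rg)
  t <- switch(method,
    otsu = EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256),
    mean = mean(norm))
  mask <- norm > t
  attr(mask, "threshold") <- t
  mask
}

#' Phansalkar adaptive local threshold
#'
#' Binarises an image with the Phansalkar criterion designed for
#' low-contrast stained images: a pixel (value `v`, min-max normalised to
#' `[0, 1]`) is foreground iff
#' `v > m * (1 + p * exp(-q * m) + k * (s / r - 1))`,
#' where `m` and `s` are the local mean and (population) standard deviation
#' in a circular window of the given radius. Borders are handled by
#' symmetric (mirror) padding.
#'
#' @param image `projected_image` or numeric matrix.
#' @param radius window radius in pixels (default 15).
#' @param k,r,p,q Phansalkar constants (defaults 0.25, 0.5, 2, 10).
#' @return logical matrix with the local threshold map attached as attribute
#'   `"threshold"`.
#' @export
threshold_phansalkar <- function(image, radius = 15, k = 0.25, r = 0.5,
                                 p = 2, q = 10) {
  m0 <- img_data(image)
  ny <- nrow(m0); nx <- ncol(m0)
  if (radius < 1) stop("radius must be >= 1")
  if (radius >= ny || radius >= nx) stop("radius larger than image")
  rg <- range(m0)
  norm <- if (diff(rg) > 0) (m0 - rg[1]) / diff(rg) else m0 * 0
  # symmetric padding (edge pixel duplicated)
  ys <- c(radius:1, 1:ny, ny:(ny - radius + 1))
  xs <- c(radius:1, 1:nx, nx:(nx - radius + 1))
  padded <- norm[ys, xs]
  off <- disk_offsets(radius)
  nw <- nrow(off)
  s1 <- matrix(0, ny, nx); s2 <- matrix(0, ny, nx)
  for (i in seq_len(nw)) {
    sub <- padded[(radius + off$dy[i]) + seq_len(ny),
                  (radius + off$dx[i]) + seq_len(nx)]
    s1 <- s1 + sub
    s2 <- s2 + sub^2
  }
  mu <- s1 / nw
  sd_loc <- sqrt(pmax(s2 / nw - mu^2, 0))
  thr <- mu * (1 + p * exp(-q * mu) + k * (sd_loc / r - 1))
  mask <- norm > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Extract particles (connected regions and their holes) from a binary mask
#'
#' Foreground components are 8-connected and reported with their holes
#' filled (the outline ROI); interior 4-connected background components are
#' reported as separate hole regions referencing their parent. Regions and
#' holes below the area bound are dropped.
#'
#' @param mask logical matrix.
#' @param px_um pixel size in micrometres per pixel.
#' @param min_area_um2 minimum particle area (default 3).
#' @return list of regions; each has `id`, `idx` (linear pixel indices),
#'   `dim`, `area_um2`, `is_hole`, `parent`, `centroid_px` (x, y).
#' @export
extract_particles <- function(mask, px_um, min_area_um2 = 3) {
  stopifnot(px_um > 0)
  dm <- dim(mask)
  lab <- label_components(mask, 8)
  k <- max(lab)
  regions <- list()
  next_id <- 1L
  for (comp in seq_len(k)) {
    idx <- which(lab == comp)
    # fill holes of this component to get the outline ROI
    sub <- matrix(FALSE, dm[1], dm[2]); sub[idx] <- TRUE
    holes <- hole_components(sub)
    filled_idx <- sort(c(idx, which(holes > 0)))
    area <- length(filled_idx) * px_um^2
    if (area < min_area_um2) next
    xy <- idx_to_xy(filled_idx, dm[1])
    rid <- next_id; next_id <- next_id + 1L
    regions[[length(regions) + 1L]] <- list(
      id = rid, idx = filled_idx, dim = dm, area_um2 = area,
      is_hole = FALSE, parent = NA_integer_,
      centroid_px = c(mean(xy[, 1]), mean(xy[, 2])))
    nh <- max(holes)
    for (hh in seq_len(nh)) {
      hidx <- which(holes == hh)
      harea <- length(hidx) * px_um^2
      if (harea < min_area_um2) next
      hxy <- idx_to_xy(hidx, dm[1])
      hid <- next_id; next_id <- next_id + 1L
      regions[[length(regions) + 1L]] <- list(
        id = hid, idx = hidx, dim = dm, area_um2 = harea,
        is_hole = TRUE, parent = rid,
        centroid_px = c(mean(hxy[, 1]), mean(hxy[, 2])))
    }
  }
  regions
}

#' Construct a cell outline object from a full-frame mask
#'
#' Crops to the bounding box, traces the outer boundary and hole boundaries,
#' and stores pixel size. If the mask has several 8-connected components the
#' largest is kept with a warning. Holes below the particle area bound are
#' filled: a hole ROI below the bound is never selected in the reference
#' outline workflow, so it belongs to the cell.
#'
#' @param mask logical matrix (full frame).
#' @param px_um pixel size (um/px).
#' @param min_hole_area_um2 holes smaller than this are filled (default 3,
#'   the particle bound).
#' @return a `cell_outline`: `mask` (cropped), `offset` (x0, y0 such that
#'   cropped pixel (1,1) is frame pixel (x0+1, y0+1)), `px_um`, `outer`
#'   (boundary polygon, frame coordinates), `holes` (list of polygons).
#' @export
cell_outline <- function(mask, px_um, min_hole_area_um2 = 3) {
  if (!any(mask)) stop("empty mask")
  lab <- label_components(mask, 8)
  if (max(lab) > 1) {
    warning("outline mask is disconnected; keeping largest component")
    sizes <- tabulate(lab[lab > 0])
    mask <- lab == which.max(sizes)
  }
  mask <- fill_small_holes(mask, min_hole_area_um2 / px_um^2)
  xy <- idx_to_xy(which(mask), nrow(mask))
  x0 <- min(xy[, 1]) - 1L; y0 <- min(xy[, 2]) - 1L
  cropped <- mask[(min(xy[, 2])):(max(xy[, 2])), (min(xy[, 1])):(max(xy[, 1])),
                  drop = FALSE]
  outer <- trace_boundary(cropped)
  outer[, 1] <- outer[, 1] + x0; outer[, 2] <- outer[, 2] + y0
  hl <- hole_components(cropped)
  holes <- lapply(seq_len(max(hl)), function(h) {
    b <- trace_boundary(hl == h)
    b[, 1] <- b[, 1] + x0; b[, 2] <- b[, 2] + y0
    b
  })
  out <- list(mask = cropped, offset = c(x0, y0), px_um = px_um,
              outer = outer, holes = holes)
  class(out) <- "cell_outline"
  out
}

#' @export
print.cell_outline <- function(x, ...) {
  cat(sprintf("cell_outline: %d px (%.1f um^2), %d hole(s), px=%g um\n",
              sum(x$mask), sum(x$mask) * x$px_um^2, length(x$holes), x$px_um))
  invisible(x)
}

#' Full-frame logical mask of a cell outline
#' @param outline a `cell_outline`.
#' @param dim frame dimensions `c(ny, nx)`.
#' @return logical matrix.
#' @export
outline_mask <- function(outline, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  ys <- outline$offset[2] + seq_len(nrow(outline$mask))
  xs <- outline$offset[1] + seq_len(ncol(outline$mask))
  m[ys, xs] <- outline$mask
  m
}

#' Compose a complex cell outline by XOR of selected regions
#'
#' The selected region masks (outline ROIs and hole ROIs from
#' [extract_particles()]) are combined by symmetric difference, reproducing
#' the outline/hole composition step: outer ROI XOR hole ROI leaves the
#' annular cell body.
#'
#' @param regions region list from [extract_particles()].
#' @param selected_ids integer ids to combine (at least one non-hole).
#' @param px_um pixel size; defaults to sqrt of region area per pixel.
#' @return a [cell_outline()].
#' @export
compose_outline <- function(regions, selected_ids, px_um) {
  ids <- vapply(regions, function(r) r$id, integer(1))
  sel <- match(selected_ids, ids)
  if (anyNA(sel)) stop("unknown region id(s): ",
                       paste(selected_ids[is.na(sel)], collapse = ", "))
  if (all(vapply(regions[sel], function(r) r$is_hole, logical(1)))) {
    stop("selection must include at least one non-hole region")
  }
  dm <- regions[[sel[1]]]$dim
  acc <- logical(prod(dm))
  for (s in sel) acc[regions[[s]]$idx] <- !acc[regions[[s]]$idx]
  if (!any(acc)) stop("selection yields empty mask")
  # exact symmetric difference: sub-bound holes cannot arise here because
  # the input ROIs are already area-filtered, so no hole filling is applied
  cell_outline(matrix(acc, dm[1], dm[2]), px_um, min_hole_area_um2 = 0)
}

#' Automated region selection at a seed point
#'
#' Stand-in for the interactive ROI selection step: picks the non-hole
#' region whose filled mask contains (or whose centroid is nearest to) the
#' seed point, plus all holes belonging to it.
#'
#' @param regions region list from [extract_particles()].
#' @param point_xy seed point `(x, y)` in pixels.
#' @return integer vector of region ids.
#' @export
select_regions_at <- function(regions, point_xy) {
  outers <- Filter(function(r) !r$is_hole, regions)
  if (!length(outers)) stop("no regions")
  ny <- outers[[1]]$dim[1]
  pidx <- xy_to_idx(round(point_xy[1]), round(point_xy[2]), ny)
  hit <- Filter(function(r) pidx %in% r$idx, outers)
  target <- if (length(hit)) {
    hit[[1]]
  } else {
    d <- vapply(outers, function(r) pt_dist(r$centroid_px, point_xy), numeric(1))
    outers[[which.min(d)]]
  }
  holes <- Filter(function(r) r$is_hole && identical(r$parent, target$id), regions)
  c(target$id, vapply(holes, function(r) r$id, integer(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
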