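# Scene assembly: place cells over the vessel bed, render the five-channel
# stack, and assemble the complete ground-truth record.

#' Filamentous marker subset of a cell mask at a fixed area fraction
#'
#' Emulates an intermediate-filament label that covers only part of the
#' membrane-defined cell: the cell skeleton is dilated inside the mask until
#' the target pixel count is reached, then trimmed (farthest-from-skeleton
#' pixels first) to hit the fraction exactly.
#'
#' @param mask logical cell mask.
#' @param fraction target area fraction in `[0, 1]`.
#' @return logical matrix, subset of `mask`, with
#'   `sum(out) == round(fraction * sum(mask))` whenever attainable.
#' @export
gfap_subset <- function(mask, fraction) {
  target <- round(fraction * sum(mask))
  if (target <= 0) return(mask & FALSE)
  skel <- skeletonize_mask(mask)
  g <- skel & mask
  while (sum(g) < target) {
    g2 <- mask_dilate(g, 1) & mask
    if (sum(g2) == sum(g)) break
    g <- g2
  }
  if (sum(g) > target) {
    dist_to_skel <- edt(!skel)
    gi <- which(g)
    ord <- gi[order(dist_to_skel[gi], gi, decreasing = TRUE)]
    g[ord[seq_len(sum(g) - target)]] <- FALSE
  }
  g
}

masks_touch <- function(c1, c2) {
  # bbox overlap with 1 px adjacency margin
  a1 <- c(c1$offset[1] + 1, c1$offset[1] + ncol(c1$mask),
          c1$offset[2] + 1, c1$offset[2] + nrow(c1$mask))
  a2 <- c(c2$offset[1] + 1, c2$offset[1] + ncol(c2$mask),
          c2$offset[2] + 1, c2$offset[2] + nrow(c2$mask))
  if (a1[1] > a2[2] + 1 || a2[1] > a1[2] + 1 ||
      a1[3] > a2[4] + 1 || a2[3] > a1[4] + 1) return(FALSE)
  x0 <- min(a1[1], a2[1]) - 2L; y0 <- min(a1[3], a2[3]) - 2L
  nx <- max(a1[2], a2[2]) - x0 + 2L; ny <- max(a1[4], a2[4]) - y0 + 2L
  m1 <- matrix(FALSE, ny, nx); m2 <- matrix(FALSE, ny, nx)
  m1[(a1[3]:a1[4]) - y0, (a1[1]:a1[2]) - x0] <- c1$mask
  m2[(a2[3]:a2[4]) - y0, (a2[1]:a2[2]) - x0] <- c2$mask
  any(mask_dilate(m1, 1) & m2)
}

embed_mask <- function(mask, offset, field) {
  m <- matrix(FALSE, field[2], field[1])
  m[offset[2] + seq_len(nrow(mask)), offset[1] + seq_len(ncol(mask))] <- mask
  m
}

paint_line <- function(canvas, p1, p2, width_px, value = 1) {
  ny <- nrow(canvas); nx <- ncol(canvas)
  r <- width_px / 2
  x0 <- max(1L, floor(min(p1[1], p2[1]) - r - 1))
  x1 <- min(nx, ceiling(max(p1[1], p2[1]) + r + 1))
  y0 <- max(1L, floor(min(p1[2], p2[2]) - r - 1))
  y1 <- min(ny, ceiling(max(p1[2], p2[2]) + r + 1))
  if (x0 > x1 || y0 > y1) return(canvas)
  gx <- rep(x0:x1, times = y1 - y0 + 1)
  gy <- rep(y0:y1, each = x1 - x0 + 1)
  d <- point_segment_dist(gx, gy, p1, p2)
  sel <- d <= r
  if (any(sel)) canvas[cbind(gy[sel], gx[sel])] <- value
  canvas
}

#' Render a complete synthetic flat-mount scene
#'
#' Generates the vessel bed, places astrocytes according to the connection
#' class fractions (enveloping cells anchored on vessels, mural cells at
#' branch points), renders the five channels (membrane, GFAP-like subset,
#' vessel, soma, axon/neuronal) as a Z-stack with per-plane intensity
#' modulation and optional additive Gaussian noise, and returns the full
#' ground truth. Cells overlapping another labelled cell are reported with
#' a warning (such cells are excluded from analysis downstream).
#'
#' @param scene a [scene_params()].
#' @return list with `stack` (an `astro_stack`: `channels` as
#'   `[y, x, z]` arrays, `px_um`, `z_um`) and `truth` (a `scene_truth`).
#' @export
render_flatmount <- function(scene) {
  stopifnot(inherits(scene, "scene_params"))
  set.seed(scene$seed)
  nx <- scene$field_px[1]; ny <- scene$field_px[2]
  px <- scene$px_um; nz <- scene$nz
  vt <- generate_vessel_network(scene)

  # --- class allocation (largest remainder) --------------------------------
  fr <- scene$connection_fractions
  n <- scene$n_cells
  raw <- fr * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  classes <- rep(names(counts), counts)

  cells <- list()
  margin <- 30
  used_branch <- integer(0)
  for (i in seq_len(n)) {
    ci <- classes[i]
    placed <- FALSE
    for (attempt in 1:80) {
      area <- stats::runif(1, scene$cell_area_um2[1], scene$cell_area_um2[2])
      # in crowded fields fall back to progressively smaller cells
      if (attempt > 20) area <- area * 0.97^(attempt - 20)
      R0 <- sqrt(area / pi) / px
      if (ci == "enveloping") {
        ok <- which(vt$nodes$x > margin + R0 & vt$nodes$x < nx - margin - R0 &
                    vt$nodes$y > margin + R0 & vt$nodes$y < ny - margin - R0)
        if (!length(ok)) ok <- seq_len(nrow(vt$nodes))
        ndi <- sample(ok, 1)
        ctr <- c(vt$nodes$x[ndi], vt$nodes$y[ndi])
      } else if (ci == "mural") {
        bp <- vt$branch_points
        if (!is.null(bp) && nrow(bp)) {
          avail <- setdiff(seq_len(nrow(bp)), used_branch)
          if (!length(avail)) avail <- seq_len(nrow(bp))
          bi <- if (length(avail) == 1) avail else sample(avail, 1)
          ctr <- c(bp[bi, 1], bp[bi, 2])
        } else {
          ndi <- sample(nrow(vt$nodes), 1)
          ctr <- c(vt$nodes$x[ndi], vt$nodes$y[ndi])
        }
      } else {
        # anchor near (but not on) a vessel so that, as observed, every
        # cell contacts at least one vessel
        ok <- which(vt$nodes$x > margin + R0 & vt$nodes$x < nx - margin - R0 &
                    vt$nodes$y > margin + R0 & vt$nodes$y < ny - margin - R0)
        if (length(ok)) {
          ndi <- if (length(ok) == 1) ok else sample(ok, 1)
          a <- stats::runif(1, 0, 2 * pi)
          # abut the vessel (contact via the cell margin or an end-foot)
          # rather than straddle it
          d <- vt$nodes$radius_um[ndi] / px + stats::runif(1, 0.95, 1.25) * R0
          ctr <- c(vt$nodes$x[ndi] + d * cos(a), vt$nodes$y[ndi] + d * sin(a))
          ctr <- pmin(pmax(ctr, margin + R0), c(nx, ny) - margin - R0)
        } else {
          ctr <- c(stats::runif(1, margin + R0, nx - margin - R0),
                   stats::runif(1, margin + R0, ny - margin - R0))
        }
      }
      motifs <- names(scene$motif_rates)[
        stats::runif(length(scene$motif_rates)) < scene$motif_rates]
      if (ci != "non-enveloping") motifs <- setdiff(motifs, c("end-foot", "hole", "sail"))
      spec <- list(center_px = ctr, area_um2 = area, px_um = px,
                   field_px = c(nx, ny), irregularity = scene$irregularity,
                   n_processes = if (ci == "non-enveloping") scene$n_processes else 1,
                   motifs = motifs, connection = ci,
                   motif_probs = scene$motif_probs,
                   soma_offset_um = scene$soma_offset_um)
      cand <- try(generate_astrocyte(spec, vessel_context = vt), silent = TRUE)
      if (inherits(cand, "try-error")) next
      if (true_unique_contacts(cand, vt) < 1) next  # every cell contacts a vessel
      collision <- FALSE
      for (cc in cells) if (masks_touch(cand, cc)) { collision <- TRUE; break }
      if (!collision) {
        if (ci == "mural" && !is.null(vt$branch_points) && nrow(vt$branch_points)) {
          used_branch <- c(used_branch, bi)
        }
        cells[[length(cells) + 1L]] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) warning(sprintf("could not place cell %d without contact", i))
  }
  # deliberately overlapping pairs
  overlap_planted <- integer(0)
  if (scene$overlap_pairs > 0 && length(cells)) {
    for (k in seq_len(scene$overlap_pairs)) {
      base_i <- sample(length(cells), 1)
      base <- cells[[base_i]]
      spec <- list(center_px = base$center_px + c(1.1, 0.3) * base$R0_px,
                   area_um2 = pi * (base$R0_px * px)^2, px_um = px,
                   field_px = c(nx, ny), irregularity = scene$irregularity,
                   n_processes = scene$n_processes, motifs = character(0),
                   connection = "non-enveloping",
                   motif_probs = scene$motif_probs,
                   soma_offset_um = scene$soma_offset_um)
      cand <- try(generate_astrocyte(spec, vessel_context = vt), silent = TRUE)
      if (!inherits(cand, "try-error")) {
        cells[[length(cells) + 1L]] <- cand
        overlap_planted <- c(overlap_planted, base_i, length(cells))
      }
    }
  }

  # --- overlap bookkeeping -------------------------------------------------
  overlaps <- NULL
  if (length(cells) > 1) {
    for (i in seq_len(length(cells) - 1)) {
      for (j in (i + 1):length(cells)) {
        if (masks_touch(cells[[i]], cells[[j]])) {
          overlaps <- rbind(overlaps, c(i, j))
        }
      }
    }
  }
  if (!is.null(overlaps)) {
    warning(sprintf("%d cell pair(s) in contact with another labelled cell",
                    nrow(overlaps)))
  }

  # --- channels (2D) -------------------------------------------------------
  ch_membrane <- matrix(0, ny, nx)
  ch_gfap <- matrix(0, ny, nx)
  ch_soma <- matrix(0, ny, nx)
  ch_axon <- matrix(0, ny, nx)
  gfap_masks <- vector("list", length(cells))
  soma_sigma_px <- 2.5 / px
  for (i in seq_along(cells)) {
    cc <- cells[[i]]
    amp <- stats::runif(1, 0.75, 1)
    fm <- embed_mask(cc$mask, cc$offset, c(nx, ny))
    ch_membrane[fm] <- pmax(ch_membrane[fm], amp)
    g <- gfap_subset(cc$mask, scene$gfap_fraction)
    gm <- embed_mask(g, cc$offset, c(nx, ny))
    ch_gfap[gm] <- pmax(ch_gfap[gm], amp)
    gfap_masks[[i]] <- list(mask = g, offset = cc$offset)
    # soma blob
    sp <- cc$soma_um / px
    x0 <- max(1L, floor(sp[1] - 3 * soma_sigma_px))
    x1 <- min(nx, ceiling(sp[1] + 3 * soma_sigma_px))
    y0 <- max(1L, floor(sp[2] - 3 * soma_sigma_px))
    y1 <- min(ny, ceiling(sp[2] + 3 * soma_sigma_px))
    if (x0 <= x1 && y0 <= y1) {
      gx <- rep(x0:x1, times = y1 - y0 + 1)
      gy <- rep(y0:y1, each = x1 - x0 + 1)
      v <- exp(-((gx - sp[1])^2 + (gy - sp[2])^2) / (2 * soma_sigma_px^2))
      ch_soma[cbind(gy, gx)] <- pmax(ch_soma[cbind(gy, gx)], v)
    }
  }
  # background axon streaks
  for (k in seq_len(scene$n_axons)) {
    a <- stats::runif(1, 0, pi)
    c0 <- c(stats::runif(1, 1, nx), stats::runif(1, 1, ny))
    p1 <- c0 - 600 * c(cos(a), sin(a)); p2 <- c0 + 600 * c(cos(a), sin(a))
    ch_axon <- paint_line(ch_axon, p1, p2, 1.4 / px, stats::runif(1, 0.5, 0.9))
  }
  # structures under contact-flagged motifs
  for (i in seq_along(cells)) {
    mi <- cells[[i]]$motif_instances
    for (r in seq_len(nrow(mi))) {
      anchor <- c(mi$x[r], mi$y[r])
      if (isTRUE(mi$axon[r])) {
        a <- stats::runif(1, 0, pi)
        ch_axon <- paint_line(ch_axon, anchor - 60 * c(cos(a), sin(a)),
                              anchor + 60 * c(cos(a), sin(a)), 1.4 / px, 0.9)
      }
      if (isTRUE(mi$soma[r])) {
        # RGC soma: small neuronal disk at the anchor
        ch_axon <- paint_line(ch_axon, anchor, anchor + c(0.1, 0), 7 / px, 0.8)
      }
    }
  }
  ch_vessel <- vt$mask * 1

  # --- Z-stack assembly ----------------------------------------------------
  two_d <- list(membrane = ch_membrane, gfap = ch_gfap, vessel = ch_vessel,
                soma = ch_soma, axon = ch_axon)
  channels <- lapply(two_d, function(m) {
    fz <- stats::runif(nz, 0.55, 1)
    arr <- array(0, c(ny, nx, nz))
    for (z in seq_len(nz)) {
      plane <- m * fz[z]
      if (scene$blur_sigma > 0) {
        plane <- EBImage::imageData(EBImage::gblur(EBImage::Image(plane),
                                                   sigma = scene$blur_sigma))
      }
      if (scene$noise_sd > 0) {
        plane <- plane + stats::rnorm(length(plane), 0, scene$noise_sd)
        plane[plane < 0] <- 0
      }
      arr[, , z] <- plane
    }
    arr
  })
  stack <- structure(list(channels = channels, px_um = px, z_um = scene$z_um),
                     class = "astro_stack")

  # --- geography + contact truth -------------------------------------------
  geo <- scene$geo
  for (i in seq_along(cells)) {
    cc <- cells[[i]]
    pos_um <- cc$truth$cvh_centroid_um
    rel <- pos_um - geo$onh_um
    r <- sqrt(sum(rel^2))
    lat <- (r / geo$rim_um - 1) * pi / 2
    alpha <- atan2(rel[2], rel[1])
    ad <- geo$dorsal_deg * pi / 180
    lon <- if (identical(geo$eye, "left")) (pi / 2 - (alpha - ad)) else
      (pi / 2 + (alpha - ad))
    lon <- lon %% (2 * pi)
    cells[[i]]$lat_rad <- lat
    cells[[i]]$lon_rad <- lon
    cells[[i]]$position_um <- pos_um
    cells[[i]]$id <- i
    cells[[i]]$true_n_unique <- true_unique_contacts(cc, vt)
  }

  truth <- structure(list(params = scene, cells = cells, vessels = vt,
                          gfap_masks = gfap_masks, overlaps = overlaps,
                          overlap_planted = overlap_planted,
                          channel_names = names(channels)),
                     class = "scene_truth")
  list(stack = stack, truth = truth)
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("scene_truth: %d cell(s), %d unique vessel(s), field %dx%d px\n",
              length(x$cells), x$vessels$n_unique,
              x$params$field_px[1], x$params$field_px[2]))
  invisible(x)
}

#' True unique-vessel contact count of a generated cell
#' @keywords internal
true_unique_contacts <- function(cell, vt, tol_px = 1.5) {
  xy <- idx_to_xy(which(cell$mask), nrow(cell$mask))
  if (!nrow(xy)) return(0L)
  cx <- xy[, 1] + cell$offset[1]; cy <- xy[, 2] + cell$offset[2]
  nd <- vt$nodes
  hit <- logical(max(nd$vessel_id))
  for (v in unique(nd$vessel_id)) {
    sel <- which(nd$vessel_id == v)
    found <- FALSE
    for (s in sel) {
      r_px <- nd$radius_um[s] / vt$px_um + tol_px
      # quick bbox rejection
      dx <- cx - nd$x[s]; dy <- cy - nd$y[s]
      close <- abs(dx) <= r_px & abs(dy) <= r_px
      if (any(close) && any(dx[close]^2 + dy[close]^2 <= r_px^2)) {
        found <- TRUE
        break
      }
    }
    hit[v] <- found
  }
  sum(hit)
}

# ---------------------------------------------------------------------------
# annotation tables

#' Motif annotation table from scene ground truth
#'
#' One row per planted motif instance with the contacted-structure flags
#' (axon, RGC soma, neighbouring astrocyte) recorded at generation time.
#'
#' @param truth a `scene_truth` (or list of `astro_cell`s).
#' @return data.frame with columns `cell_id, motif, axon, soma, astrocyte`
#'   (flags as 0/1 integers).
#' @export
generate_annotation_table <- function(truth) {
  cells <- if (inherits(truth, "scene_truth")) truth$cells else truth
  rows <- list()
  for (i in seq_along(cells)) {
    mi <- cells[[i]]$motif_instances
    if (!is.null(mi) && nrow(mi)) {
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cells[[i]]$id %||% i, motif = mi$motif,
        axon = as.integer(mi$axon), soma = as.integer(mi$soma),
        astrocyte = as.integer(mi$astrocyte))
    }
  }
  if (!length(rows)) {
    return(data.frame(cell_id = integer(0), motif = character(0),
                      axon = integer(0), soma = integer(0),
                      astrocyte = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# stack / truth I/O

#' Write an `astro_stack` as a multi-page TIFF
#'
#' Pages are ordered Z-major, channel-minor (axis order ZCYX); channel
#' names, pixel size and z-step are stored in a JSON sidecar
#' (`<path>.json`). Intensities are scaled to the global maximum.
#' @param stack an `astro_stack`.
#' @param path output file.
#' @export
write_stack_tiff <- function(stack, path) {
  nz <- dim(stack$channels[[1]])[3]
  mx <- max(1e-12, max(vapply(stack$channels, max, numeric(1))))
  pages <- list()
  for (z in seq_len(nz)) {
    for (ch in names(stack$channels)) {
      pages[[length(pages) + 1L]] <- stack$channels[[ch]][, , z] / mx
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(channels = names(stack$channels),
                            px_um = stack$px_um, z_um = stack$z_um,
                            nz = nz, axes = "ZCYX", scale = mx),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stack written by [write_stack_tiff()]
#' @param path TIFF file path (its `.json` sidecar must sit beside it).
#' @return an `astro_stack`.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  nc <- length(meta$channels); nz <- meta$nz
  channels <- list()
  for (ci in seq_len(nc)) {
    arr <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), nz))
    for (z in seq_len(nz)) {
      arr[, , z] <- pages[[(z - 1) * nc + ci]] * (meta$scale %||% 1)
    }
    channels[[meta$channels[ci]]] <- arr
  }
  structure(list(channels = channels, px_um = meta$px_um, z_um = meta$z_um),
            class = "astro_stack")
}

#' @export
print.astro_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("astro_stack: %s | %d x %d x %d, px %g um, z %g um\n",
              paste(names(x$channels), collapse = "/"),
              d[1], d[2], d[3], x$px_um, x$z_um))
  invisible(x)
}

rle_encode_mask <- function(mask) {
  r <- rle(as.integer(mask))
  list(lengths = r$lengths, values = r$values, dim = dim(mask))
}

#' Serialise scene ground truth to JSON
#'
#' Masks are stored run-length encoded; metrics, motifs, soma positions,
#' coordinates and the vessel centreline/branch records are stored as-is.
#' @param truth a `scene_truth`.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  cells <- lapply(truth$cells, function(cc) {
    list(id = cc$id, connection = cc$connection,
         offset = cc$offset, mask_rle = rle_encode_mask(cc$mask),
         metrics = cc$truth[setdiff(names(cc$truth), "cvh_centroid_um")],
         cvh_centroid_um = cc$truth$cvh_centroid_um,
         soma_um = cc$soma_um, soma_offset_um = cc$soma_offset_um,
         lat_rad = cc$lat_rad, lon_rad = cc$lon_rad,
         true_n_unique = cc$true_n_unique,
         motifs = cc$motif_instances)
  })
  vessels <- list(paths = truth$vessels$paths,
                  branch_points = truth$vessels$branch_points,
                  n_unique = truth$vessels$n_unique)
  jsonlite::write_json(list(cells = cells, vessels = vessels,
                            field_px = truth$params$field_px,
                            px_um = truth$params$px_um),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
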