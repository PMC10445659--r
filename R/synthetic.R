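# Synthetic flat-mount retina generator.
#
# Emulates the study geometry: a field of membrane-labelled astrocytes laid
# over a branching vessel bed, with a filamentous GFAP-like subset, soma
# blobs, axon streaks, planted structural motifs (bead, sail, tube, bristle,
# pad, end-foot, hole) and a full ground-truth record so that every
# downstream stage can be tested by parameter recovery.
#
# All generator coordinates are scene pixels (1-based pixel centres,
# x = column, y = row, y down); physical calibration is carried separately.

MOTIF_VOCAB <- c("bead", "sail", "tube", "bristle", "pad", "end-foot", "hole")

#' Scene parameters for the synthetic retina generator
#'
#' Defaults encode the emulated acquisition (0.3 um z-steps, 0.5 um pixels)
#' and the study-scale biology: GFAP covering ~21.1% of the cell area, soma
#' displaced from the convex-hull centroid by ~17.1 +/- 9.1 um, connection
#' classes at 8/7/85% and motif-to-structure contact probabilities at the
#' observed association-table rates.
#'
#' @param field_px field size `c(nx, ny)` in pixels.
#' @param nz number of Z planes.
#' @param px_um pixel size (um/px), > 0.
#' @param z_um z-step (um), > 0.
#' @param vessels list: `root_radius_um`, `n_branches`, `radius_decay`
#'   (new-branch factor), `cont_decay` (continuing-branch factor).
#' @param n_cells number of astrocytes.
#' @param cell_area_um2 range of target cell core areas (um^2).
#' @param irregularity radial modulation amplitude of the cell core.
#' @param n_processes processes per cell (non-motif).
#' @param motif_rates named per-motif planting probabilities.
#' @param connection_fractions named fractions for
#'   enveloping / mural / non-enveloping cells.
#' @param motif_probs per-motif structure-contact probabilities (rows
#'   axon/soma/astrocyte, values in percent).
#' @param gfap_fraction planted GFAP-positive area fraction of each cell.
#' @param soma_offset_um `c(mean, sd)` of the planted soma-to-centroid
#'   displacement (um).
#' @param noise_sd additive Gaussian noise sigma relative to peak signal.
#' @param blur_sigma optional Gaussian blur sigma (px); 0 disables.
#' @param n_axons number of background axon streaks.
#' @param overlap_pairs number of deliberately overlapping cell pairs.
#' @param geo list: `onh_um` (ONH position in field coordinates, um),
#'   `rim_um` (rim distance), `dorsal_deg` (planar dorsal direction),
#'   `eye` ("left"/"right").
#' @param seed integer seed fixing all randomness.
#' @return a `scene_params` list.
#' @export
scene_params <- function(field_px = c(384, 384), nz = 5, px_um = 0.5,
                         z_um = 0.3,
                         vessels = list(root_radius_um = 4, n_branches = 5,
                                        radius_decay = 0.75, cont_decay = 0.92),
                         n_cells = 8,
                         cell_area_um2 = c(600, 1600),
                         irregularity = 0.22,
                         n_processes = 4,
                         motif_rates = c(bead = 0.5, sail = 0.5, pad = 0.5,
                                         bristle = 0.6, hole = 0.35,
                                         `end-foot` = 0.5),
                         connection_fractions = c(enveloping = 0.08,
                                                  mural = 0.07,
                                                  `non-enveloping` = 0.85),
                         motif_probs = default_motif_probs(),
                         gfap_fraction = 0.211,
                         soma_offset_um = c(mean = 17.1, sd = 9.1),
                         noise_sd = 0.05, blur_sigma = 0,
                         n_axons = 8, overlap_pairs = 0,
                         geo = list(onh_um = c(-1000, -800), rim_um = 2600,
                                    dorsal_deg = 90, eye = "left"),
                         seed = 1) {
  stopifnot(px_um > 0, z_um > 0, nz >= 1, n_cells >= 0,
            all(field_px > 0), gfap_fraction >= 0, gfap_fraction <= 1)
  out <- list(field_px = field_px, nz = nz, px_um = px_um, z_um = z_um,
              vessels = vessels, n_cells = n_cells,
              cell_area_um2 = cell_area_um2, irregularity = irregularity,
              n_processes = n_processes, motif_rates = motif_rates,
              connection_fractions = connection_fractions,
              motif_probs = motif_probs, gfap_fraction = gfap_fraction,
              soma_offset_um = soma_offset_um, noise_sd = noise_sd,
              blur_sigma = blur_sigma, n_axons = n_axons,
              overlap_pairs = overlap_pairs, geo = geo,
              seed = as.integer(seed))
  class(out) <- "scene_params"
  out
}

#' Default motif-to-structure contact probabilities (percent)
#'
#' Sail/bead/pad/bristle rates follow the observed association table;
#' tube and end-foot contacts are vascular by construction.
#' @export
default_motif_probs <- function() {
  data.frame(
    motif = c("sail", "bead", "pad", "bristle", "tube", "end-foot", "hole"),
    axon = c(65, 76, 43, 41, 10, 5, 0),
    soma = c(41, 22, 43, 34, 0, 5, 0),
    astrocyte = c(6, 3, 20, 20, 0, 5, 0)
  )
}

# ---------------------------------------------------------------------------
# vessel network

rot2 <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                         sin(a) * v[1] + cos(a) * v[2])

#' Generate a branching vessel tree with known topology
#'
#' Grows a tree of centreline polylines from a field-edge root. At every
#' branch event one child continues the parent vessel identity and the other
#' starts a new unique vessel, so the true number of unique vessels equals
#' one plus the number of branch events.
#'
#' @param params a [scene_params()] (its `field_px`, `px_um` and `vessels`
#'   entries are used) or a list with those fields.
#' @param seed optional integer seed.
#' @return a `vessel_truth`: `paths` (list of data.frames x, y, radius_um,
#'   vessel_id), `nodes` (bound rows), `branch_points`, `n_unique`, `mask`
#'   (logical field matrix), `px_um`, `field_px`.
#' @export
generate_vessel_network <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vs <- params$vessels
  px <- params$px_um
  nx <- params$field_px[1]; ny <- params$field_px[2]
  if (vs$root_radius_um / px < 1) {
    stop("unresolvable vessel: root radius below 1 px")
  }
  step <- 3
  margin <- 24
  centre <- c((nx + 1) / 2, (ny + 1) / 2)
  # root on a random edge heading inward
  edge <- sample.int(4, 1)
  t0 <- stats::runif(1, 0.25, 0.75)
  start <- switch(edge,
                  c(1, t0 * ny), c(nx, t0 * ny), c(t0 * nx, 1), c(t0 * nx, ny))
  dir <- (centre - start) / sqrt(sum((centre - start)^2))
  paths <- list()
  keep_path <- logical(0)
  branch_points <- NULL
  drop_bp <- integer(0)
  next_vessel_id <- 1L
  n_branch_realised <- 0L
  min_tail_px <- 45  # collision-truncated stubs below this are not realised
  occ <- matrix(numeric(0), 0, 3)  # x, y, radius_px of accepted points
  grow <- function(pos, dir, radius_um, vid, branches_left, depth) {
    r_px <- radius_um / px
    origin <- pos
    junction_zone <- 2 * r_px + 12
    clear_at <- function(p) {
      if (!nrow(occ)) return(TRUE)
      # parent/sibling points near the junction are exempt only while the
      # candidate itself is still inside the junction fan-out
      p_in_zone <- sqrt(sum((p - origin)^2)) <= junction_zone + 6
      if (p_in_zone) {
        d_or <- sqrt((occ[, 1] - origin[1])^2 + (occ[, 2] - origin[2])^2)
        cand <- which(d_or > junction_zone)
      } else {
        cand <- seq_len(nrow(occ))
      }
      if (!length(cand)) return(TRUE)
      d <- sqrt((occ[cand, 1] - p[1])^2 + (occ[cand, 2] - p[2])^2)
      all(d > r_px + occ[cand, 3] + 3)
    }
    tip_clear <- function(p) {
      if (!nrow(occ)) return(TRUE)
      d <- sqrt((occ[, 1] - p[1])^2 + (occ[, 2] - p[2])^2)
      all(d > 2 * r_px + 20)
    }
    pts <- matrix(pos, 1, 2)
    nsteg <- if (branches_left > 0) round(stats::runif(1, 12, 24)) else
      round(stats::runif(1, 30, 55))
    max_steps <- if (branches_left > 0) nsteg + 60 else nsteg
    i <- 0L
    straight_steps <- ceiling(junction_zone / step) + 1
    repeat {
      i <- i + 1L
      if (i > max_steps) break
      # past the nominal length, keep going only to find a clear branch site
      if (i > nsteg && tip_clear(pts[nrow(pts), ])) break
      # hold course until out of the junction fan-out so that sibling tubes
      # separate monotonically (keeps the rendered bed loop-free)
      if (i > straight_steps) {
        dir <- rot2(dir, stats::rnorm(1, 0, if (branches_left > 0) 0.10 else 0.06))
      }
      # steer back toward the interior near the border
      p <- pts[nrow(pts), ] + dir * step
      near <- p[1] < margin || p[2] < margin || p[1] > nx - margin ||
        p[2] > ny - margin
      if (near && branches_left > 0 && i > straight_steps) {
        to_c <- centre - p
        dir <- dir + 0.35 * to_c / sqrt(sum(to_c^2))
        dir <- dir / sqrt(sum(dir^2))
        p <- pts[nrow(pts), ] + dir * step
      }
      # collision avoidance against non-adjacent vessels keeps the bed a tree
      accepted <- FALSE
      for (rot_deg in c(0, 20, -20, 40, -40, 60, -60)) {
        dir_try <- rot2(dir, rot_deg * pi / 180)
        p_try <- pts[nrow(pts), ] + dir_try * step
        if (clear_at(p_try)) { dir <- dir_try; p <- p_try; accepted <- TRUE; break }
      }
      if (!accepted) break
      if (p[1] < 2 || p[2] < 2 || p[1] > nx - 1 || p[2] > ny - 1) break
      pts <- rbind(pts, p)
    }
    # only branch from an interior site clear of unrelated vessels
    tp <- pts[nrow(pts), ]
    do_branch <- branches_left > 0 && nrow(pts) > 3 && tip_clear(tp) &&
      tp[1] > 25 && tp[2] > 25 && tp[1] < nx - 25 && tp[2] < ny - 25
    path <- data.frame(x = pts[, 1], y = pts[, 2],
                       radius_um = radius_um, vessel_id = vid)
    paths[[length(paths) + 1L]] <<- path
    keep_path[length(paths)] <<- TRUE
    my_idx <- length(paths)
    occ <<- rbind(occ, cbind(pts[, 1], pts[, 2], r_px))
    tip <- pts[nrow(pts), ]
    my_len <- if (nrow(pts) > 1) sum(sqrt(rowSums(diff(pts)^2))) else 0
    if (do_branch) {
      n_branch_realised <<- n_branch_realised + 1L
      branch_points <<- rbind(branch_points, tip)
      my_bp <- nrow(branch_points)
      b_new <- if (branches_left > 1) stats::rbinom(1, branches_left - 1, 0.5) else 0
      b_cont <- branches_left - 1 - b_new
      side <- sample(c(-1, 1), 1)
      a <- stats::runif(1, 35, 65) * pi / 180
      dir_new <- rot2(dir, side * a)
      dir_cont <- rot2(dir, -side * stats::runif(1, 2, 10) * pi / 180)
      new_id <- next_vessel_id + 1L
      next_vessel_id <<- new_id
      res_cont <- grow(tip, dir_cont, radius_um * vs$cont_decay, vid,
                       b_cont, depth + 1)
      res_new <- grow(tip, dir_new, max(radius_um * vs$radius_decay, px),
                      new_id, b_new, depth + 1)
      # a collision-truncated stub cannot be realised as a branch: drop the
      # stub and un-count the event so the rendered bed matches the truth
      if (res_new$pure_tail && res_new$len < min_tail_px) {
        keep_path[res_new$idx] <<- FALSE
        n_branch_realised <<- n_branch_realised - 1L
        drop_bp <<- c(drop_bp, my_bp)
      } else if (res_cont$pure_tail && res_cont$len < min_tail_px) {
        keep_path[res_cont$idx] <<- FALSE
        n_branch_realised <<- n_branch_realised - 1L
        drop_bp <<- c(drop_bp, my_bp)
      }
    }
    list(idx = my_idx, len = my_len, pure_tail = !do_branch)
  }
  grow(start, dir, vs$root_radius_um, 1L, vs$n_branches, 0)
  paths <- paths[keep_path]
  if (length(drop_bp)) branch_points <- branch_points[-drop_bp, , drop = FALSE]
  mask <- matrix(FALSE, ny, nx)
  for (p in paths) mask <- paint_tube(mask, p, px)
  nodes <- do.call(rbind, paths)
  out <- list(paths = paths, nodes = nodes,
              branch_points = branch_points,
              n_unique = n_branch_realised + 1L,
              n_branch_events = n_branch_realised,
              mask = mask, px_um = px, field_px = c(nx, ny))
  class(out) <- "vessel_truth"
  out
}

#' @export
print.vessel_truth <- function(x, ...) {
  cat(sprintf("vessel_truth: %d path(s), %d branch event(s), %d unique vessel(s)\n",
              length(x$paths), x$n_branch_events, x$n_unique))
  invisible(x)
}

#' Paint a tube of given per-node radius around a polyline into a mask
#' @keywords internal
paint_tube <- function(mask, path, px_um) {
  ny <- nrow(mask); nx <- ncol(mask)
  n <- nrow(path)
  segs <- if (n >= 2) seq_len(n - 1) else integer(0)
  for (i in segs) {
    p1 <- c(path$x[i], path$y[i]); p2 <- c(path$x[i + 1], path$y[i + 1])
    r <- path$radius_um[i] / px_um
    x0 <- max(1L, floor(min(p1[1], p2[1]) - r - 1))
    x1 <- min(nx, ceiling(max(p1[1], p2[1]) + r + 1))
    y0 <- max(1L, floor(min(p1[2], p2[2]) - r - 1))
    y1 <- min(ny, ceiling(max(p1[2], p2[2]) + r + 1))
    if (x0 > x1 || y0 > y1) next
    gx <- rep(x0:x1, times = y1 - y0 + 1)
    gy <- rep(y0:y1, each = x1 - x0 + 1)
    d <- point_segment_dist(gx, gy, p1, p2)
    sel <- d <= r
    if (any(sel)) mask[cbind(gy[sel], gx[sel])] <- TRUE
  }
  if (n == 1) {
    r <- path$radius_um[1] / px_um
    gx <- rep(seq_len(nx), times = ny); gy <- rep(seq_len(ny), each = nx)
    d <- sqrt((gx - path$x[1])^2 + (gy - path$y[1])^2)
    mask[cbind(gy[d <= r], gx[d <= r])] <- TRUE
  }
  mask
}

#' Vectorised point-to-segment distance
#' @keywords internal
point_segment_dist <- function(px, py, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < .Machine$double.eps) {
    return(sqrt((px - a[1])^2 + (py - a[2])^2))
  }
  t <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (a[1] + t * ab[1]))^2 + (py - (a[2] + t * ab[2]))^2)
}

# ---------------------------------------------------------------------------
# astrocyte construction

circle_polygon <- function(centre, r, n = 28) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(centre[1] + r * cos(t), centre[2] + r * sin(t))
}

capsule_polygon <- function(p1, p2, r, n_arc = 10) {
  d <- p2 - p1
  len <- sqrt(sum(d^2))
  if (len < .Machine$double.eps) return(circle_polygon(p1, r, 2 * n_arc))
  th <- atan2(d[2], d[1])
  a_end <- th - pi / 2 + seq(0, pi, length.out = n_arc)    # cap around p2
  a_start <- th + pi / 2 + seq(0, pi, length.out = n_arc)  # cap around p1
  rbind(cbind(p2[1] + r * cos(a_end), p2[2] + r * sin(a_end)),
        cbind(p1[1] + r * cos(a_start), p1[2] + r * sin(a_start)))
}

#' Capsules covering a polyline at width w (union rasterises to a tube)
#' @keywords internal
polyline_capsules <- function(pts, w) {
  out <- list()
  for (i in seq_len(nrow(pts) - 1)) {
    out[[i]] <- capsule_polygon(pts[i, ], pts[i + 1, ], w / 2)
  }
  out
}

ring_sector_polygon <- function(centre, r_in, r_out, a0, a1, n = 40) {
  t <- seq(a0, a1, length.out = n)
  rbind(cbind(centre[1] + r_out * cos(t), centre[2] + r_out * sin(t)),
        cbind(centre[1] + r_in * cos(rev(t)), centre[2] + r_in * sin(rev(t))))
}

#' Random curved polyline leaving `start` along `dir`
#' @keywords internal
wiggle_polyline <- function(start, dir, length_px, n_seg = 5, curl = 0.25) {
  pts <- matrix(start, 1, 2)
  step <- length_px / n_seg
  for (i in seq_len(n_seg)) {
    dir <- rot2(dir, stats::rnorm(1, 0, curl))
    pts <- rbind(pts, pts[nrow(pts), ] + dir * step)
  }
  pts
}

#' Generate one synthetic astrocyte with planted motifs and ground truth
#'
#' The cell is built as a radially modulated core polygon plus processes
#' (dilated polylines) and motif geometry at the observed length scales:
#' bristles are fine projections of at most ~5 um (the smallest 0.7-2.5 um),
#' sails are polygonal membrane sheets, tubes fully enwrap a vessel,
#' end-feet terminate on a vessel without enveloping it, pads are rounded
#' endings away from vessels, beads are inflations along thin processes and
#' holes are interior voids.
#'
#' @param cell_spec list: `center_px`, `area_um2` (core target), `px_um`,
#'   `field_px`, optional `irregularity`, `n_processes`, `motifs` (character
#'   vector from the motif vocabulary, repeats allowed), `connection`
#'   ("enveloping", "mural", "non-enveloping"), `motif_probs`,
#'   `soma_offset_um`, `small_bristles` (logical).
#' @param vessel_context a `vessel_truth` or NULL; required by tube and
#'   end-foot motifs and by enveloping/mural construction.
#' @param seed optional integer seed.
#' @return an `astro_cell` with polygon lists, the 1x mask (cropped +
#'   offset), supersampled truth metrics, planted soma and motif records.
#' @export
generate_astrocyte <- function(cell_spec, vessel_context = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  px <- cell_spec$px_um
  field <- cell_spec$field_px
  ctr <- cell_spec$center_px
  conn <- cell_spec$connection %||% "non-enveloping"
  motifs <- cell_spec$motifs %||% character(0)
  irr <- cell_spec$irregularity %||% 0.22
  nproc <- cell_spec$n_processes %||% 4
  probs <- cell_spec$motif_probs %||% default_motif_probs()
  R0 <- sqrt((cell_spec$area_um2 %||% 1000) / pi) / px  # core radius, px

  if (any(motifs %in% c("tube", "end-foot")) && is.null(vessel_context)) {
    missing <- intersect(motifs, c("tube", "end-foot"))[1]
    stop(sprintf("%s motif requires a vessel, but no vessel context was given",
                 missing))
  }

  polys <- list(); holes <- list()
  motif_rec <- list()
  add_motif <- function(motif, x, y, length_um = NA_real_) {
    pr <- probs[probs$motif == motif, ]
    flags <- if (nrow(pr)) {
      c(axon = stats::runif(1) * 100 < pr$axon,
        soma = stats::runif(1) * 100 < pr$soma,
        astrocyte = stats::runif(1) * 100 < pr$astrocyte)
    } else c(axon = FALSE, soma = FALSE, astrocyte = FALSE)
    motif_rec[[length(motif_rec) + 1L]] <<- data.frame(
      motif = motif, x = x, y = y, length_um = length_um,
      axon = unname(flags["axon"]), soma = unname(flags["soma"]),
      astrocyte = unname(flags["astrocyte"]))
  }

  # --- core polygon ---------------------------------------------------------
  nth <- 240
  th <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  rad <- rep(1, nth)
  for (kk in 2:6) {
    rad <- rad + (stats::runif(1, 0, irr) / sqrt(kk)) *
      cos(kk * th + stats::runif(1, 0, 2 * pi))
  }
  rad <- pmax(rad, 0.35) * R0
  radius_at <- stats::approxfun(c(th, 2 * pi), c(rad, rad[1]), rule = 2)

  if (conn == "enveloping") {
    geom <- build_enveloping(ctr, R0, vessel_context, px)
    polys <- geom$polys; holes <- geom$holes
    add_motif("tube", geom$anchor[1], geom$anchor[2], geom$length_um)
  } else if (conn == "mural") {
    geom <- build_mural(ctr, R0, vessel_context, px)
    polys <- geom$polys
  } else {
    core <- cbind(ctr[1] + rad * cos(th), ctr[2] + rad * sin(th))
    polys <- list(core)
  }

  # --- processes ------------------------------------------------------------
  # keep distinct processes separated by more than a pixel so that the
  # rendered geometry stays resolvable at acquisition resolution (fused
  # processes would make the supersampled truth unrecoverable by design)
  proc_pts <- matrix(numeric(0), 0, 2)
  proc_w_px <- 1.6 / px
  proc_clear <- function(pl) {
    if (!nrow(proc_pts)) return(TRUE)
    for (i in seq_len(nrow(pl))) {
      d_ctr <- sqrt(sum((pl[i, ] - ctr)^2))
      if (d_ctr < 0.9 * R0) next  # near the core everything meets anyway
      d <- sqrt((proc_pts[, 1] - pl[i, 1])^2 + (proc_pts[, 2] - pl[i, 2])^2)
      if (any(d < proc_w_px + 2.5)) return(FALSE)
    }
    TRUE
  }
  add_process <- function(a, len, width_px, n_seg = 5, curl = 0.25) {
    r_here <- radius_at(a %% (2 * pi))
    start <- c(ctr[1] + (r_here - 1) * cos(a), ctr[2] + (r_here - 1) * sin(a))
    pl <- NULL
    for (try_i in 1:8) {
      cand <- wiggle_polyline(start, c(cos(a), sin(a)), len, n_seg, curl)
      if (proc_clear(cand)) { pl <- cand; break }
    }
    if (is.null(pl)) pl <- cand
    proc_pts <<- rbind(proc_pts, pl)
    polys <<- c(polys, polyline_capsules(pl, width_px))
    pl
  }
  if (conn == "non-enveloping" && nproc > 0) {
    angs <- seq(0, 2 * pi, length.out = nproc + 1)[-(nproc + 1)] +
      stats::runif(nproc, -0.3, 0.3)
    for (a in angs) {
      add_process(a, stats::runif(1, 0.35, 0.8) * R0, proc_w_px)
    }
  }

  # --- planted motifs -------------------------------------------------------
  stem_polyline <- function(len_px, n_seg = 3, curl = 0.25) {
    # boundary-anchored stem kept clear of existing processes
    for (try_i in 1:8) {
      a <- stats::runif(1, 0, 2 * pi)
      r_here <- radius_at(a)
      bpt <- c(ctr[1] + (r_here - 0.5) * cos(a),
               ctr[2] + (r_here - 0.5) * sin(a))
      pl <- wiggle_polyline(bpt, c(cos(a), sin(a)), len_px, n_seg, curl)
      if (proc_clear(pl)) break
    }
    proc_pts <<- rbind(proc_pts, pl)
    list(a = a, pl = pl)
  }
  for (motif in motifs) {
    a <- stats::runif(1, 0, 2 * pi)
    r_here <- radius_at(a)
    bpt <- c(ctr[1] + (r_here - 0.5) * cos(a), ctr[2] + (r_here - 0.5) * sin(a))
    if (motif == "bristle") {
      small <- isTRUE(cell_spec$small_bristles)
      len_um <- if (small) stats::runif(1, 0.7, 2.5) else stats::runif(1, 2.5, 5)
      pl <- stem_polyline(len_um / px, n_seg = 3, curl = 0.15)$pl
      polys <- c(polys, polyline_capsules(pl, max(0.6 / px, 1.2)))
      tip <- pl[nrow(pl), ]
      add_motif("bristle", tip[1], tip[2], len_um)
    } else if (motif == "pad") {
      pl <- stem_polyline(stats::runif(1, 3, 6) / px, n_seg = 3)$pl
      polys <- c(polys, polyline_capsules(pl, 1.2 / px))
      tip <- pl[nrow(pl), ]
      pr <- stats::runif(1, 1.5, 2.5) / px
      polys <- c(polys, list(circle_polygon(tip, pr)))
      add_motif("pad", tip[1], tip[2], pr * 2 * px)
    } else if (motif == "bead") {
      pl <- stem_polyline(stats::runif(1, 5, 9) / px, n_seg = 4)$pl
      polys <- c(polys, polyline_capsules(pl, 0.8 / px))
      nb <- sample(2:3, 1)
      at <- seq(0.4, 1, length.out = nb)
      for (tt in at) {
        ii <- 1 + tt * (nrow(pl) - 1)
        p <- pl[floor(ii), ] * (1 - ii %% 1) + pl[ceiling(ii), ] * (ii %% 1)
        polys <- c(polys, list(circle_polygon(p, stats::runif(1, 0.8, 1.2) / px)))
      }
      tip <- pl[nrow(pl), ]
      add_motif("bead", tip[1], tip[2], NA_real_)
    } else if (motif == "sail") {
      a2 <- a + stats::runif(1, 0.7, 1.3)
      arc <- th[th >= min(a, a2) & th <= max(a, a2)]
      if (length(arc) < 3) arc <- seq(min(a, a2), max(a, a2), length.out = 5)
      base <- cbind(ctr[1] + radius_at(arc %% (2 * pi)) * cos(arc) * 0.98,
                    ctr[2] + radius_at(arc %% (2 * pi)) * sin(arc) * 0.98)
      amid <- (a + a2) / 2
      apex <- c(ctr[1] + (radius_at(amid %% (2 * pi)) + 0.55 * R0) * cos(amid),
                ctr[2] + (radius_at(amid %% (2 * pi)) + 0.55 * R0) * sin(amid))
      sail <- rbind(base, apex)
      polys <- c(polys, list(sail))
      add_motif("sail", apex[1], apex[2], NA_real_)
    } else if (motif == "hole") {
      hr <- stats::runif(1, 1.5, 4) / px
      d0 <- stats::runif(1, 0.25, 0.55)
      hc <- c(ctr[1] + d0 * r_here * cos(a), ctr[2] + d0 * r_here * sin(a))
      if (conn == "non-enveloping") {
        holes <- c(holes, list(circle_polygon(hc, hr)))
        add_motif("hole", hc[1], hc[2], hr * 2 * px)
      }
    } else if (motif == "end-foot") {
      near <- nearest_vessel_point(vessel_context, ctr)
      if (near$dist_px > 4 * R0 + 40) {
        stop("end-foot motif requires a vessel within reach")
      }
      dirv <- (near$point - ctr) / max(near$dist_px, 1)
      start <- c(ctr[1] + (radius_at(atan2(dirv[2], dirv[1]) %% (2 * pi)) - 1) * dirv[1],
                 ctr[2] + (radius_at(atan2(dirv[2], dirv[1]) %% (2 * pi)) - 1) * dirv[2])
      r_v <- near$radius_um / px
      # pad tangent to the vessel surface: touches without enveloping
      stop_at <- near$point - dirv * (r_v + 1.4 / px)
      pl <- rbind(start, (start + stop_at) / 2, stop_at)
      polys <- c(polys, polyline_capsules(pl, 1.4 / px))
      polys <- c(polys, list(circle_polygon(stop_at, 1.8 / px)))
      add_motif("end-foot", stop_at[1], stop_at[2], NA_real_)
    } else if (motif == "tube" && conn != "enveloping") {
      near <- nearest_vessel_point(vessel_context, ctr)
      if (near$dist_px > 4 * R0 + 40) {
        stop("tube motif requires a vessel within reach")
      }
      geom <- build_enveloping(near$point, R0 / 2, vessel_context, px,
                               length_um = stats::runif(1, 10, 16))
      polys <- c(polys, geom$polys); holes <- c(holes, geom$holes)
      dirv <- (near$point - ctr) / max(near$dist_px, 1)
      pl <- rbind(ctr, near$point - dirv * (near$radius_um / px + 1))
      polys <- c(polys, polyline_capsules(pl, 1.6 / px))
      add_motif("tube", geom$anchor[1], geom$anchor[2], geom$length_um)
    }
  }

  # --- rasterise ------------------------------------------------------------
  allpts <- do.call(rbind, polys)
  x0 <- max(0L, floor(min(allpts[, 1])) - 2L)
  y0 <- max(0L, floor(min(allpts[, 2])) - 2L)
  x1 <- min(field[1], ceiling(max(allpts[, 1])) + 2L)
  y1 <- min(field[2], ceiling(max(allpts[, 2])) + 2L)
  loc_polys <- lapply(polys, function(p) cbind(p[, 1] - x0, p[, 2] - y0))
  loc_holes <- lapply(holes, function(p) cbind(p[, 1] - x0, p[, 2] - y0))
  nxl <- x1 - x0; nyl <- y1 - y0
  mask1 <- rasterize_polygons(loc_polys, loc_holes, nxl, nyl, scale = 1)
  # keep the largest component (numerical slivers can detach)
  lab <- label_components(mask1, 8)
  if (max(lab) > 1) mask1 <- lab == which.max(tabulate(lab[lab > 0]))
  ss <- 4L
  mask4 <- rasterize_polygons(loc_polys, loc_holes, nxl * ss, nyl * ss, scale = ss)
  lab4 <- label_components(mask4, 8)
  if (max(lab4) > 1) mask4 <- lab4 == which.max(tabulate(lab4[lab4 > 0]))
  truth <- truth_metrics_from_mask(mask4, px / ss)
  truth$cvh_centroid_um <- truth$cvh_centroid_um + c(x0, y0) * px

  # analytic truth for the bare core (no motifs, no processes)
  analytic <- NULL
  if (conn == "non-enveloping" && nproc == 0 && !length(motifs)) {
    core <- polys[[1]]
    analytic <- list(area_um2 = abs(shoelace_area(core)) * px^2,
                     perimeter_um = polygon_length(core) * px)
  }

  # --- soma -----------------------------------------------------------------
  off <- cell_spec$soma_offset_um %||% c(mean = 17.1, sd = 9.1)
  mag_um <- if (!is.null(cell_spec$soma_offset_exact_um)) {
    cell_spec$soma_offset_exact_um
  } else {
    abs(stats::rnorm(1, off[1], off[2]))
  }
  sdir <- stats::runif(1, 0, 2 * pi)
  mag_um <- min(mag_um, 0.75 * radius_at(sdir) * px)
  soma_um <- truth$cvh_centroid_um + mag_um * c(cos(sdir), sin(sdir))

  out <- list(center_px = ctr, R0_px = R0,
              polys = polys, holes = holes,
              core_radius_at = radius_at,
              mask = mask1, offset = c(x0, y0), field_px = field, px_um = px,
              motif_instances = if (length(motif_rec)) do.call(rbind, motif_rec)
                                else empty_motif_df(),
              soma_um = soma_um, soma_offset_um = mag_um,
              connection = conn,
              truth = truth, analytic = analytic)
  class(out) <- "astro_cell"
  out
}

empty_motif_df <- function() {
  data.frame(motif = character(0), x = numeric(0), y = numeric(0),
             length_um = numeric(0), axon = logical(0), soma = logical(0),
             astrocyte = logical(0))
}

#' @export
print.astro_cell <- function(x, ...) {
  cat(sprintf("astro_cell: %d px, %s connection, motifs: %s\n",
              sum(x$mask), x$connection,
              if (nrow(x$motif_instances)) paste(x$motif_instances$motif,
                                                 collapse = ", ") else "none"))
  invisible(x)
}

#' Nearest vessel centreline point to a scene position
#' @keywords internal
nearest_vessel_point <- function(vessel_context, pos) {
  nd <- vessel_context$nodes
  d <- sqrt((nd$x - pos[1])^2 + (nd$y - pos[2])^2)
  i <- which.min(d)
  list(point = c(nd$x[i], nd$y[i]), radius_um = nd$radius_um[i],
       dist_px = d[i], vessel_id = nd$vessel_id[i], node = i)
}

#' Sleeve (fully enveloping) geometry around the nearest vessel section
#' @keywords internal
build_enveloping <- function(anchor, R0, vessel_context, px, length_um = NULL) {
  if (is.null(vessel_context)) stop("tube motif requires a vessel")
  near <- nearest_vessel_point(vessel_context, anchor)
  nd <- vessel_context$nodes
  same <- which(nd$vessel_id == near$vessel_id)
  # contiguous run of nodes on this vessel around the nearest node
  len_um <- length_um %||% stats::runif(1, 15, 25)
  half_px <- len_um / px / 2
  d_along <- sqrt((nd$x[same] - near$point[1])^2 + (nd$y[same] - near$point[2])^2)
  keep <- same[d_along <= half_px]
  keep <- keep[order(keep)]
  if (length(keep) < 2) keep <- same[order(d_along)][1:min(2, length(same))]
  pts <- cbind(nd$x[keep], nd$y[keep])
  r_v <- mean(nd$radius_um[keep]) / px
  thick <- min(max(0.8 * r_v, 1 / px), 3 / px)
  outer <- polyline_capsules(pts, 2 * (r_v + thick))
  inner <- polyline_capsules(pts, 2 * max(r_v - 0.75, 0.5))
  list(polys = outer, holes = inner, anchor = near$point,
       length_um = len_um, r_v_um = r_v * px)
}

#' Partial-wrap (mural) geometry near a vessel branch point
#'
#' A one-sided band hugging a short vessel section adjacent to the branch
#' point (a partial, not complete, envelopment) plus a small soma mass on
#' the band's outer edge.
#' @keywords internal
build_mural <- function(anchor, R0, vessel_context, px) {
  if (is.null(vessel_context)) stop("mural construction requires a vessel")
  bp <- vessel_context$branch_points
  pt <- if (!is.null(bp) && nrow(bp)) {
    d <- sqrt((bp[, 1] - anchor[1])^2 + (bp[, 2] - anchor[2])^2)
    c(bp[which.min(d), 1], bp[which.min(d), 2])
  } else nearest_vessel_point(vessel_context, anchor)$point
  near <- nearest_vessel_point(vessel_context, pt)
  nd <- vessel_context$nodes
  same <- which(nd$vessel_id == near$vessel_id)
  len_px <- stats::runif(1, 14, 22) / px
  d_along <- sqrt((nd$x[same] - pt[1])^2 + (nd$y[same] - pt[2])^2)
  keep <- same[d_along <= len_px]
  keep <- keep[order(keep)]
  if (length(keep) < 2) keep <- same[order(d_along)][seq_len(min(3, length(same)))]
  pts <- cbind(nd$x[keep], nd$y[keep])
  r_v <- mean(nd$radius_um[keep]) / px
  thick <- min(max(0.8 * r_v, 1 / px), 3 / px)
  # per-point unit normals (one consistent side)
  nseg <- nrow(pts)
  tang <- pts[c(2:nseg, nseg), , drop = FALSE] - pts[c(1, 1:(nseg - 1)), , drop = FALSE]
  nrm <- cbind(-tang[, 2], tang[, 1])
  nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-9)
  side <- sample(c(-1, 1), 1)
  inner <- pts + side * nrm * max(r_v - 0.75, 0.5)
  outer <- pts + side * nrm * (r_v + thick)
  band <- rbind(outer, inner[rev(seq_len(nrow(inner))), , drop = FALSE])
  mid <- ceiling(nseg / 2)
  body_c <- pts[mid, ] + side * nrm[mid, ] * (r_v + thick + 0.5 * r_v)
  body <- circle_polygon(body_c, max(r_v * 0.8, 3), 24)
  list(polys = list(band, body), anchor = pt)
}

# ---------------------------------------------------------------------------
# supersampled ground-truth metrics

#' Ground-truth shape metrics from a supersampled mask
#'
#' Computes the truth record for a generated cell from its 4x-supersampled
#' rasterisation by polygon geometry: traced boundary chains (corner-cut
#' smoothed) for the perimeter, the shoelace formula on the convex hull for
#' hull area, and a brute-force pairwise maximum over hull vertices of
#' boundary-pixel corners for the Feret diameter (independent of the
#' rotating-calipers measurement path).
#'
#' @param mask4 logical matrix at supersampled resolution.
#' @param px_um_eff effective pixel size of `mask4` (um/px).
#' @param smooth_passes corner-cut passes applied to the traced boundary
#'   chains. The default (3) smooths the supersampled chain at roughly the
#'   same physical scale as the single pass used by the measurement path at
#'   acquisition resolution, so truth and measurement describe the boundary
#'   at a common scale.
#' @param min_hole_area_um2 holes below this bound are filled before
#'   measuring, mirroring the particle bound of the outline workflow.
#' @return list of truth metrics in micrometres.
#' @export
truth_metrics_from_mask <- function(mask4, px_um_eff, smooth_passes = 3,
                                    min_hole_area_um2 = 3) {
  mask4 <- fill_small_holes(mask4, min_hole_area_um2 / px_um_eff^2)
  npx <- sum(mask4)
  b <- trace_boundary(mask4)
  per <- polygon_length(smooth_closed_polygon(b, smooth_passes))
  hl <- hole_components(mask4)
  nh <- max(hl)
  for (h in seq_len(nh)) {
    per <- per + polygon_length(
      smooth_closed_polygon(trace_boundary(hl == h), smooth_passes))
  }
  corners <- boundary_corners(b)
  hull_c <- convex_hull(corners)
  # brute-force max pairwise distance over hull vertices
  dmax <- if (nrow(hull_c) >= 2) max(stats::dist(hull_c)) else 0
  hull_ctr <- convex_hull(b)
  hull_area_px <- abs(shoelace_area(hull_ctr))
  ctr <- polygon_centroid(hull_ctr)
  list(area_um2 = npx * px_um_eff^2,
       perimeter_um = per * px_um_eff,
       feret_um = dmax * px_um_eff,
       solidity = min(npx / max(hull_area_px, npx), 1),
       cvh_area_um2 = hull_area_px * px_um_eff^2,
       cvh_perimeter_um = polygon_length(hull_ctr) * px_um_eff,
       cvh_centroid_um = ctr * px_um_eff,
       n_holes = nh)
}
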