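# Astrocyte-vessel relationships: skeleton extraction with per-node radii,
# unique-vessel partitioning after branch events, nearest-vessel distances,
# per-cell contact statistics and the three-way connection classification.

#' Skeletonize a vessel mask into a centreline graph
#'
#' Thins the mask to a 1-px medial-axis skeleton (Zhang-Suen), assigns each
#' skeleton node the distance-transform radius, and connects 8-adjacent
#' skeleton pixels into a graph. Branch points are nodes of degree >= 3.
#'
#' @param mask logical vessel mask.
#' @param px_um pixel size (um/px).
#' @param prune prune terminal skeleton spurs shorter than about three
#'   local vessel radii (artefacts of thinning wide tubes); default TRUE.
#' @param fill_holes_px fill background holes up to this many pixels before
#'   thinning (junction-fusion slivers; genuine capillary loops are far
#'   larger at this resolution). 0 disables.
#' @return a `vessel_network`: `nodes` (data.frame node, x, y, radius_um,
#'   degree, vessel_id), `graph` (igraph), `branch_nodes`, `segments`
#'   (list of node-index paths between branch/end nodes), `px_um`, `dim`.
#' @export
skeletonize_vessels <- function(mask, px_um, prune = TRUE,
                                fill_holes_px = 1200) {
  if (!any(mask)) stop("empty vessel mask")
  # fill sub-capillary holes (junction-fusion slivers and discretisation
  # artefacts) that would otherwise introduce spurious skeleton loops; a
  # genuine capillary loop lumen (~25 um across) exceeds 1200 px at 0.5 um/px
  if (fill_holes_px > 0) {
    hl <- hole_components(mask)
    if (max(hl) > 0) {
      sizes <- tabulate(hl[hl > 0])
      small <- which(sizes <= fill_holes_px)
      if (length(small)) mask[hl %in% small] <- TRUE
    }
  }
  skel <- break_2x2_blocks(skeletonize_mask(mask))
  if (!any(skel)) stop("vessel mask thinner than 1 px after binarization")
  dmap <- edt(mask)
  if (prune) skel <- prune_skeleton_spurs(skel, dmap)
  sg <- build_skel_graph(skel)
  radius <- pmax(dmap[sg$idx] - 0.5, 0.5) * px_um
  nodes <- data.frame(node = seq_along(sg$idx), x = sg$xy[, 1], y = sg$xy[, 2],
                      radius_um = radius, degree = sg$deg,
                      vessel_id = NA_integer_)
  segments <- skeleton_segments(sg$graph, sg$deg)
  g <- sg$graph
  deg <- sg$deg
  out <- list(nodes = nodes, graph = g,
              branch_nodes = which(deg >= 3),
              segments = segments, px_um = px_um, dim = dim(mask))
  class(out) <- "vessel_network"
  out
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf("vessel_network: %d node(s), %d branch point(s), %d segment(s)%s\n",
              nrow(x$nodes), length(x$branch_nodes), length(x$segments),
              if (all(is.na(x$nodes$vessel_id))) "" else
                sprintf(", %d unique vessel(s)", length(unique(x$nodes$vessel_id)))))
  invisible(x)
}

#' Pixel-adjacency graph of a 1-px skeleton
#'
#' 8-adjacency, with diagonal edges dropped when an axial skeleton pixel
#' bridges the pair (removes spurious 3-cycles in the pixel graph).
#' @keywords internal
build_skel_graph <- function(skel) {
  ny <- nrow(skel); nxm <- ncol(skel)
  idx <- which(skel)
  xy <- idx_to_xy(idx, ny)
  node_of <- integer(length(skel))
  node_of[idx] <- seq_along(idx)
  has_skel <- function(x, y) {
    ok <- x >= 1 & x <= nxm & y >= 1 & y <= ny
    out <- logical(length(x))
    out[ok] <- node_of[xy_to_idx(x[ok], y[ok], ny)] > 0
    out
  }
  edges <- NULL
  for (d in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    nb_x <- xy[, 1] + d[2]; nb_y <- xy[, 2] + d[1]
    ok <- nb_x >= 1 & nb_x <= nxm & nb_y >= 1 & nb_y <= ny
    nb_idx <- xy_to_idx(nb_x[ok], nb_y[ok], ny)
    hit <- node_of[nb_idx] > 0
    src <- which(ok)[hit]
    dst <- node_of[nb_idx[hit]]
    if (d[1] != 0 && d[2] != 0 && length(src)) {
      bridged <- has_skel(xy[src, 1] + d[2], xy[src, 2]) |
                 has_skel(xy[src, 1], xy[src, 2] + d[1])
      src <- src[!bridged]; dst <- dst[!bridged]
    }
    if (length(src)) edges <- rbind(edges, cbind(src, dst))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  list(idx = idx, xy = xy, node_of = node_of, graph = g,
       deg = igraph::degree(g))
}

#' Iteratively remove terminal skeleton spurs shorter than the local radius
#' @keywords internal
prune_skeleton_spurs <- function(skel, dmap, max_iter = 20) {
  ny <- nrow(skel)
  for (iter in seq_len(max_iter)) {
    sg <- build_skel_graph(skel)
    if (!any(sg$deg >= 3)) break
    segs <- skeleton_segments(sg$graph, sg$deg)
    removed <- FALSE
    for (p in segs) {
      d_ends <- sg$deg[c(p[1], p[length(p)])]
      if (!(any(d_ends == 1) && any(d_ends >= 3))) next
      branch_end <- if (d_ends[1] >= 3) p[1] else p[length(p)]
      pxy <- sg$xy[p, , drop = FALSE]
      len <- sum(sqrt(rowSums(diff(pxy)^2)))
      # junction bulges (and adjacent junction pairs) shed spurs up to
      # roughly three radii / a couple dozen pixels
      d_br <- dmap[sg$idx[branch_end]]
      thr <- max(3 * d_br, 26)
      if (len < thr) {
        drop_nodes <- setdiff(p, branch_end)
        skel[sg$idx[drop_nodes]] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  skel
}

#' Decompose a skeleton graph into branch-free segments
#'
#' Removes branch nodes (degree >= 3); each remaining connected run of
#' degree-<=2 nodes forms a segment, extended back to the branch nodes it
#' attaches to.
#' @keywords internal
skeleton_segments <- function(g, deg) {
  keep <- which(deg <= 2)
  if (!length(keep)) return(list())
  sub <- igraph::induced_subgraph(g, keep)
  comp <- igraph::components(sub)
  segments <- list()
  for (ci in seq_len(comp$no)) {
    members <- keep[comp$membership == ci]
    # order along the path: start from an endpoint within the sub-path
    subg <- igraph::induced_subgraph(g, members)
    dsub <- igraph::degree(subg)
    startv <- if (any(dsub <= 1)) which(dsub <= 1)[1] else 1L
    ord <- igraph::dfs(subg, root = startv)$order
    path <- members[as.integer(ord)]
    # attach adjacent branch nodes at both ends
    ends <- c(path[1], path[length(path)])
    for (e in seq_along(ends)) {
      nb <- as.integer(igraph::neighbors(g, ends[e]))
      br <- nb[deg[nb] >= 3]
      if (length(br)) {
        path <- if (e == 1) c(br[1], path) else c(path, br[1])
      }
    }
    segments[[length(segments) + 1L]] <- path
  }
  segments
}

seg_tangent_at <- function(network, seg, at_node, k = 5) {
  path <- seg
  if (path[1] != at_node) path <- rev(path)
  if (path[1] != at_node) {
    # branch node not on this segment end; fall back to nearest end
    d1 <- which(seg == at_node)
    path <- if (length(d1) && d1[1] > length(seg) / 2) rev(seg) else seg
  }
  n <- min(length(path), k + 1)
  if (n < 2) return(c(1, 0))
  a <- c(network$nodes$x[path[1]], network$nodes$y[path[1]])
  b <- c(network$nodes$x[path[n]], network$nodes$y[path[n]])
  v <- b - a
  len <- sqrt(sum(v^2))
  if (len < .Machine$double.eps) c(1, 0) else v / len
}

#' Partition a skeleton into unique vessels after branch events
#'
#' At every branch event one incident segment pair continues the same
#' vessel and the remaining segment starts a new one. The continuing pair
#' is chosen as the most collinear tangents (largest `|cos|`); at nodes of
#' degree > 3 pairs are matched greedily by collinearity, with unpaired
#' segments each starting a new vessel. Components containing cycles fall
#' back to one vessel per inter-branch segment with a warning.
#'
#' @param network a `vessel_network`.
#' @param pairing `"collinearity"` (default) or `"radius"` (most similar
#'   mean radii continue).
#' @return the network with `nodes$vessel_id` and `vessel_of_segment`
#'   filled; `n_unique` attached.
#' @export
split_unique_vessels <- function(network, pairing = c("collinearity", "radius")) {
  pairing <- match.arg(pairing)
  segs <- network$segments
  ns <- length(segs)
  if (!ns) stop("network has no segments")
  deg <- network$nodes$degree
  # union-find over segments
  parent <- seq_len(ns)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { parent[find(i)] <<- find(j) }

  # cycle check per component of the full graph
  comp <- igraph::components(network$graph)
  cyclic <- logical(comp$no)
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(network$graph, vs)
    cyclic[ci] <- igraph::ecount(sub) >= igraph::vcount(sub)
  }
  if (any(cyclic)) {
    warning("cyclic vessel component: each inter-branch segment kept as its own vessel")
  }
  seg_comp <- vapply(segs, function(p) as.integer(comp$membership[p[1]]),
                     integer(1))

  for (bn in network$branch_nodes) {
    if (cyclic[comp$membership[bn]]) next
    inc <- which(vapply(segs, function(p) p[1] == bn || p[length(p)] == bn,
                        logical(1)))
    if (length(inc) < 2) next
    tang <- lapply(segs[inc], function(p) seg_tangent_at(network, p, bn))
    mrad <- vapply(segs[inc], function(p) mean(network$nodes$radius_um[p]),
                   numeric(1))
    avail <- seq_along(inc)
    first_pair <- TRUE
    while (length(avail) >= 2) {
      best <- c(NA, NA); best_score <- -Inf
      for (a in seq_along(avail)) {
        for (b in seq_along(avail)) {
          if (b <= a) next
          s <- if (pairing == "collinearity") {
            abs(sum(tang[[avail[a]]] * tang[[avail[b]]]))
          } else {
            -abs(mrad[avail[a]] - mrad[avail[b]])
          }
          if (s > best_score) { best_score <- s; best <- c(a, b) }
        }
      }
      # beyond the first (continuing) pair, only merge genuinely collinear
      # segments: at a degree-4+ node formed by coincident branch events the
      # remaining daughters each start their own vessel
      if (!first_pair && pairing == "collinearity" && best_score < cos(pi / 6)) break
      union_(inc[avail[best[1]]], inc[avail[best[2]]])
      avail <- avail[-best]
      first_pair <- FALSE
    }
  }
  roots <- vapply(seq_len(ns), find, integer(1))
  ids <- match(roots, unique(roots))
  # assign node vessel ids (branch nodes take the id of their first segment)
  vid <- rep(NA_integer_, nrow(network$nodes))
  for (s in seq_len(ns)) {
    vid[segs[[s]]] <- ids[s]
  }
  # isolated nodes (degree 0) each their own vessel
  iso <- which(is.na(vid))
  if (length(iso)) vid[iso] <- max(ids, 0L) + seq_along(iso)
  network$nodes$vessel_id <- vid
  network$vessel_of_segment <- ids
  network$n_unique <- length(unique(vid))
  network
}

#' Distance from a point to the nearest vessel
#'
#' Euclidean distance (um) from a point to the nearest vessel-mask pixel
#' edge (half a pixel inside the nearest pixel centre), 0 on the vessel.
#'
#' @param point_px point `(x, y)` in pixels.
#' @param vessel_mask logical matrix.
#' @param px_um pixel size.
#' @return distance in micrometres.
#' @export
distance_to_nearest_vessel <- function(point_px, vessel_mask, px_um) {
  if (!any(vessel_mask)) stop("no vessels")
  ny <- nrow(vessel_mask); nx <- ncol(vessel_mask)
  x <- round(point_px[1]); y <- round(point_px[2])
  if (x < 1 || y < 1 || x > nx || y > ny) stop("point outside image")
  if (vessel_mask[y, x]) return(0)
  d <- edt(!vessel_mask)
  max(d[y, x] - 0.5, 0) * px_um
}

#' Per-cell unique-vessel contacts with diameters
#'
#' A contact exists where the cell mask dilated by the tolerance intersects
#' the vessel mask; intersection pixels are attributed to the unique vessel
#' of the nearest centreline node and only unique vessels are counted.
#' Diameters are twice the node radius over the contacted nodes.
#'
#' @param cell_mask full-frame logical matrix (or a [cell_outline()]).
#' @param network a `vessel_network` with the unique partition filled.
#' @param vessel_mask logical matrix.
#' @param tol_px dilation tolerance in pixels (default 1).
#' @return data.frame `vessel_id, n_pixels, d_min_um, d_mean_um, d_max_um`.
#' @export
find_contacts <- function(cell_mask, network, vessel_mask, tol_px = 1) {
  if (inherits(cell_mask, "cell_outline")) {
    cell_mask <- outline_mask(cell_mask, dim(vessel_mask))
  }
  if (all(is.na(network$nodes$vessel_id))) {
    stop("unique-vessel partition not filled; run split_unique_vessels()")
  }
  dil <- mask_dilate(cell_mask, tol_px)
  contact <- dil & vessel_mask
  if (!any(contact)) {
    return(data.frame(vessel_id = integer(0), n_pixels = integer(0),
                      d_min_um = numeric(0), d_mean_um = numeric(0),
                      d_max_um = numeric(0)))
  }
  cxy <- idx_to_xy(which(contact), nrow(vessel_mask))
  nd <- network$nodes
  near <- nearest_node_index(cxy, nd)
  vid <- nd$vessel_id[near]
  out <- lapply(sort(unique(vid)), function(v) {
    sel <- vid == v
    nodes_v <- unique(near[sel])
    dia <- 2 * nd$radius_um[nodes_v]
    data.frame(vessel_id = v, n_pixels = sum(sel),
               d_min_um = min(dia), d_mean_um = mean(dia), d_max_um = max(dia))
  })
  out <- do.call(rbind, out)
  attr(out, "contact_nodes") <- sort(unique(near))
  out
}

#' Nearest skeleton node for each query point (chunked brute force)
#' @keywords internal
nearest_node_index <- function(xy, nodes) {
  n <- nrow(xy)
  out <- integer(n)
  chunk <- max(1L, floor(2e6 / max(nrow(nodes), 1)))
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1)
    dx <- outer(xy[s:e, 1], nodes$x, `-`)
    dy <- outer(xy[s:e, 2], nodes$y, `-`)
    out[s:e] <- max.col(-(dx^2 + dy^2), ties.method = "first")
  }
  out
}

#' Angular wrap of a cell around a centreline node
#'
#' Occupied 10-degree angular bins of cell pixels within `2 * radius`
#' (at least 3 px) of the node, normalised to the feasible bins: angular
#' directions fully occupied by the vessel cross-section itself (the tube
#' continuing through the node) cannot hold cell signal and are excluded
#' from the denominator, so a complete sleeve reads as a full wrap on thick
#' vessels too.
#' @keywords internal
wrap_angle_at_node <- function(cell_xy, node_xy, radius_px,
                               vessel_mask = NULL, bin_deg = 10) {
  r <- max(2 * radius_px, 3)
  dx <- cell_xy[, 1] - node_xy[1]; dy <- cell_xy[, 2] - node_xy[2]
  sel <- dx^2 + dy^2 <= r^2
  if (!any(sel)) return(NA_real_)
  nbin <- as.integer(360 / bin_deg)
  occ <- unique(floor(((atan2(dy[sel], dx[sel]) * 180 / pi) %% 360) / bin_deg))
  if (is.null(vessel_mask)) return(length(occ) * bin_deg)
  # feasible bins: contain at least one non-vessel pixel inside the disk
  ny <- nrow(vessel_mask); nx <- ncol(vessel_mask)
  x0 <- max(1L, floor(node_xy[1] - r)); x1 <- min(nx, ceiling(node_xy[1] + r))
  y0 <- max(1L, floor(node_xy[2] - r)); y1 <- min(ny, ceiling(node_xy[2] + r))
  gx <- rep(x0:x1, times = y1 - y0 + 1); gy <- rep(y0:y1, each = x1 - x0 + 1)
  gdx <- gx - node_xy[1]; gdy <- gy - node_xy[2]
  inside <- gdx^2 + gdy^2 <= r^2 & (gdx != 0 | gdy != 0)
  nonves <- inside & !vessel_mask[cbind(gy, gx)]
  if (!any(nonves)) return(length(occ) * bin_deg)
  feas <- unique(floor(((atan2(gdy[nonves], gdx[nonves]) * 180 / pi) %% 360) / bin_deg))
  feas <- union(feas, occ)
  blocked <- setdiff(0:(nbin - 1), feas)
  # a blocked run (the tube passing through) counts as wrapped only when the
  # cell occupies the bins on both of its flanks
  extra <- 0L
  if (length(blocked)) {
    in_blocked <- (0:(nbin - 1)) %in% blocked
    # find circular runs of blocked bins
    start <- which(in_blocked & !in_blocked[c(nbin, 1:(nbin - 1))])
    for (s in start) {
      len <- 0L; i <- s
      while (in_blocked[i]) { len <- len + 1L; i <- i %% nbin + 1L }
      before <- (s - 2L) %% nbin
      after <- (i - 1L) %% nbin
      if ((before %in% occ) && (after %in% occ)) extra <- extra + len
    }
    if (all(in_blocked)) extra <- 0L
  }
  min((length(occ) + extra) * bin_deg, 360)
}

#' Classify a cell's vascular connection
#'
#' Computes the on-vessel mass fraction `f` (fraction of cell pixels within
#' `max(2 px, local vessel radius)` of the vessel surface) and the median
#' angular wrap over contacted centreline nodes, then applies the
#' three-way rule: enveloping if wrap >= `psi_env` and `f >= f_min`; mural
#' if wrap >= `psi_mur` and `f >= f_min`; otherwise non-enveloping. The
#' three classes are mutually exclusive and exhaustive; cells with no
#' vessel contact are non-enveloping with a warning.
#'
#' @param cell_mask full-frame logical matrix or [cell_outline()].
#' @param network `vessel_network` with partition filled.
#' @param vessel_mask logical matrix.
#' @param psi_env,psi_mur wrap thresholds in degrees (defaults 300, 120).
#' @param f_min on-vessel mass fraction threshold (default 0.5).
#' @param tol_px contact tolerance passed to [find_contacts()].
#' @param t_max_um cap on the on-vessel band half-width (um, default 3):
#'   cell mass counts as "at the vessel" when within
#'   `max(2 px, min(local radius, t_max_um))` of the vessel surface.
#' @return list `class`, `wrap_deg`, `mass_fraction`, `contacts`.
#' @export
classify_connection <- function(cell_mask, network, vessel_mask,
                                psi_env = 300, psi_mur = 120, f_min = 0.5,
                                tol_px = 1, t_max_um = 3) {
  if (inherits(cell_mask, "cell_outline")) {
    cell_mask <- outline_mask(cell_mask, dim(vessel_mask))
  }
  contacts <- find_contacts(cell_mask, network, vessel_mask, tol_px)
  if (!nrow(contacts)) {
    warning("cell contacts no vessel; classified non-enveloping")
    return(list(class = "non-enveloping", wrap_deg = 0, mass_fraction = 0,
                contacts = contacts))
  }
  ny <- nrow(vessel_mask)
  cell_xy <- idx_to_xy(which(cell_mask), ny)
  nd <- network$nodes
  # on-vessel mass fraction: distance to vessel surface vs local radius
  dsurf <- edt(!vessel_mask)  # distance to nearest vessel pixel (centre)
  near <- nearest_node_index(cell_xy, nd)
  r_loc_px <- nd$radius_um[near] / network$px_um
  t_class <- pmax(2, pmin(r_loc_px, t_max_um / network$px_um))
  dcell <- dsurf[xy_to_idx(cell_xy[, 1], cell_xy[, 2], ny)]
  f <- mean(dcell <= t_class + 0.5)
  # wrap per contacted vessel over its contact-supporting nodes (nearest
  # nodes of contact pixels). Per vessel the 80th-percentile node wrap is
  # used (a fully wrapped tube section need not span the entire vessel);
  # the cell statistic is the largest per-vessel value, so enwrapping any
  # one vessel counts.
  cand <- attr(contacts, "contact_nodes")
  # cross-sections are ill-defined at junctions: drop contact nodes close to
  # a branch point unless nothing else remains
  if (length(network$branch_nodes)) {
    bx <- nd$x[network$branch_nodes]; by <- nd$y[network$branch_nodes]
    excl <- vapply(cand, function(i) {
      r_px <- nd$radius_um[i] / network$px_um
      any((bx - nd$x[i])^2 + (by - nd$y[i])^2 <= (2 * r_px + 3)^2)
    }, logical(1))
    if (!all(excl)) cand <- cand[!excl]
  }
  wraps <- vapply(cand, function(i) {
    wrap_angle_at_node(cell_xy, c(nd$x[i], nd$y[i]),
                       nd$radius_um[i] / network$px_um, vessel_mask)
  }, numeric(1))
  keep <- !is.na(wraps)
  wrap <- if (any(keep)) {
    max(vapply(split(wraps[keep], nd$vessel_id[cand][keep]),
               function(w) unname(stats::quantile(w, 0.8, type = 1)),
               numeric(1)))
  } else 0
  cls <- if (wrap >= psi_env && f >= f_min) "enveloping"
         else if (wrap >= psi_mur && f >= f_min) "mural"
         else "non-enveloping"
  list(class = cls, wrap_deg = wrap, mass_fraction = f, contacts = contacts)
}

#' Export a vessel network as GraphML
#'
#' Node attributes: `x`, `y`, `radius_um`, `vessel_id`.
#' @param network a `vessel_network`.
#' @param path output file.
#' @export
write_network_graphml <- function(network, path) {
  g <- network$graph
  g <- igraph::set_vertex_attr(g, "x", value = network$nodes$x)
  g <- igraph::set_vertex_attr(g, "y", value = network$nodes$y)
  g <- igraph::set_vertex_attr(g, "radius_um", value = network$nodes$radius_um)
  g <- igraph::set_vertex_attr(g, "vessel_id",
                               value = as.integer(network$nodes$vessel_id))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
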