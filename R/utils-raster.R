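# Raster (binary-mask) utilities. Masks are logical/integer matrices indexed
# m[y, x] with y increasing downward; pixel centres at integer coordinates.

#' Shift a matrix by (dy, dx), padding with `fill`
#' @keywords internal
shift_mat <- function(m, dy, dx, fill = 0) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- max(1, 1 + dy):min(ny, ny + dy)
  xs <- max(1, 1 + dx):min(nx, nx + dx)
  if (length(ys) && length(xs)) {
    out[ys, xs] <- m[ys - dy, xs - dx]
  }
  out
}

#' Integer offsets of a circular window
#' @param radius window radius in pixels; offsets satisfy dy^2 + dx^2 <= r^2.
#' @keywords internal
disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
}

#' Label connected components with 8-connected foreground
#'
#' EBImage's labeller is 4-connected, so diagonally adjacent labels are merged
#' afterwards through a label-adjacency graph.
#' @param mask logical matrix.
#' @return integer matrix of labels (0 = background).
#' @keywords internal
label_components <- function(mask, connectivity = 8) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  if (connectivity == 4 || max(lab) <= 1) return(lab)
  pairs <- NULL
  for (d in list(c(1, 1), c(1, -1))) {
    s <- shift_mat(lab, d[1], d[2])
    sel <- lab > 0 & s > 0 & lab != s
    if (any(sel)) pairs <- rbind(pairs, cbind(lab[sel], s[sel]))
  }
  if (is.null(pairs)) return(lab)
  g <- igraph::graph_from_edgelist(matrix(as.character(unique(pairs)), ncol = 2),
                                   directed = FALSE)
  comp <- igraph::components(g)
  remap <- seq_len(max(lab))
  remap[as.integer(igraph::V(g)$name)] <- comp$membership + max(lab)
  lab2 <- lab
  lab2[lab > 0] <- remap[lab[lab > 0]]
  # renumber 1..k in first-appearance order
  u <- unique(lab2[lab2 > 0])
  final <- integer(max(lab2))
  final[u] <- seq_along(u)
  lab2[lab2 > 0] <- final[lab2[lab2 > 0]]
  lab2
}

#' Binary dilation by a chessboard/disc radius
#' @keywords internal
mask_dilate <- function(mask, r_px = 1, shape = c("box", "disc")) {
  shape <- match.arg(shape)
  if (r_px <= 0) return(mask)
  if (shape == "box") {
    out <- mask
    for (d in seq_len(r_px)) {
      acc <- out
      for (dy in -1:1) for (dx in -1:1) {
        if (dy || dx) acc <- acc | shift_mat(out, dy, dx, FALSE)
      }
      out <- acc
    }
    return(out)
  }
  off <- disk_offsets(r_px)
  out <- mask
  for (i in seq_len(nrow(off))) {
    out <- out | shift_mat(mask, off$dy[i], off$dx[i], FALSE)
  }
  out
}

#' Euclidean distance transform (distance of TRUE pixels to nearest FALSE)
#' @keywords internal
edt <- function(mask) {
  EBImage::imageData(EBImage::distmap(mask * 1))
}

#' Trace the outer boundary of a connected region (Moore neighbourhood)
#'
#' Returns the closed chain of boundary pixel centres as an (x, y) matrix,
#' traced with Jacob's stopping criterion. The region must be 8-connected.
#' @keywords internal
trace_boundary <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) stop("empty mask", call. = FALSE)
  # start: topmost of leftmost foreground pixels
  xs <- (idx - 1L) %/% ny + 1L
  ys <- (idx - 1L) %% ny + 1L
  ord <- order(xs, ys)
  start <- c(xs[ord[1]], ys[ord[1]])
  if (length(idx) == 1L) return(matrix(start, 1, 2, dimnames = list(NULL, c("x", "y"))))
  # Moore neighbours clockwise on screen (y down), starting west
  nbr <- matrix(c(-1, 0, -1, -1, 0, -1, 1, -1, 1, 0, 1, 1, 0, 1, -1, 1),
                ncol = 2, byrow = TRUE)  # (dx, dy)
  inside <- function(x, y) x >= 1 && x <= nx && y >= 1 && y <= ny && mask[y, x]
  pts <- matrix(0L, 4L * length(idx) + 8L, 2L)
  np <- 0L
  cur <- start
  b <- 1L          # search start: direction we backtracked from (west at start)
  first_dir <- NA_integer_
  repeat {
    d <- NA_integer_
    for (k in 0:7) {
      dd <- (b + k - 1L) %% 8L + 1L
      if (inside(cur[1] + nbr[dd, 1], cur[2] + nbr[dd, 2])) { d <- dd; break }
    }
    if (is.na(d)) { np <- 1L; pts[1, ] <- cur; break }  # isolated pixel
    # Jacob's criterion: stop on re-entering start with the same first move
    if (np > 0L && all(cur == start) && d == first_dir) break
    if (np == 0L) first_dir <- d
    np <- np + 1L
    pts[np, ] <- cur
    cur <- c(cur[1] + nbr[d, 1], cur[2] + nbr[d, 2])
    b <- (d + 4L) %% 8L + 1L  # one past the direction pointing back at cur
    if (np >= nrow(pts)) break  # safety
  }
  colnames(pts) <- c("x", "y")
  pts[seq_len(np), , drop = FALSE]
}

#' Identify hole components of a region mask
#'
#' Background 4-connected components that do not touch the frame of the
#' (padded) mask are interior holes.
#' @param mask logical matrix of one region.
#' @return integer matrix labelling holes 1..k (0 elsewhere).
#' @keywords internal
hole_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  pad <- matrix(FALSE, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- mask
  bg <- EBImage::imageData(EBImage::bwlabel((!pad) * 1))  # 4-connected
  outside <- bg[1, 1]
  holes <- bg[2:(ny + 1), 2:(nx + 1)]
  holes[holes == outside] <- 0L
  u <- setdiff(unique(as.integer(holes)), 0L)
  if (length(u)) {
    remap <- integer(max(holes))
    remap[u] <- seq_along(u)
    holes[holes > 0] <- remap[holes[holes > 0]]
  }
  holes
}

#' Fill interior holes below an area bound (in pixels)
#' @keywords internal
fill_small_holes <- function(mask, max_px) {
  if (max_px <= 0) return(mask)
  hl <- hole_components(mask)
  if (max(hl) == 0) return(mask)
  sizes <- tabulate(hl[hl > 0])
  small <- which(sizes < max_px)
  if (length(small)) mask[hl %in% small] <- TRUE
  mask
}

#' Zhang-Suen binary thinning to a 1-px skeleton
#'
#' Vectorised over the full matrix; iterates until no pixel is removed.
#' @keywords internal
skeletonize_mask <- function(mask) {
  m <- mask
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- shift_mat(m, -1, 0, FALSE); p3 <- shift_mat(m, -1, 1, FALSE)
      p4 <- shift_mat(m, 0, 1, FALSE);  p5 <- shift_mat(m, 1, 1, FALSE)
      p6 <- shift_mat(m, 1, 0, FALSE);  p7 <- shift_mat(m, 1, -1, FALSE)
      p8 <- shift_mat(m, 0, -1, FALSE); p9 <- shift_mat(m, -1, -1, FALSE)
      bp <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      ap <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
            (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (phase == 1) {
        cond <- m & bp >= 2 & bp <= 6 & ap == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & bp >= 2 & bp <= 6 & ap == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Break residual 2x2 blocks in a thinned skeleton
#'
#' Zhang-Suen thinning can leave 2x2 solid blocks, which read as spurious
#' 4-cycles in the pixel-adjacency graph. For each block the pixel with the
#' fewest neighbours outside the block is removed; its external neighbours
#' remain 8-adjacent to the other block pixels.
#' @keywords internal
break_2x2_blocks <- function(skel) {
  ny <- nrow(skel); nx <- ncol(skel)
  repeat {
    blk <- skel[-ny, -nx] & skel[-1, -nx] & skel[-ny, -1] & skel[-1, -1]
    idx <- which(blk)
    if (!length(idx)) break
    i <- idx[1]
    y0 <- (i - 1L) %% (ny - 1L) + 1L
    x0 <- (i - 1L) %/% (ny - 1L) + 1L
    cand <- rbind(c(y0, x0), c(y0 + 1L, x0), c(y0, x0 + 1L), c(y0 + 1L, x0 + 1L))
    nb_out <- apply(cand, 1, function(p) {
      cnt <- 0L
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0 && dx == 0) next
        y2 <- p[1] + dy; x2 <- p[2] + dx
        if (y2 < 1 || x2 < 1 || y2 > ny || x2 > nx) next
        inblock <- y2 >= y0 && y2 <= y0 + 1L && x2 >= x0 && x2 <= x0 + 1L
        if (!inblock && skel[y2, x2]) cnt <- cnt + 1L
      }
      cnt
    })
    drop <- cand[which.min(nb_out), ]
    skel[drop[1], drop[2]] <- FALSE
  }
  skel
}

#' Linear indices to (x, y) coordinates
#' @keywords internal
idx_to_xy <- function(idx, ny) {
  cbind(x = (idx - 1L) %/% ny + 1L, y = (idx - 1L) %% ny + 1L)
}

#' (x, y) coordinates to linear indices
#' @keywords internal
xy_to_idx <- function(x, y, ny) {
  (x - 1L) * ny + y
}
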