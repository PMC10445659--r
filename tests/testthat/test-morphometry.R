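# Shape descriptors: Feret, fitted ellipse, circularity/roundness/solidity,
# soma displacement, and scale equivariance.

test_that("ideal shapes recover their analytic descriptors", {
  o <- cell_outline(disk_mask(40), 1)
  sm <- shape_metrics(o)
  expect_gte(sm$fo_circularity, 0.95)
  expect_gte(sm$fo_roundness, 0.98)
  expect_gte(sm$fo_solidity, 0.98)
  expect_lt(abs(sm$fo_area_um2 - pi * 1600) / (pi * 1600), 0.02)
  expect_lt(abs(sm$fo_perimeter_um - 2 * pi * 40) / (2 * pi * 40), 0.03)
  # 30x40 rectangle: 3-4-5 diagonal
  or <- cell_outline(rect_mask(30, 40), 1)
  expect_lt(abs(feret_diameter(or)$max_um - 50), 1)
  expect_equal(shape_metrics(or)$cvh_feret_um, feret_diameter(or)$max_um)
})

test_that("max Feret equals the exhaustive pairwise maximum on hull vertices", {
  for (s in 1:50) {
    m <- random_blob_mask(s)
    o <- cell_outline(m, 1)
    pts <- astromorph:::boundary_corners(o$outer)
    hull <- astromorph:::convex_hull(pts)
    brute <- max(dist(hull))
    expect_equal(feret_diameter(o)$max_um, brute)
  }
})

test_that("Feret is invariant under 90-degree rotation and handles degenerate inputs", {
  m <- random_blob_mask(99)
  f1 <- feret_diameter(cell_outline(m, 1))
  f2 <- feret_diameter(cell_outline(t(m)[ncol(m):1, ], 1))
  expect_equal(f1$max_um, f2$max_um, tolerance = 1e-12)
  expect_equal(f1$min_um, f2$min_um, tolerance = 1e-12)
  # a single pixel reports the pixel diagonal
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  fs <- feret_diameter(cell_outline(single, 1))
  expect_equal(fs$max_um, sqrt(2))
  # a straight segment of length L
  seg <- matrix(FALSE, 5, 40); seg[3, 6:35] <- TRUE
  fseg <- feret_diameter(cell_outline(seg, 1))
  expect_lt(abs(fseg$max_um - sqrt(30^2 + 1)) / 30, 0.05)
  expect_lte(fseg$min_um, 1.5)
})

test_that("fitted ellipse recovers planted axes and matches the moment formula", {
  em <- matrix(FALSE, 80, 140)
  for (y in 1:80) for (x in 1:140) {
    if (((x - 70) / 60)^2 + ((y - 40) / 20)^2 <= 1) em[y, x] <- TRUE
  }
  fe <- fit_ellipse(cell_outline(em, 1))
  expect_lt(abs(fe$major_um - 120) / 120, 0.02)
  expect_lt(abs(fe$minor_um - 40) / 40, 0.02)
  # disk: axes equal within 1%
  fd <- fit_ellipse(cell_outline(disk_mask(30), 1))
  expect_lt(abs(fd$major_um - fd$minor_um) / fd$major_um, 0.01)
  # direct pixel-summation moment oracle on a random blob
  m <- random_blob_mask(4)
  fb <- fit_ellipse(cell_outline(m, 1))
  xy <- which(m, arr.ind = TRUE)  # (row=y, col=x)
  n <- nrow(xy)
  cx <- mean(xy[, 2]); cy <- mean(xy[, 1])
  cxx <- sum((xy[, 2] - cx)^2) / n + 1 / 12
  cyy <- sum((xy[, 1] - cy)^2) / n + 1 / 12
  cxy <- sum((xy[, 2] - cx) * (xy[, 1] - cy)) / n
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2))$values
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
  scale_f <- sqrt(n / (pi / 4 * major * minor))
  expect_equal(fb$major_um, major * scale_f, tolerance = 1e-8)
  expect_equal(fb$minor_um, minor * scale_f, tolerance = 1e-8)
  # collinear region: zero minor axis with a warning
  seg <- matrix(FALSE, 5, 30); seg[3, 4:27] <- TRUE
  expect_warning(fit_ellipse(cell_outline(seg, 1)), "collinear")
})

test_that("solidity equals the pixel-count ratio against a hull rasterisation oracle", {
  for (s in c(2, 6, 13)) {
    m <- random_blob_mask(s)
    o <- cell_outline(m, 1)
    sm <- shape_metrics(o)
    hull <- astromorph:::convex_hull(o$outer)
    # oracle: test every pixel centre against the hull polygon half-planes
    nh <- nrow(hull)
    inside <- matrix(TRUE, nrow(m), ncol(m))
    xs <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
    ys <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
    for (i in seq_len(nh)) {
      j <- i %% nh + 1
      ex <- hull[j, 1] - hull[i, 1]; ey <- hull[j, 2] - hull[i, 2]
      # counter-clockwise hull: interior has non-negative cross product
      inside <- inside & (ex * (ys - hull[i, 2]) - ey * (xs - hull[i, 1])) >= -1e-9
    }
    oracle_count <- sum(inside | m)
    expect_equal(sm$fo_solidity, min(sum(m) / oracle_count, 1), tolerance = 5e-3)
    expect_gte(sm$cvh_area_um2, sm$fo_area_um2)
  }
})

test_that("soma displacement is a translation-invariant Euclidean distance", {
  o <- cell_outline(disk_mask(25), 0.5)
  cen <- shape_metrics(o)
  centre <- c(cen$cvh_centroid_x_um, cen$cvh_centroid_y_um)
  expect_equal(soma_displacement(o, centre)$distance_um, 0, tolerance = 1e-9)
  off <- soma_displacement(o, centre + c(3, 4))
  expect_equal(off$distance_um, 5, tolerance = 1e-9)
  expect_error(soma_displacement(o, c(-50, -50), frame_dim = c(71, 71)),
               "outside")
})

test_that("planted soma offsets are recovered from the rendered soma channel", {
  r <- cached_scene(seed = 11)
  px <- r$stack$px_um
  proj_soma <- project_std(r$stack, "soma")
  for (cc in r$truth$cells[seq_len(min(3, length(r$truth$cells)))]) {
    o <- cell_outline(astromorph:::embed_mask(cc$mask, cc$offset,
                                              r$truth$params$field_px), px)
    # soma centroid from the soma-channel blob nearest the cell
    sp_px <- cc$soma_um / px
    win <- 12
    ys <- max(1, round(sp_px[2]) - win):min(nrow(proj_soma$data), round(sp_px[2]) + win)
    xs <- max(1, round(sp_px[1]) - win):min(ncol(proj_soma$data), round(sp_px[1]) + win)
    blob <- proj_soma$data[ys, xs]
    wy <- sum(ys * rowSums(blob)) / sum(blob)
    wx <- sum(xs * colSums(blob)) / sum(blob)
    meas <- soma_displacement(o, c(wx, wy) * px)$distance_um
    expect_lt(abs(meas - cc$soma_offset_um), 0.5)
  }
})

test_that("calibration scales areas and lengths consistently", {
  m <- random_blob_mask(21)
  s1 <- shape_metrics(cell_outline(m, 0.5))
  s2 <- shape_metrics(cell_outline(m, 1.0))
  expect_equal(s2$fo_area_um2 / s1$fo_area_um2, 4)
  expect_equal(s2$fo_perimeter_um / s1$fo_perimeter_um, 2)
  expect_equal(s2$fo_feret_um / s1$fo_feret_um, 2)
  expect_equal(s2$fo_solidity, s1$fo_solidity)
  expect_equal(s2$fo_circularity, s1$fo_circularity)
})

test_that("marker coverage is the marker fraction inside the outline", {
  m <- disk_mask(20)
  o <- cell_outline(m, 1)
  marker <- m & (matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE) <= 31)
  sm <- shape_metrics(o, marker = marker)
  expect_equal(sm$pct_marker, 100 * sum(marker & m) / sum(m))
})
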