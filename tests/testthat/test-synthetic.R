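# Synthetic retina generator: vessel trees, astrocyte construction with
# planted motifs, rendering, ground truth and annotation tables.

test_that("vessel trees realise the planted branch topology", {
  p0 <- scene_params(vessels = list(root_radius_um = 3, n_branches = 0,
                                    radius_decay = 0.75, cont_decay = 0.92),
                     seed = 3)
  v0 <- generate_vessel_network(p0, seed = 3)
  expect_equal(v0$n_unique, 1L)
  expect_equal(length(v0$paths), 1L)
  # Y-shape: one branch event gives two unique vessels
  p1 <- scene_params(vessels = list(root_radius_um = 4, n_branches = 1,
                                    radius_decay = 0.75, cont_decay = 0.92),
                     seed = 4)
  v1 <- generate_vessel_network(p1, seed = 4)
  expect_equal(v1$n_branch_events, 1L)
  expect_equal(v1$n_unique, 2L)
  # each branch event adds exactly one unique vessel
  for (s in 5:8) {
    ps <- scene_params(vessels = list(root_radius_um = 4, n_branches = s - 2,
                                      radius_decay = 0.75, cont_decay = 0.92),
                       seed = s)
    vs <- generate_vessel_network(ps, seed = s)
    expect_equal(vs$n_unique, 1L + vs$n_branch_events)
  }
  # sub-pixel root radius is rejected
  pbad <- scene_params(px_um = 2,
                       vessels = list(root_radius_um = 1, n_branches = 1,
                                      radius_decay = 0.75, cont_decay = 0.92))
  expect_error(generate_vessel_network(pbad, seed = 1), "unresolvable vessel")
})

test_that("a straight tube rasterises at its analytic width", {
  tf <- tube_fixture(radius_um = 3, px_um = 0.5)
  # width 6 um = 12 px, +- 1 px, measured column-wise away from the ends
  widths <- colSums(tf$mask[, 40:160])
  expect_true(all(abs(widths * tf$px_um - 6) <= 1 * tf$px_um + 0.5))
})

test_that("a bare disk cell carries analytic truth within 1%", {
  spec <- list(center_px = c(100, 100), area_um2 = pi * 20^2, px_um = 0.5,
               field_px = c(256, 256), irregularity = 0, n_processes = 0,
               motifs = character(0))
  cell <- generate_astrocyte(spec, seed = 5)
  expect_lt(abs(cell$truth$area_um2 - pi * 400) / (pi * 400), 0.01)
  expect_lt(abs(cell$analytic$area_um2 - pi * 400) / (pi * 400), 0.01)
  # supersampled-oracle consistency against the analytic polygon
  expect_lt(abs(cell$truth$area_um2 - cell$analytic$area_um2) /
              cell$analytic$area_um2, 0.005)
})

test_that("planted bristles leave short skeleton endpoints outside the core", {
  spec <- list(center_px = c(128, 128), area_um2 = 1200, px_um = 0.5,
               field_px = c(256, 256), irregularity = 0.1, n_processes = 0,
               motifs = rep("bristle", 3))
  cell <- generate_astrocyte(spec, seed = 9)
  mi <- cell$motif_instances
  expect_equal(sum(mi$motif == "bristle"), 3)
  expect_true(all(mi$length_um[mi$motif == "bristle"] <= 5))
  expect_true(all(mi$length_um[mi$motif == "bristle"] >= 0.7))
  # skeleton endpoints outside the core radius
  skel <- astromorph:::skeletonize_mask(cell$mask)
  sg <- astromorph:::build_skel_graph(skel)
  tips <- which(sg$deg == 1)
  tip_xy <- cbind(sg$xy[tips, 1] + cell$offset[1], sg$xy[tips, 2] + cell$offset[2])
  d <- sqrt((tip_xy[, 1] - 128)^2 + (tip_xy[, 2] - 128)^2)
  r_core <- vapply(seq_len(nrow(tip_xy)), function(i) {
    cell$core_radius_at(atan2(tip_xy[i, 2] - 128, tip_xy[i, 1] - 128) %% (2 * pi))
  }, numeric(1))
  expect_gte(sum(d > r_core - 1), 3)
  # smallest-bristle variant stays in the 0.7-2.5 um range
  spec$small_bristles <- TRUE
  cs <- generate_astrocyte(spec, seed = 10)
  expect_true(all(cs$motif_instances$length_um <= 2.5))
})

test_that("tube and end-foot motifs require a vessel context", {
  spec <- list(center_px = c(100, 100), area_um2 = 900, px_um = 0.5,
               field_px = c(256, 256), motifs = "tube")
  expect_error(generate_astrocyte(spec, vessel_context = NULL, seed = 1),
               "tube motif requires a vessel")
  spec$motifs <- "end-foot"
  expect_error(generate_astrocyte(spec, vessel_context = NULL, seed = 1),
               "end-foot motif requires a vessel")
})

test_that("a planted tube cell wraps its vessel by at least 300 degrees", {
  tf <- tube_fixture(radius_um = 2.5, px_um = 0.5, nx = 300, ny = 200, y0 = 100)
  vtx <- list(nodes = data.frame(x = seq(25, 275, by = 2), y = 100,
                                 radius_um = 2.5, vessel_id = 1L),
              branch_points = NULL, mask = tf$mask, px_um = 0.5,
              n_unique = 1L)
  class(vtx) <- "vessel_truth"
  cell <- generate_astrocyte(list(center_px = c(150, 100), area_um2 = 600,
                                  px_um = 0.5, field_px = c(300, 200),
                                  connection = "enveloping"),
                             vtx, seed = 7)
  cm <- astromorph:::embed_mask(cell$mask, cell$offset, c(300, 200))
  net <- split_unique_vessels(skeletonize_vessels(tf$mask, 0.5))
  # wrap measured at mid-tube cross-sections on the generated mask
  cl <- classify_connection(cm, net, tf$mask)
  expect_gte(cl$wrap_deg, 300)
  # the cell touches vessel voxels
  expect_true(any(astromorph:::mask_dilate(cm, 1) & tf$mask))
})

test_that("rendered scenes have exact noise-free support, planted GFAP fraction, and are deterministic", {
  r <- cached_scene(seed = 11)
  sc <- r$truth$params
  union_mask <- Reduce(`|`, lapply(r$truth$cells, function(cc) {
    astromorph:::embed_mask(cc$mask, cc$offset, sc$field_px)
  }))
  supp <- apply(r$stack$channels$membrane, c(1, 2), max) > 0
  expect_identical(unname(supp), unname(union_mask))
  # planted GFAP coverage within rounding of the target fraction
  for (i in seq_along(r$truth$cells)) {
    g <- r$truth$gfap_masks[[i]]
    frac <- sum(g$mask) / sum(r$truth$cells[[i]]$mask)
    expect_lt(abs(frac - sc$gfap_fraction),
              1 / sum(r$truth$cells[[i]]$mask) + 1e-9)
  }
  # bit-identical re-render under the same seed
  r2 <- small_scene(seed = 11)
  expect_identical(r$stack, r2$stack)
  expect_identical(generate_annotation_table(r$truth),
                   generate_annotation_table(r2$truth))
})

test_that("supersampled truth is self-consistent on re-rasterisation", {
  # recompute truth from an independently supersampled mask: < 0.5% drift
  spec <- list(center_px = c(128, 128), area_um2 = 1100, px_um = 0.5,
               field_px = c(256, 256), irregularity = 0.2, n_processes = 3)
  cell <- generate_astrocyte(spec, seed = 21)
  loc_polys <- lapply(cell$polys, function(p) {
    cbind(p[, 1] - cell$offset[1], p[, 2] - cell$offset[2])
  })
  loc_holes <- lapply(cell$holes, function(p) {
    cbind(p[, 1] - cell$offset[1], p[, 2] - cell$offset[2])
  })
  m4 <- astromorph:::rasterize_polygons(loc_polys, loc_holes,
                                        ncol(cell$mask) * 4L,
                                        nrow(cell$mask) * 4L, scale = 4L)
  t2 <- truth_metrics_from_mask(m4, 0.5 / 4)
  expect_lt(abs(t2$area_um2 - cell$truth$area_um2) / cell$truth$area_um2, 0.005)
  expect_lt(abs(t2$feret_um - cell$truth$feret_um) / cell$truth$feret_um, 0.005)
})

test_that("annotation tables mirror the planted motif flags", {
  r <- cached_scene(seed = 11)
  tbl <- generate_annotation_table(r$truth)
  expect_named(tbl, c("cell_id", "motif", "axon", "soma", "astrocyte"))
  # per-class flag counts equal the planted truth counts
  planted <- do.call(rbind, lapply(seq_along(r$truth$cells), function(i) {
    mi <- r$truth$cells[[i]]$motif_instances
    if (nrow(mi)) cbind(cell_id = i, mi) else NULL
  }))
  expect_equal(nrow(tbl), nrow(planted))
  for (m in unique(tbl$motif)) {
    expect_equal(sum(tbl$axon[tbl$motif == m]),
                 sum(planted$axon[planted$motif == m]))
    expect_equal(sum(tbl$soma[tbl$motif == m]),
                 sum(planted$soma[planted$motif == m]))
  }
  # empty truth gives an empty table with the header
  empty <- generate_annotation_table(list())
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("cell_id", "motif", "axon", "soma", "astrocyte"))
})

test_that("planted tube and end-foot cells touch vessel voxels", {
  r <- cached_scene(seed = 11)
  vm <- r$truth$vessels$mask
  for (cc in r$truth$cells) {
    if (any(cc$motif_instances$motif %in% c("tube", "end-foot"))) {
      cm <- astromorph:::embed_mask(cc$mask, cc$offset, r$truth$params$field_px)
      expect_true(any(astromorph:::mask_dilate(cm, 1) & vm))
    }
  }
})

test_that("stacks round-trip through multi-page TIFF", {
  r <- cached_scene(seed = 11)
  path <- file.path(tempdir(), "stack.tif")
  write_stack_tiff(r$stack, path)
  s2 <- read_stack_tiff(path)
  expect_equal(names(s2$channels), names(r$stack$channels))
  expect_equal(s2$px_um, r$stack$px_um)
  expect_lt(max(abs(s2$channels$membrane - r$stack$channels$membrane)), 1e-6)
  unlink(c(path, paste0(path, ".json")))
})
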