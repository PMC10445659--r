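# Vessel skeletonization, unique-vessel partition, distances, contacts and
# connection classification.

test_that("a straight tube skeletonizes to one path with the right radii", {
  tf <- tube_fixture(radius_um = 3, px_um = 0.5)
  net <- skeletonize_vessels(tf$mask, tf$px_um)
  expect_equal(length(net$branch_nodes), 0)
  expect_equal(length(net$segments), 1)
  mid <- net$nodes$x > 40 & net$nodes$x < 160
  expect_true(all(abs(net$nodes$radius_um[mid] - 3) <= 0.5 * tf$px_um + 0.26))
  net <- split_unique_vessels(net)
  expect_equal(net$n_unique, 1L)
  expect_error(skeletonize_vessels(matrix(FALSE, 10, 10), 0.5), "empty")
})

test_that("a Y-mask yields one degree-3 branch point and two unique vessels", {
  yf <- y_vessel_fixture()
  net <- skeletonize_vessels(yf$mask, yf$px_um)
  expect_equal(length(net$branch_nodes), 1)
  expect_equal(net$nodes$degree[net$branch_nodes], 3)
  net <- split_unique_vessels(net)
  expect_equal(net$n_unique, 2L)
})

test_that("unique-vessel counts equal 1 + branch events on random trees", {
  for (s in 1:20) {
    set.seed(1000 + s)
    nb <- sample(2:6, 1)
    sc <- scene_params(vessels = list(root_radius_um = 4, n_branches = nb,
                                      radius_decay = 0.75, cont_decay = 0.92),
                       seed = s)
    vt <- generate_vessel_network(sc, seed = s)
    net <- split_unique_vessels(skeletonize_vessels(vt$mask, sc$px_um))
    expect_equal(net$n_unique, 1L + vt$n_branch_events)
    # partition conservation: every node carries exactly one vessel id
    expect_false(anyNA(net$nodes$vessel_id))
    expect_equal(sort(unique(net$vessel_of_segment)),
                 seq_len(net$n_unique))
  }
})

test_that("distance to the nearest vessel matches analytic and brute-force values", {
  tf <- tube_fixture(radius_um = 3, px_um = 0.5)
  # tube edge at y = 50 +- 6 px; point 50 px above the axis
  d <- distance_to_nearest_vessel(c(100, 10), tf$mask, tf$px_um)
  expect_lt(abs(d - (50 - 10 - 6) * 0.5), 1 * 0.5 + 0.3)
  expect_equal(distance_to_nearest_vessel(c(100, 50), tf$mask, tf$px_um), 0)
  # brute-force oracle over all vessel pixels
  vxy <- which(tf$mask, arr.ind = TRUE)
  for (pt in list(c(30, 15), c(150, 90), c(7, 60))) {
    brute <- max(min(sqrt((vxy[, 2] - pt[1])^2 + (vxy[, 1] - pt[2])^2)) - 0.5, 0) * 0.5
    expect_equal(distance_to_nearest_vessel(pt, tf$mask, tf$px_um), brute,
                 tolerance = 1e-6)
  }
  expect_error(distance_to_nearest_vessel(c(5, 5), matrix(FALSE, 9, 9), 1),
               "no vessels")
})

test_that("contacts count unique vessels and report tube diameters", {
  yf <- y_vessel_fixture()
  net <- split_unique_vessels(skeletonize_vessels(yf$mask, yf$px_um))
  # cell overlapping the parent and both daughters: 2 unique contacts
  cm <- matrix(FALSE, 200, 200)
  for (y in 60:140) for (x in 70:140) {
    if ((x - 105)^2 + (y - 100)^2 <= 35^2) cm[y, x] <- TRUE
  }
  ct <- find_contacts(cm, net, yf$mask)
  expect_equal(nrow(ct), 2)
  expect_true(all(ct$d_min_um <= ct$d_mean_um & ct$d_mean_um <= ct$d_max_um))
  # a far-away cell contacts nothing
  far <- matrix(FALSE, 200, 200); far[10:20, 150:170] <- TRUE
  expect_equal(nrow(find_contacts(far, net, yf$mask)), 0)
  # straight tube of radius 4 um: all contact diameters 8 +- 1 um
  tf <- tube_fixture(radius_um = 4, px_um = 0.5)
  nets <- split_unique_vessels(skeletonize_vessels(tf$mask, tf$px_um))
  cell <- matrix(FALSE, 100, 200); cell[20:41, 80:120] <- TRUE
  cts <- find_contacts(cell, nets, tf$mask)
  expect_equal(nrow(cts), 1)
  expect_lt(abs(cts$d_mean_um - 8), 1)
})

test_that("connection classification is total, single-valued, and recovers planted classes", {
  px <- 0.5
  m <- matrix(FALSE, 300, 300)
  m <- astromorph:::paint_tube(m, data.frame(x = c(20, 150), y = c(150, 150),
                                             radius_um = 3, vessel_id = 1L), px)
  m <- astromorph:::paint_tube(m, data.frame(x = c(150, 280), y = c(150, 100),
                                             radius_um = 2.5, vessel_id = 1L), px)
  m <- astromorph:::paint_tube(m, data.frame(x = c(150, 280), y = c(150, 200),
                                             radius_um = 2.5, vessel_id = 1L), px)
  vtx <- list(nodes = rbind(
    data.frame(x = seq(20, 150, by = 2), y = 150, radius_um = 3, vessel_id = 1L),
    data.frame(x = seq(152, 280, by = 2), y = seq(150, 100, length.out = 65),
               radius_um = 2.5, vessel_id = 1L),
    data.frame(x = seq(152, 280, by = 2), y = seq(150, 200, length.out = 65),
               radius_um = 2.5, vessel_id = 2L)),
    branch_points = matrix(c(150, 150), 1, 2), mask = m, px_um = px,
    n_unique = 2L)
  class(vtx) <- "vessel_truth"
  net <- split_unique_vessels(skeletonize_vessels(m, px))
  classes <- c("enveloping", "mural", "non-enveloping")
  n_ok <- 0L
  for (s in 1:4) {
    env <- generate_astrocyte(list(center_px = c(80, 150), area_um2 = 600,
                                   px_um = px, field_px = c(300, 300),
                                   connection = "enveloping"), vtx, seed = s)
    mur <- generate_astrocyte(list(center_px = c(150, 150), area_um2 = 500,
                                   px_um = px, field_px = c(300, 300),
                                   connection = "mural"), vtx, seed = s + 10)
    ef <- generate_astrocyte(list(center_px = c(80, 60), area_um2 = 900,
                                  px_um = px, field_px = c(300, 300),
                                  motifs = "end-foot", n_processes = 3),
                             vtx, seed = s + 20)
    for (pair in list(list(env, "enveloping"), list(mur, "mural"),
                      list(ef, "non-enveloping"))) {
      cm <- astromorph:::embed_mask(pair[[1]]$mask, pair[[1]]$offset, c(300, 300))
      cl <- classify_connection(cm, net, m)
      expect_true(cl$class %in% classes)
      expect_length(cl$class, 1)
      n_ok <- n_ok + (cl$class == pair[[2]])
    }
  }
  expect_gte(n_ok, 11)  # 12 planted cells; allow one borderline geometry
  # a cell with no contact is non-enveloping with a warning
  lone <- matrix(FALSE, 300, 300); lone[20:30, 20:30] <- TRUE
  expect_warning(cl0 <- classify_connection(lone, net, m), "no vessel")
  expect_equal(cl0$class, "non-enveloping")
})

test_that("GraphML export writes node radii and vessel ids", {
  yf <- y_vessel_fixture()
  net <- split_unique_vessels(skeletonize_vessels(yf$mask, yf$px_um))
  path <- file.path(tempdir(), "net.graphml")
  write_network_graphml(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_true(all(c("x", "y", "radius_um", "vessel_id") %in%
                    igraph::vertex_attr_names(g)))
  unlink(path)
})
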