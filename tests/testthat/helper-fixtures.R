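# Shared fixtures: small analytic masks and compact synthetic scenes, built
# in code at test time.

disk_mask <- function(R, n = 2 * R + 21, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  (xs - cx)^2 + (ys - cy)^2 <= R^2
}

rect_mask <- function(w, h, pad = 10) {
  m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- TRUE
  m
}

annulus_mask <- function(R, r, n = 2 * R + 21) {
  disk_mask(R, n) & !disk_mask(r, n)
}

# random blob: thresholded sum of Gaussian bumps, one 8-connected component
random_blob_mask <- function(seed, n = 96) {
  set.seed(seed)
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  acc <- matrix(0, n, n)
  for (k in 1:6) {
    cx <- runif(1, n * 0.3, n * 0.7); cy <- runif(1, n * 0.3, n * 0.7)
    s <- runif(1, n / 12, n / 6)
    acc <- acc + exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * s^2))
  }
  m <- acc > quantile(acc, 0.85)
  lab <- astromorph:::label_components(m, 8)
  lab == which.max(tabulate(lab[lab > 0]))
}

# straight-tube vessel mask + matching truth-like path
tube_fixture <- function(radius_um = 3, px_um = 0.5, nx = 200, ny = 100,
                         y0 = 50) {
  path <- data.frame(x = c(20, nx - 20), y = c(y0, y0),
                     radius_um = radius_um, vessel_id = 1L)
  mask <- astromorph:::paint_tube(matrix(FALSE, ny, nx), path, px_um)
  list(mask = mask, path = path, px_um = px_um)
}

y_vessel_fixture <- function(px_um = 0.5) {
  m <- matrix(FALSE, 200, 200)
  m <- astromorph:::paint_tube(m, data.frame(x = c(20, 100), y = c(100, 100),
                                             radius_um = 2.5, vessel_id = 1L), px_um)
  m <- astromorph:::paint_tube(m, data.frame(x = c(100, 180), y = c(100, 60),
                                             radius_um = 2, vessel_id = 1L), px_um)
  m <- astromorph:::paint_tube(m, data.frame(x = c(100, 180), y = c(100, 140),
                                             radius_um = 2, vessel_id = 1L), px_um)
  list(mask = m, px_um = px_um)
}

small_scene <- function(seed = 11, n_cells = 5, noise_sd = 0,
                        field = c(384, 384)) {
  sc <- scene_params(n_cells = n_cells, field_px = field, noise_sd = noise_sd,
                     seed = seed)
  suppressWarnings(render_flatmount(sc))
}

# cache one rendered scene across tests within a run
scene_cache <- new.env(parent = emptyenv())
cached_scene <- function(key = "default", ...) {
  if (is.null(scene_cache[[key]])) scene_cache[[key]] <- small_scene(...)
  scene_cache[[key]]
}
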