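# Projection, thresholding, particle extraction and XOR outline composition.

test_that("standard-deviation projection matches closed forms and a brute-force oracle", {
  # constant stack projects to zero
  arr <- array(3, c(8, 8, 4))
  expect_true(all(project_std(arr)$data == 0))
  # two planes {0, 2}: sample SD (n-1) is sqrt(2)
  arr2 <- array(0, c(5, 5, 2)); arr2[, , 2] <- 2
  expect_equal(project_std(arr2)$data, matrix(sqrt(2), 5, 5))
  # random 10-plane stack equals the per-pixel loop
  set.seed(42)
  arr3 <- array(runif(6 * 7 * 10), c(6, 7, 10))
  p <- project_std(arr3)$data
  oracle <- matrix(0, 6, 7)
  for (i in 1:6) for (j in 1:7) oracle[i, j] <- sd(arr3[i, j, ])
  expect_equal(p, oracle)
  # single plane rejected
  expect_error(project_std(array(1, c(4, 4, 1))), "2 planes")
})

test_that("global threshold separates bimodal images and rejects constants", {
  set.seed(7)
  img <- matrix(sample(c(10, 200), 400, replace = TRUE), 20, 20)
  mask <- threshold_global(img)
  expect_identical(as.vector(mask), as.vector(img == 200))
  # symmetry: thresholding the negated image swaps the classes
  mask_neg <- threshold_global(-img)
  expect_identical(as.vector(mask_neg), as.vector(!mask))
  expect_error(threshold_global(matrix(5, 4, 4)), "degenerate histogram")
})

test_that("global threshold recovers noise-free synthetic masks exactly", {
  r <- cached_scene(seed = 11)
  proj <- project_std(r$stack, "membrane")
  mask <- threshold_global(proj)
  truth_union <- Reduce(`|`, lapply(r$truth$cells, function(cc) {
    astromorph:::embed_mask(cc$mask, cc$offset, r$truth$params$field_px)
  }))
  expect_identical(matrix(as.vector(mask), nrow(mask)), unname(truth_union))
})


test_that("Phansalkar threshold handles constants and equals brute force on random images", {
  # constant image is degenerate under min-max normalisation: all background
  cimg <- matrix(0.5, 40, 40)
  mask <- suppressWarnings(threshold_phansalkar(cimg, radius = 5))
  expect_false(any(mask))
  # the closed form at s = 0: t = m * (1 + p*exp(-q*m) - k); for the
  # normalised value m the threshold map must match it exactly
  set.seed(8)
  img0 <- matrix(runif(30 * 30), 30, 30)
  msk <- threshold_phansalkar(img0, radius = 29 %/% 2)
  expect_true(is.matrix(attr(msk, "threshold")))
  # brute-force windowed evaluation on a 64x64 image, exact agreement
  set.seed(3)
  img <- matrix(runif(64 * 64), 64, 64)
  fast <- threshold_phansalkar(img, radius = 7)
  slow <- phansalkar_bruteforce(img, radius = 7)
  expect_identical(as.vector(fast), as.vector(slow))
  expect_equal(max(abs(attr(fast, "threshold") -
                         attr(threshold_phansalkar(img, radius = 7), "threshold"))), 0)
  expect_error(threshold_phansalkar(img, radius = 70), "larger than image")
})

test_that("Phansalkar recovers a bright filament on a dark field", {
  img <- matrix(0.05, 80, 80)
  img[40, 10:70] <- 1
  mask <- threshold_phansalkar(img, radius = 15)
  expect_true(all(mask[40, 10:70]))
  expect_lt(sum(mask & img < 0.5) / sum(img < 0.5), 0.01)
})

test_that("particle extraction applies the area bound and flags holes", {
  px <- 1  # 1 um/px: areas in px equal areas in um^2
  m <- matrix(FALSE, 60, 60)
  m[10:12, 10] <- TRUE               # 3 px speck < 3 um^2? exactly 3 -> kept
  m[20, 20] <- TRUE                  # 1 px speck, dropped
  m[35:52, 35:52] <- TRUE            # 18x18 blob
  regs <- extract_particles(m, px, min_area_um2 = 3)
  expect_equal(sum(!vapply(regs, `[[`, logical(1), "is_hole")), 2)
  regs5 <- extract_particles(m, px, min_area_um2 = 5)
  expect_equal(length(regs5), 1)
  # annulus: one filled outer region plus one hole region
  am <- annulus_mask(20, 10)
  regs_a <- extract_particles(am, px, min_area_um2 = 3)
  expect_equal(vapply(regs_a, `[[`, logical(1), "is_hole"), c(FALSE, TRUE))
  expect_equal(regs_a[[2]]$parent, regs_a[[1]]$id)
})

flood_fill_count <- function(mask) {
  # independent 8-connected component counter
  n <- 0L
  visited <- matrix(FALSE, nrow(mask), ncol(mask))
  for (start in which(mask & !visited)) {
    if (visited[start]) next
    n <- n + 1L
    queue <- start
    visited[start] <- TRUE
    ny <- nrow(mask)
    while (length(queue)) {
      cur <- queue[length(queue)]; queue <- queue[-length(queue)]
      y <- (cur - 1L) %% ny + 1L; x <- (cur - 1L) %/% ny + 1L
      for (dy in -1:1) for (dx in -1:1) {
        y2 <- y + dy; x2 <- x + dx
        if (y2 >= 1 && y2 <= ny && x2 >= 1 && x2 <= ncol(mask)) {
          i2 <- (x2 - 1L) * ny + y2
          if (mask[i2] && !visited[i2]) { visited[i2] <- TRUE; queue <- c(queue, i2) }
        }
      }
    }
  }
  n
}

test_that("region count matches a flood-fill oracle on random masks", {
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(runif(50 * 50) > 0.7, 50, 50)
    regs <- extract_particles(m, px_um = 10, min_area_um2 = 0)
    n_outer <- sum(!vapply(regs, `[[`, logical(1), "is_hole"))
    expect_equal(n_outer, flood_fill_count(m))
  }
})

test_that("XOR composition reproduces the annulus and is order-independent", {
  px <- 1
  am <- annulus_mask(20, 10)
  regs <- extract_particles(am, px, 3)
  o <- compose_outline(regs, c(regs[[1]]$id, regs[[2]]$id), px)
  expect_equal(sum(o$mask), sum(am))
  expect_lt(abs(sum(o$mask) - pi * (400 - 100)) / (pi * 300), 0.02)
  expect_equal(length(o$holes), 1)
  # single selection is the identity
  o1 <- compose_outline(regs, regs[[1]]$id, px)
  expect_equal(sum(o1$mask), length(regs[[1]]$idx))
  # XOR order independence and exact set-algebra agreement
  set.seed(5)
  m <- matrix(runif(40 * 40) > 0.55, 40, 40)
  regs2 <- extract_particles(m, px, 0)
  ids <- vapply(regs2, `[[`, integer(1), "id")
  sel <- ids[seq_len(min(5, length(ids)))]
  ref <- compose_outline(regs2, sel, px)
  ref_mask <- outline_mask(ref, dim(m))
  # set-algebra oracle
  acc <- rep(FALSE, length(m))
  for (id in sel) acc <- xor(acc, seq_along(acc) %in% regs2[[which(ids == id)]]$idx)
  lab <- astromorph:::label_components(matrix(acc, 40, 40), 8)
  largest <- lab == which.max(tabulate(lab[lab > 0]))
  expect_identical(unname(ref_mask), unname(largest))
  for (rep_i in 1:3) {
    perm <- sample(sel)
    expect_identical(outline_mask(compose_outline(regs2, perm, px), dim(m)),
                     ref_mask)
  }
  expect_error(compose_outline(regs2, max(ids) + 1L, px), "unknown region")
})

test_that("automated region selection picks the particle at a seed point plus its holes", {
  px <- 1
  am <- annulus_mask(20, 10)
  regs <- extract_particles(am, px, 3)
  ids <- select_regions_at(regs, c(31, 31))  # centre of the annulus frame
  expect_setequal(ids, c(regs[[1]]$id, regs[[2]]$id))
  o <- compose_outline(regs, ids, px)
  expect_equal(sum(o$mask), sum(am))
})
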