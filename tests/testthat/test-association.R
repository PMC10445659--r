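# Association tables, population summaries, the feature matrix, embedding /
# clustering, and the parameter correlation dendrogram.


test_that("motif probabilities are exact counts and allow non-exclusive contacts", {
  tbl <- data.frame(motif = rep("sail", 10), axon = rep(c(1, 0), c(6, 4)),
                    soma = 0, astrocyte = 0)
  at <- motif_structure_probabilities(tbl)
  expect_equal(at$p_axon, 60)
  expect_equal(at$n, 10)
  # all flags set: each probability 100, row sum 300
  tbl2 <- data.frame(motif = rep("bead", 5), axon = 1, soma = 1, astrocyte = 1)
  at2 <- motif_structure_probabilities(tbl2)
  expect_equal(at2$p_axon + at2$p_soma + at2$p_astrocyte, 300)
  expect_equal(at2$error, 0)
})

test_that("probabilities match an exhaustive counting oracle on random tables", {
  tbl <- random_annotation_table(200, seed = 31)
  at <- motif_structure_probabilities(tbl)
  for (i in seq_len(nrow(at))) {
    sub <- tbl[tbl$motif == at$motif[i], ]
    expect_equal(at$n[i], nrow(sub))
    expect_equal(at$p_axon[i], 100 * sum(sub$axon) / nrow(sub))
    expect_equal(at$p_soma[i], 100 * sum(sub$soma) / nrow(sub))
    expect_equal(at$p_astrocyte[i], 100 * sum(sub$astrocyte) / nrow(sub))
    # exact rational counts: p * n / 100 is an integer
    expect_equal(at$p_axon[i] * at$n[i] / 100,
                 round(at$p_axon[i] * at$n[i] / 100), tolerance = 1e-9)
    # binomial error at the mean flagged proportion
    pbar <- mean(c(at$p_axon[i], at$p_soma[i], at$p_astrocyte[i])) / 100
    expect_equal(at$error[i], 100 * sqrt(pbar * (1 - pbar) / at$n[i]))
  }
  # Wilson alternative is labelled and differs for small n
  atw <- motif_structure_probabilities(tbl, error_method = "wilson")
  expect_equal(attr(atw, "error_method"), "wilson")
  # cell-level denominator counts each cell once
  atc <- motif_structure_probabilities(tbl, denominator = "cell")
  for (i in seq_len(nrow(atc))) {
    sub <- tbl[tbl$motif == atc$motif[i], ]
    expect_equal(atc$n[i], length(unique(sub$cell_id)))
  }
})

test_that("population summaries match closed forms and recover planted means", {
  rec <- data.frame(n_unique_contacts = c(1, 2, 3, 4))
  s <- population_summaries(rec)
  expect_equal(s$pct_contacting_vessel, 100)
  expect_equal(s$mean_unique_contacts, 2.5)
  expect_equal(s$sem_unique_contacts, sd(1:4) / 2)
  expect_equal(sum(s$freq_unique_contacts), 4)
  expect_error(population_summaries(data.frame()), "empty")
  # Monte-Carlo recovery of a planted mean 2.6 within 2 SEM
  coh <- generate_contact_cohort(n = 1000, lambda = 1.6, seed = 77)
  sc <- population_summaries(coh)
  expect_lt(abs(sc$mean_unique_contacts - 2.6), 2 * sc$sem_unique_contacts + 1e-9)
  expect_equal(sc$pct_contacting_vessel, 100)
})

test_that("the feature matrix enforces the canonical 20-column order", {
  coh <- generate_feature_cohort(5, seed = 2)
  rec <- coh$features
  rec$cell_id <- seq_len(nrow(rec))
  fm <- build_feature_matrix(rec)
  expect_equal(ncol(fm), 20)
  expect_identical(names(fm), feature_columns())
  rec_bad <- rec
  rec_bad$longitude_rad[3] <- NA
  expect_error(build_feature_matrix(rec_bad), "longitude")
  rec_missing <- rec[, setdiff(names(rec), "fo_solidity")]
  expect_error(build_feature_matrix(rec_missing), "fo_solidity")
})

test_that("embedding separates planted morphology populations", {
  skip_if_not_installed("mclust")
  coh <- generate_feature_cohort(100, k = 3, seed = 4)
  res <- embed_cluster(coh$features, seed = 9)
  expect_equal(dim(res$embedding), c(300, 2))
  keep <- res$cluster != -1
  ari <- mclust::adjustedRandIndex(res$cluster[keep], coh$labels[keep])
  expect_gte(length(unique(res$cluster[keep])), 2)
  expect_gte(ari, 0.8)
  # determinism under a fixed seed
  res2 <- embed_cluster(coh$features, seed = 9)
  expect_identical(res$embedding, res2$embedding)
  expect_identical(res$cluster, res2$cluster)
  # stage isolation: swapping the clustering backend leaves the embedding
  # (the upstream output) unchanged
  res_km <- embed_cluster(coh$features, seed = 9, cluster_method = "kmeans")
  expect_identical(res_km$embedding, res$embedding)
})

test_that("duplicate-row matrices collapse to one co-located cluster", {
  m <- as.data.frame(matrix(rep(c(1, 2, 3), each = 40), nrow = 40))
  colnames(m) <- paste0("f", 1:3)
  res <- embed_cluster(m, seed = 1, n_neighbors = 10, min_cluster_size = 10)
  expect_lt(max(dist(res$embedding)), 1e-8)
  expect_equal(unique(res$cluster), 1L)
})

test_that("correlation dendrogram merges perfect correlates first and matches a brute-force agglomeration", {
  set.seed(12)
  n <- 300
  a <- rnorm(n)
  m <- data.frame(a = a, b = 2 * a + 5, c = rnorm(n), d = rnorm(n), e = rnorm(n))
  cd <- correlation_dendrogram(m)
  expect_equal(cd$hclust$height[1], 0, tolerance = 1e-12)
  first <- colnames(m)[-cd$hclust$merge[1, ]]
  expect_setequal(first, c("a", "b"))
  # newick string parses with the feature names as tips
  tr <- ape::read.tree(text = cd$newick)
  expect_setequal(tr$tip.label, colnames(m))
  # brute-force average-linkage agglomeration oracle on 5 features
  D <- 1 - abs(cor(m))
  active <- as.list(seq_len(5))
  heights <- c()
  repeat {
    k <- length(active)
    if (k == 1) break
    best <- c(NA, NA); bh <- Inf
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      h <- mean(D[active[[i]], active[[j]]])
      if (h < bh) { bh <- h; best <- c(i, j) }
    }
    heights <- c(heights, bh)
    active[[best[1]]] <- c(active[[best[1]]], active[[best[2]]])
    active[[best[2]]] <- NULL
  }
  expect_equal(sort(cd$hclust$height), sort(heights), tolerance = 1e-12)
  # zero-variance columns are excluded with a warning
  m$z <- 1
  expect_warning(correlation_dendrogram(m), "zero-variance")
})

test_that("independent features stay weakly correlated at n = 1000", {
  set.seed(99)
  m <- matrix(rnorm(1000 * 6), 1000, 6)
  r <- cor(m)
  expect_lt(max(abs(r[upper.tri(r)])), 0.1)
  cd <- correlation_dendrogram(as.data.frame(m))
  expect_true(all(cd$hclust$height > 0.8))
})
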