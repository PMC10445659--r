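# Motif-structure association tables, population contact summaries, the
# 20-parameter feature matrix, embedding + density clustering, and the
# parameter correlation dendrogram.

MOTIF_LEVELS <- c("sail", "bead", "pad", "bristle", "tube", "end-foot", "hole")

#' The 20 morphology feature columns, in canonical order
#' @export
feature_columns <- function() {
  c("fo_area_um2", "fo_perimeter_um", "fo_major_axis_um",
    "fo_minor_axis_um", "fo_circularity", "fo_feret_um", "fo_roundness",
    "fo_solidity", "cvh_area_um2", "cvh_perimeter_um", "cvh_feret_um",
    "latitude_rad", "longitude_rad", "pct_gfap",
    "dist_cvh_centroid_to_vessel_um", "dist_cvh_centroid_to_com_um",
    "mean_vessel_diam_um", "min_vessel_diam_um", "max_vessel_diam_um",
    "n_unique_vessels")
}

#' Conditional structure probabilities given a motif
#'
#' For every motif class, the probability (percent) of each contacted
#' structure given an observation of the motif, `p(structure | motif)`,
#' as exact instance counts (no smoothing). The error column is the
#' binomial standard error of the mean flagged proportion
#' `100 * sqrt(pbar * (1 - pbar) / n)` by default, or the half-width of
#' the Wilson 95% interval at `pbar`.
#'
#' @param table annotation data.frame with columns `motif` and logical/0-1
#'   `axon`, `soma`, `astrocyte` (one row per motif instance).
#' @param error_method `"binomial"` (default) or `"wilson"`.
#' @param denominator `"instance"` (default: each planted motif instance
#'   counts once) or `"cell"` (each cell exhibiting the motif counts once;
#'   requires a `cell_id` column).
#' @return data.frame `motif, p_axon, p_soma, p_astrocyte, error, n` with
#'   attribute `"error_method"`; motifs absent from the table are omitted.
#' @export
motif_structure_probabilities <- function(table,
                                          error_method = c("binomial", "wilson"),
                                          denominator = c("instance", "cell")) {
  error_method <- match.arg(error_method)
  denominator <- match.arg(denominator)
  need <- c("motif", "axon", "soma", "astrocyte")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  rows <- list()
  for (m in intersect(MOTIF_LEVELS, unique(table$motif))) {
    sub <- table[table$motif == m, , drop = FALSE]
    if (denominator == "cell") {
      if (is.null(sub$cell_id)) stop("cell denominator requires a cell_id column")
      agg <- stats::aggregate(sub[c("axon", "soma", "astrocyte")],
                              by = list(cell_id = sub$cell_id),
                              FUN = function(v) as.integer(any(v > 0)))
      sub <- agg
    }
    n <- nrow(sub)
    p <- vapply(c("axon", "soma", "astrocyte"),
                function(f) 100 * sum(sub[[f]] > 0) / n, numeric(1))
    pbar <- mean(p) / 100
    err <- if (error_method == "binomial") {
      100 * sqrt(pbar * (1 - pbar) / n)
    } else {
      z <- stats::qnorm(0.975)
      100 * z * sqrt(pbar * (1 - pbar) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    }
    rows[[m]] <- data.frame(motif = m, p_axon = p[["axon"]],
                            p_soma = p[["soma"]],
                            p_astrocyte = p[["astrocyte"]],
                            error = err, n = n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "error_method") <- error_method
  out
}

#' Population-level contact summaries
#'
#' Fractions of cells contacting at least one vessel, axons, somas and any
#' neuronal element; the mean +/- SEM of unique vessel contacts; and the
#' full contact-count frequency distribution.
#'
#' @param records data.frame with `n_unique_contacts` and (optionally)
#'   logical `contacts_axon`, `contacts_soma`.
#' @return list of summaries (fractions as percentages).
#' @export
population_summaries <- function(records) {
  if (is.null(records) || !nrow(records)) stop("empty input")
  nuc <- records$n_unique_contacts
  if (is.null(nuc)) stop("records lack n_unique_contacts")
  n <- length(nuc)
  freq <- table(factor(nuc, levels = 0:max(nuc)))
  out <- list(
    n = n,
    pct_contacting_vessel = 100 * mean(nuc >= 1),
    mean_unique_contacts = mean(nuc),
    sem_unique_contacts = stats::sd(nuc) / sqrt(n),
    freq_unique_contacts = as.integer(freq),
    freq_levels = as.integer(names(freq))
  )
  if (!is.null(records$contacts_axon)) {
    out$pct_contacting_axon <- 100 * mean(records$contacts_axon > 0)
  }
  if (!is.null(records$contacts_soma)) {
    out$pct_contacting_soma <- 100 * mean(records$contacts_soma > 0)
  }
  if (!is.null(records$contacts_axon) && !is.null(records$contacts_soma)) {
    out$pct_contacting_neuronal <-
      100 * mean(records$contacts_axon > 0 | records$contacts_soma > 0)
  }
  out
}

#' Assemble the 20-parameter cell feature matrix
#'
#' Validates completeness and returns the features in the canonical column
#' order (geometry in um/um^2, coordinates in radians, GFAP coverage in
#' percent, contact counts as integers).
#'
#' @param records data.frame with (at least) the columns of
#'   [feature_columns()]; a `cell_id` column is carried through as
#'   rownames.
#' @return numeric data.frame with exactly the 20 feature columns.
#' @export
build_feature_matrix <- function(records) {
  cols <- feature_columns()
  for (cn in cols) {
    if (is.null(records[[cn]])) stop("missing column: ", cn)
    bad <- which(!is.finite(records[[cn]]))
    if (length(bad)) {
      id <- if (!is.null(records$cell_id)) records$cell_id[bad[1]] else bad[1]
      stop(sprintf("missing value in column %s for cell %s", cn, id))
    }
  }
  out <- records[cols]
  if (!is.null(records$cell_id)) rownames(out) <- records$cell_id
  out
}

#' Embed the feature matrix in 2D and cluster by density
#'
#' The embedding stage is pluggable: the default is principal components
#' of the z-scored features; clustering is HDBSCAN (in-package,
#' `min_samples`/`min_cluster_size` as in the study configuration) or
#' k-means. Neighbourhood-graph parameters are recorded in the metadata for
#' provenance.
#'
#' @param matrix feature data.frame/matrix (rows = cells).
#' @param seed integer seed.
#' @param embed_method `"pca"`.
#' @param cluster_method `"hdbscan"` (default) or `"kmeans"`.
#' @param scale z-score features first (default TRUE).
#' @param n_neighbors recorded neighbourhood size (metadata).
#' @param min_samples,min_cluster_size HDBSCAN parameters (defaults 3, 10).
#' @param k clusters for k-means (default 3).
#' @return list `embedding` (n x 2 matrix, columns u1/u2), `cluster`
#'   (integer labels, -1 = noise), `metadata`.
#' @export
embed_cluster <- function(matrix, seed = 1, embed_method = c("pca"),
                          cluster_method = c("hdbscan", "kmeans"),
                          scale = TRUE, n_neighbors = 15, min_samples = 3,
                          min_cluster_size = 10, k = 3) {
  embed_method <- match.arg(embed_method)
  cluster_method <- match.arg(cluster_method)
  m <- as.matrix(matrix)
  if (nrow(m) < max(min_cluster_size, 2)) {
    stop("fewer rows than min_cluster_size")
  }
  if (nrow(m) < n_neighbors) stop("fewer rows than n_neighbors")
  if (any(!is.finite(m))) stop("feature matrix contains missing values")
  set.seed(seed)
  if (scale) {
    sds <- apply(m, 2, stats::sd)
    keep <- sds > 0
    m <- scale(m[, keep, drop = FALSE])
  }
  if (ncol(m) == 0) {
    # fully degenerate input (all columns constant): co-located embedding
    m <- matrix(0, nrow(m), 1)
  }
  emb <- stats::prcomp(m, center = !scale, scale. = FALSE)$x
  if (ncol(emb) < 2) emb <- cbind(emb, 0)
  emb <- emb[, 1:2, drop = FALSE]
  colnames(emb) <- c("u1", "u2")
  labels <- if (cluster_method == "hdbscan") {
    hdbscan_fit(emb, min_samples = min_samples,
                min_cluster_size = min_cluster_size)$labels
  } else {
    as.integer(stats::kmeans(emb, centers = k, nstart = 10)$cluster)
  }
  list(embedding = emb, cluster = labels,
       metadata = list(embed_method = embed_method,
                       cluster_method = cluster_method,
                       scaled = scale, n_neighbors = n_neighbors,
                       min_samples = min_samples,
                       min_cluster_size = min_cluster_size, seed = seed))
}

#' Correlation dendrogram over the feature columns
#'
#' Pairwise Pearson correlations, distance `1 - |r|`, average-linkage
#' hierarchical clustering; returns the ordered linkage so that strongly
#' related parameters sit together.
#'
#' @param matrix feature data.frame/matrix (columns = parameters).
#' @return list `hclust`, `order` (leaf order, column names), `cor`
#'   (correlation matrix), `newick` (Newick string over feature names).
#' @export
correlation_dendrogram <- function(matrix) {
  m <- as.matrix(matrix)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("excluding zero-variance column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  if (ncol(m) < 3) stop("need >= 3 features with variance > 0")
  r <- stats::cor(m)
  d <- stats::as.dist(1 - abs(r))
  hc <- stats::hclust(d, method = "average")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, order = colnames(m)[hc$order], cor = r, newick = nwk)
}
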