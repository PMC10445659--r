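# End-to-end orchestration: configuration, the cell inclusion filter, the
# full synthetic-scene pipeline run with standard-format outputs and a
# reproducibility manifest.

#' Pipeline configuration
#'
#' All stage parameters with their study defaults: Otsu global threshold,
#' Phansalkar radius 15 (k=0.25, r=0.5, p=2, q=10), particle bound 3 um^2,
#' 1 px contact tolerance, connection-class thresholds 300/120 degrees at
#' mass fraction 0.5, hemisphere rim angle 22 degrees (provenance), and
#' embedding parameters n_neighbors=15, min_samples=3, min_cluster_size=10.
#'
#' @param scene list of [scene_params()] arguments for synthetic runs.
#' @param global_method global threshold method ("otsu").
#' @param phansalkar list `radius, k, r, p, q`.
#' @param min_area_um2 particle lower bound (um^2).
#' @param contact_tol_px contact dilation tolerance (px).
#' @param connection list `psi_env, psi_mur, f_min`.
#' @param phi0_deg dissection rim angle, carried for provenance.
#' @param embedding list `n_neighbors, min_samples, min_cluster_size,
#'   cluster_method, scale`.
#' @param seed integer master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(scene = list(),
                            global_method = "otsu",
                            phansalkar = list(radius = 15, k = 0.25,
                                              r = 0.5, p = 2, q = 10),
                            min_area_um2 = 3,
                            contact_tol_px = 1,
                            connection = list(psi_env = 300, psi_mur = 120,
                                              f_min = 0.5),
                            phi0_deg = 22,
                            embedding = list(n_neighbors = 15,
                                             min_samples = 3,
                                             min_cluster_size = 10,
                                             cluster_method = "hdbscan",
                                             scale = TRUE),
                            seed = 1) {
  stopifnot(min_area_um2 > 0, contact_tol_px >= 0, phansalkar$radius >= 1)
  out <- list(scene = scene, global_method = global_method,
              phansalkar = phansalkar, min_area_um2 = min_area_um2,
              contact_tol_px = contact_tol_px, connection = connection,
              phi0_deg = phi0_deg, embedding = embedding,
              seed = as.integer(seed))
  class(out) <- "pipeline_config"
  out
}

#' Write / read a pipeline configuration (YAML)
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Inclusion filter: drop cells touching another labelled cell
#'
#' A cell is excluded if its composed outline is missing (outline
#' determination failed) or if its mask lies within 1 px of another
#' labelled cell's mask. Every exclusion carries a reason string.
#'
#' @param outlines list; each element a [cell_outline()] or NULL when
#'   composition failed.
#' @return list `included` (integer indices), `excluded` (data.frame
#'   `cell, reason`).
#' @export
apply_inclusion_filter <- function(outlines) {
  n <- length(outlines)
  reasons <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (is.null(outlines[[i]])) reasons[i] <- "outline could not be determined"
  }
  ok <- which(is.na(reasons))
  if (length(ok) > 1) {
    for (a in seq_along(ok)[-length(ok)]) {
      for (b in (a + 1):length(ok)) {
        i <- ok[a]; j <- ok[b]
        if (masks_touch(outlines[[i]], outlines[[j]])) {
          reasons[i] <- reasons[j] <- "contact with labeled cell"
        }
      }
    }
  }
  list(included = which(is.na(reasons)),
       excluded = data.frame(cell = which(!is.na(reasons)),
                             reason = reasons[!is.na(reasons)]))
}

#' Run the full pipeline on a synthetic scene
#'
#' Renders (or reuses) a synthetic flat-mount, then runs every stage:
#' standard-deviation projection, global thresholding and particle
#' extraction of the membrane channel, per-cell XOR outline composition
#' seeded at the true hull centroids, the inclusion filter, Phansalkar
#' binarisation of the GFAP channel, shape metrics, vessel
#' skeletonization + unique-vessel contacts + connection classification,
#' retinal coordinates, the 20-parameter feature matrix, association
#' table, population summaries, embedding/clustering and the correlation
#' dendrogram. Deterministic given the config seed.
#'
#' @param config a [pipeline_config()].
#' @param scene_data optional pre-rendered list(stack, truth) from
#'   [render_flatmount()]; generated from `config$scene` when NULL.
#' @param outdir optional output directory; when given, all products are
#'   written (CSV/JSON/YAML/GraphML/Newick) together with a run manifest.
#' @return (invisibly) a results list: `records`, `features`,
#'   `association`, `summaries`, `embedding`, `dendrogram`, `inclusion`,
#'   `network`, `manifest`.
#' @export
run_pipeline <- function(config, scene_data = NULL, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(scene_data)) {
    sc <- do.call(scene_params, c(config$scene, list(seed = config$seed)))
    scene_data <- suppressWarnings(render_flatmount(sc))
  }
  stack <- scene_data$stack
  truth <- scene_data$truth
  px <- stack$px_um
  field <- dim(stack$channels[[1]])[1:2]  # ny, nx

  # --- segmentation --------------------------------------------------------
  proj_mem <- project_std(stack, "membrane")
  mask_mem <- threshold_global(proj_mem, config$global_method)
  particles <- extract_particles(mask_mem, px, config$min_area_um2)
  outlines <- vector("list", length(truth$cells))
  primary_region <- integer(length(truth$cells))
  for (i in seq_along(truth$cells)) {
    seedpt <- truth$cells[[i]]$truth$cvh_centroid_um / px
    res <- try({
      ids <- select_regions_at(particles, seedpt)
      primary_region[i] <- ids[1]
      compose_outline(particles, ids, px)
    }, silent = TRUE)
    outlines[[i]] <- if (inherits(res, "try-error")) NULL else res
  }
  incl <- apply_inclusion_filter(outlines)
  # cells resolving to the same particle are mutual contacts by construction
  dup <- which(primary_region > 0 & duplicated(primary_region) |
                 primary_region > 0 &
                 duplicated(primary_region, fromLast = TRUE))
  if (length(dup)) {
    newly <- setdiff(dup, incl$excluded$cell)
    if (length(newly)) {
      incl$excluded <- rbind(incl$excluded,
                             data.frame(cell = newly,
                                        reason = "contact with labeled cell"))
    }
    incl$included <- setdiff(incl$included, dup)
    incl$excluded <- incl$excluded[order(incl$excluded$cell), , drop = FALSE]
  }

  # --- marker + vessels ----------------------------------------------------
  proj_gfap <- project_std(stack, "gfap")
  mask_gfap <- threshold_phansalkar(proj_gfap, config$phansalkar$radius,
                                    config$phansalkar$k, config$phansalkar$r,
                                    config$phansalkar$p, config$phansalkar$q)
  proj_ves <- project_std(stack, "vessel")
  mask_ves <- threshold_global(proj_ves, config$global_method)
  network <- split_unique_vessels(skeletonize_vessels(mask_ves, px))

  # --- per-cell records ----------------------------------------------------
  ann <- generate_annotation_table(truth)
  geo <- truth$params$geo
  records <- list()
  for (i in incl$included) {
    ol <- outlines[[i]]
    sm <- shape_metrics(ol, intensity = proj_mem$data, marker = mask_gfap)
    cen_px <- c(sm$cvh_centroid_x_um, sm$cvh_centroid_y_um) / px
    dves <- distance_to_nearest_vessel(pmin(pmax(round(cen_px), 1),
                                            c(field[2], field[1])),
                                       mask_ves, px)
    cls <- suppressWarnings(
      classify_connection(ol, network, mask_ves,
                          psi_env = config$connection$psi_env,
                          psi_mur = config$connection$psi_mur,
                          f_min = config$connection$f_min,
                          tol_px = config$contact_tol_px))
    co <- harmonize_eye(map_to_sphere(
      c(sm$cvh_centroid_x_um, sm$cvh_centroid_y_um), geo$onh_um,
      geo$rim_um, geo$dorsal_deg, geo$eye, config$phi0_deg))
    nvc <- nrow(cls$contacts)
    amot <- ann[ann$cell_id == i, , drop = FALSE]
    records[[length(records) + 1L]] <- data.frame(
      cell_id = i,
      sm[c("fo_area_um2", "fo_perimeter_um", "fo_major_axis_um",
           "fo_minor_axis_um", "fo_circularity", "fo_feret_um",
           "fo_roundness", "fo_solidity", "cvh_area_um2",
           "cvh_perimeter_um", "cvh_feret_um")],
      latitude_rad = co$lat_rad, longitude_rad = co$lon_rad,
      pct_gfap = sm$pct_marker,
      dist_cvh_centroid_to_vessel_um = dves,
      dist_cvh_centroid_to_com_um = sm$dist_centroid_com_um,
      mean_vessel_diam_um = if (nvc) mean(cls$contacts$d_mean_um) else NA_real_,
      min_vessel_diam_um = if (nvc) min(cls$contacts$d_min_um) else NA_real_,
      max_vessel_diam_um = if (nvc) max(cls$contacts$d_max_um) else NA_real_,
      n_unique_vessels = nvc,
      n_unique_contacts = nvc,
      connection_class = cls$class,
      wrap_deg = cls$wrap_deg,
      mass_fraction = cls$mass_fraction,
      contacts_axon = any(amot$axon > 0),
      contacts_soma = any(amot$soma > 0),
      soma_x_um = truth$cells[[i]]$soma_um[1],
      soma_y_um = truth$cells[[i]]$soma_um[2],
      soma_displacement_um = soma_displacement(ol, truth$cells[[i]]$soma_um,
                                               field)$distance_um)
  }
  records <- if (length(records)) do.call(rbind, records) else NULL

  features <- if (!is.null(records) &&
                  all(stats::complete.cases(records[feature_columns()]))) {
    build_feature_matrix(records)
  } else NULL

  association <- if (nrow(ann)) motif_structure_probabilities(ann) else NULL
  summaries <- if (!is.null(records)) population_summaries(records) else NULL

  emb <- NULL
  ecfg <- config$embedding
  if (!is.null(features) &&
      nrow(features) >= max(ecfg$min_cluster_size, ecfg$n_neighbors)) {
    emb <- embed_cluster(features, seed = config$seed,
                         cluster_method = ecfg$cluster_method,
                         scale = isTRUE(ecfg$scale),
                         n_neighbors = ecfg$n_neighbors,
                         min_samples = ecfg$min_samples,
                         min_cluster_size = ecfg$min_cluster_size)
  }
  dend <- if (!is.null(features) && nrow(features) >= 4) {
    tryCatch(suppressWarnings(correlation_dendrogram(features)),
             error = function(e) NULL)
  } else NULL

  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    package_version = tryCatch(
      as.character(utils::packageVersion("astromorph")),
      error = function(e) "dev"),
    n_cells_generated = length(truth$cells),
    n_cells_segmented = sum(!vapply(outlines, is.null, logical(1))),
    n_cells_included = length(incl$included),
    n_particles = length(particles),
    n_unique_vessels = network$n_unique,
    seed = config$seed)

  results <- list(records = records, features = features,
                  association = association, summaries = summaries,
                  embedding = emb, dendrogram = dend, inclusion = incl,
                  network = network, outlines = outlines,
                  annotation = ann, manifest = manifest, truth = truth)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(d, f) utils::write.csv(d, file.path(outdir, f),
                                            row.names = FALSE)
    if (!is.null(records)) wcsv(records, "records.csv")
    if (!is.null(features)) wcsv(cbind(cell_id = rownames(features), features),
                                 "features.csv")
    if (!is.null(association)) wcsv(association, "association.csv")
    wcsv(ann, "annotations.csv")
    if (!is.null(emb)) {
      wcsv(data.frame(cell_id = rownames(features),
                      u1 = emb$embedding[, 1], u2 = emb$embedding[, 2],
                      cluster = emb$cluster), "embedding.csv")
    }
    if (!is.null(dend)) {
      writeLines(dend$newick, file.path(outdir, "dendrogram.nwk"))
    }
    if (!is.null(summaries)) {
      jsonlite::write_json(summaries, file.path(outdir, "summaries.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    write_config(config, file.path(outdir, "config.yaml"))
    write_network_graphml(network, file.path(outdir, "vessels.graphml"))
    wcsv(data.frame(cell = incl$excluded$cell, reason = incl$excluded$reason),
         "excluded.csv")
  }
  invisible(results)
}
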