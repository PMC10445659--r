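# Lightweight cohort generators: population-scale synthetic records that do
# not require image rendering. Used for statistical recovery tests of the
# association, summary and trend stages.

#' Synthetic vessel-contact cohort
#'
#' Unique-contact counts are drawn as `1 + Poisson(lambda)` so that every
#' cell contacts at least one vessel (the observed regime) with mean
#' `1 + lambda`; axon/soma contact flags are Bernoulli at the observed
#' population rates.
#'
#' @param n cells (default 1000).
#' @param lambda Poisson rate; default 1.57 gives mean 2.57 unique
#'   contacts.
#' @param p_axon,p_soma contact probabilities (defaults 0.99, 0.978).
#' @param seed integer seed.
#' @return data.frame `cell_id, n_unique_contacts, contacts_axon,
#'   contacts_soma`.
#' @export
generate_contact_cohort <- function(n = 1000, lambda = 1.57, p_axon = 0.99,
                                    p_soma = 0.978, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(cell_id = seq_len(n),
             n_unique_contacts = 1L + stats::rpois(n, lambda),
             contacts_axon = stats::runif(n) < p_axon,
             contacts_soma = stats::runif(n) < p_soma)
}

#' Synthetic eccentricity cohort with a planted mid-retina maximum
#'
#' Latitudes are uniform over the hemisphere span `[-pi/2, 0]`; the value
#' follows a quadratic with (negative) curvature `a` peaking at
#' `peak_lat`, plus Gaussian noise.
#'
#' @param n cells (default 500).
#' @param a quadratic curvature (default -800, a mid-retina maximum).
#' @param peak_lat latitude of the extremum (default -pi/4, mid-retina).
#' @param base value at the extremum (default 2000, an area scale in um^2).
#' @param noise_sd Gaussian noise sd (default 400).
#' @param seed integer seed.
#' @return data.frame `lat_rad, value`.
#' @export
generate_eccentricity_cohort <- function(n = 500, a = -800,
                                         peak_lat = -pi / 4, base = 2000,
                                         noise_sd = 400, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lat <- stats::runif(n, -pi / 2, 0)
  val <- base + a * (lat - peak_lat)^2 + stats::rnorm(n, 0, noise_sd)
  data.frame(lat_rad = lat, value = val)
}

#' Synthetic morphology feature cohort with known class structure
#'
#' Draws cells from `k` morphology populations with distinct size and
#' vascular-contact profiles across the 20-parameter feature set, for
#' embedding/clustering recovery tests. Class centres are separated by
#' `separation` within-class standard deviations along the size axis.
#'
#' @param n_per_class cells per class (default 100).
#' @param k number of classes (default 3).
#' @param separation centre separation in within-class SD units.
#' @param seed integer seed.
#' @return list `features` (data.frame, 20 named columns), `labels`
#'   (integer class per row).
#' @export
generate_feature_cohort <- function(n_per_class = 100, k = 3,
                                    separation = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- c(fo_area_um2 = 1200, fo_perimeter_um = 260,
            fo_major_axis_um = 55, fo_minor_axis_um = 30,
            fo_circularity = 0.25, fo_feret_um = 60, fo_roundness = 0.5,
            fo_solidity = 0.75, cvh_area_um2 = 1700,
            cvh_perimeter_um = 160, cvh_feret_um = 60,
            latitude_rad = -0.8, longitude_rad = pi,
            pct_gfap = 21, dist_cvh_centroid_to_vessel_um = 8,
            dist_cvh_centroid_to_com_um = 15,
            mean_vessel_diam_um = 7, min_vessel_diam_um = 5,
            max_vessel_diam_um = 9, n_unique_vessels = 2.6)
  rel_sd <- 0.08
  # class effects: size scaling, contact count shift, gfap shift
  size_cols <- c("fo_area_um2", "fo_perimeter_um", "fo_major_axis_um",
                 "fo_minor_axis_um", "fo_feret_um", "cvh_area_um2",
                 "cvh_perimeter_um", "cvh_feret_um")
  rows <- list(); labels <- integer(0)
  for (cl in seq_len(k)) {
    centre <- base
    centre[size_cols] <- centre[size_cols] * (1 + separation * rel_sd * (cl - 1))
    centre["n_unique_vessels"] <- base["n_unique_vessels"] + (cl - 1) * 1.2
    centre["pct_gfap"] <- base["pct_gfap"] + (cl - 1) * separation * rel_sd * 15
    m <- matrix(stats::rnorm(n_per_class * length(centre)),
                n_per_class, length(centre))
    m <- sweep(m, 2, abs(centre) * rel_sd + 1e-6, `*`)
    m <- sweep(m, 2, centre, `+`)
    colnames(m) <- names(centre)
    rows[[cl]] <- as.data.frame(m)
    labels <- c(labels, rep(cl, n_per_class))
  }
  list(features = do.call(rbind, rows), labels = labels)
}
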