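# astromorph

Single-cell morphometry of retinal astrocytes and their vascular contacts.

Astrocytes of the retinal nerve fibre and ganglion cell layers, when
labelled through their entire membrane, show far richer morphology than the
classical stellate picture: recurring structural motifs (beads, sails,
tubes, bristles, pads, end-feet, membrane holes) that contact specific
partners, somas displaced far from the cell's centroid, GFAP covering only
about a fifth of the true cell area, and universal vascular contact through
three mutually exclusive connection classes (enveloping, mural,
non-enveloping). `astromorph` is a tested R implementation of the full
measurement pipeline for this kind of flat-mount data, plus a synthetic
retina generator with analytic ground truth so every stage can be validated
by parameter recovery.

## What it computes

For each cell with full outline *FO* and convex hull *CVH*:

* **Outline extraction** — standard-deviation Z-projection, automatic
  global threshold (Otsu), particle extraction with the 3 µm² lower bound,
  and XOR composition of outline/hole ROIs into the final complex outline.
* **Shape descriptors** — area, perimeter, fitted-ellipse axes,
  circularity `4πA/P²`, roundness `4A/(π·major²)`, solidity `A/A_CVH`,
  maximum Feret diameter (rotating calipers), CVH area/perimeter/Feret,
  centre of mass vs hull centroid, soma displacement, and marker coverage
  (Phansalkar local threshold, radius 15) as percent of projection area.
* **Vasculature** — medial-axis vessel skeletons with per-node radii;
  *unique vessels* defined after branching events (each branch yields one
  continuing and one new vessel, so on a tree
  `unique = 1 + branch events`); per-cell unique-contact counts, contacted
  diameters, nearest-vessel distances, and the three-way connection
  classification from an angular-wrap statistic and an on-vessel mass
  fraction.
* **Retinal geography** — azimuthal-equidistant hemisphere coordinates
  (ONH at −90° latitude, rim at 0°, dorsal always 90° longitude),
  right-to-left eye harmonisation, and quadratic eccentricity-trend fits.
* **Statistics** — motif→structure association tables `p(structure|motif)`
  with error estimates, population contact summaries, the canonical
  20-parameter feature matrix, a pluggable 2D embedding (PCA) with density
  clustering (in-package HDBSCAN, `min_samples = 3`,
  `min_cluster_size = 10`; noise = −1), and a parameter correlation
  dendrogram (1 − |r|, average linkage, Newick export).

## Worked example

```r
library(astromorph)

cfg <- pipeline_config(scene = list(n_cells = 6, field_px = c(448, 448),
                                    noise_sd = 0), seed = 42)
res <- run_pipeline(cfg)

print(res$truth)
#> scene_truth: 6 cell(s), 5 unique vessel(s), field 448x448 px

round(res$records[, c("cell_id", "fo_area_um2", "fo_feret_um",
                      "fo_solidity", "pct_gfap", "n_unique_vessels")], 2)
#>   cell_id fo_area_um2 fo_feret_um fo_solidity pct_gfap n_unique_vessels
#> 1       1      136.50       26.80        0.56    21.06                1
#> 2       2     1611.50       65.52        0.70    21.07                2
#> 3       3     1178.25       62.97        0.64    21.09                3
#> 4       4     1061.25       60.71        0.60    21.11                1
#> 5       5      473.50       37.48        0.74    21.12                1
#> 6       6      844.50       53.03        0.57    21.11                2

res$records$connection_class
#> [1] "enveloping"     "non-enveloping" "enveloping"     "non-enveloping"
#> [5] "non-enveloping" "non-enveloping"

s <- res$summaries
sprintf("vessel contact: %.0f%%  mean unique contacts: %.2f +/- %.2f",
        s$pct_contacting_vessel, s$mean_unique_contacts, s$sem_unique_contacts)
#> "vessel contact: 100%  mean unique contacts: 1.67 +/- 0.33"
```

The scene is synthetic, so every number above is checkable against the
generator's ground truth (`res$truth`): the measured areas and Feret
diameters recover the supersampled truth within 2%, the GFAP coverage
recovers the planted 21.1% fraction, and the unique-contact counts match
the true vessel topology. `run_pipeline(cfg, outdir = "out")` additionally
writes `records.csv`, `features.csv` (the 20-parameter matrix),
`association.csv`, `embedding.csv`, `vessels.graphml`, `dendrogram.nwk`,
`summaries.json`, a resolved `config.yaml` and a run `manifest.json`;
reruns under the same configuration are byte-identical.

A thin command-line front end over the same functions ships in
`inst/cli/astromorph` with subcommands `simulate`, `segment`, `measure`,
`vessels`, `mapcoords`, `associate`, `embed` and `run-all`.

## Package layout

```
R/                  synthetic generator, segmentation, morphometry,
                    vasculature, retinal geometry, association statistics,
                    HDBSCAN, pipeline orchestration
tests/testthat/     unit, property and acceptance suites (fixtures built
                    in code)
scripts/acceptance.R   validation-report generator
vignettes/          methods vignette: models, conventions, parameter
                    choices, limitations
inst/cli/astromorph    command-line front end
```
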