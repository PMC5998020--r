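# smlmnet — network analysis of 3D SMLM point clouds

Single-molecule localization microscopy (SMLM) reconstructs sub-diffraction
structure from millions of stochastic fluorophore emissions ("blinks"), each
localized to ~20 nm laterally and ~40 nm axially. The raw product is an
*event list* — one `(x, y, z)` row per blink — not an image, and the central
analysis problems are (i) one molecule blinks many times, so blink counts
overcount molecules, and (ii) the structures of interest (for instance
caveolae and caveolin scaffolds, 50–250 nm membrane domains) are sparse
clusters buried in background labeling.

`smlmnet` treats the localization cloud as a spatial proximity network and
provides the full analysis chain:

1. **Blink merging** — iteratively replaces every blink and its neighbors
   within `T = 20` nm (the resolution limit) by their average position until
   no pair is closer than `T`, yielding predicted molecule positions.
2. **ROI tiling** — partitions the cell extent (nominally 18×18×1 µm³) into
   3×3×1 µm³ tiles (36 per cell) for independent, parallelizable analysis.
3. **Multi-threshold network features** — graphs with an edge wherever
   `d_ij ≤ T` (weighted variant `w_ij = 1/d_ij`), for `T = 20, 30, …, 250`
   nm; 32 registry measures × 24 thresholds = 768 features per ROI, compared
   between populations by two-sided Mann–Whitney tests, L2-norm aggregation
   across experiments and Bonferroni correction, and validated by
   random-forest leave-one-cell-out classification.
4. **Noise filtering** — a node is kept iff its degree at 80 nm exceeds
   `α × mean(δ_rand)` (default `α = 4`), where `δ_rand` comes from matched
   random point clouds (X/Y uniform, Z normal fitted to the ROI).
5. **Blob segmentation and description** — flat-kernel mean shift separates
   the retained cloud into blobs; each blob gets a 28-feature signature
   (size, shape, hollowness, and network measures at 80 nm, including Newman
   leading-eigenvector modularity).
6. **Blob identification** — X-means (BIC-selected K) discovers blob groups
   per population; groups are matched across populations by centroid
   distance with threshold `β = 30`; test-phase blobs are labeled by nearest
   centroid.

A built-in simulator (ground-truth rods and spheres, epitope placement,
labeling efficiency, linker displacement, geometric blink multiplicity,
anisotropic Gaussian localization noise) makes every stage testable without
microscope data, including the single-antibody calibration analysis
(area/blink gating and K-means single-vs-cluster split).

## Worked example

Simulate a small cell containing eight 60 nm sphere structures (145 epitopes
each, the caveola-matched density) plus uniform background, then run the
chain:

```r
library(smlmnet)
set.seed(42)
cell <- make_test_cell(replicate(8, ground_truth("sphere"), simplify = FALSE),
                       n_noise = 600,
                       extent = cbind(c(0, 0, 0), c(6000, 6000, 1000)),
                       seed = 42)
ev <- cell$events
locs <- merge_blinks(ev, merge_params(20))
merge_report(ev, locs)
#> merge: 6504 -> 1536 blinks (76.4% reduction)

kept <- degree_filter(as_roi(locs), filter_params(T_filter = 80, alpha = 4),
                      seed = 1)
#> filter: retained 952 of 1536 localizations (null mean degree 0.12)

sb <- segment_blobs(kept, bandwidth = 80)
sb
#> <blob_set> 8 blobs (bandwidth 80 nm), 12 unassigned points

head(blob_table(sb)[, c("n_nodes", "mean_dist_centroid", "min_dist_centroid",
                        "sphericity", "n_modules")], 5)
#>   n_nodes mean_dist_centroid min_dist_centroid sphericity n_modules
#> 1     127              75.17              5.72       0.38         3
#> 2     125              73.24             16.95       0.34         3
#> 3     123              72.84             11.99       0.41         3
#> 4     118              72.37             16.76       0.35         4
#> 5     114              73.70             17.87       0.32         2
```

All eight planted spheres are recovered as blobs: each holds ~120 predicted
molecule positions, spans ~73 nm mean distance-to-centroid, and decomposes
into 2–4 network modules at the 80 nm threshold. The blob tables feed
`discover_groups()` / `match_groups()` / `assign_blobs()` for unsupervised
class discovery, and `run_pipeline()` drives the whole chain (including the
population statistics) from a named list of event lists.

A command-line front end is installed with the package:

```sh
$(Rscript -e 'cat(system.file("..", "exec", "netlyze", package="smlmnet"))') \
    merge --in events.csv --T 20 --out locs.csv --stats merge.json
```

(subcommands: `convert`, `merge`, `tile`, `filter`, `blobs`, `simulate`,
`calibrate`, `roistats`, `run`).

## Further reading

The methods vignette (`vignettes/smlm-network-analysis.Rmd`) documents the
models, the tunable parameters with their defaults and units, what the
simulator does and does not emulate, the numerical choices, and known
limitations.
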