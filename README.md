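# fluosim

Simulation of fluorescence cell micrographs with pixel-exact ground truth,
for benchmarking cell segmentation pipelines.

Validating cell segmentation against hand annotations inherits the
annotators' errors and their inter-observer variability — worst exactly
where segmentation is hardest, on touching, overlapping and overlaying
cells. `fluosim` instead *simulates* realistic fluorescent cell scenes
whose ground truth is exact by construction, so pipeline accuracy can be
measured as a function of controlled scene properties (cell count,
clustering, degree of overlap, background, noise).

The simulator has three core components plus an evaluation stack:

* **Shape model** — cell outlines as a PCA statistical shape model over
  corresponded contours: `x = x_m + P b`, with per-mode Gaussian
  coefficients clamped at ±3σ and a minimum-size floor `r_min` that
  rejects degenerate small shapes.
* **Texture warp** — the texture of an annotated cell is mapped onto a
  generated outline by minimizing a three-term elastic energy
  `E = w_fix E_fix + w_border E_border + w_bulk E_bulk`, where the bulk
  springs between 8-connected interior points carry intensity-weighted
  stiffness `log(1+I(p))·log(1+I(n))` — bright texture deforms less.
* **Placement** — cells are assigned to clusters and moved outward from
  the cluster center along random directions until every pairwise Jaccard
  overlap satisfies `J_cur ≤ J_max`; presets cover the isolated /
  touching / overlapping / overlaying series.
* **Scene synthesis** — Perlin background fluorescence, additive cell
  composition (fluorescence adds where cells overlap), Gaussian noise;
  emitted with instance label maps and full per-cell masks/contours.
* **Metrics** — mean in-cell intensity and the summed mean difference
  `SMD = (1/N_C) Σ_c (1/N_c) Σ_p |I(p) − A_c|`.
* **Segmentation harness** — DoG → k-means figure-ground → hybrid or
  seeded watershed, scored by the combined Jaccard (greedy one-to-one
  matching normalized by `max(n_pred, n_gt)`), with coordinate-descent
  parameter optimization and 3-fold cross-validation.

## Worked example

```r
library(fluosim)

# a procedural patch pool stands in for hand-annotated cells
patches <- generate_patches(fixture_spec("blob", c(9, 13), "radial",
                                         c(50, 110), n_patches = 10,
                                         rng_seed = 8, n_points = 64))
model <- train_shape_model(lapply(patches, `[[`, "mask"),
                           n_points = 64, r_min = 6)
model
#> PCA cell shape model: 64 contour points, 6 modes, r_min = 6 px
#> eigenvalues: 107.252   7.530   3.174   1.975   1.404   1.041

cfg <- scene_config(layout_spec(6, 1, image_size = c(128, 128)),
                    noise_sigma = 3, rng_seed = 41, n_images = 12)
series <- simulate_overlap_series(model, patches, cfg)
series_table(series)
#>                metric isolated touching overlapping overlaying
#> 1 mean_cell_intensity 55.65322 55.38701    72.48440  128.43886
#> 2                 smd 13.42310 13.40260    18.16806   48.64109
```

The six eigenvalues say most outline variance in this pool is overall
size (mode 1) with progressively finer boundary undulations behind it.

With additive composition the mean in-cell intensity rises with the
overlap degree (overlap pixels carry both cells' fluorescence), while the
isolated and touching columns tie — those datasets contain identical
cells with zero pixel overlap. Scoring the reference pipeline on the same
series,

```r
scores <- sapply(series, function(ds)
  cross_validated_score(seg_dataset(ds$scenes[1:10]), folds = 3,
                        initial = seg_params(1, 4, 2, 0.2, 2, 50),
                        grids = list(sigma_low = c(1, 1.5, 2),
                                     sigma_high = c(3, 4, 5), k = 2:3,
                                     w = c(0, 0.2, 0.4), sigma_ws = c(1, 2),
                                     a_min = c(20, 50, 100)),
                        seed = 5, max_cycles = 2)$mean_score)
round(scores, 3)
#>    isolated    touching overlapping  overlaying
#>       0.740       0.673       0.291       0.128
```

segmentation performance falls monotonically as cells overlap more — the
watershed-based pipeline can separate touching cells but not resolve true
overlaps, and the simulator quantifies exactly how much accuracy each
degree costs.

A command-line front end (`inst/cli/fluosim.R`) exposes the same pipeline
as subcommands `make-fixtures`, `train-model`, `simulate`,
`overlap-series`, `measure` and `evaluate`, reading/writing TIFF images,
JSON ground-truth sidecars and a dataset manifest.

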