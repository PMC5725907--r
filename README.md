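# sproutr

Quantification of fibrin-gel **bead sprouting angiogenesis assays** from
multi-channel fluorescence images, for labs screening compounds against
vascular sprouting and pericyte coverage.

In this assay, endothelial cells — optionally co-cultured with pericytes at
a 10:1 seeding ratio — are coated on dextran microcarrier beads (~150–250 µm
diameter) embedded in fibrin gel, where they grow lumenized vascular
sprouts. After staining (F-actin, DAPI, the endothelial nuclear marker
Erg-1/2/3, the pericyte marker NG2) and imaging, `sproutr` measures, per
image or well:

- **bead count** — bright, near-circular objects gated by equivalent radius
  $r_{eq} = \sqrt{A/\pi}$ and circularity $4\pi A/P^2$, with touching beads
  split by distance-transform watershed;
- **sprout number** — skeleton branches crossing each bead's perimeter
  band, so a distally bifurcating sprout counts once;
- **total and average sprout length** — from a topology-preserving skeleton
  of the sprout mask, branch lengths measured by Euclidean chords along the
  ordered branch paths;
- **average sprout width** — attached sprout area / total skeleton length;
- **branch points per sprout** — skeleton junction clusters, spur-pruned;
- **nucleus count, EC/pericyte classes and their ratio** — DAPI blobs
  classified by presence of the nuclear EC marker (object-level Otsu with a
  bimodality guard);
- **cell density** — sprout nuclei per 10⁴ µm² of sprout area;
- **pericyte area and coverage** — NG2-positive area, and the fraction of
  bead-attached sprout area it overlaps.

Plate-level screening statistics are included: per-condition well
aggregation weighted by bead count, normalization to the solvent-matched
control (PBS or DMSO), and a two-sided one-sample t-test of per-assay fold
changes against 1, with 0.05 and 0.01 significance tiers.

A synthetic scene generator (`random_scene()` / `render_scene()`) renders
beads, tubular sprouts, nuclei, marker channels and NG2 ribbons with exact
ground truth for every measurement, degraded by a Gaussian PSF and Poisson
noise — it is the package's benchmark and test fixture.

## Worked example

Render a synthetic two-bead scene with all four channels and a painted
pericyte coverage of 0.4, then run the full pipeline:

```r
library(sproutr)

scene <- render_scene(random_scene(seed = 1, n_beads = 2,
                                   field_um = c(900, 900),
                                   coverage_fraction = 0.4))
row <- analyze_image(scene$image)
t(row)
#> source_id               "scene-1"
#> n_beads                "2"
#> n_sprouts              "7"
#> total_sprout_length    "1358.45"
#> avg_sprout_length      "194.0643"
#> avg_sprout_width       "25.16986"
#> sprout_area            "34192"
#> n_nuclei               "55"
#> n_ec                   "50"
#> n_pericyte             "5"
#> ec_pericyte_ratio      "10"
#> cell_density           "12.57604"
#> pericyte_area          "13563"
#> pericyte_coverage      "0.3715781"
#> avg_branch_points      "0"
```

Both beads and all 7 sprouts are found; the measured total sprout length
(1358 µm) is within 3% of the generator's ground truth (1396 µm); all 55
nuclei are detected and classified into the seeded 50 EC : 5 pericytes
(ratio 10); measured coverage 0.372 tracks the painted ground truth 0.383.

For real data, put the channel assignments and pixel size in a YAML config
and process a folder with frozen parameters:

```r
cfg <- read_run_config("config.yaml")   # channels, pixel_size, params
analyze_folder("images/", cfg, "out/")  # results.csv + params.json + run.log
run_stats("out/results.csv", "layout.csv", out = "out/summary.csv")
```

A thin command-line wrapper with `analyze`, `tune`, `simulate`,
`make-fixtures` and `stats` subcommands lives in
`inst/scripts/sprout_analyzer.R`.

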