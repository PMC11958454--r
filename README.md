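# aggretrack

Quantification of fluorescent protein aggregates in live budding yeast at
single-molecule resolution. The package is aimed at microscopists and
image analysts working with millisecond-timescale (Slimfield-type)
single-molecule movies and dual-colour confocal time-lapses of aggregation
reporters: it provides the full analysis chain — spot detection inside
per-cell outlines, sub-pixel localization and tracking, molecule counting
by stepwise-photobleaching calibration, diffusion estimation, and
population statistics — together with a synthetic-data generator with
exact ground truth so every stage is verifiable by parameter recovery.

## The quantities at the core

For each tracked aggregate focus:

- **Stoichiometry** `S = I0 / I1`: the initial unbleached track intensity
  `I0` (single-exponential fit evaluated at frame 0) divided by the
  brightness `I1` of one fluorophore, calibrated in situ as the modal size
  of terminal photobleaching steps (the last molecule of a fully-bleached
  trace dropping to background). An optional dark-fraction correction
  multiplies by `1/(1 - p_dark)` for the ~7% of fluorescent proteins that
  never mature.
- **Diffusion coefficient** `D = slope / 4`: the weighted initial gradient
  of the mean squared displacement `MSD(n·Δt)` over the first 4 lags, the
  intercept retained as the localization-noise offset.
- **Population summaries**: percentage of aggregate-positive cells (cells
  with ≥1 detected focus), mother/daughter focus asymmetry after
  interquartile outlier removal, centroid-to-mask organelle colocalization
  at the 250 nm resolution limit, aggregate inheritance across budding
  time-lapses, Welch t and Mann–Whitney U condition comparisons, and
  fold-change arithmetic.

## Worked example

Simulate one Slimfield field of four cells, each with one diffusing
aggregate of 157 molecules photobleaching over 1000 frames at 5 ms/frame,
then run the full pipeline:

```r
library(aggretrack)

cfg   <- sim_config(n_frames = 1000, image_shape = c(64L, 64L),
                    rng_seed = 101L)
stack <- simulate_slimfield_stack(cfg, n_molecules = 157, d_coeff = 0.99,
                                  n_cells = 4)
res   <- run_pipeline(stack, pipeline_config(), condition = "control")

res$calibration$value        # single-molecule brightness (A.U.)
#> [1] 302.7188
res$stoichiometry$stoichiometry   # molecules per aggregate (true: 157)
#> [1] 150.5323 161.4204 160.2320 160.8237
res$diffusion$d_coeff        # per-track D in um^2/s (true: 0.99)
#> [1] 0.8510032 0.8085708 0.9025529 0.9196959
```

The calibration lands within ~1% of the generator's 300 photons/frame per
fluorophore and the recovered stoichiometries scatter around the true 157
molecules. The MSD-gradient diffusion estimates sit slightly below the
nominal 0.99 µm²/s because the walk is confined to a ~1.3 µm cell radius;
on unconfined tracks (see `diffusion_recovery_experiment`) the estimator
is unbiased. With `out_dir` set, `run_pipeline` also writes
`foci.csv`, `tracks.csv`, `diffusion.csv`, `stoichiometry.csv`,
`condition_summary.csv` and a reproducibility manifest.

## Analysis workflow

The `analysis/` directory holds the narrative workflow, each stage a thin
driver over the package:

| script | what it does |
|---|---|
| `01_simulate.R` | synthetic acquisitions for a three-condition osmotic-stress series and two confocal budding time-lapses (movies under `scratch/data/`) |
| `02_detect_foci.R` | per-cell foci detection, aggregate-positive fractions, fold-change arithmetic |
| `03_track_diffusion.R` | tracking, per-track MSD-gradient diffusion, condition comparisons |
| `04_stoichiometry.R` | brightness calibration, molecule counts, KDE distributions, U tests |
| `05_population.R` | inheritance scoring, mother/daughter asymmetry, organelle colocalization |

Run them in order from the repository root:
`Rscript analysis/01_simulate.R`, etc. Tables land in `results/`.

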