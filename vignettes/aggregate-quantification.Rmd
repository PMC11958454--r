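---
title: "Quantifying protein aggregates at single-molecule resolution: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein aggregates at single-molecule resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggretrack)
```

## The problem

Misfolded cytoplasmic proteins in budding yeast coalesce into fluorescent
aggregates when tagged with a monomeric fluorescent reporter. Two
acquisition regimes probe them at different scales. Millisecond-timescale
narrow-field ("Slimfield") movies resolve single fluorescent protein
molecules, so an aggregate's molecular content and mobility can be measured
directly: its molecular *stoichiometry* S (how many reporter molecules it
contains) and its effective diffusion coefficient D. Slower dual-colour
confocal time-lapses follow whole budding events, asking which cell keeps
the aggregates while organelles (vacuole, nucleus) are partitioned into the
growing bud.

`aggretrack` implements both analysis chains over a synthetic-data
generator with exact ground truth, so every stage is testable by parameter
recovery rather than by eye.

## The measurement model

**Image formation.** Each photoactive fluorophore contributes an isotropic
2D Gaussian of standard deviation $\sigma_\mathrm{PSF}$, integrated over
the pixel grid; all fluorophores of one aggregate are co-located because
aggregates here are below the optical resolution limit. A pixel records
$\mathrm{Poisson}(S + b) + \mathcal{N}(0, \sigma_r^2)$ counts, where $S$ is
the integrated Gaussian signal, $b$ the background and $\sigma_r$ the read
noise, clipped at zero and quantised (unit gain). EMCCD excess noise,
vectorial PSF structure, stage drift, spectral crosstalk and fluorophore
blinking are deliberately not modelled; the defaults are a calibration
point, not a camera data sheet.

**Photobleaching.** Every non-dark fluorophore bleaches irreversibly and
independently with per-frame probability $p_b$, so the photoactive count of
an $N$-molecule aggregate decays in expectation as $N(1-p_b)^t$ and ends in
resolvable single-molecule steps. A *dark fraction* $p_d$ of fluorophores
(typically around 7% for fluorescent proteins) never matures to a
photoactive state and is invisible throughout.

**Motion.** Aggregate centres follow 2D Brownian motion with per-axis step
variance $2D\,\Delta t$, reflected at the cell boundary (radially for disk
cells, by step reversal for arbitrary masks). The medium is treated as
purely viscous; anomalous or viscoelastic models are out of scope.

## The analysis chain

1. **Detection** (`detect_foci`). A threshold is computed *per cell ROI*
   from that ROI's pixels only (Otsu by default; mean, percentile and fixed
   thresholds are available), and 8-connected components of suprathreshold
   pixels of at least `min_area_px` pixels become foci, each carrying area,
   raw and background-subtracted integrated intensity, and mean intensity.
   Per-ROI thresholding makes detection in one cell provably independent of
   everything outside it.
2. **Localization** (`localize_focus`). Iterative Gaussian-mask fitting:
   the centre is the centroid of the background-subtracted window under a
   Gaussian weight re-centred each iteration, to convergence below
   $10^{-3}$ px. Background and its noise come from the outer two rings of
   the fit window; the background-corrected intensity is summed over a
   tight circular aperture (radius $\approx 5\sigma_\mathrm{PSF}$). The
   aperture matters: summing the full window would multiply the
   background-mean error by ~300 pixels and bury single-molecule
   photobleaching steps in noise.
3. **Linking** (`link_tracks`). Greedy nearest-neighbour assignment between
   consecutive frames, closest pairs first, links forbidden beyond
   `max_disp`; no gap closing (at 5 ms frames gaps are rare, and a focus
   that disappears has usually photobleached).
4. **Stoichiometry** (`single_molecule_brightness`, `initial_intensity`,
   `stoichiometry`). Traces are Chung–Kennedy filtered (variance-weighted
   forward/backward running means, which smooth plateaus but never average
   across an edge) and segmented by recursive least-squares change-point
   splitting. The single-molecule brightness $I_1$ is the KDE mode of the
   *terminal* step sizes — the last molecule of a fully-bleached trace
   dropping to background — and each aggregate's initial intensity $I_0$ is
   a single-exponential fit evaluated at frame 0 (robust to bleaching
   before the first usable frame). Then $S = I_0 / I_1$, optionally scaled
   by $1/(1-p_d)$; the correction is off by default since reported values
   in this field are typically uncorrected.
5. **Diffusion** (`compute_msd`, `estimate_diffusion`). All-pairs MSD per
   track; a weighted least-squares line through the first `n_points`
   (default 4) MSD points gives $D = \mathrm{slope}/4$, with the intercept
   retained as the localization-noise offset ($\approx 4\sigma_{loc}^2$ for
   a static emitter) rather than corrected away.
6. **Population statistics** (`aggregate_positive_fraction`, `colocalize`,
   `mother_daughter_stats`, `inheritance_score`, `compare_conditions`,
   `fold_changes`). A cell is aggregate-positive when it contains at least
   one detected focus. Colocalization is centroid-to-mask distance at the
   optical resolution limit (250 nm default). Condition comparisons use
   Welch's t-test or the Mann–Whitney U test (exact enumeration for small
   tie-free samples, tie-corrected normal approximation otherwise).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `pixel_size` | 120 | nm | typical sCMOS/EMCCD magnification for this regime |
| `frame_interval` | 0.005 | s | millisecond sampling of the fast acquisitions |
| `n_frames` | 1000 | — | within the 1,000–1,500 frames of one acquisition |
| `psf_sigma` | 87 | nm | $0.25\lambda/\mathrm{NA}$ at $\lambda$ = 488 nm, NA 1.4 |
| `photons_per_fluorophore_per_frame` | 300 | photons | calibration point; puts localization precision well under 40 nm |
| `background_photons` | 10 | photons/px | realistic cytoplasmic autofluorescence level |
| `read_noise_sd` | 1 | counts | modern low-noise camera |
| `bleach_prob` | 0.008 | /frame | a 157-molecule aggregate fully bleaches within 1000 frames with ~95% probability while terminal dwells stay above `min_dwell` |
| `dark_fraction` | 0 (sim), 0.07 documented | — | correction exposed but off by default |
| `max_disp` | 5 | px | ~6x the per-frame Brownian step at D = 1 µm²/s |
| `window_radius` | 8 | px | fit window ~11 $\sigma_\mathrm{PSF}$ half-width |
| `msd_n_points` | 4 | — | "initial gradient": short enough to avoid confinement curvature, long enough for a stable slope |
| CK `window`, `min_dwell` | 10, 5 | frames | plateau smoothing vs shortest resolvable dwell |
| `min_snr` | 5 | — | detection quality gate, see below |
| `coloc max_distance` | 250 | nm | optical resolution limit |
| IQR `k` | 1.5 | — | standard interquartile fence |

## Numerical choices and degenerate inputs

- **Thresholding.** Otsu is computed on a 256-bin histogram of the ROI's
  own pixels; a zero-variance ROI yields its single value and strictly
  suprathreshold selection then returns no foci. Because Otsu always splits
  the histogram, a signal-free ROI would otherwise promote Poisson
  background speckle (whose suprathreshold fraction sits near the
  8-connectivity percolation threshold) into large spurious components; the
  `min_snr` gate — component peak at least 5 robust sd above the whole-ROI
  median — removes these while passing any real spot by a wide margin. Set
  `min_snr = 0` to recover bare thresholding.
- **Step detection.** Recursive binary segmentation accepts a split only
  when the level change exceeds `min_step` and both segments persist for
  `min_dwell` frames. The automatic `min_step` is 3x the robust noise sd of
  the *bleached tail* of the trace, because shot noise scales with
  intensity and a whole-trace estimate would sit above the single-molecule
  step. A terminal step is only accepted when it lands at a statistically
  zero level.
- **Initial intensity.** The exponential fit drops the fully-bleached tail
  (frames below 3x tail noise): those frames carry no information about
  $I_0$ and otherwise bias the fit upward on step-shaped (low-N) traces.
  Degenerate inputs: an all-zero trace gives $I_0 = 0$; fit failure falls
  back to the mean of the first 4 frames.
- **KDE.** Gaussian kernels with reflection at zero (stoichiometries are
  non-negative), Silverman bandwidth floored at 0.7 molecules; the grid
  extends past the data maximum far enough that the density integrates to
  1 within $10^{-3}$. An all-equal sample returns a single delta-like peak.
- **Ties and degeneracies.** Two identical zero-variance samples under the
  t-test return p = 1 with a flag instead of erroring; the U test switches
  from exact enumeration to the tie-corrected normal approximation when
  ties are present or samples exceed 20.
- **Determinism.** A `sim_config` seed makes stacks bit-identical;
  `run_pipeline` re-runs byte-identical CSVs and manifests (timestamps
  aside).

## What the generator emulates — and what it does not

The simulator reproduces the features the estimators rely on: Poisson/read
camera noise at a realistic photon budget, per-fluorophore geometric
photobleaching down to the single-molecule level, sub-resolution aggregates
diffusing inside cell boundaries, dark fluorophores, and (for the confocal
fixtures) a growing bud whose organelle marker transfers at ~20 min
(vacuole) or ~60 min (nucleus) into budding while aggregates stay in the
mother. It does not emulate cytoplasmic autofluorescence texture, cell-wall
scattering, focal drift, aggregate growth or splitting during acquisition,
EMCCD excess noise, or the finite axial extent of a real yeast cell.
Passing recovery tests therefore demonstrates that the estimators are
unbiased under this noise model at realistic SNR — not that raw microscopy
of arbitrary quality will yield the same accuracy.

## Study conditions used in the recovery experiments

The packaged experiments hold the simulation at the published condition
values: aggregates of 157 (control) and 290 (1 M NaCl) molecules, control
diffusion 0.99 µm²/s, 5 ms frames, 1000-frame acquisitions.
`stoichiometry_recovery_experiment` simulates 100 aggregates (one per disk
cell, four cells per 64x64 field), pools all fully-bleached traces for a
single brightness calibration, and reports the recovered population mean;
the acceptance checks require agreement within 15%. The test suite runs a
40-aggregate version of the same experiment; the `analysis/` workflow uses
four fields per condition at 800 frames so the full narrative run stays
interactive. `diffusion_recovery_experiment` uses 200 tracks of 60 frames
with 8 nm/axis localization noise — the measured precision of the Gaussian
fit at the default photon budget (RMS 2D error ~10 nm, comfortably below
the 40 nm figure typical of intracellular single-molecule tracking).
`localization_precision_experiment` uses 500 isolated single-molecule foci.

## Known limitations

- Stoichiometries beyond a few hundred molecules bleach so fast at fixed
  `bleach_prob` that the exponential-fit extrapolation dominates the
  estimate; the calibration itself remains anchored by terminal steps.
- Greedy nearest-neighbour linking is exact only for well-separated foci;
  dense fields with crossing tracks need a global assignment algorithm.
- Detection is per-slice 2D; z-stacks are analysed slice by slice and no
  3D object fusion is attempted.
- The Chung–Kennedy/change-point defaults were chosen for step dwells of
  at least ~5 frames; much faster bleaching needs shorter windows and pays
  in plateau noise.
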