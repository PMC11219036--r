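# fxmtools

Single-cell volumetry and motility analysis for Fluorescence eXclusion
Microscopy (FxM), with a ground-truth synthetic experiment generator and
the companion bulk assays (buoyant-density gradients, Coulter counting).

## The problem

Neutrophils and other rapidly migrating cells change their volume within
minutes of chemoattractant stimulation — a transient spreading-induced
volume loss of a few percent, followed by active swelling of roughly 15%
that accompanies the potentiation of migration. Measuring this requires
absolute single-cell volumes at ~10 s cadence while the cells move.

FxM does this by imaging a fluorescent dye that cells exclude inside a
shallow chamber of known height `h`: wherever a cell of height
`h_cell(x, y)` displaces dye, the signal drops below the local background
`Imax`. After darkfield subtraction and flatfield correction, the excluded
volume of a cell with footprint `A` is

    V = (p² / α) · Σ_{(x,y) ∈ A} ( Imax − I(x, y) ),      α = (Imax − Imin) / h

where `p` is the pixel size, `Imin` the signal over the support pillars
(which exclude all dye) and `α` converts corrected intensity to dye-column
height. Track-level kinematics use the windowed velocity
`ν_i = |p_{i+τ} − p_{i−τ}| / (t_{i+τ} − t_{i−τ})` and an angular-alignment
statistic in [−1, 1] (+1 = straight, −1 = reversal) computed between track
anchors separated by 10 µm of travelled path.

The package implements the full analysis chain — Scharr-edge foreground
segmentation with a log-normal threshold, nuclear-seeded instance
splitting, frame-to-frame track linking, multiquadric flatfield modelling,
pillar calibration, per-cell local backgrounds, volume/motility traces and
replicate-aware population summaries — plus a synthetic FxM experiment
generator whose per-cell, per-frame rasterised ground truth makes every
stage verifiable by parameter recovery.

For whom: cell biologists and biophysicists running FxM chambers (or
evaluating FxM pipelines), and anyone needing a tested reference
implementation of dye-exclusion volumetry.

## Worked example

```r
library(fxmtools)

# a synthetic experiment: 8 cells in a 6 µm chamber, 20 frames at 10 s,
# uncaging after frame 5, 1% noise, 20% illumination amplitude
cfg <- sim_config(fov_rows = 300, fov_cols = 300, n_frames = 20,
                  n_cells = 8, stim_frame = 5,
                  pillar_centers = rbind(c(80, 80), c(220, 220)), seed = 7)
ds  <- simulate_experiment(cfg)
res <- run_pipeline(as_frameset(ds))
print(res)
#> fxm_result: 20 frames, 8 tracks, 160 cell-frames (160 volumes), 15.0 s

subset(res$volumes, track_id == 1 & frame <= 2,
       select = c(frame, area_um2, volume_um3, volume_norm))
#>    frame area_um2 volume_um3 volume_norm
#> 1      0 212.0950   321.8817   0.9808586
#> 9      1 213.3625   328.1632   1.0000000
#> 17     2 212.0950   331.9049   1.0114018
```

Every cell-frame row carries the footprint area (µm²), the absolute
excluded volume (µm³) and the volume normalised to that cell's median over
the two minutes before stimulation. `res$summary_volume` and
`res$summary_velocity` hold the population curves (mean of per-replicate
medians with 95% CI); `res$calibration` the per-frame α. Against the
generator's ground truth this run recovers per-cell-frame volumes with a
median absolute error of 0.25%.

Bulk assays work from plain tables:

```r
cal <- fit_density_calibration(c(1.3419, 1.3467), c(1.045, 1.074))
ri_to_density(cal, 1.3443)
#> [1] 1.0595
```

A thin command-line wrapper with `simulate`, `run`, `density` and
`coulter` subcommands is installed at `inst/cli/fxm.R`
(`Rscript fxm.R simulate --output-dir sim --seed 1`). Simulated datasets
are written as multi-page 16-bit TIFFs (one per channel) with
`timestamps.csv`, `ground_truth.csv` and a flat `config.yaml` holding
`pixel_size`, `chamber_height`, `stim_time`, `frame_interval`, `io_scale`
and `seed`.

## Vignette

`vignettes/fxm-methods.Rmd` describes the imaging model, every tunable
parameter with its units and default, what the synthetic generator does
and does not emulate, and the numerical design choices.
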