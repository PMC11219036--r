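---
title: "Dye-exclusion volumetry and motility analysis: models and methods"
author: "fxmtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dye-exclusion volumetry and motility analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the imaging model, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical choices made where
the design was genuinely open. It states no empirical result beyond what
the test suite and `scripts/acceptance.R` themselves compute.

## The imaging model

Fluorescence exclusion microscopy measures absolute cell volume without
any assumption about cell shape. Cells sit in a shallow chamber (height
$h$, a few µm) filled with a fluorescent dextran they cannot take up.
Above a cell of height $h_\mathrm{cell}(x,y)$, the dye column shrinks to
$h - h_\mathrm{cell}$, so the fluorescence drops in proportion to the
displaced height. Two landmarks anchor the intensity-to-height map: the
cell-free background (full column, intensity $I_\mathrm{max}$) and the
PDMS pillars that support the chamber ceiling (zero column, intensity
$I_\mathrm{min}$). With

$$\alpha = \frac{I_\mathrm{max} - I_\mathrm{min}}{h}$$

the volume excluded by a cell with footprint $A$ is

$$V = \frac{p^2}{\alpha} \sum_{(x,y) \in A}
      \big( I_\mathrm{max} - I(x,y) \big),$$

where $p$ is the pixel size in µm. The intensity sum alone is an
intensity, and $\alpha$ an intensity per µm, so the quotient is a height
integral: the pixel-footprint factor $p^2$ is required for the result to
be a volume in µm³. The package keeps the two roles of $I_\mathrm{max}$
separate: the *frame-level* background median enters the calibration
$\alpha$, while each cell's own $I_\mathrm{max}$ is the median over an
annulus of background 2–10 px (1.3–6.5 µm at the default pixel size)
outside its border, avoiding other cells and pillars. The local estimate
is what makes the sum robust to residual large-scale illumination error:
a smooth percent-level bias that is common to the annulus and the cell
interior cancels in $I_\mathrm{max} - I$.

Two practical points inherited from the method: per-pixel heights are not
trustworthy (light scatter), so only whole-cell sums are reported; and
footprints are deliberately segmented slightly larger than the cell
(1 px dilation by default) so that scattered signal at the rim is
captured — the extra pixels carry $I_\mathrm{max} - I \approx 0$ and are
volume-neutral, which the test suite verifies directly.

## Analysis chain

1. **Denoise** (`denoise`): Gaussian smoothing, default $\sigma$ = 0.5 px.
   The method's original patch-based denoiser is licensing-encumbered;
   smoothing is a pluggable stand-in whose identity is not load-bearing
   for the volume equation. The small default matters: at 1 px the rim
   gradient spreads outward enough that detected footprints grow
   systematically by ~1 px beyond the intended dilation.
2. **Edge enhancement** (`edge_magnitude`): 3×3 Scharr convolutions
   (weights 3, 10, 3, normalised by 16), mirrored borders, per-pixel
   magnitude.
3. **Foreground** (`threshold_foreground`): edge magnitudes on noisy
   images are close to log-normal; the edge set is
   $\{ m \ge e^{\mu + k\sigma} \}$ with $\mu,\sigma$ the mean and SD of
   log-magnitudes over positive pixels and $k = 1$ by default.
   Magnitudes below 1% of the frame's peak count as zero: an integer
   detector would quantise them away, and including Gaussian blur-tail
   residues (down to $10^{-16}$ of peak) makes $\sigma$ meaningless.
   Closing (radius 1) seals 1–2 px contour gaps, the background is
   flood-filled from the border, and its complement — edges plus
   everything they enclose — is the foreground. Components under
   `min_component_area` (60 px) are noise and removed; the survivors are
   dilated by `footprint_dilation_radius` (1 px); pillars are forced to
   background. Foreground components are 8-connected, the background
   fill 4-connected: the dual connectivities are required, since an
   8-connected fill leaks through the diagonal joints of a thin closed
   ring. The mean/SD are computed per frame (the threshold is applied
   per image), an interpretation noted as such.
4. **Seeds and instances** (`detect_seeds`, `split_instances`): the
   nuclear channel is smoothed ($\sigma$ = 2 px), Otsu-thresholded, and
   components in [20, 2000] px become seed centroids. A trained
   instance-segmentation model is deliberately not used: synthetic nuclei
   are high-contrast blobs and the classical detector is fully testable.
   Labels grow geodesically from the seeds within the foreground
   (equivalent to a watershed on the negative distance-to-seed relief
   for a binary mask), so two cells in one component split along the
   equidistant line. Components without seeds remain foreground but
   unlabelled, and are flagged.
5. **Tracking** (`link_tracks`): nuclear seeds are linked frame to frame
   by greedy nearest-distance matching gated at `max_disp` (15 µm),
   ties broken by detection index, with `memory` = 2 frames before a
   track closes. Gap positions are not interpolated; downstream series
   simply skip missing frames. An exact mode solves the
   minimum-total-distance assignment (Hungarian algorithm, maximising
   link count first) and is verified against brute-force enumeration;
   greedy is the default because at neutrophil speeds (≲ 20 µm/min,
   ≲ 3.5 µm/frame at 10 s) detections are far apart relative to motion
   and the two modes agree.
6. **Flatfield** (`sample_background_points`, `fit_background_field`,
   `correct_frame`): background samples are placed along a sinusoidal
   path (200 points, 4 periods, 10 px margin) that is densest at the top
   and bottom of the field; points landing on (3 px-dilated) cells or
   pillars move to the nearest free pixel within 20 px or are dropped,
   and the result is thinned to ≥ 8 px pairwise spacing — the path is
   locally dense at its crests, and near-duplicate centres under a wide
   kernel make the fit ill-conditioned. The field is a multiquadric
   radial basis $\sum_j w_j \sqrt{\lVert p - p_j \rVert^2 + \varepsilon^2}$
   augmented with a linear polynomial under moment constraints; the
   augmentation reproduces constant and ramped backgrounds exactly and
   pins the kernel's behaviour outside the sample hull, where the plain
   expansion diverges. $\varepsilon$ defaults to the mean
   nearest-neighbour spacing and the kernel block carries a ridge
   $\lambda = 10^{-8}$. The pipeline fits the field to a $\sigma$ = 2 px
   smoothed copy of the raw frame — illumination is smooth, so heavier
   smoothing of the *samples* suppresses noise without biasing the
   surface — and corrects as
   $(\mathrm{raw} - \mathrm{DF}) / (\mathrm{field} - \mathrm{DF})$,
   which is invariant to a common gain and maps background to 1 and
   pillars to ≈ 0. The field is fitted to raw (pre-subtraction) values
   and the darkfield subtracted at evaluation, matching the order of
   operations of the source method.
7. **Volumetry and traces** (`alpha_calibration`, `local_background`,
   `cell_volume`, `build_volume_trace`): $\alpha$ is recomputed per
   frame (configurable); annulus distances are measured from the
   pre-dilation footprint boundary; cells touching the frame border are
   flagged and excluded; an annulus under 30 px raises "locality
   occluded", which the pipeline records per cell-frame rather than
   aborting. Per-cell volumes are never clamped — noise can make empty
   footprints integrate slightly negative, and clamping would bias the
   statistics. Baselines are the median over the two-minute window
   before stimulation; the rolling median uses a centred 7-frame window
   (~1 min at 10 s spacing) that shrinks at the trace ends.
8. **Motility** (`track_velocity`, `angular_alignment`,
   `population_summary`): velocity uses $\tau$ = 3 frames (≈ 1 min
   window) and is reported in µm/min. Angular alignment takes, for each
   position $B_i$, the latest prior anchor $A$ and earliest subsequent
   anchor $C$ separated from $B_i$ by ≥ 10 µm of cumulative path, and
   maps the angle $\angle_i = \mathrm{atan2}(\lVert BA \times BC \rVert,
   BA \cdot BC) \in [0, \pi]$ affinely to $2\angle_i/\pi - 1$. A straight
   continuation has $BA$ and $BC$ antiparallel ($\angle = \pi$, value
   +1); an immediate reversal has them parallel ($\angle = 0$, value
   −1); an uncorrelated random walk has median ≈ 0. A plain division of
   $\angle$ by $\pi$ maps to [0, 1] and cannot span [−1, 1]; the affine
   map is the unique linear form consistent with all three anchor facts
   and is adopted as this package's reading. Population summaries take
   the median across cells within each replicate, then mean, SD and
   normal-approximation 95% CI across replicate medians.

## The synthetic generator

`simulate_experiment` emulates the structure of a chamber uncaging
experiment so that every stage can be validated by ground-truth recovery:

- **Geometry**: 600×600 px field at 0.65 µm/px (the scale at which
  2–10 px is 1.3–6.5 µm), chamber height 6 µm, four pillars of 15 px
  radius. Chamber height, pixel size and frame interval are not dictated
  by the source method's acquisitions and are declared, configurable
  defaults.
- **Illumination**: a multiplicative surface of three random low-frequency
  cosine modes scaled to a peak deviation of 20%, over a constant
  darkfield of 100 units; additive Gaussian noise of 6 units ≈ 1% of the
  600-unit dye-column signal ($\alpha_\mathrm{true}$ = 100 units/µm).
  Photon statistics are deliberately omitted — the oracle stays simple
  and the additive model is what the threshold's log-normal assumption
  needs.
- **Cells**: smooth domes $h(r) = h_\mathrm{peak}\,
  \max(0, 1-(r/R)^2)^{1.5}$ with fixed aspect $h_\mathrm{peak} = 0.67R$,
  clipped at the ceiling; the scale for a target volume is found by 1-D
  root finding (relative tolerance $10^{-6}$). A resting 350 µm³ cell
  then stands ~5 µm tall in the 6 µm chamber — nearly confined, as real
  neutrophils are. Baseline volumes are lognormal (median 350 µm³,
  CV 0.12). No claim is made that real cells are domes; any
  dye-excluding shape serves the oracle, and ground truth is defined
  *after* rasterisation (pixel-size² × summed height map, exactly), so
  analytic-vs-grid discrepancies cannot contaminate recovery tests.
- **Volume program**: before stimulation the factor is 1 plus a
  minute-scale sinusoidal fluctuation (amplitude 0.02, period 60 s,
  random phase per cell). From stimulation: a half-sine dip of depth
  0.06 over 120 s (the spreading-induced loss, within the observed 5–8%
  band), then a saturating rise to 1.15 with $\tau$ = 240 s — chosen so
  the population sits within ~1% of its +15% plateau by 20 min after
  stimulation, matching the reported swelling kinetics.
- **Motility**: a persistent random walk (heading increments
  $\mathcal{N}(0, 0.2^2)$ rad/step) at 0.5 µm/min before stimulation
  (quiescent) and 12 µm/min after (chemokinetic), with reflecting walls;
  cells repel each other and the pillars so footprints stay disjoint,
  and the per-frame stimulation switch makes the velocity summary a
  step-recovery oracle.
- **Channels**: the FxM channel follows the exclusion model exactly; the
  nuclear channel is a Gaussian spot (σ 3 px) per cell; the cytoplasmic
  channel is the filled footprint at constant brightness.

Determinism is part of the contract: identical configurations (including
seed) produce bit-identical datasets, and the analysis pipeline itself
contains no randomness, so reruns write byte-identical tables.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: optics (no PSF, no light scatter,
no z-dependence), photon noise, cell–cell contact and overlap, division,
entry/exit through chamber ports, chamber-height gradients, debris, and
dye photobleaching. Recovery results on synthetic data validate the
*computational* chain, not the microscope.

## Bulk assays

Percoll gradient media have density linear in refractive index, so a
two-point calibration (e.g. RI 1.3419 → 1.045 g/mL, 1.3467 →
1.074 g/mL) fixes the line exactly; more pairs are least-squares fitted,
and per-tube calibration lines are used rather than a cross-tube
alignment rule. Fraction counts are summarised by a weighted median that
interpolates linearly within the median fraction (fraction boundaries =
midpoints between adjacent fraction densities): continuous median
densities from discrete fractions imply interpolation. The stimulation
shift is the difference of population medians. Screen-style binning cuts
fractions where the cumulative count first crosses k/n of the total,
yielding contiguous bins of approximately equal population. Coulter
series take per-timepoint medians normalised to the mean of the first
three (pre-stimulation) timepoints. Cells denser or lighter than the
gradient range are counted in the end fractions, as they would collect
at the tube extremes.

## Numerical choices and degenerate inputs

- Thresholding a constant (edge-free) image returns an empty mask;
  fewer than 100 positive magnitudes is a degenerate distribution and an
  error; a frame whose filled foreground exceeds 80% leaves no reliable
  border seed for the background fill and errors.
- The field evaluation over a frame computes exact kernel values on a
  4 px grid and interpolates bilinearly between; multiquadric surfaces
  are smooth at that scale and the constant/ramp reproductions remain
  exact.
- The assignment solver pads rectangular problems to square with a large
  sentinel cost, which makes "maximise links, then minimise distance"
  the effective objective.
- Missing values propagate as NA internally and as empty CSV fields on
  disk; sentinel numbers are never written.
- Image stacks are stored as 16-bit TIFFs with a recorded intensity
  scale (float TIFF support is unreliable for values outside [0, 1]);
  quantisation is ~$10^{-5}$ of full scale, far below the noise floor.

## Problem sizes

The validation suite simulates the default experiment at 50 cells ×
120 frames × 600² px (the scale at which per-frame displacement,
cell spacing and annulus geometry are all in their realistic regimes)
and smaller 300² px experiments for module-level oracles; the gradient
and Coulter recoveries use 5000 cells/samples per population, matching
the per-timepoint sampling of the real instruments.

## Known limitations

- The linker handles neither division nor merging; crossing cells at
  high density can swap identities (greedy mode) — the exact mode
  reduces but does not eliminate this.
- Flatfield accuracy degrades toward frame corners outside the sampled
  sine path; the local-background construction absorbs most of this for
  volumes, but absolute background values near corners are less
  reliable.
- The log-normal threshold presumes noise-dominated magnitude
  distributions; on strictly noise-free images it is only usable thanks
  to the 1%-of-peak floor, and truly noise-free volumetry validation is
  done on ground-truth footprints instead.
- Angular alignment is undefined until a track has accumulated 10 µm of
  path on both sides of a frame, so quiescent cells report no alignment
  — a property, not a bug, but one to remember when averaging.
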