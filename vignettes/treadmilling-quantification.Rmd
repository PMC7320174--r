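---
title: "Quantifying FtsZ ring treadmilling: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying FtsZ ring treadmilling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringdyn)
```

## The measurement model

FtsZ filaments anchored to a supported lipid bilayer self-organize into
ring-shaped vortices. Individual monomers stay put; polymerization at one
filament end and depolymerization at the other (treadmilling) makes the
intensity pattern travel around the ring. The package's core measurement
model is therefore purely kinematic: a ring is an annulus whose azimuthal
intensity profile rotates rigidly at angular speed
$\omega = v / R$, where $v$ is the treadmilling speed along the
circumference and $R$ the ring radius.

On a kymograph $K(t, x)$ sampled along the ring circumference ($x$ in arc
columns, $t$ in frame rows), this rotation is a family of parallel stripes
of slope $s$ columns/row, and $v = s \,\Delta x / \Delta t$. Two
estimation routes are provided:

* **manual** — the user identifies two points on a stripe; the slope is
  the rise over run. This mirrors the interactive workflow and serves as
  the reference for cross-validation (`cross_validate`, a paired
  two-sided t-test on per-ring differences).
* **automatic** — windowed Fourier phase analysis (`estimate_slope_auto`).
  In each vertical window the temporal spectrum (column-summed, after
  per-column mean removal) is searched for the dominant frequency $f^*$;
  the phase $\varphi(j)$ of each column's coefficient at $f^*$ is unwrapped
  along the cyclic column axis and fitted with a line, giving
  $s = -2\pi f^* / (d\varphi/dj)$. The sign of $s$ encodes the rotation
  direction.

The key assumptions are: one dominant rotating pattern per ring (no
counter-rotating populations), approximately rigid rotation over a
50-row window, and a pattern that closes on itself around the ring — a
periodic azimuthal profile with an integer number of repeats. The quality
gates below test exactly these assumptions window by window.

## Quality gating

A window contributes to the slope distribution only if all of the
following hold (all thresholds are arguments of `estimate_slope_auto`):

1. **Power fraction** — the dominant temporal frequency must carry at
   least `min_power_fraction = 0.2` of the total positive-frequency
   power. Featureless or purely noisy windows fail here (a flat spectrum
   over ~24 bins leaves each bin near 0.04).
2. **Phase-line fit** — $R^2 \ge$ `min_phase_r2 = 0.8` for the
   unwrapped-phase regression. Incoherent phases fail here.
3. **Wrap-around closure** — the total phase change over the $N$ cyclic
   columns must lie within `wrap_tol` (default $\pi/2$) of a *non-zero*
   multiple of $2\pi$. A periodic ring pattern must wind an integer
   number of times; a zero winding number would imply no spatial
   structure at all.
4. **Spatial consistency** — the winding number of the fitted phase line
   must equal the dominant spatial frequency of the window (from the
   row-wise spatial spectrum). Both count the number of pattern repeats
   around the ring, so a disagreement marks noise-driven phases rather
   than a rotating pattern. This gate is what keeps static rings static:
   contrast enhancement can fabricate weak but internally coherent
   temporal structure whose phase line winds an arbitrary number of
   times, and gates 1–3 alone let a few percent of such windows through.

A ring with no accepted windows is flagged *no reliable slope* and
classified static (`classify_static`; threshold 5 nm/s, below which a
measured speed is treated as no directional motion). This reproduces the
phenotype of GTPase-dead variants, which assemble into rings but do not
rotate.

## Preprocessing choices

`preprocess_kymograph` runs three steps, in this order:

* **Bleach correction** (`bleach_correct = TRUE`): each time row is
  divided by its mean. Photobleaching is global and multiplicative, so
  this removes it exactly in expectation. Without it, the decay trend
  dominates the low-frequency end of every column's spectrum and starves
  the power-fraction gate.
* **Savitzky–Golay smoothing** along time, order 2, window 7 rows. The
  order preserves quadratic signal content; the window length is the
  binding numerical choice. A quadratic SG filter of window $n$ begins to
  attenuate strongly near $1.8/n$ cycles/row, and the temporal signal
  frequency of a rotating ring is $f = v\,\Delta t\, m / (2\pi R)$ ($m$ =
  pattern repeats). At 3 s frames, $R = 500$ nm and $m = 5$, speeds of
  15–45 nm/s put $f$ at 0.07–0.22 cycles/row: an 11-point window has its
  stopband dip (gain 0.07) right at the 35 nm/s frequency and erases the
  signal, while a 7-point window keeps gain 0.67 there. Hence the
  default 7; users with slower acquisition (10 s frames) can raise it.
* **CLAHE** (clip 0.01, tile 16 px along the arc axis). Local contrast
  equalization helps stripe visibility when labeling density varies
  around the ring. Along the *time* axis the kymograph is tiled only
  minimally (two tiles): equalizing short time tiles independently
  injects temporal structure at the tile frequency into static rings —
  an artifact, not a measurement. The matrix is padded to tile-divisible
  dimensions (edge-replicated in time, wrapped along the cyclic arc
  axis) and cropped back afterwards.

Two further numerical choices matter:

* **Off-grid frequency refinement** (`refine_freq = TRUE`): $f^*$ from a
  50-row DFT is quantized to 0.02 cycles/row, which alone is a ~14%
  relative error at the slowest speeds of interest. The log-power peak is
  therefore refined by parabolic interpolation, and the phase is read out
  at the refined frequency via a direct DTFT. Ties in the bin search go
  to the lowest frequency (prefer the fundamental over harmonics).
* **Bilinear interpolation** for all sub-pixel sampling (trajectories,
  drift resampling). It is exact on affine images — which several oracle
  tests exploit — and adequate at the ~1 px arc sampling used here.

## Geometry conventions

Images are indexed (row, col), 1-based; the angle $\theta$ is measured
from the +col axis increasing toward +row; positive speed means
counter-clockwise in those coordinates. "Two clicked points" define a
ring as the endpoints of a diameter (midpoint = center); a center+edge
mode is available behind `mode = "center_edge"`. Arc sampling density
defaults to $n = \mathrm{round}(2\pi r)$ so that one kymograph column is
about one pixel of arc and the three trajectories at $r-1, r, r+1$ px are
commensurate with the 50-pixel windows. Windows half-overlap (stride 25)
to enlarge the slope distribution; both size and stride are arguments.

## The synthetic-data generator

`simulate_ring_movie` renders the measurement model directly: a radially
Gaussian annulus (σ 100 nm) whose azimuthal intensity is cos²-modulated
with period ~600 nm (adjusted so the circumference holds an integer
number of periods; cos² keeps expectations non-negative, as a Poisson
mean must be), rotated rigidly frame to frame, convolved with a Gaussian
PSF, bleached exponentially, drifted linearly, and corrupted with Poisson
shot noise (plus optional Gaussian read noise). Defaults describe the
targeted imaging regime: 65 nm/px (6.5 µm sCMOS pixel behind a 100×
objective), PSF σ 110 nm (≈ diffraction limit for 488 nm at NA 1.49),
3 s frame interval, 100 frames, 1 µm ring diameter, 200 peak / 20
background photons, bleach rate 0.003 s⁻¹. Neither pixel size nor photon
counts are published quantities for this kind of experiment; they are
realistic choices, fixed once, and every one is a config field.

`simulate_qcmd_trace` produces the canonical bilayer-formation shape
(baseline, vesicle overshoot dipping below the final plateau, relaxation
to −25 Hz, exponential protein-binding step) with white Gaussian noise;
`simulate_gtpase_plate` produces a serial-dilution standard series and a
linear phosphate time course through a linear absorbance response.

What the generator deliberately does **not** emulate: filament-scale
kinetics (nucleation, fragmentation, finite filament number), partial or
fluctuating ring occupancy, non-rigid rotation (velocity gradients along
the ring), structured background, camera fixed-pattern noise, QCM-D
viscoelastic (non-Sauerbrey) responses, and pipetting errors in the plate
assay. Passing the recovery tests therefore shows that the estimator
chain is correct and robust to shot noise, bleaching and drift at
realistic levels — not that it handles every pathology of real
recordings; the quality gates are the run-time guard for those.

## Companion assays

* **QCM-D** (`sauerbrey_coverage`, `detect_slb_formation`,
  `extract_binding_shift`, `fold_changes`): coverage
  $= -C\,\Delta f / n$ with $C = 17.7$ ng cm⁻² Hz⁻¹ (5 MHz AT-cut
  crystal) and $n$ the overtone (default 9). Files differ in whether they
  store raw overtone shifts or $\Delta f/n$; a `normalized` flag selects
  the dialect instead of guessing, and the −25 ± 1 Hz bilayer criterion
  is always checked on normalized shifts. Plateaus are medians of the
  last rolling-sd-stable window (30 samples, sd < 3× the baseline noise,
  with a 0.01 Hz instrument-resolution floor so that noise-free
  synthetic traces are handled sensibly).
* **GTPase** (`fit_standard_curve`, `activity_from_timeseries`): blanks
  are subtracted before the OLS standard curve; the time-zero point is
  included in the rate fit (no burst-phase exclusion rule is imposed);
  negative fitted rates are flagged, not clamped. The stopped-well rate
  is scaled by a dilution factor (default 50/13, i.e. 13 µL reaction
  into 37 µL stop solution) and by 60/[FtsZ] (default 5 µM) for
  turnover; normalization to a reference construct is emitted alongside
  the raw and turnover rates since either convention is defensible.
* **Statistics** (`summarize_group`, `welch_t_from_summary`,
  `welch_t_from_samples`): quartiles use linear interpolation (R type 7,
  the convention of the common plotting frameworks; selectable), notches
  are $1.58\,\mathrm{IQR}/\sqrt{n}$. The t-test defaults to the Welch
  unequal-variance form — the groups being compared here have variances
  differing several-fold, which makes the pooled form hard to defend —
  with the pooled variant behind `pooled = TRUE`. Fold changes are
  displayed with one decimal below 10-fold and as integers above, with
  ratios within 0.25 of a whole number snapped to that integer,
  matching how whole-number folds are conventionally reported; the raw
  ratio is always returned alongside the display string.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on simulated data:
48 × 48 px movies of 100 frames (yielding 100 × 48 kymographs and three
half-overlapping 50-row windows per ring), 20 seeds per condition for the
velocity-recovery and static-detection studies, 100 seeds for the
plate-assay bias study. These sizes were chosen so a full analysis of one
ring takes well under a second while each study still has enough
replication for stable means. All randomness flows from explicit seeds;
two runs with the same configuration are bit-identical, which
`run_pipeline` exposes by hashing every output into its manifest.

## Known limitations

* The estimator reports one velocity per ring; co-existing
  counter-rotating subpopulations would partially cancel rather than be
  resolved.
* Rings must be provided as ROIs (two points); there is no automatic
  ring detection across the field of view, matching the semi-manual
  workflow the package scripts.
* The Fourier analysis reads "vertical frequency" per column; a 2-D
  spectral variant (estimating the stripe orientation from the 2-D power
  spectrum) would be a natural extension.
* Sauerbrey conversion assumes a thin rigid film; soft, hydrated protein
  layers violate this and the derived coverages are then effective, not
  absolute, masses. No dissipation analysis is performed.
* Diameter estimation assumes a single annular maximum; nested or
  strongly incomplete rings raise an error rather than a guess.
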