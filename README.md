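# ringdyn

Quantification of treadmilling dynamics in membrane-bound FtsZ rings.

FtsZ, the bacterial tubulin homologue, self-organizes on supported lipid
bilayers into rotating ring-shaped vortices. The rotation is not transport
of material: filaments treadmill — they grow at one end and shrink at the
other — so an azimuthal intensity pattern sweeps around the ring at the
treadmilling speed. `ringdyn` turns time-lapse TIRF movies of such rings
into per-ring treadmilling velocities, and covers the two companion assays
used to compare FtsZ variants: membrane binding by quartz crystal
microbalance (QCM-D) and GTPase activity by colorimetric phosphate
release. A synthetic-data generator with known ground truth makes every
stage testable without any experimental data.

The package is aimed at in-vitro reconstitution labs analyzing
membrane-bound cytoskeletal dynamics, and at anyone who wants a fully
scripted, reproducible version of the classic semi-manual
kymograph-and-slope workflow.

## The method

**Kymograph.** A ring is defined by two clicked points (treated as the
ends of a diameter). Intensity is sampled by bilinear interpolation along
three concentric circular trajectories of radius r − 1, r and r + 1
pixels, at ≈1 px arc spacing, and averaged; stacking one row per frame
gives a cyclic kymograph K(t, x) with calibration Δx nm/column and Δt
s/row. Rotation appears as stripes of slope s columns/row.

**Fourier-phase slope estimation.** For each vertical window of 50 rows
(half-overlapping), each column's time series is demeaned and Fourier
transformed. The dominant temporal frequency f* (cycles/row) is the argmax
of the column-summed power spectrum, refined off the DFT grid by parabolic
interpolation of the log-power peak. The phase φ(j) of the coefficient at
f* advances linearly with arc position j for a rotating pattern, and the
stripe slope follows from the phase gradient:

    s = −2π f* / (dφ/dj)      [columns/row]
    v = s · Δx / Δt           [nm/s]

Windows are quality-gated: power fraction at f* ≥ 0.2, phase-line R² ≥
0.8, the total phase change over the N cyclic columns must be a non-zero
multiple of 2π (within tolerance), and the phase line's winding number
must equal the pattern's dominant spatial frequency. A ring whose windows
all fail the gates is reported as having *no reliable slope* — the static
phenotype of GTPase-dead variants. The final velocity is the mean of the
per-window slope distribution; a manual route (two clicked points on a
stripe) is provided for cross-validation.

**QCM-D.** Adsorbed areal mass follows the Sauerbrey relation
Δm = −C·Δf/n (C = 17.7 ng cm⁻² Hz⁻¹ for a 5 MHz crystal, n the overtone,
default 9). The package verifies bilayer formation (plateau at −25 ± 1 Hz,
overtone-normalized), extracts binding shifts as median step heights, and
builds coverage tables with fold changes between constructs.

**GTPase assay.** A 1:2 serial-dilution phosphate standard curve
(blank-subtracted OLS) converts absorbances to [Pi]; the production rate
is the OLS slope of [Pi] against time over the stopped 0–120 s series, and
activities are reported raw, dilution-corrected, as turnover and
normalized to a reference construct.

**Statistics.** Group summaries include notched-boxplot statistics
(notch half-width 1.58·IQR/√n) and two-sided Welch t-tests computable from
raw samples *or* from printed summary statistics (mean, SD, n), as needed
when comparing against published values.

## Worked example

```r
library(ringdyn)

# simulate a ring: 1 um diameter, treadmilling at 35 nm/s, 3 s frames
cfg   <- ring_sim_config(speed = 35, seed = 42)
movie <- simulate_ring_movie(cfg)
movie
#> <movie_stack> 48 x 48 px, 100 frames, 65 nm/px, 3 s/frame

# define the ring from two diameter points, build and analyze the kymograph
roi  <- circle_from_two_points(c(24.5, 16.8), c(24.5, 32.2),
                               image_size = c(48, 48))
kymo <- build_kymograph(movie, roi)
kymo
#> <kymograph> 100 time rows x 48 arc columns, 65.5 nm/col, 3 s/row

est <- estimate_slope_auto(preprocess_kymograph(kymo))
est
#> <slope_estimate> method: auto, windows: 3 (3 accepted)
#>   mean slope: 1.5696 columns/row  (velocity 34.28 nm/s)

coef(est)
#>         slope velocity_nm_s
#>      1.569589     34.277367

estimate_ring_diameter(movie, roi)
#> [1] 977.4406
```

All three 50-row windows pass the quality gates; the recovered velocity
(34.3 nm/s) sits within 2% of the simulated ground truth (35 nm/s), and
the measured diameter (977 nm) within one pixel of the true 1000 nm.

Comparing two variants from printed summaries alone:

```r
welch_t_from_summary(35, 13, 1359, 25, 6, 216)
#> <summary_t_test> welch: t = 18.54, df = 602.4, two-sided p = 4.9e-61
#>   mean difference 10 [8.941, 11.06]
```

A demo of the full pipeline (simulate → kymograph → slope → velocity →
summary, with a manifest and log) runs with
`run_pipeline(pipeline_config(), "out_dir")`, or from a shell via
`Rscript inst/scripts/ringdyn-run.R --out out_dir --seed 1`.

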