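# bilateralflow

Biophysical quantification of the bilateral counterrotating cellular flows
("polonaise movements") of the early amniote gastrula from time-lapse
fluorescence imaging.

Before and during primitive-streak extension, epiblast cells move in two
large counterrotating vortices, one either side of the forming midline:
with anterior up, the left vortex turns counterclockwise and the right
clockwise.  Whether — and when — these flows break left–right symmetry is a
quantitative question.  This package provides the full measurement chain
for answering it from images, for developmental biologists and biophysicists
working with embryo time-lapse data:

* a **PIV engine**: zero-mean normalized FFT cross-correlation of
  interrogation windows with unbiased per-lag normalization, two-pass grid
  refinement, 3-point Gaussian subpixel peak fitting and normalized-median
  vector validation;
* **flow derivatives**: speed \(\sqrt{u^2+v^2}\) and vorticity
  \(\omega = \partial v/\partial x - \partial u/\partial y\) maps, hourly /
  half-duration / full-duration time averaging, streamlines, circular-ROI
  masking;
* **midline geometry**: vortex-center detection by the \(\Gamma_1\) swirl
  criterion (closed vortex iff \(|\Gamma_1| > 2/\pi\)), and the three
  midline axes — anatomical (AM), biophysical (BM, perpendicular bisector
  of the center segment) and flow (FM, along the local flow at the center
  midpoint) — with angles to the vertical;
* **asymmetry metrics**: thresholded left/right areas
  \(A_L, A_R\) at 30/50/70% of the per-window maximum, fractional areas
  \(f_R = A_R/(A_L+A_R)\) (0.5 = line of symmetry), dominance
  classification with onset estimation, and an exact paired Wilcoxon
  signed-rank test;
* a **synthetic generator**: confined Lamb–Oseen bilateral-vortex
  scenarios, tracer advection (RK4) and Gaussian-spot rendering to
  multi-page TIFF, with per-frame ground truth, providing a no-download
  benchmark for every stage.

## Worked example

Simulate a right-dominant embryo (right-vortex circulation amplified 1.5x
from 6 h), run the full pipeline, and read off the per-window fractional
areas of 50%-thresholded speed split by the flow midline:

```r
library(bilateralflow)

cfg <- pipeline_config(preset = "right_dominant", seed = 2,
                       output_dir = "demo-run")
run <- run_pipeline(cfg)

rows <- run$areas$kind == "speed" & run$areas$threshold == 0.5
data.frame(window = sprintf("%d-%d h", run$areas$window_start[rows],
                            run$areas$window_start[rows] + 1),
           f_L = round(run$areas$f_L[rows], 3),
           f_R = round(run$areas$f_R[rows], 3),
           label = run$dominance$labels)
```

```
   window   f_L   f_R label
1   0-1 h 0.509 0.491  none
2   1-2 h 0.486 0.514  none
3   2-3 h 0.509 0.491  none
4   3-4 h 0.479 0.521     R
5   4-5 h 0.506 0.494  none
6   5-6 h 0.463 0.537     R
7   6-7 h 0.229 0.771     R
8   7-8 h 0.239 0.761     R
9   8-9 h 0.238 0.762     R
10 9-10 h 0.184 0.816     R
```

Up to 6 h the left and right fractional areas hover around the 0.5 line of
symmetry; from the 6–7 h window on, `f_R` jumps to ~0.77–0.82 and stays
there.  The dominance classifier summarizes this:

```r
run$dominance$end_dominance   # "R"
run$dominance$onset           # 5  (hours; true amplification onset: 6 h)
run$rank_test                 # V = 0, p = 0.125, n = 4 (windows >= 6 h)
```

`demo-run/` then contains `asymmetry.csv` (all windows x kinds x
thresholds), `midlines.csv` (AM/BM/FM angles, vortex centers, closed
flags), `center_track.csv`, per-window field tables, PNG heatmaps of the
time-averaged speed and vorticity, a streamline map, and `manifest.json`
with an md5 checksum of every output.  Identical configuration and seed
reproduce the tables byte for byte.

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/bilateralflow-cli.R run-all --preset right_dominant \
    --seed 2 --out demo-run
```

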