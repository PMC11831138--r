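---
title: "Quantifying left-right asymmetry of bilateral cellular flows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying left-right asymmetry of bilateral cellular flows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Before and during primitive-streak (PS) extension, the epiblast of the
amniote gastrula exhibits two large counterrotating cellular vortices — the
"polonaise movements" — one on each side of the forming midline.  With
anterior up, the left vortex rotates counterclockwise and the right vortex
clockwise, so cells stream from posterior to anterior along the midline and
return laterally.  `bilateralflow` quantifies how symmetric these two
vortices are over time, from time-lapse images of fluorescently tagged
cells: it estimates velocity fields by particle image velocimetry (PIV),
derives speed and vorticity maps on hourly, half-duration and full-duration
averaging windows, constructs three midline axes, and reduces each window
to left/right thresholded areas, fractional areas and a dominance label.

Because no raw imaging accession is bundled, the package ships a
first-class synthetic generator that produces fluorescence-like image
stacks from a known ground-truth flow.  Every downstream stage is tested
against that ground truth.

## The synthetic flow model

A scenario is a circular embryonic disc (the surrounding extraembryonic
material is stationary) containing two Lamb–Oseen vortices with tangential
speed

$$u_\theta(r) = \frac{\Gamma}{2\pi r}\left(1 - e^{-r^2/r_c^2}\right),$$

which is regular at the core center (PIV interrogation windows straddle the
centers, so a point-vortex singularity would be unusable).  Positive
circulation is counterclockwise in the package's y-up frame; the left
vortex has $\Gamma > 0$, the right $\Gamma < 0$.

Two modelling choices deserve emphasis:

* **Confinement.**  The bare two-vortex superposition has open streamlines
  that cross the disc rim: in early experiments roughly half of the
  in-disc tracers exited (and froze) within 10 h, and the anterior midline
  region lost almost all of its tracers — unlike the real flows, whose
  recirculation loops close inside the embryonic region.  Each off-center
  vortex is therefore accompanied by its circle-theorem image (opposite
  circulation at the inverse point with respect to the disc), which cancels
  the boundary-normal velocity.  The rim becomes a streamline, tracer
  density stays statistically uniform, and the classic closed polonaise
  loops emerge.  A vortex at the disc center needs no image, so the
  single-vortex closed forms used in the tests are unaffected.
* **Physical time.**  Circulations and drift are expressed per frame at
  the 3-min reference frame interval, and the flow is fixed in physical
  time: re-imaging the same scenario at half the frame interval halves the
  per-frame displacements, as it must for any real time-lapse.

Default conditions (256 x 256 px frames): disc radius 110 px, vortex
centers 45 px either side of the vertical diameter, core radius 30 px,
$|\Gamma| = 350$ px^2/frame (peak tangential speed about 1.2 px/frame),
3-min frames for 10 h (201 frames), a 2-h linear circulation ramp standing
in for the initial flow transient, tracer density 0.02 per px^2 with
Gaussian spots of sigma 1.5 px, and additive background noise of SD 0.05
(in units of a unit spot peak).  Presets encode the observed regimes:
`symmetric`, `right_dominant` (right circulation x1.5 after 6 h),
`left_then_right`, and `single_right_vortex` (the mitotic-arrest-like
degenerate flow).  The ramp shape, drift magnitudes and dominance factor
are qualitative choices: the source observations report these regimes
without parameterizing them.

Tracers are advected with one classical 4th-order Runge–Kutta step per
frame; halving the step changes positions by well under 1e-2 px per frame.
Tracers that nevertheless cross the rim (discretization stragglers) freeze
in place, emulating the stationary surround.

## The PIV engine

Velocities are estimated per consecutive frame pair by zero-mean normalized
cross-correlation of interrogation windows, computed via frequency-domain
products.  Two details matter for accuracy:

* **Unbiased (per-lag overlap) normalization.**  The raw windowed
  correlation is attenuated at larger lags because less content overlaps
  ("loss of pairs"), which pulls fitted peaks toward zero displacement —
  we measured 0.1–0.15 px of systematic underestimation at spot sigma
  1.5.  The surface is therefore divided by the per-lag overlap fraction.
  Because that correction amplifies wrap-around noise at extreme lags, the
  peak search is confined to lags within a quarter window.
* **Subpixel peak.**  A three-point Gaussian fit per axis around the
  integer peak (parabolic fallback when a sample is non-positive).  The
  peak must be a strict interior maximum; flat or border-peaked surfaces
  invalidate the vector.

The default configuration is two passes: a coarse non-overlapping
predictor pass at the configured 32-px window, then a refining pass at half
the window with 50% overlap, seeded by the (validated, interpolated,
integer-rounded) first-pass field.  Vectors are validated by the
normalized median test (threshold 2.0, stabilizer eps = 0.1 px/frame) plus
a minimum peak ratio of 1.2; outliers are replaced once by the
component-wise median of their valid neighbors.  These settings are
conventional; the source analysis delegated them to its PIV package
without reporting values, so all are configurable.

At the default tracer density a 16-px window holds about 5 spots, which
bounds the random error of a single vector at roughly 0.15 px; medians
over the grid are accurate to a few hundredths of a pixel, and hourly
averaging (20 frame pairs) reduces cell-level noise further.  The
32-px windows of the predictor pass (about 20 spots) recover imposed
translations with a mean absolute error below 0.1 px.

## Derived fields and windows

Speed is the vector magnitude; vorticity is the curl by central differences
(one-sided at grid borders; a cell is invalid if any stencil neighbor is).
Quantification windows are hourly, plus the two half-duration windows and
the full duration.  Averages are computed on velocity first, with speed and
vorticity derived from the averaged field (the per-frame-derived
alternative is available via `derive = "derive_then_average"` — the source
presentation is compatible with either, so both are exposed).  A cell of an
averaged field is valid when at least half its members are valid.  All
quantification is restricted to the circular embryonic ROI.

## Midlines and vortex centers

Vortex centers are found with the $\Gamma_1$ swirl criterion (the mean,
over a neighborhood disc of four grid spacings, of the sine of the angle
between the offset to a neighbor and the velocity there), one candidate
per rotation sign, refined to the vorticity-weighted centroid of the
connected region above half the candidate's peak |vorticity|.  A side is
"closed" when $|\Gamma_1| > 2/\pi$, the conventional closed-swirl bound.
Cells whose neighborhood disc is substantially truncated (grid or ROI
border) are excluded as candidates: a one-sided neighborhood reports
spurious swirl even in uniform flow.  The procedure is a design choice —
the source describes the midlines it derived from the centers but not how
the centers themselves were located.

Three midline axes are built per window: **AM** (anatomical) from a
two-point annotation along the PS — for synthetic data the disc's vertical
diameter, since the generator has no PS; **BM** (biophysical), the
perpendicular bisector of the center segment; **FM** (flow), through the
inter-center midpoint along the mean velocity within 10% of the
inter-center distance (a single interpolated vector between the vortices
is noise-dominated, hence the neighborhood average).  Lines are oriented
toward the anterior and angles to the vertical are reported clockwise
positive in (-90, 90].  Windows in which either vortex is open leave BM
and FM undefined, as in the degenerate single-vortex regime; during the
0-2 h transient the estimates exist but are noisy, and downstream
consumers should treat pre-ramp windows separately.

## Asymmetry metrics

For each window, kind (speed / |vorticity|) and threshold fraction (0.3,
0.5, 0.7), cells at or above the threshold times the per-window maximum
are retained and assigned to the embryo's left or right by the sign of the
cross product of the dividing midline direction with the cell offset;
cells exactly on the midline count half to each side, which makes mirror
equivariance exact.  The FM is the default dividing midline (AM and BM are
selectable); when the FM is undefined in a window the AM is used and the
substitution is recorded in the output.  The per-window maximum is the
default normalization, with a global-max mode behind a flag.  Fractional
areas $f_L = A_L/(A_L + A_R)$ and $f_R$ sum to one; 0.5 is the line of
symmetry.

Dominance per window: `R` if $f_R > 0.5 + \delta$, `L` if below
$0.5 - \delta$, else `none`, with $\delta = 0.02$; the end dominance is the
final window's label and the onset is the start of the earliest unbroken
run of that label reaching the final window, requiring at least two
windows.  With the full PIV chain the per-window $f_R$ of a symmetric run
fluctuates with SD about 0.035, so occasional short false runs at the
dead-band edge are expected in individual runs even though the mean over
seeds sits at 0.5; this is a property of the estimator noise at these
conditions, not a left/right bias (false calls split evenly between L and
R).

The paired left/right comparison uses a two-sided Wilcoxon signed-rank
test with zero differences dropped and average ranks for ties.  For up to
25 pairs the p-value is exact: the null distribution over all $2^n$ sign
assignments is evaluated by dynamic programming over doubled ranks, which
is arithmetically identical to full enumeration (the test suite verifies
this against explicit enumeration at small n).  Above 25 pairs a normal
approximation with tie and continuity corrections takes over.  Windows
starting at or after 6 h form the default pairing unit; the source pooled
an unstated unit, so this is exposed in the configuration and n is always
reported.

## Numerical and degenerate-input choices

Constant-intensity interrogation windows are flagged degenerate, never
fatal.  All-invalid fields validate to themselves with a warning.
Streamlines integrate the normalized direction field with a fixed RK4 step
of a quarter grid spacing and stop at the ROI/grid boundary, in invalid
cells, or where speed falls below 1e-3 px/frame.  Serialization of field
grids uses full `%.17g` precision so write/read cycles are bit-exact, and
pipeline CSVs are formatted deterministically: identical configuration and
seed reproduce byte-identical tables.

## Problem sizes used in the checks

The end-to-end checks run the study conditions at reduced resolution:
256 x 256 px frames, 3-min intervals, 10 h (200 frame pairs).  The
symmetry anchor averages 20 seeded runs; dominance-onset recovery uses 10
seeded `right_dominant` runs (true onset 6 h, factor 1.5); oracle checks
(correlation equivalence, closed-form vorticity, rank-test enumeration)
run on small synthetic inputs in seconds.

## What passing tests do and do not show

The generator emulates tracer imaging of an idealized confined two-vortex
flow: smooth, exactly mirror-symmetric unless configured otherwise, with
spatially uniform tracer density and stationary Gaussian noise.  Real
embryos add cell division and ingression, non-rigid tissue deformation,
uneven labelling, photobleaching and drift of the imaging frame — none of
which are modelled.  Passing the suite therefore demonstrates that the
measurement chain recovers known asymmetries (and reports symmetry as
symmetric) under controlled conditions; it does not validate the
biological conclusions drawn from any particular dataset.

## Known limitations

* Window-level dominance labels are noisy at the default dead band; trust
  persistent runs and seed-averaged fractional areas over single windows.
* The vortex-center detector assumes at most one dominant swirl candidate
  per rotation sign inside the ROI.
* No window deformation, ensemble correlation or 3-D PIV; flows with
  strong in-window gradients relative to the window size will bias
  velocities toward their local mean.
* The anatomical midline is an annotation, not a segmentation: analyses of
  real stacks must supply it (or accept the synthetic default, which is
  only meaningful for generated data).
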