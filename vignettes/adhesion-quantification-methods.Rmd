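---
title: "Quantifying cell-substrate adhesions: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-substrate adhesions: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhesioquant)
```

## The problem

Amoeboid cells such as *Dictyostelium* form small, short-lived,
focal-adhesion-like structures — fluorescent punctae of Paxillin- and
Vinculin-family proteins at the ventral surface — that are an order of
magnitude smaller (hundredths of a square micron) than classical metazoan
focal adhesions. Quantifying them requires a chain of small, individually
unglamorous measurements: counting and sizing thresholded spots, deciding
whether spots in two channels are the same structure, measuring how fast and
how directionally cells move, timing the assembly and disassembly of
individual adhesions, measuring how strongly cells resist shear flow, and
cleaning group measurements of gross outliers before comparison.

`adhesioquant` implements that chain as composable R functions, together
with a synthetic-data module that generates ground-truthed images, tracks,
kinetic traces and detachment counts. Every stage is therefore testable
end to end with no microscopy data: the generators define known truth, the
analysis recovers it, and independent brute-force oracles check the
recovery.

## Punctae detection

A single-cell fluorescence image is segmented by a global Otsu threshold
(`segment_cell()`); the largest connected foreground component, holes
filled, is the cell mask. The mean fluorescence intensity (MFI) and
standard deviation (SD) are computed **over mask pixels only** — background
"removal" is implemented as exclusion-from-statistics, never zero-filling,
because zero-filled pixels would drag down the MFI and inflate the SD.
The upstream toolchains this mirrors re-run an auto-threshold after
background removal; restricting the statistics to the mask subsumes that
second pass, so segmentation happens once.

Punctae are 8-connected components of mask pixels with intensity in
`[MFI + k_sd * SD, bit_max]`, both bounds inclusive, kept when their area in
square microns lies within `[area_min_um2, area_max_um2]`:

| parameter | default | meaning |
|---|---|---|
| `k_sd` | 3 | threshold multiplier; 2 for markers in a different signal-to-noise regime |
| `area_min_um2` | 0.02 | lower size cut (2 px at 0.1 um/px) |
| `area_max_um2` | 0.5 | upper size cut (50 px at 0.1 um/px) |
| `connectivity` | 8 | particle-analysis convention |

Numerical detail: the inclusive area bounds are evaluated on **pixel
counts** (`ceiling(area_min / px^2)` to `floor(area_max / px^2)`), because
`50 * 0.1^2` is not exactly `0.5` in floating point and a 50-pixel
component must sit exactly on the upper bound, not epsilon above it.

Which auto-threshold variant upstream tools apply ("Default"/IsoData vs
Otsu) is not knowable from their descriptions; Otsu was chosen as the
standard parameter-free bimodal splitter and the choice is exposed as an
argument. The upper intensity limit is generalised from the 16-bit constant
65535 to the image dtype maximum.

## Colocalization

Object-based, not pixel-correlation-based: two punctae colocalize when
their pixel sets share at least one pixel. Because a manual overlap call is
not reproducible, the pairing is made deterministic: candidate pairs are
ranked by descending overlap area, ties broken by ascending (a id, b id),
and resolved one-to-one greedily, so each punctum joins at most one pair.
An optional `min_overlap_frac` argument tightens the criterion from
"incidental overlap" to a fraction of the smaller punctum. `colocalize(a,
b)` and `colocalize(b, a)` give the same number of double-positive pairs by
construction.

## Migration metrics

Tracks are linked from per-frame centroids by greedy nearest-neighbour
assignment (ascending distance, each endpoint used once, links beyond
`link_max_um` forbidden), then a gap-closing pass joins track ends to later
track starts within `gap_max_frames` and `gap_max_um`. The defaults — 25 um
linking, 10 um gap closing, 5-frame gaps — are the simple
linear-assignment-tracker settings used for chemotaxing amoebae. Greedy
assignment rather than a full LAP solve is deliberate: at amoeboid cell
densities the assignment is collision-sparse and the greedy and optimal
solutions coincide except during close encounters, which the tests probe
explicitly with crossing-walker geometries.

* **Speed** (`track_speed()`): the mean over consecutive samples of
  displacement over interval, reported in um/min whatever the sampling
  interval (5 s for random migration, 15 s for chemotaxis). Gap-closed
  intervals contribute one displacement over the full gapped time.
  Localization noise biases this estimator upward (it adds positive
  increments to every step length); the property suite asserts the
  direction of that bias rather than pretending it away.
* **MSD** (`msd()`): time-averaged per track over all overlapping interval
  pairs at each lag, then the unweighted mean across tracks, up to half
  each track's duration (longer lags have too few intervals to be worth
  reporting). Stationary tracks give identically zero; ballistic tracks
  give exactly `(v tau)^2`; both are asserted against a brute-force
  all-pairs oracle.
* **Chemotaxis gate** (`chemotaxis_gate()`): a track counts "toward" the
  source when its net displacement (endpoint minus start) has **strictly
  positive** projection on the gradient axis; zero projection counts
  against passing. A dataset passes when the toward-fraction reaches the
  threshold (default 0.8). Net displacement, not mean instantaneous
  heading, is used because it matches how spider plots are read: a
  spider plot (`spider_coordinates()`) translates each track to the origin
  and the eye judges endpoints. The gradient axis defaults to +x and is a
  configuration field, not an inference.
* **Gradient validation** (`gradient_profile()`): a line-scan mean per
  column (or row) with a least-squares slope, to confirm a chemoattractant
  gradient actually exists before gating on it.

## Adhesion lifetime kinetics

Time-lapse stacks (default 750 ms interval) are background-suppressed with
a 3x3 white top-hat (`regional_maxima_3x3()`): each frame minus its
grayscale opening with a 3x3 square element. This realises the stated
purpose of the vendor "Regional Maxima 3x3" operation — suppressing smooth
background and uneven illumination while keeping punctae-scale local maxima
— with a transform whose semantics are public. The filters use replicate
padding so a flat frame maps to exactly zero everywhere, including borders.
(A strict regional-maxima *labelling* would return a binary mask and
discard intensities, which the downstream intensity traces need, so the
top-hat reading was adopted.)

Punctae are detected per frame and linked with a tight radius
(`track_punctae()`); a track contributes a trace only if it

1. never touches the first or last frame (its assembly or disassembly
   would be censored),
2. lasts at least `min_frames` = 8 frames — 6 s under the convention that a
   track's duration is `frames x interval` (each frame owns one full
   interval),
3. never skips a frame and never shares a pixel with another track
   (the automated stand-in for manual curation of merged or flickering
   punctae — a conservative rule that discards rather than repairs).

Each trace is baseline-subtracted (first-frame value removed), smoothed
with a centred 5-frame running average (windows truncate at the ends), and
fitted piecewise by `fit_lifetime()`:

* assembly, samples up to the trace maximum: logistic
  `A / (1 + exp(-r (t - t0)))`;
* disassembly, samples after the maximum: exponential
  `A_dis exp(-k (t - t_peak))`;

both by bounded Levenberg-Marquardt least squares with deterministic,
derivative-free starts (`A` from the trace maximum, `t0` from the first
half-max crossing, `r = 4 / (t90 - t10)` from the empirical rise, `k` from
a log-linear fit of the positive tail). The assembly t-half is the logistic
midpoint `t0`; the disassembly t-half is `t_peak + ln 2 / k`; the
**lifetime** is the interval between them. "Sum of both half-times" is the
other reading of a lifetime "based on the t-half of both fits"; it is
available as `lifetime_mode = "sum"`, but the interval is the default
because a sum of two times anchored at different origins has no meaning on
the time axis.

Two numerical choices matter more than they look:

* the discrete argmax locates the peak only to one frame interval, and the
  sample at the argmax usually still lies on the *rising* branch (the true
  peak rarely falls on the sampling grid). The decay fit therefore starts
  half a smoothing window past the peak — samples whose running-average
  window straddles the peak mix both branches and bias the decay rate low —
  and falls back to earlier starts only when the tail is shorter than
  three samples;
* once both branches converge, the peak time is refined to the
  intersection of the two fitted curves, restoring the half-time accuracy
  that the frame-quantised argmax destroys. On noiseless synthetic traces
  this makes parameter recovery exact to optimizer tolerance; at 5%
  amplitude noise the median recovered `t0` and `ln 2 / k` stay within a
  few percent of truth (the test suite runs 100 seeds of this).

Monotone traces leave the missing branch flagged unconverged and the
lifetime undefined rather than extrapolated. `fit_lifetime()` returns a
classed object with `print`, `summary`, `coef`, `predict`, `fitted`,
`residuals` and `plot` methods, so it behaves like any R model fit.

## Bulk assays

* `spreading_area()`: mask pixel count times pixel area — deliberately
  nothing more; classification into masks is upstream's job.
* `percent_detached()`: cumulative `100 (N0 - N_i) / N0` against the
  post-wash reference count over the 500-1500 ul/min flow ladder. Counts
  exceeding `N0` (cells drifting into view) are flagged and clamped, not
  silently accepted.
* `rear_front_ratio()`: the cell is split by the line through its centroid
  perpendicular to the instantaneous migration direction; the ratio is
  mean rear intensity over mean front intensity. The half-plane split is
  the minimal assumption (a thirds-based variant with the middle excluded
  is available); pixels exactly on the dividing line belong to neither
  half, which makes the ratio exactly reciprocal under axis reversal.

## ROUT outlier identification

Group measurements are cleaned with the ROUT procedure at Q = 1% before
comparison. Because the measurements are univariate, the "regression" being
made robust is the constant model: the centre is a Lorentzian-loss
M-estimate initialised at the median, and the robust standard deviation of
the residuals (RSDR) is the 68.27th percentile of absolute residuals
inflated by `n / (n - K)` with `K = 1` fitted parameter. Residuals ranked
by magnitude are then tested largest-first with `t = |res| / RSDR` on
`n - 1` degrees of freedom against the rank-dependent threshold
`alpha_i = Q (n - i + 1) / n`, and everything at least as extreme as the
deepest significant rank is flagged (a step-up walk), so the flag set is
always a suffix of the residual ordering. Flags are scale- and
shift-equivariant because both the statistic and the threshold are.

Guard rails: never more than `max_fraction_removed` (default 30%) of a
sample is flagged; samples with fewer than 3 values or all-identical values
are left untouched; and groups with more than 50% zero values are exempt
from filtering entirely — zero-inflated counts (e.g. punctae per cell in a
localization-deficient mutant) are signal, not contamination. The exact
small-sample critical-value interpolation of the commercial implementation
is proprietary; this implementation follows the published recipe and is
checked against an independently coded version of that recipe, not against
the commercial tool.

Standard hypothesis tests (normality batteries, t tests, ANOVA,
Kruskal-Wallis, regression) are deliberately **not** reimplemented;
`group_summary()` provides the n / mean / SEM plumbing and everything else
is base R's job.

## What the synthetic data does and does not emulate

The generators define the conditions under which the pipeline is
validated:

* `gen_punctae_image()` — one elliptical cell (semi-axes 7 x 5 um at
  0.1 um/px) at a cytoplasmic level of 300 counts over a dark exterior,
  Gaussian noise SD 30 counts (Poisson selectable), and sub-resolution
  Gaussian spots (sigma 1-2 px, i.e. at or near the diffraction limit)
  rendered at pixel centres. Spots are placed uniformly with a minimum
  pairwise separation and a 3-sigma margin from the cell edge; impossible
  packings fail loudly after bounded retries. No real noise statistics are
  reproduced — none are published for the imaging this emulates — so the
  background/noise defaults are fixtures chosen once at plausible
  camera-count levels.
* `gen_two_channel()` — shared spots at identical centres, exclusive spots
  separated from everything, independent noise per channel.
* `gen_tracks()` — a persistent random walk (heading diffusion with
  rotational diffusivity `1 / persistence_time`), fixed step length
  `speed x dt`, and chemotactic bias as a fraction of each step replaced
  by +x drift. Defaults: 6 um/min, 60 s persistence, 5 s sampling.
* `gen_intensity_trace()` — the logistic-rise / matched-exponential-decay
  model above, sampled at 750 ms, with i.i.d. Gaussian noise as a fraction
  of amplitude.
* `gen_detachment_counts()` — per-step binomial survival, so counts are
  monotone non-increasing by construction.

Every generator takes an explicit integer seed and touches no global RNG
state; identical spec + seed is bit-identical output.

Not emulated, hence not validated by passing tests: photobleaching, camera
gain structure, 3-D point-spread functions, cell-shape dynamics, adhesion
sliding/treadmilling, track merging and splitting. Real images also break
the generator's cleanest assumption — that spots are isolated Gaussians on
a statistically uniform cytoplasm — so recovery rates measured on
synthetic data are upper bounds for real data.

## Limits of count recovery

The validation grid for detection (spot amplitude 10-50x the background
SD, 1-15 spots per cell, sigma 1-2 px, centre separation down to 4 sigma;
10 images per cell of the 3x3x3 grid, 270 images) recovers the planted
count in roughly 94% of images, and the shortfall is informative about the
method rather than the code — detection agrees exactly with a brute-force
flood-fill oracle on every image:

* a *single* very bright, wide spot (sigma 2 px at 50x SD) produces a
  thresholded blob of ~0.53 um^2, just above the 0.5 um^2 size cap, and is
  rejected by the same filter that makes the pipeline robust on real
  cells. Count recovery and the published size filter genuinely conflict
  at that corner of parameter space;
* two bright spots at the 4-sigma separation floor have suprathreshold
  radii up to ~2 sigma and can touch under 8-connectivity, merging into
  one particle — a physical resolution limit of interval thresholding, not
  a linking error;
* at the lowest amplitudes, pairs of adjacent noise pixels occasionally
  reach the inclusive 0.02 um^2 floor and count as an extra punctum.

Away from these boundary regimes (separation above ~5 sigma, amplitude
10-25x SD, or any multi-spot cell at sigma <= 1.5 px) recovery is
effectively complete.

## Problem sizes used in validation

The test suite and the reproduction script run entirely on synthetic data
at sizes chosen to make sampling error small relative to the tolerances
being asserted: 270 images for the detection grid, 100 two-channel layouts
for colocalization, 50 random tracks (plus 500-track ensembles for
diffusive scaling) for MSD, 100 noisy traces for kinetic recovery, 100
planted-outlier and 200 clean samples (n = 1000) for ROUT, 200 detachment
simulations, and 20 track ensembles per gate condition.

## Known limitations

* Greedy linking is not a global LAP solve; dense fields with frequent
  close encounters need a real tracker.
* The logistic/exponential pair is assumed, not selected; adhesions with
  multiple peaks or sliding need a different model and are better excluded
  upstream.
* When a trace plateaus long before decay onset (`t_peak` well past
  `t0 + 4 / r`), noise makes the argmax land anywhere on the plateau, so
  the *peak time* (and with it the disassembly t-half) is biased early by
  up to the plateau length even though `t0` and `ln 2 / k` themselves stay
  accurate. Peaked traces — the common shape for real adhesions — do not
  suffer from this.
* ROUT equivalence is to the published recipe; small-sample flags may
  differ from the commercial implementation's proprietary interpolation.
* The rear/front ratio depends on the (configurable) partition; absolute
  values are comparable only within one partition convention.
* Segmentation is a global threshold; cells touching other bright objects
  need upstream masks (`detect_punctae()` accepts any logical mask).
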