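---
title: "Models and methods behind lamellikine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lamellikine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lamellikine)
```

This vignette is the package's own account of the measurement models it
implements, the parameters that matter, the numerical decisions taken
where the design was genuinely open, and what the synthetic-data tests do
and do not establish. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# Track speed and persistence at the usable time interval

## Model

Speed and persistence estimates from tracking tables are corrupted by
positional error (manual clicking, nuclear repositioning) whose
contribution grows as the sampling interval shrinks. The remedy
implemented here samples displacements `d_n` every δt, an integer multiple
k of the frame interval, and selects k from replicate blinded observations
of the same cell: the positional error of a displacement is estimated as
√2 times the per-coordinate RMS deviation across replicates (a
displacement is a difference of two noisy points, per axis, combined over
two axes), and `usable_time_interval()` returns the smallest k whose
error-to-mean-displacement ratio falls below 10%. Taking the *smallest*
passing k avoids under-sampling the true path.

- `MTS = mean(d_n)/δt`. Sub-sampling shortens curved paths, so MTS at
  k·frame intervals is ≤ MTS at the frame interval for every track — an
  exact inequality the property tests assert. Speeds are therefore only
  comparable at a common δt.
- Persistence is scored per window of Δt = TR·δt as the directionality
  ratio `D_N / Σ d_n` and averaged over consecutive non-overlapping
  windows anchored at the first frame (trailing incomplete windows
  discarded). Windowing makes tracks of different lengths comparable.

## The normalisation factor α

The persistence score is "multiplied by a normalisation factor α" that
maps a straight path to 1 and a pure random walk to its floor. Those two
requirements are not simultaneously satisfiable by a single multiplicative
constant (the raw ratio already attains 1 on a straight path), so two
modes are exposed and every reported value states its mode:

- `raw` (default): α ≡ 1. The raw mean directionality ratio; straight
  paths score exactly 1, a TR = 4 random-walk population scores ≈ 0.5.
- `affine_rw`: affine rescaling so the random-walk baseline maps to 0 and
  a straight path to 1. The baseline is either supplied or estimated by
  Monte Carlo: the track's own `d_n` are shuffled and re-emitted with
  uniform random headings, scored with the identical windowing, and
  averaged over `mc_reps` repetitions. Using the track's own step lengths
  keeps the baseline conditional on the observed speed distribution.

Both modes agree (exactly 1) on the straight-path acceptance target.

## Windowing choices

Displacement intervals and persistence windows are non-overlapping:
"a displacement measurement every 3 frames" describes decimation, not a
sliding window. Mean-square displacement, by contrast, uses overlapping
ordered pairs — the convention of the published macros it mirrors — which
halves variance at no cost. A window in which the cell never moved has
directionality ratio 1 by convention (no path, no directional error);
this affects only degenerate synthetic inputs.

## The correlated-random-walk generator

`simulate_crw()` draws step speeds from a lognormal parameterised by the
target mean and sd (per-cell speeds are positive and right-skewed) and
evolves headings by von Mises increments with concentration κ — the single
persistence knob, sampled with the Best–Fisher rejection algorithm; κ = 0
is an uncorrelated walk (MSD log–log slope 1), κ ≥ 10⁶ a straight path,
and raw MTP is monotone in κ, which the recovery tests assert at the
fibronectin settings (5 min frames, δt = 15 min, TR = 4). Observed tracks
add i.i.d. Gaussian noise per coordinate. The usable-interval
demonstration scenario is a strongly persistent cell (κ = 50, 0.4 µm/min)
tracked for 121 frames with 1.2 µm noise: at that noise a 10-hour record
of a directed cell is needed before some k ≤ 10 passes the 10% rule —
shorter or more meandering tracks correctly raise the "no candidate
passes" error.

# Leading-edge morphodynamics

## Edge velocity

Masks come from per-frame percentile contrast stretch, Gaussian blur,
histogram matching to frame 1 (photobleach correction), a frame-1 Otsu
threshold propagated to all frames, largest connected component and hole
filling; a mask-override argument accepts externally edited masks. The
signed edge-normal velocity at a boundary point of frame t is the
distance to the boundary of frame t+1, positive if the point lies inside
the t+1 mask (growth), divided by the frame interval — a forward
difference, so the last frame carries no velocity.

Two digital-geometry corrections matter at this resolution:

- Boundary polygons of both frames are smoothed with a 5-point circular
  moving average before distances are taken. Raw pixel boundaries
  fluctuate ±0.5 px; taking a minimum distance over such a fluctuating
  vertex set is biased low by ~0.35 px per frame. Smoothing removes the
  bias (and identical masks still give exactly zero velocity because
  their smoothed polygons coincide). With it, the boundary integral of
  velocity × arc element reproduces the mask area change within ~2% on
  discs — the conservation property test.
- Arc lengths use Vossepoel–Smeulders chain weights (0.948 per straight
  step, 1.340 per diagonal), the standard unbiased perimeter estimator
  for 8-connected digital curves; naive chain length overestimates a
  circle's perimeter by ~5%.

A resolution limit follows from the construction: per-frame edge motion
below ~1 px is invisible to the signed-distance estimator. The synthetic
sector movies therefore default to 30 s frames and 0.25 µm pixels so that
1 µm/min protrusion moves 2 px per frame. Real 5 s acquisitions should be
analysed with a frame stride that brings the expected motion above a
pixel.

## Cone speed, stability, runs

The migration direction is the centroid displacement smoothed with a
5-frame centred moving average (raw per-frame centroid jitter makes the
60° cone unstable); frames with zero smoothed displacement are flagged
and skipped. Protrusion stability is reported in two variants because the
underlying statistic can be read spatially or temporally: the default
pools all per-point cone velocity samples across frames; `per_frame`
takes the S.D. across frames of per-frame cone means. The longest
uninterrupted lamellipodium is the maximal contiguous boundary arc with
velocity > `v_min` (default 0 — the only parameter-free reading of
"protruding"; exposed as a flag), with circular wrap-around handled by
merging runs that touch both ends of the traversal.

## Curved-ROI length and width

`curve_length()` follows the centerline construction: the maximally
separated boundary point pair are the endpoints (ties broken
lexicographically by boundary index), the closed boundary splits into the
two connecting arcs, both are re-parameterised to normalised arc length
and averaged pointwise. On a full disc — no meaningful endpoints — this
averaging collapses the two half-boundary arcs onto the diameter, so the
documented
degenerate result is ≈ 2r, a direct consequence of the algorithm.
Width is the mean mask extent along the local centerline normal at ten
equally spaced interior centerline points, probed in quarter-pixel steps;
the two one-sided reaches stop at the physical mask edge, so their sum is
the transect width without further correction.

# Retrograde-flow PIV

Matching uses the zero-normalised (Pearson) correlation — the stated 0.5
threshold on a "correlation coefficient" implies normalisation, and it
buys exact invariance to global gain and offset. Box sizes convert to the
nearest odd pixel count ≥ 3. One consequential interpretation: candidate
box *centres* span the search box, so displacements up to search_box/2
(0.25 µm) are measurable. Requiring whole candidate boxes inside the
search box would cap measurable flow at (0.5−0.3)/2 = 0.1 µm per 3.22 s
frame = 1.86 µm/min — below flow speeds this method is routinely applied
to (up to 3 µm/min) — so that reading is rejected on physical grounds.

Sub-pixel refinement (default on) fits a three-point Gaussian through the
correlation peak per axis, falling back to a parabola when a neighbour is
non-positive; without it, per-frame displacements at realistic flow
speeds quantise to whole pixels and the recovered speed is biased by up
to 25%. Displacements become velocities over exactly one frame interval.

Interpolation to the dense field is normalised convolution: Gaussian
weights in space (kernel 3 µm, σ 0.5 µm) and time (15 s, σ 6 s),
truncated at the kernel size, with the weighted vector sum divided by the
weight sum. Division by the accumulated weight makes constants reproduce
exactly and linear ramps to within 2% in the interior; pixels with zero
weight are flagged missing rather than zero-filled, and
threshold-rejected vectors are simply dropped (they carry no weight).
The assembly rate is `|flow| + |protrusion|` per cell, with protrusion
speed taken from the edge module's cone speed (or ground truth in
synthetic recovery tests).

The synthetic flow movie translates a periodic filtered-noise texture by
Fourier shift — exact for integer shifts (a pixel permutation, giving the
assertable identity and coefficient-1 cases) and interpolation-free for
sub-pixel shifts, so PIV accuracy tests are not confounded by generator
blur. Per-frame intensity noise is redrawn independently.

# FLIM–FRET

Per-pixel decays are tail-fitted from the peak bin with
`A·exp(−t/τ) + B` by Levenberg–Marquardt (cap 200 iterations,
convergence on relative parameter change < 10⁻⁶ with per-parameter scale
floors so a background pinned at machine zero cannot block termination).
No IRF deconvolution: the synthetic data carries none, a stated
simplification. Pixels below `min_photons` (default 100) or without
convergence are invalid with a reason code rather than an error.

Two numerical decisions deserve emphasis:

- **Weights.** Weighted least squares with weights from the *observed*
  counts (1/max(c, 1)) is biased: bins fluctuating low get too much
  weight, pulling τ down ~1% at 10⁴ photons — enough to shift an
  efficiency map's zero point detectably. The implementation therefore
  re-evaluates Poisson-motivated weights from the current model
  prediction at each iteration (iteratively reweighted LM). With that
  choice, τ estimates are unbiased within Monte-Carlo resolution and the
  E distribution for τ_DA = τ_D is centred at 0.
- **Record length.** With a record of only ~3τ and no pre-peak bins, the
  free background B is nearly degenerate with τ and the τ spread at 10⁴
  photons is several times the Cramér–Rao scale. The synthetic default is
  therefore 128 bins × 0.2 ns (25.6 ns ≈ 6.4 τ_D), a standard TCSPC
  record, which pins B and brings the spread to ~1.3%.

Efficiency is `E = 1 − τ/τ_D` per valid pixel; τ_D is a supplied donor
lifetime or, with `"auto"`, the mode (not mean — robust to a quenched
subpopulation) of a donor-only control image's lifetime histogram.
Negative E values from noise are kept for statistics and clipped only for
display. The per-cell "weighted average mean" weights pixels by photon
count — the information-proportional choice, made explicit because the
original weighting is unspecified — and the unweighted mean is always
co-reported. For the default synthetic mixture (τ 4.0/3.0 ns, 30%
quenched, equal photons) the implied whole-cell efficiency is
0.25 × 0.30 = 0.075, which the recovery test reproduces.

# Orchestration and reproducibility

`run_pipeline()` executes the enabled stages in dependency order. The
master seed is split per stage by hashing (seed, stage name), so adding a
stage never reshuffles another stage's randomness; every generator also
takes an explicit seed, and identical configurations produce
byte-identical result tables (asserted in the acceptance suite). SEM in
`compare_groups()` is sd/√n with n = cells, never frames. Because no
TIFF reader exists in the supported environment, movies and TCSPC stacks
serialise to a plain-text stack format (`write_stack()`/`read_stack()`)
with JSON ground-truth sidecars.

# What the synthetic tests establish — and what they do not

The generators reproduce the statistical structure each analysis stage
assumes: lognormal speeds and von Mises turning for tracks, rigid
sub-pixel texture translation for PIV, a disc with a protruding sector
for edge metrics, mono-exponential Poisson decays for FLIM. Green
recovery tests therefore establish correctness of the estimators under
their own model assumptions and calibrations. They do not establish
robustness to what real data adds: segmentation errors on low-contrast
edges, texture deformation and out-of-plane motion in flow movies,
IRF convolution and multi-exponential decays in FLIM, or the biological
noise of shape change during nuclear tracking. Group-level hypothesis
testing is deliberately out of scope — the package emits per-cell values
and leaves statistics to downstream tools.
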