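# lamellikine

Quantification tools for random cell-migration imaging experiments, for
cell biologists measuring how a perturbation (knockout, rescue, drug)
changes motility and lamellipodial behaviour. The package implements four
independent measurement pipelines plus a synthetic-data module that
generates inputs with known ground truth, so every stage is testable
without microscope data:

1. **Track statistics** — cell speed and persistence from manually tracked
   positions, computed at the *usable time interval* δt: the smallest
   integer multiple of the frame interval at which tracking positional
   error falls below 10% of the mean displacement. With displacements
   `d_n` sampled every δt and windows Δt = TR·δt (TR = Time Ratio):

   - Mean Track Speed `MTS = mean(d_n) / δt` (µm/min)
   - directionality ratio per window `DR_N = D_N / Σ d_n` (net over total
     path)
   - Mean Track Persistence `MTP = α · mean(DR_N)`, with α ≡ 1 in the
     default `raw` mode and an affine random-walk normalisation (straight
     path → 1, random walk → 0) in `affine_rw` mode

   plus mean-square displacement (log–log slope: 1 diffusive, 2
   ballistic), directionality ratio over time, direction autocorrelation
   and the mean persistence profile over a δt grid.

2. **Leading-edge morphodynamics** — segmentation of LifeAct-style movies,
   signed edge-normal velocity from the distance between consecutive
   boundaries (protrusion positive), protrusion speed in a 60° cone about
   the migration direction, protrusion stability (S.D. of cone speeds),
   the longest uninterrupted lamellipodium (maximal contiguous protruding
   boundary arc, µm), protrusion length distributions, and curved-ROI
   morphometrics (centerline length, width, length/area, intensity/area).

3. **F-actin retrograde flow (PIV)** — zero-normalised cross-correlation
   template matching (source box 0.3 µm, search box 0.5 µm, grid 0.2 µm,
   correlation threshold 0.5, optional Gaussian sub-pixel peak
   refinement), normalised-convolution interpolation to a dense field
   (spatial kernel 3 µm, σ 0.5 µm; temporal kernel 15 s, σ 6 s), mean flow
   speed per cell, and the F-actin assembly rate
   `assembly = |flow| + |protrusion|`.

4. **FLIM–FRET biosensor analysis** — per-pixel Levenberg–Marquardt tail
   fits of mono-exponential TCSPC decays `A·exp(−t/τ) + B` with
   Poisson-motivated model-based weights, FRET efficiency maps
   `E = 1 − τ_DA/τ_D`, efficiency histograms and photon-weighted per-cell
   mean efficiencies.

A `run_pipeline()` orchestrator (and a `lamellikine` CLI under `exec/`)
chains simulate → analyse → summarise with per-stage seed splitting and
byte-reproducible result tables.

## Worked example

Thirty simulated cells (correlated random walks: mean speed 0.4 µm/min,
von Mises κ = 4, 0.3 µm tracking noise, 48 frames at 5 min), scored at the
usable time interval δt = 15 min with TR = 4:

```r
library(lamellikine)
pop <- lapply(1:30, function(i)
  simulate_crw(crw_params(n_frames = 48L, frame_interval = 5,
                          speed_mean = 0.4, speed_sd = 0.15, kappa = 4,
                          noise_sd = 0.3, seed = 100 + i),
               cell_id = sprintf("cell%02d", i)))
pp  <- persistence_params(delta_t = 15, TR = 4)
mts <- sapply(pop, mean_track_speed, delta_t = 15)
mtp <- sapply(pop, function(t) as.numeric(mean_track_persistence(t, pp)))
sprintf("MTS mean %.3f sem %.3f | MTP mean %.3f sem %.3f",
        mean(mts), sd(mts)/sqrt(30), mean(mtp), sd(mtp)/sqrt(30))
#> "MTS mean 0.378 sem 0.005 | MTP mean 0.820 sem 0.017"
```

MTS (0.378 µm/min) sits slightly below the generating 0.4 µm/min because
sampling every 15 min shortens a curved path — which is exactly why speed
and persistence are always reported together with their δt and TR. The raw
MTP of 0.82 reflects strongly persistent walkers (κ = 4); a pure random
walk population scores ≈ 0.5 under the same windowing and a straight path
scores exactly 1.

The same per-cell numbers come from the CLI:

```sh
lamellikine tracks --in tracks.csv --frame-interval 5 --pixel-size 0.65 \
    --delta-t 15 --tr 4 --alpha-mode raw --out stats --msd
```

## Layout

- `R/` — implementation (synthetic generators, track metrics, edge
  dynamics, PIV, FLIM-FRET, pipeline, CLI)
- `tests/testthat/` — unit, property and acceptance suites with
  code-built fixtures
- `vignettes/lamellikine-methods.Rmd` — the methods vignette: models,
  assumptions, parameter choices, numerical decisions and limitations
- `scripts/acceptance.R` — the acceptance report generator
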