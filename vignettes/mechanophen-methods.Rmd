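---
title: "Methods: models, estimators and design choices in mechanophen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in mechanophen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanophen)
```

`mechanophen` quantifies four mechanophenotypes of cultured tumor cells —
silhouette morphology, migratory behavior, cortical stiffness and
focal-adhesion organisation — and runs the statistical battery that such
studies use to compare cell lines or substrate conditions. Every analysis
stage is paired with a synthetic-data generator that produces inputs with
exact ground truth, so the whole pipeline can be validated end-to-end
without any raw microscopy data. This vignette documents the underlying
models, the estimators, the tunable parameters, and the design decisions
that were genuinely open.

## Particle morphometry

Suspended cells and calibration beads appear as bright, nearly convex
particles after brightness/contrast maximisation and thresholding.
`segment_particles()` reproduces the ImageJ-style chain: global
auto-threshold (Otsu by default; the iterative-intermeans IsoData variant,
ImageJ's default, is available and both behave identically on bimodal
synthetic images), hole filling, 8-connected component labeling, and
optional removal of border-touching particles (on by default: partial
particles bias area downward). `filter_particles()` applies the
conventional suspended-cell settings — area 300–1,250 px² and circularity
0.65–1 — which drop debris and multi-cell aggregates.

Descriptors per particle:

* **Area** `A`: pixel count × (pixel size)².
* **Perimeter** `P`: Crofton multi-direction estimate,
  `P = (π/4)[C0 + C90 + (C45 + C135)/√2]`, where `C` counts boundary
  chords met by scan lines in four directions. Naive boundary-pixel
  counting overestimates the perimeter of a digital circle by ~27% and
  drives its circularity to ≈ 0.8; the Crofton estimator restores the
  circle-has-circularity-1 semantics (within 1% for radii ≥ 15 px).
* **Circularity** `4πA/P²`, clipped at 1 (digitization can nudge it
  above).
* **Inverse aspect ratio**: minor/major axis of the moment-equivalent
  ellipse from second-order central moments (with the 1/12 unit-pixel
  term), the "Fit Ellipse" convention.
* **Solidity** `A / A_hull` with the hull taken over pixel centers and
  the ratio clipped at 1.
* **Equivalent diameter** `√(4A/π)`.

The rasterizer marks a pixel as foreground iff its *center* lies inside
the analytic shape, with no anti-aliasing, so ground-truth areas are
reproducible as pixel counts; the discretization error for disk areas is
below 2% at radius ≥ 15 px.

The bead generator (`generate_bead_image()`) draws diameters from a
normal distribution truncated at zero — defaults 9.94 ± 1.01 µm, a
manufacturer-certified 10-µm batch — and places disks on a jittered grid
whose pitch makes overlap impossible. Imaging pixel size is a free
parameter (0.3 µm/px by default, a typical 20× configuration); none of
the descriptor ratios depend on it. Phase-contrast halo artifacts are
deliberately *not* simulated: real bead images are over-segmented by the
halo and measure high, and that optical effect is outside what a
segmentation benchmark with known truth can certify.

## Migration: MSD and the persistent random walk

Trajectories are sampled at a uniform interval (5 min is the common
frame rate). `compute_speed()` is path-based — total path length over
elapsed time — because "speed" in tracking workflows conventionally means
the mean frame-to-frame displacement rate; the displacement-based
alternative is recoverable from the chemotactic index. The
time-averaged MSD uses **all overlapping pairs** at each lag
(`n_pairs = N − k`), and by default only lags up to 50% of track duration
are kept, since long-lag estimates average few, strongly correlated
pairs.

The persistent-random-walk model is the Fürth form

$$\mathrm{MSD}(t) = 4D\,[\,t - \tau(1 - e^{-t/\tau})\,],$$

ballistic (`(2D/τ)t²`) below the persistence time τ and diffusive
(`4Dt`) above it. (Printed versions of this equation sometimes carry
typographical corruption — a π in place of τ, a mangled exponent; the
standard form above is the only dimensionally consistent reading and is
what the package implements.)

`generate_prw_trajectory()` simulates the integral of a 2D
Ornstein–Uhlenbeck velocity process using the **exact joint Gaussian
transition** of (position, velocity) per step — decay factor
`exp(−dt/τ)`, innovation covariance from the closed-form integrated-OU
expressions — with the initial velocity drawn from the stationary
distribution. The ensemble MSD therefore equals the Fürth form exactly at
every lag and any `dt`; an Euler scheme would introduce a step-size bias
that the validation suite would have to absorb into its tolerances.

`fit_prw()` estimates (D, τ) by constrained Levenberg–Marquardt. Residual
weighting matters: the MSD spans orders of magnitude across lags, and
unweighted (or pair-count-weighted) least squares lets the large long-lag
values dominate, washing out the short-lag curvature that identifies τ.
We measured worst-case τ errors across the full recovery grid
(D ∈ {1, 10, 50} µm²/min × τ ∈ {2, 10} min, 200 tracks × 100 steps, three
independent seed sets) of 31–41% for absolute/pair-count/inverse-pair
weights, versus 10.6% for **relative weighting** (1/MSD², equivalent to
fitting log-MSD), which is therefore the default; the other schemes
remain selectable. Initialisation: D from the slope of the last lag
quartile over 4, τ from the first lag.

Two sampling constraints shape any such experiment and our test
conditions: τ is identifiable only when `dt < τ` (at `dt = 5` min a
τ = 2 min walk is already diffusive at the first lag), and D needs total
duration ≫ τ. The recovery analyses therefore use `dt = 1` min with 100
steps (10× the largest τ); the Fürth-convergence check runs at the native
`dt = 5` min where it holds exactly by construction.

The chemotactic index is net displacement projected on the gradient axis
divided by total path length — bounded in [−1, 1], 1 for a straight run
up the gradient, 0 for perpendicular motion or any closed loop. This is
the standard definition for microchannel chemotaxis assays.

## AFM stiffness: the Hertz model

Force curves follow the spherical-tip Hertz law

$$F = \tfrac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{r}\,\delta^{3/2},$$

with Poisson's ratio ν = 0.45 (the standard live-cell assumption), tip
radius r = 30 nm, and indentation δ. `fit_hertz()` estimates E jointly
with the contact point z₀ and a force baseline: pre-detecting z₀ by
thresholding biases E on soft samples, and treating it as a free
parameter is the robust default when the acquisition software's method is
undisclosed. Exactly the spherical `√r δ^{3/2}` form is used — no Sneddon
cone variant. Raw deflection-vs-piezo data are converted via Hooke's law
and the tip–sample separation correction (`force_curve_from_deflection()`).

`aggregate_force_map()` condenses a per-cell force map (typically 100
curves over a few µm²) into one modulus. The aggregation statistic is not
standardised across instruments; the default is the **median**, robust to
occasional corrupted curves and substrate-proximity stiffening, with the
mean available. The fraction of non-converged curves is always reported.
An optional trigger-force cutoff (≈ 1.35 nN for a 1 V trigger on a
0.02 N/m lever) truncates fits the way a fixed-trigger acquisition would;
on synthetic 1–100 kPa curves this changes recovered moduli by < 5%.
Recovery bias stays below 5% up to ~100 kPa at 10 pN noise; far stiffer
samples indent only a few grid samples before the force range is
exhausted, and accuracy degrades — the package documents rather than
hides this regime.

## Focal adhesions

The processing chain mirrors the conventional ImageJ recipe:
`subtract_background()` (white top-hat: grayscale opening by a disc of
radius 50 px subtracted from the image — features smaller than the disc
survive, smooth background is removed; boundary effects are confined to
within one radius of the border), `segment_fas()` (auto-threshold,
8-connected labeling, minimum adhesion size), `fa_statistics()` (cell
area from the actin channel: threshold, largest component, fill holes;
density = count / area).

Two ambiguities were resolved as follows. A printed minimum adhesion
"size" of 4.14 μm is interpreted as an **area** (4.14 µm²), since the
particle-analysis workflows it configures take area bounds; it is
configurable. And adhesions are assigned to a cell by the **centroid
containment** rule — counted only if their centroid falls inside the
actin-derived mask — because density is defined per cell. Working in
native bit depth versus converting to 8-bit first changes nothing on
synthetic data (the suite checks mask equality under both orders), so
native depth is the default.

## The statistical battery

`compare_groups()` reproduces the normality-gated decision tree of GUI
statistics packages: per-group D'Agostino–Pearson omnibus test (K² from
the D'Agostino skewness and Anscombe–Glynn kurtosis z-scores, χ² with
2 df; requires n ≥ 8, with a Shapiro–Wilk fallback for 3 ≤ n < 8 and
zero-variance groups recorded as non-normal), then either ANOVA (one- or
two-way, Tukey HSD follow-up) or Kruskal–Wallis with Dunn's post hoc. The
gate defaults to the **permissive rule** — parametric if *any* group
looks normal ("partially follows a normal distribution") — matching the
convention of the workflows this package emulates; the orthodox
all-normal rule is one argument away. Dunn p-values are
Bonferroni-adjusted over all pairs by default (again the GUI-package
convention; Holm and unadjusted available). Significance is called at
α = 0.05.

`rout_outliers()` implements the univariate special case of the ROUT
procedure (the original is defined for nonlinear regression): robust
location = median, scale = normal-consistent MAD (IQR fallback with a
warning when the MAD degenerates), residual p-values from the t
distribution, and Benjamini–Hochberg FDR control at Q = 1%. Flags are
returned, never silently applied; the documented order of operations is
flag → exclude → re-test. On clean normal samples of 100 the false-flag
count stays ≤ 2 in ≥ 95% of seeded repetitions.

Type-I calibration: over 1,000 null simulations (3 groups × n = 30) the
Kruskal–Wallis rejection rate at α = 0.05 lies within [0.03, 0.07].

## Reproducibility and problem sizes

All generators take an integer seed and restore the caller's RNG state;
identical arguments and seed give bit-identical outputs.
`run_pipeline()` fans a single global seed out to per-stage seeds by
fixed offsets, so one number reproduces a full run, and writes a
provenance log (seed, parameters, versions) next to the per-stage CSVs.

Validation problem sizes were chosen as the smallest that make the
statistical tolerances meaningful: 300+ beads for sizing (3 SEM ≈ 0.17 µm
of the 9.94 µm mean), 200-track ensembles for (D, τ) recovery, 100-curve
force maps at 10 pN noise, 1,000 null simulations for test calibration.

## What passing tests do and do not show

The synthetic generators emulate geometry, kinetics, contact mechanics
and counting statistics with exact truth — they do not emulate
phase-contrast halos, uneven illumination, cell–cell contact,
segmentation-confusing texture, viscoelastic (rate-dependent) AFM
response, or tracking errors. Passing the suite certifies the
*quantification machinery*: segmentation arithmetic, estimator
consistency, filter logic and statistical calibration. It does not
certify that any particular real image set is segmented correctly; on
real data the dominant error sources are optical and biological —
phase-contrast halos alone can inflate apparent bead diameters by well
over the tolerances used here, which is precisely why calibration-bead
controls are run on the real instrument.
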