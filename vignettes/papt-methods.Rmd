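---
title: "Quantifying patterned tracer uptake as a single-cell secretion surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying patterned tracer uptake as a single-cell secretion surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paptkit)
```

## The measurement and its model

A pancreatic islet held in a perifusion chamber is bathed in a small
polar fluorescent tracer. The tracer is membrane-impermeant: it fills the
extracellular clefts (outlining each cell) and the only way it enters a
cell is by endocytosis. Because compensatory endocytosis is coupled to
exocytosis, a secreting cell accumulates bright sub-resolution puncta —
tracer trapped in retrieved vesicles — at a rate that follows its
secretion rate. The integrated intensity of this patterned uptake
(PAPT), and especially its first temporal derivative dPAPT/dt, is a
per-cell secretion read-out that needs no transgene or loaded indicator.

Three facts shape the analysis:

* **Puncta persist.** Once formed, a labelled vesicle remains detectable
  for hours. PAPT is therefore cumulative, and the patterned-system mask
  that defines it must be monotone non-decreasing over time (an optional
  per-frame mode exists for non-cumulative analyses).
* **Not all uptake is patterned.** Vascular endothelial cells (and dying
  cells) take up the tracer intensely and *uniformly*; bulk-mode
  endocytosis produces diffuse rather than dotted signal. Both must be
  excluded before PAPT means anything.
* **The chamber has kinetics of its own.** Tracer concentration at the
  tissue follows a dead time (lag) plus a single-exponential
  equilibration with time constant τ. The defaults used throughout
  (lag 138 s = 2.3 min, τ = 126 s = 2.1 min) reproduce the measured
  behaviour of a blotted microperifusion circuit at 50 µL/min.

## Detection: DoG maxima and Hessian shape analysis

Candidate puncta are strict local maxima of the band-pass response
`G(σ_small) − G(σ_large)` (defaults 1.0 / 1.6 px — the classic DoG ratio,
matched to diffraction-limited puncta at 0.4 µm/px). The detection
threshold is robust and relative: `k × MAD` of the response over the
first, pre-stimulus frame (default k = 5), so classification is invariant
to overall intensity scaling.

Each maximum is then classified by the γ-normalised Hessian
(σ²-scaled second derivatives at `hessian_sigma`, default 1.6 px):

* `extracellular` — the position falls on the border mask (dilated 1 px);
* `membrane_ridge` — any eigenvalue ≥ 0, or blobness `λ₂/λ₁ < 0.25`;
* `bulk` — the coarse-scale DoG response (`bulk_sigma` = 6 px) exceeds
  1.5 × the fine-scale response: the structure lives at the coarse scale;
* `punctate` — everything that survives.

Two defaults were calibrated on the synthetic generator and differ from
common first guesses. Blobness 0.4, a usual ridge cut, discards real
puncta whenever two of them sit 2–4 px apart (their joint intensity
profile is elongated); 0.25 keeps those pairs while synthetic ridges at
any orientation still score essentially 0. The minimum separation
between reported maxima is 2 px; larger values silently merge close
pairs. Both remain exposed in `scale_space_params()`.

The paper-era distinction between clathrin-mediated (seconds) and bulk
(minutes) endocytosis by *onset time* is deliberately not used for
classification: at a 22–36 s frame interval, second-scale onsets are
unresolvable, so the scale-ratio test stands in. The temporal criterion
can still be applied downstream from the detection table.

## Segmentation and exclusion rules

The tracer-outlined tissue is segmented in three steps on a reference
frame taken after wash-in completes (default: first frame past
lag + 3τ, when borders are brightest and puncta still sparse). A
permissive threshold (0.35 × the 0.99 intensity quantile) gives a
gap-free border net whose complement inside the islet footprint yields
one seed region per cell; fused seeds are split by a watershed on the
distance transform (tolerance 2 px); seeds then grow over the interior
bounded by the crisp border (0.65 threshold). The published border mask
itself uses a 0.85 threshold (near the half-maximum of the blurred
clefts), removes isolated bright components and blob-like protrusions
(puncta are not membrane), and adds the 1-px islet rim, which is
extracellular by construction.

Cells with **high and uniform** uptake are flagged endothelial-like /
non-viable and excluded from all PAPT statistics (the flag is recorded,
never deleted). "Uniform" is a spatial coefficient of variation below
`cv_max` (0.3) over the temporal mean of a few post-wash-in frames;
"high" is a median intensity above the `q_hi` (0.95) quantile of the
medians of the *punctate-uptake* (high-CV) cells. Referencing the
quantile to the punctate population rather than to all cells matters:
when uniform-uptake cells exceed 5% of the population, an all-cell
quantile lands inside the endothelial group and the rule can never flag
them all.

Depth is the Euclidean distance transform of the islet footprint at the
cell centroid, in µm; `depth_profile()` bins cells into layers
`[0, w), [w, 2w), …` (default w = 10 µm).

## From detections to kinetics

The patterned-system mask is the union of disks (radius 3 px ≈ 3 PSF σ,
capturing ~99% of a punctum's flux) around punctate maxima and of
in-cell pixels whose fine-DoG response clears a network threshold — the
connected endosomal system between discrete maxima. Two guards keep this
mask honest: the network cut is floored at 10% of the running median
punctate response (without it, a noise-free response image floods the
mask with numerically-positive ripple), and network pixels must sit
≥ 2 px from the cell boundary, because the bright extracellular border
bleeds band-pass response into the first pixels of each cell.

Per cell and frame, PAPT is the summed intensity over
`cell ∩ mask(t)` minus the occupied area times the per-cell background —
the median intensity of the cell *outside* the mask, which absorbs the
dim cytosolic haze and its wash-in dynamics. Negative values are clipped
to zero. dPAPT/dt is a Savitzky–Golay (local quadratic) first derivative
over 5 frames (~2.5 min at 30 s sampling: below the phasic-secretion
timescale, above frame noise), with shrunken one-sided windows at the
ends so linear ramps differentiate exactly.

A cell is an **active responder** when its stimulus-window mean
derivative exceeds its baseline mean by 2 baseline SDs; degenerate
baseline SDs are floored at the across-cell median. The active fraction
carries a Wilson 95% interval. Wash-in/washout curves are fitted by
`A·(1 − e^{−(t−lag)/τ})` (mirrored for washout) with
Levenberg–Marquardt least squares, initialised from the 10%-rise time
and the 10→63% interval, with a derivative-free simplex fallback for the
kinked near-step limit.

## Statistics

`distance_correlation()` implements the classical (biased, V-statistic)
sample distance correlation — double-centred distance matrices, dCov² as
the mean elementwise product — which is bounded in [0, 1] and equals 1
under affine dependence; the bias-corrected U-statistic variant is an
option. Constant signals return 0 with a degeneracy flag. Group
comparisons use the tie-corrected Kruskal–Wallis or Friedman omnibus
statistic with all-pairs Nemenyi p-values from the studentized-range
approximation on mean ranks; omnibus p-values are reported unadjusted
(Nemenyi controls the pairwise family-wise error by construction).
Whether dCor is computed on raw traces or derivatives is configurable;
raw traces are the default.

## What the synthetic generator emulates — and what it does not

`generate_islet_geometry()` packs seeded random centres into a disk,
partitions by nearest centre, and erodes each cell by 1 px, producing
islet-like polygonal cells separated by 1–3 px tracer-filled borders.
`render_movie()` adds: chamber wash-in on the borders and a faint
(8%) intracellular haze; punctum births by an inhomogeneous Poisson
process with per-cell piecewise-constant rates gated by the wash-in
curve; persistent Gaussian puncta (σ = PSF); endothelial cells ramping
uniformly once tracer arrives; global mono-exponential photobleaching;
and Poisson–Gaussian noise (`Poisson(scale·I)/scale + N(0, σ_read)`).
Defaults — 512×512 px at 0.4 µm, 30 s frames, 80 frames, punctum
peak-to-noise ≈ 5 — mirror standard confocal acquisition for this
preparation.

The default stimulus is biphasic: 20 min basal (multiplier 0.2), a 1-min
first-phase burst (×25), then a sustained second phase (×6) — the
classic shape of glucose-stimulated insulin secretion, and the reason an
islet-mean derivative peak exists to locate. Per-cell heterogeneity is
lognormal with CV 0.6. The baseline rate (3×10⁻³ puncta/s before
multipliers) yields roughly 25 stimulated events per cell over the
20-min stimulus, matching the dense dotted patterns stimulated islets
show. This event budget is also a statistical floor worth knowing
about: at ~11 events per cell the per-cell rate ranking is
Poisson-limited to a Spearman ρ of about 0.81 *for a perfect estimator*,
so sparse-uptake regimes cannot be validated by rank recovery no matter
the algorithm.

Not emulated: optical sectioning and a 3-D PSF, vascular geometry,
kiss-and-run fusion pores, cell movement, and focus drift. Passing the
synthetic suite therefore says nothing about motion artefacts or
out-of-focus haze in real recordings; it does validate the detection,
classification, segmentation, tracing and statistical machinery under
realistic photon statistics.

Two test fixtures intentionally depart from the generator defaults:
perfect-recall detection tests place puncta with a minimum separation
(`puncta_min_sep_px`), because two events closer than the optical
resolution merge into one maximum for *any* detector; and the border
mask purity test keeps puncta 3 px clear of the membrane, because a
punctum overlapping a border junction is optically part of the membrane
signal. The acceptance-level benchmarks all run with merging allowed.

## Numerical choices and edge cases

* Gaussian kernels are sampled with a 6σ support; at unit pixel spacing
  the discrete sums approximate the continuous forms to better than
  1e-8, which is why the analytic Hessian tests can demand 1e-6.
* Convolution boundaries are reflecting (edge pixel repeated), for both
  the separable filters and the pointwise kernel evaluations.
* Local maxima are strict (plateaus yield none); minimum separation is
  enforced greedily, strongest response first, ties broken by smallest
  (y, x).
* The noise-free detection threshold is floored at 1e-8 a.u. so that a
  zero-MAD first frame cannot make float ripple detectable.
* Wash-in curves evaluate exactly: the rendered border at
  t = lag + τ is (1 − 1/e) of plateau to 1e-9.
* 3-D stacks are canonicalised to (t, z, c, y, x) and analysed per
  z-plane with the 2-D Hessian; full 3-D blob/plate analysis is a known
  limitation, acceptable for the 2-D acquisition geometry this targets.
* The washout-fit recovery benchmark samples at 5 s over 20 min — the
  cadence of a chamber characterisation, not of cell imaging; at 30 s
  sampling the τ error at SNR 20 sits at the 5% boundary.
* All randomness flows from one seed through named sub-streams;
  generation restores the caller's RNG state.

## Problem sizes used by the shipped benchmarks

Rate-recovery and latency run on twenty 64-cell, 512×512, 80-frame
movies (seeds 0–19); detection and segmentation quality on a 64-cell,
50-frame movie with ~200 events at punctum SNR ≈ 5; responder recovery
on 100 α-type cells with the programmed 66% silenced at SNR ≈ 10; test
calibration on 2000 null simulations per omnibus test. The acceptance
script reproduces the same quantities with six default movies to keep a
single-CPU run short.
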