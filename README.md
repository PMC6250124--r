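# paptkit

Image analysis of **patterned accumulation of a polar tracer (PAPT)** in
perifused pancreatic islets — a single-cell surrogate of hormone secretion
rate, for R.

## The problem and the method

When an islet is perifused with a small polar fluorescent tracer (such as
sulforhodamine B), the dye fills the extracellular space and sharply
outlines every cell. Stimulated exocytosis is followed by compensatory
endocytosis, which traps a little extracellular tracer in each newly
retrieved vesicle. Under stimulation the cell interior therefore fills
with sub-resolution fluorescent puncta, and the accumulated intensity of
this *patterned system* — the PAPT signal — tracks the cell's cumulative
secretion. Its first temporal derivative, dPAPT/dt, tracks the secretion
*rate*: its peaks coincide with stimulus-induced secretory maxima.

`paptkit` implements the full analysis chain:

1. **Detection** — candidate endocytotic maxima by an adjustable
   difference of Gaussians (DoG), `response = G(σ_small) − G(σ_large)`;
2. **Shape classification** — the γ-normalised Hessian `σ²·∇²I` at each
   maximum: bright puncta have two strongly negative eigenvalues
   (blobness `λ₂/λ₁` near 1), membrane and extracellular tracer form
   ridges (`λ₂ ≈ 0`), and diffuse bulk-mode uptake is recognised by a
   dominant coarse-scale response; only `punctate` maxima count;
3. **Segmentation** — the tracer-bright borders partition the tissue into
   cells (two-level thresholding, watershed seeding, constrained region
   growing); cells with high *and uniform* uptake are flagged
   endothelial-like/non-viable and excluded;
4. **Kinetics** — per-cell background-corrected PAPT traces over the
   cumulative patterned-system mask, Savitzky–Golay dPAPT/dt, responder
   classification (active iff the stimulus-window mean derivative exceeds
   baseline mean + 2 SD), depth profiles, and delayed-exponential fits of
   the perifusion wash-in/washout
   `f(t) = A·(1 − e^{−(t−t_lag)/τ})`;
5. **Statistics** — distance correlation (dCor) between paired per-cell
   signals, response sorting for surface plots, and Kruskal–Wallis /
   Friedman omnibus tests with Nemenyi post-hoc analysis;
6. **Synthetic ground truth** — a generator of islet-like movies
   (packed cells, chamber wash-in with lag and exponential equilibration,
   persistent Poisson-process puncta, endothelial-like uniform uptake,
   photobleaching, Poisson + Gaussian noise) so every stage is testable
   without real data.

## A worked example

```r
library(paptkit)

# synthesize a default islet movie: 64 cells, 512x512 px (0.4 um/px),
# 80 frames at 30 s, biphasic glucose-step stimulus at t = 20 min
geom  <- generate_islet_geometry(64, 512, seed = 1)
rates <- simulate_rates(default_protocol(), geom$cell_types, seed = 1)
sim   <- render_movie(geom, rates, n_frames = 80, seed = 1)

# detect maxima, classify them, build the patterned-system mask and the
# per-cell traces in one pass (here over the generator's ground-truth
# segmentation, so the result can be compared to the programmed rates;
# segment_cells() recovers the same partition from the image alone)
ana <- papt_analyze(sim$stack, scale_space_params(), sim$truth$label_map,
                    border_mask = sim$truth$border_mask)
table(ana$detections$class)
#>           bulk  extracellular membrane_ridge       punctate
#>           1357          26299           3194          11897

# how well does the estimated per-cell secretion rate rank the truth?
tr  <- ana$traces
sel <- tr$frame %in% 42:80                 # stimulus window
est <- tapply(tr$dpapt_dt[sel], tr$cell_label[sel], mean)
cor(est, rates$lambda[as.integer(names(est)), 3], method = "spearman")
#> [1] 0.8696886
```

The class table says most maxima sit on the tracer-filled extracellular
space (discarded), a minority are membrane ridges or bulk uptake, and the
~12k punctate detections (puncta × frames) drive the per-cell traces. The
Spearman ρ ≈ 0.87 shows the dPAPT/dt read-out recovers the programmed
per-cell secretion-rate ranking.

Fitting the chamber wash-in curve recovers the perifusion characteristics
(printed in minutes):

```r
tt <- seq(0, 1195, 5)
fit_washout(ifelse(tt < 138, 0, 1 - exp(-(tt - 138) / 126)), tt)
#> perifusion onset fit: lag 138 s (2.30 min), tau 126 s (2.10 min), amplitude 1, RMS 0
```

A full run — movie, detections CSV, label map, ROI/trace/responder
tables, stats JSON, run log — is one call (or
`Rscript inst/scripts/papt.R run --seed 1 --out out/` from a shell):

```r
run_pipeline(default_config(seed = 1), "out/")
```

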