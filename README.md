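# endozone

Quantitative image analysis of the postsynaptic **endocytic zone (EZ)** —
the stable clathrin-coated structure apposed to the postsynaptic density
(PSD) in dendritic spines — for microscopists and neurobiologists working
with single-molecule localization microscopy (SMLM), confocal/STED
morphometry, live-cell imaging and FRAP of clathrin and endocytic
proteins.

The package implements the full measurement chain as reusable, tested R
functions, and ships a seeded synthetic-scene generator with analytic
ground truth so that every stage can be validated without raw microscopy
data:

* **SMLM preprocessing** — consecutive-frame merging of blinking runs
  (precision-weighted, idempotent), 15 nm precision cutoff, ROI cropping,
  CSV dialects (`merge_consecutive()`, `precision_filter()`,
  `read_localizations()`).
* **Nanoscale cluster geometry** — DBSCAN (eps 0.2 µm / minPts 100 and
  0.35 µm / 50 regimes), convex or alpha-shape borders, signed
  border distances (negative inside), FWTM dimensions
  (FWTM = 2√(2 ln 10) σ for a Gaussian), primary/secondary
  classification, and border-scaled ring density profiles: ring *k*
  between scale fractions f_k, f_{k+1} has area fraction
  (f_{k+1}² − f_k²)/1.6² for *any* simple polygon
  (`dbscan_cluster()`, `ring_density_profile()`).
* **Morphometry** — Feret length/width, circularity 4πA/P², and
  fixed-diameter circular-ROI association of clathrin puncta with PSDs
  (`punctum_shapes()`, `associate_ez_psd()`).
* **Dynamics** — kymographs, Fourier direction filtering into
  stationary / anterograde / retrograde components (an exact spectral
  partition; sign(f_x·f_t) separates the directions), intensity CV,
  greedy track linking, lifetime classes with strict < 3 min / > 9 min
  boundaries (`fourier_direction_filter()`, `lifetime_classify()`).
* **FRAP** — double normalization and bounded nonlinear least-squares of
  I(t) = A(1 − e^(−Kt)) on the 19-min non-uniform acquisition schedule
  (`normalize_frap()`, `fit_frap()`).

## Worked example

The numbered scripts under `analysis/` run the whole workflow on
simulated data and write tables under `results/`. Stage 2, for example,
merges and filters five simulated two-channel scenes, DBSCANs the EZ and
PSD channels, and profiles the accessory channel (generated with a
Beta(8,2) edge-enrichment law, mode at 87.5% of the border radius)
against the EZ border:

```sh
$ Rscript analysis/01_simulate.R
$ Rscript analysis/02_nanoscale.R
EZ geometry over 5 scenes: area 25.1 x 10^3 nm^2, FWTM 230 x 160 nm,
PSD border to EZ centroid 11.6 nm (generator truth 10.6 nm)
accessory density peaks in ring 5 (80-100% = ring 5); population profile:
[1] 0.000 0.013 0.105 0.399 0.455 0.029 0.000 0.000
```

The recovered EZ matches the generator: an ellipse drawn at the measured
EZ scale (~225 × 147 nm, area ~26 × 10³ nm²) whose centroid sits ~10.6 nm
outside the PSD border, and the area-normalized ring profile peaks in the
80–100% ring — the accessory protein is enriched near, but inside, the
EZ edge. FRAP fitting recovers its generator exactly on noiseless
traces:

```sh
$ Rscript analysis/04_frap.R
FRAP fit: A = 0.758 (mobile fraction), K = 0.0769 /min, tau = 13.0 min
  recovery at 10 min: 40.7% (fitted), 40.7% (raw point)
  recovery at 20 min: 59.5% (fitted), 58.2% (raw point)
```

The methods vignette (`vignettes/endozone-methods.Rmd`) documents the
models, parameter defaults, numerical choices and limitations — including
why the slow-turnover FRAP regime (τ ≈ 36 min) is not identifiable from
noisy 19-min traces.

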