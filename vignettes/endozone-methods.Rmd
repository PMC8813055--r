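---
title: "Methods: quantifying the postsynaptic endocytic zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the postsynaptic endocytic zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endozone)
```

The endocytic zone (EZ) is a stable clathrin-coated structure that sits
next to the postsynaptic density (PSD) in dendritic spines and locally
recycles neurotransmitter receptors. Characterizing it quantitatively
requires four rather different measurement pipelines — single-molecule
localization microscopy (SMLM) cluster geometry, pixel-level morphometry,
live-imaging dynamics, and FRAP kinetics — and `endozone` implements all
four against a seeded synthetic-scene generator with analytic ground
truth, so every stage can be validated end to end without raw microscopy
data.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and the known limitations. The numbered
scripts under `analysis/` run the whole workflow and print the quantities
discussed here; nothing below claims a result those scripts or the test
suite do not themselves compute.

## SMLM preprocessing

Localization tables carry 0-based frame indices, positions in nm, a
localization precision (the SD of the fitted position) and a channel
label. Two preprocessing steps precede all geometry:

**Consecutive-frame merging** (`merge_consecutive()`). A fluorophore that
stays on for several frames yields a run of localizations; runs are
re-linked greedily (nearest neighbour, one detection per run per frame)
within a 30 nm radius and collapsed to the precision-weighted mean
position, with pooled precision $1/\sqrt{\sum_i 1/\sigma_i^2}$. The 30 nm
default is twice the precision cutoff below; it is not a measured
constant. Rows that already represent a completed run (`n_merged > 1`)
neither extend a run nor accept extensions: a completed blink run does not
continue, and this rule is what makes merging exactly idempotent. Gap
closing across missed frames is available (`max_gap`) but off by default.

**Precision filtering** (`precision_filter()`). Localizations with
precision above 15 nm are discarded, boundary inclusive. The cutoff is
applied after merging, as a quality filter on the pooled positions.

## Cluster geometry

**DBSCAN** (`dbscan_cluster()`) uses the standard density-expansion
semantics: a core point has at least `min_pts` neighbours (self included)
within `eps`; clusters are maximal density-connected core sets plus their
border points. Two regimes are used: `eps` 0.2 um / `min_pts` 100 for
PSD and EZ outlines, and 0.35 um / 50 for sparser endocytic-protein
channels. The printed epsilons are dimensionless in common usage; we read
them as micrometers, the only physically sensible scale for structures of
150–250 nm. Border points reachable from several clusters go to the
first-discovered cluster under the deterministic input ordering, so labels
are reproducible and the implementation can be compared exactly (up to
relabeling) against a brute-force distance-matrix oracle — the test suite
does this on hundreds of random scenes.

**Borders** (`cluster_border()`) default to the convex hull of the member
localizations, the closest analogue of a polyshape drawn around a DBSCAN
cluster; a concave alpha-shape (pair-circle construction, radius `alpha`)
is available for clearly non-convex clusters. Hulls of noisy
localizations are slightly inflated: each 1 nm of localization noise adds
roughly its own magnitude to the apparent border radius. The ring
profiles below are sensitive to this (see *Numerical choices*), which is
one reason merging precedes clustering.

**Geometry measures.** `border_to_centroid_distance()` and
`distance_to_border()` return signed distances, negative inside the
polygon; `fwtm_dimensions()` projects a cluster on its principal axes,
histograms each projection (5 nm bins, Gaussian smoothing with SD 2 bins)
and reports the full width at tenth maximum with linear interpolation at
the crossings. For a Gaussian cluster of SD $\sigma$ the expected FWTM is
$2\sqrt{2\ln 10}\,\sigma \approx 4.29\sigma$; bin width and smoothing are
free choices (no measured values exist for them) and the defaults add
about 2% width at $\sigma = 50$ nm. When one PSD has several clathrin
clusters, `classify_primary_secondary()` calls the largest the primary
structure (the EZ) and the rest secondary, with area ties broken by
PSD proximity.

## Border-scaled ring profiles

To compare protein distributions across EZs of different sizes, the
border polygon is scaled about its centroid to the fractions
0.2, 0.4, ..., 1.6; ring $k$ is the region between successive scales.
Because a homothety multiplies any polygon's area by the square of its
factor, ring $k$ occupies the area fraction
$(f_{k+1}^2 - f_k^2)/1.6^2$ of the full ringed region regardless of the
polygon — an analytic identity the tests verify to $10^{-6}$. Each query
localization gets a radial scale $r/R(\theta)$ (centroid distance over
border radius along its direction, exact for star-shaped polygons, hence
for every convex border); scales are binned, the per-ring localization
fraction is divided by the ring's area fraction, and the resulting
8-vector is renormalized. "Normalized to 1" is ambiguous between sum and
maximum; we normalize the sum (switchable via `normalize = "max"`), so a
uniform point cloud gives a flat profile at $1/8 = 0.125$. Per-EZ
profiles are averaged arithmetically for population plots
(`average_ring_profiles()`).

## The synthetic generator

`make_localization_scene()` draws a circular PSD (radius 150 nm), an
elliptical EZ with semi-axes 112.3 x 73.25 nm (the measured ~225 nm
length and ~147 nm width of EZs; ellipse area ~25.8e3 nm^2), its centroid
placed 10.6 nm outside the PSD border (the measured mean border-to-
centroid separation), and an accessory channel whose normalized radius
follows a Beta($\alpha$, $\beta$) law along uniformly random directions:
$r = R(\theta)\,B$, $B \sim \mathrm{Beta}(\alpha, \beta)$. The law is the
generator's own device — the imaged proteins have no known generative
model — chosen because it is analytically tractable: Beta(1,1) is uniform
in the radius fraction and Beta(8,2) has its mode at $7/8 = 0.875$,
inside the 80–100% ring, emulating the edge enrichment of endocytic
adaptors. Molecules blink as geometric runs (mean `blink_run_length`
consecutive frames) jittered by `precision_sigma` (default 5 nm), so the
merging step has real work to do and ground truth records the
molecule-to-localization map.

What the generator does *not* emulate: fluorophore photophysics beyond
geometric runs, drift, chromatic offsets, repeat blinking of the same
molecule after a dark gap, or background localizations. Passing tests
therefore show the pipeline recovers known generative structure through
realistic blinking and noise — not that it is robust to every artifact of
real dSTORM data.

`make_dynamics_scene()` renders a 5 s / 5 min line movie (61 frames,
128 px of 100 nm) with stationary spots fluctuating at CV 0.06 and
directed spots at 1.2 um/min in both directions, keeping the per-component
movies as ground truth; an event stream with a two-exponential lifetime
mixture (p = 0.5 between means 1.5 and 15 min, the short/persistent split
seen for clathrin); and a FRAP trace on the 19-min schedule.

`make_mask_scene()` builds confocal-scale binary masks where a known
fraction of synapses has a punctum inside the association ROI.

## Live-imaging dynamics

**Kymographs** (`build_kymograph()`) sample the movie along a path, one
row per timepoint, max-projecting across the line width.
`fourier_direction_filter()` splits the 2D spectrum into three exact
partitions: the stationary band ($|f_t| \le$ `band_t`, plus the zero
spatial frequency column), and the two quadrant pairs
$\mathrm{sign}(f_x f_t) < 0$ (anterograde: energy of a feature moving
toward $+x$ lies on $f_t = -v f_x$) and $> 0$ (retrograde). Because the
masks partition the spectrum, the three inverse transforms sum exactly to
the input (Parseval-complete reconstruction, checked to $10^{-6}$).

**`band_t` defaults to 0**, keeping only the temporally constant plane in
the stationary component. With ~60-frame acquisitions a band of even one
frequency bin absorbs a large share of slowly moving particles (measured:
anterograde energy capture drops from ~0.9 to ~0.72), while truly
stationary structures are temporally constant up to intensity flicker,
which is spatially symmetric and splits evenly — and therefore harmlessly
— between the two motion components (measured crosstalk below 1%).

**Tracking** (`link_tracks()`) is greedy nearest-neighbour frame-to-frame
assignment within `max_link`, with optional gap closing. Greedy linking
is adequate for sparse, well-separated puncta and is checked against
ground-truth event streams; it is not an optimal (LAP) assignment and
will swap identities in crowded fields. Lifetimes are
$(\mathrm{last} - \mathrm{first} + 1) \times \Delta t$.
`lifetime_classify()` uses strict boundaries — short $< 3$ min,
persistent $> 9$ min, a lifetime of exactly 3 min is intermediate — and
treats censored tracks (alive at either end of the movie) as persistent
only if their observed span already exceeds 9 min, excluding them
otherwise. Excluding right-censored tracks over-represents short events
relative to the underlying mixture; the analysis script prints both the
tracked and the ground-truth fractions to make that bias visible.

**Intensity CV** (`trace_cv()`) is the sample SD over the mean,
distinguishing rapidly exchanging shaft structures (CV ~0.06) from stable
spine structures (~0.02).

## FRAP

`normalize_frap()` applies double normalization: background-subtracted
ROI over background-subtracted reference (cancelling acquisition
photobleaching), divided by the mean pre-bleach ratio, then re-zeroed at
the first post-bleach frame $t = 0^+$ so residual post-bleach intensity
is divided out and the fitted amplitude is directly the mobile fraction.
`fit_frap()` fits $F(t) = A(1 - e^{-Kt})$ by bounded
Levenberg–Marquardt least squares ($A \in [0, 1.2]$ — values above 1 are
already unphysical — and $K > 0$), all points weighted equally on the
non-uniform schedule, initialized at $A_0$ = final value and
$K_0 = 1/t_{1/2}$. A constant series is handled analytically ($A$ equals
the level, $K$ unidentifiable); non-convergence returns a flagged fit,
never a silent fallback. Reported quantities are $A$, $K$, $\tau = 1/K$,
and the recovery at caller-chosen reference times, both from the fitted
curve and as the nearest measured point (the two readings of "% recovery
after X min").

**Identifiability.** On the 19-min schedule, parameter recovery from
noiseless traces is exact to solver tolerance for any $(A, K)$ — the test
suite verifies the fast-exchange regime ($A = 0.758$, $\tau = 13$ min)
and the slow EZ regime ($A = 0.38$, $\tau = 36.2$ min). With additive
noise of SD 0.05 the two regimes behave very differently. The linearized
Cramér–Rao bound at the fast regime gives a per-fit SD of about 0.12 on
$A$; at the slow regime the curve only reaches $0.38(1 - e^{-19/36.2})
\approx 0.15$ within the window, and the bound is about 0.79 on $A$ and
250% on $\tau$ — the plateau is simply not in the data. Monte-Carlo
replicates (run by `analysis/04_frap.R` and the acceptance script)
reflect this: estimates ride a correlated $(A, K)$ ridge, a fraction
reach the $A$ bound, and mean estimates at the slow regime are biased
upward by the truncation. Slow-turnover FRAP on this schedule should be
interpreted through the fitted curve and the measured recovery at a fixed
time, not through $A$ and $\tau$ separately.

## Morphometry

Masks are logical matrices with a known pixel size. Feret length is the
maximum pairwise distance between boundary-pixel centers plus one pixel;
Feret width is the minimum caliper width over orientations (rotating
calipers on the boundary hull) plus one pixel. Circularity is
$4\pi A / P^2$, clipped to 1, with the area as the pixel count and the
perimeter as the length of the traced 8-connected boundary contour
through pixel centers; a single-pixel object is defined as circular. On
rasterized shapes this perimeter makes an axis-aligned $n \times n$
square converge to $\pi/4$ and keeps a large disc above 0.9, the two
anchor cases used in the tests. Connected components use 8-connectivity.

`associate_ez_psd()` centers a circular ROI of fixed diameter — default
0.79 um, the midpoint of the 0.69–0.89 um range used in practice — on
each PSD and scores the synapse positive if any mask component has a
pixel center inside the closed disc ("overlapped partially or
completely"); it also counts the distinct overlapping components. The
fraction of positive synapses is monotone in the ROI diameter, which the
tests check across the printed range.

## Numerical choices and degenerate inputs

* Boundary conventions are closed everywhere: precision exactly at the
  cutoff is kept, a point on an ROI edge or border polygon is inside.
* Ring scaling is a homothety about the border centroid; the outermost
  ring (160%) bounds the profile's denominator (localizations beyond it
  are excluded), matching the choice that the ringed region — not the
  crop ROI — defines the reference population.
* The ring argmax is sensitive to border calibration: for the Beta(8,2)
  law the 60–80% and 80–100% ring densities differ by ~18%, so inflating
  the border radius by only ~2.5% flips the peak ring inward. Raw 5 nm
  localizations inflate a convex hull by about that much; after merging
  (pooled precision ~2.5 nm) the bias is negligible. The acceptance test
  therefore runs the full merge–filter–cluster–profile pipeline.
* Degenerate clusters (fewer than 3 distinct points, collinear points)
  raise errors rather than returning degenerate polygons; a cluster of
  identical points has FWTM (0, 0).
* DBSCAN border-point ties, track-linking order and merge linking are all
  resolved greedily under deterministic orderings, so identical seeds give
  bit-identical outputs (`run_pipeline()` writes a manifest and reruns
  reproduce its files exactly).
* Problem sizes used by the tests and the acceptance script — scenes of
  300–800 molecules, ring profiles at $10^4$ points, 100-replicate
  Monte-Carlo fits, 100 oracle-checked clustering scenes — were chosen so
  each check is statistically decisive for its tolerance.

## Limitations

2D only (no astigmatic z); no drift correction or channel registration
(inputs are assumed registered); greedy rather than optimal tracking; no
cluster significance testing (e.g. Ripley's K) or colocalization
coefficients; segmentation of confocal images into masks is upstream of
this package. The alpha-shape border is quadratic in cluster size and
intended for per-cluster point counts, not whole-field maps.
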