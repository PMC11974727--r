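---
title: "Quantifying foam-like cellularization: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying foam-like cellularization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foamquant)
```

# The biological problem

Chytrid fungi such as *Spizellomyces punctatus* cellularize a multinucleate
sporangium in a single synchronous event: membrane furrows invade the
cytoplasm, branch and merge, and settle into a space-filling honeycomb of
polyhedral compartments — a cellularization foam — each enclosing one
nucleus. foamquant provides the image-quantification machinery needed to
measure this process from single-plane time-lapse fluorescence microscopy:

* foam geometry (the angles at which furrows meet),
* cortical nuclear migration (the transient enrichment of nuclei at the
  plasma membrane at cellularization onset),
* daughter-cell size (peak-to-peak membrane spacing in the peripheral
  cell layer),
* actin-network texture dynamics under drug treatment, and
* tension release after laser ablation (recoil velocimetry and
  receding-tip kinetics).

Because the corresponding microscopy data are not publicly deposited, the
package ships a seeded synthetic-imaging generator that emulates the
statistical and geometric structure each analysis assumes, with exact
ground truth. All validation in the test suite runs against these scenes.

# Coordinate and unit conventions

One convention is used everywhere: images are numeric matrices with rows
along y and columns along x; pixel coordinates are 0-based with pixel
centres at integers; angles are measured from the +x axis,
counter-clockwise in image coordinates. Physical calibration travels with
the data: `image_frame` and `time_lapse` carry the pixel size (µm/px,
default 0.11 µm/px in the generators, matching 100x spinning-disk
acquisition) and timestamps in seconds. Analyses report µm, µm/s, degrees
and minutes; generator ground truth uses the same units so that
truth-versus-estimate comparisons need no conversion.

# Ellipse geometry

The sporangium outline is modelled as an ellipse fitted to boundary
points by the direct conic-constrained least-squares method
(Halir–Flusser stabilisation of Fitzgibbon's fit). The method is
deterministic and needs no initialisation; on noiseless parametric
samples it recovers centre, semi-axes and orientation to better than
1e-6 px (tested). Orientation is reported modulo π; for nearly circular
cells the orientation is ill-conditioned, which is why the recovery test
relaxes only the angle tolerance when `a ≈ b`.

The "radius" of an interior point is defined as the factor `f` such that
the point lies on the concentric ellipse scaled by `f`. This makes
donut/disk membership, polar unwrapping, and band line-scans exact for
ellipses and reduces to the ordinary radius for circles.

Two scale factors matter downstream:

* `f = 0.70` — the published boundary between the outer "donut" and the
  inner disk for the cortical nuclear ratio. The exact equal-area factor
  is `sqrt(0.5) ≈ 0.707`; whether the original analysis used 0.70 or the
  exact value is ambiguous, so both are exposed and 0.70 is the default.
  The difference in expected null ratio is about 2%.
* `f = 0.85` — the line-scan ellipse for daughter-size estimation. A
  stated "0.85%" elsewhere is read as a typo for factor 0.85, consistent
  with "85% radii".

Peak-to-peak daughter spacings are measured as arc length along the
scaled ellipse (not chord length); for the published 3–3.5 µm spacings
on ~20 µm cells the difference is below 1%.

# Nuclear segmentation and the cortical ratio

Nuclei are segmented by 3-class multi-Otsu thresholding (background /
cytoplasm / nuclei; brightest class is foreground), the exact Euclidean
distance transform, and marker-controlled watershed with markers at
distance-transform maxima separated by at least 5 px. Objects under
9 px² are discarded and centroids are intensity-weighted. The class
count, marker separation and minimum area are declared defaults — the
original description names only "thresholding and watershed".

The cortical nuclear ratio is `n_outer / n_inner` for centroids inside
the perimeter ellipse. A frame with `n_inner = 0` yields an undefined
ratio which is *flagged and propagated*, never silently dropped:
dropping such frames would bias peak detection toward cortically
enriched frames. Under uniform placement at the equal-area factor the
ratio is 1 in expectation (verified by a 200-draw Monte-Carlo suite to
±0.02); at `f = 0.70` the null sits near 1.04.

Series are aligned by shifting times so the global maximum ratio is at
t = 0, ties broken by the earliest time, with an optional 3-point median
prefilter (off by default) against single-frame segmentation glitches.
Smoothing is local-linear loess (tricube weights, nearest `span*n`
neighbours), default span 0.2 with a 99% pointwise band — the published
visualisation settings.

**Resolution limit worth knowing.** The synthetic migration movie moves
every nucleus radially by a shared Gaussian pulse factor
`1 + A exp(-(t - t0)^2 / 2σ_t^2)` (defaults A = 0.25, σ_t = 5 min,
emulating the ~10-minute enrichment window). Because the pulse acts as a
common monotone map on a fixed population, the measured ratio plateaus
near the pulse top: with 1-minute sampling, the argmax is only
localisable to roughly ±σ_t/2 regardless of segmentation quality. The
peak-alignment test therefore runs at the 3-minute cadence used for the
drug time-lapses, where "within one frame" matches the intrinsic
resolution. A green test establishes that peak alignment works at that
cadence, not that 1-minute localisation is possible for broad pulses.

# Daughter size and the zoospore CV

The membrane intensity along the 0.85 ellipse is averaged across a
3-px-wide band normal to the ellipse and scanned at equally spaced
parameter values; positions are reported as arc length in µm and the
profile is periodic. Peaks are local maxima with prominence at least 10%
of the profile's dynamic range and spacing at least 1 µm (declared
defaults), refined to sub-sample positions by a parabolic fit — without
the refinement, pixel quantisation (0.11 µm) biases downstream
exponential fits by >10%. Periodic spacings include the closing gap, so
they sum exactly to the perimeter. The coefficient of variation is
100·SD/mean (sample SD).

# Texture dynamics (Haralick ASM)

The Angular Second Moment is `sum(P^2)` of a symmetric, normalised
gray-level co-occurrence matrix: 1 for a uniform image, 1/k² for
k-level i.i.d. noise. Defaults: 8 gray levels, the average of ASM over
the four unit offsets (0°, 45°, 90°, 135°); a single-offset mode is
retained for the hand-checkable cases (constant → 1; 2-level
checkerboard at offset (0,1) → 0.5).

Quantisation is the one genuinely consequential design choice:

* For a *single frame*, rank-based equal-count binning is the default —
  it makes ASM invariant to affine intensity rescaling (illumination
  drift), which is tested as a property.
* For a *time series* (`stack_texture_series`), all frames are quantised
  with one fixed set of equal-width bin edges taken from the reference
  frame (the frame right before treatment). This is not cosmetic: under
  per-frame equal-count binning the marginal histogram is uniform by
  construction, so ASM is bounded below by 1/k² and *minimised* by a
  dissolved (noise-like) frame — the homogenisation signal would be
  inverted. Fixed reference-scale bins let the shrinking intensity
  spread of a dissolving network concentrate into fewer bins, which is
  exactly what "increase in homogeneity" means.

Relative homogeneity is the ASM ratio to the reference frame (1.75 reads
as a 75% increase). On synthetic dissolution movies (dense band-pass
filament texture whose contrast decays exponentially after drug onset,
default time constant 1.5 min within the observed five-minute
disassembly) the relative series rises monotonically to a plateau and
returns to within 10% of 1 after washout.

# Ablation mechanics

PIV is standard zero-normalised FFT cross-correlation over square
interrogation windows (default 32 px windows, 16 px overlap) with a
3-point Gaussian sub-pixel estimator (parabolic fallback when a
correlation neighbour is non-positive) and SNR defined as the
first-to-second correlation peak ratio outside a 3×3 exclusion zone.
Window size, overlap and the SNR cut (1.3) are declared defaults; the
original analysis names none. Vectors must also have non-zero magnitude;
the magnitude and SNR filters commute, so their order is irrelevant.
Integer and 0.4-px constructed shifts are recovered within 0.2 and
0.1 px respectively, and the implementation is checked against two
independent oracles: a brute-force direct spatial correlation (same
estimator, no FFT) within 0.1 px, and scikit-image phase correlation on
a constructed shift.

The radial component V_A of each vector is its projection onto the unit
vector away from the ablation site; positive V_A is recoil, negative is
the repair movement back toward the cut. V_A is rotation-equivariant and
vanishes for solenoidal fields (both tested). Summaries bin records by
distance (default 1 µm) and time (default the native frame interval)
and attach seeded percentile-bootstrap CIs of the mean (default 99%,
n_boot = 2000). Empty bins are kept and flagged.

The ablation gap is handled the way the experiment forces: frames during
ablation are blank (the emission filter blocks the camera), so the first
PIV pair spans the last pre-ablation frame and the first post-ablation
frame. By default dt is the true timestamp difference (~3 s); a nominal
1-s mode exists because both processing variants were analysed, and the
3-s resampling of the whole series (`resample_stack`) is the default
main processing. Kymographs *sum* intensity across a 20-px band while
tip profiles *average* across a 10-px band — the two widths and
reductions are preserved deliberately from their respective sources.

Receding furrow tips are the two most prominent peaks of the band
profile; frames without exactly two confident peaks are flagged and
excluded from the single-exponential fit
`D(t) = D0 + A (1 - exp(-t/τ))`, which recovers (A, τ) within 10% on
synthetic movies (typically within 1%).

The recoil-duration readout is "the last time bin whose bootstrap CI
excludes zero" — with a caveat found during development: a backward-warp
synthetic movie has almost no incoherent noise, so arbitrarily small
mean velocities remain "significant". The acceptance check therefore
measures the detection floor from the pre-ablation bins and compares the
estimated duration against the truth crossing `τ ln(v0 ḡ / floor)`,
within one time bin.

# Resampling statistics

The permutation test of the difference of means is one-tailed with a
caller-supplied direction (the original tested for a size *reduction*;
no automatic direction inference). Monte-Carlo p-values use the +1
correction, `p = (1 + n_extreme)/(n_perm + 1)`, never 0; when
`choose(n1 + n2, n1) ≤ 1e5` the test enumerates all label splits and is
exact (the 3-vs-3 worked example gives exactly p = 1/20). Bootstrap CIs
are percentile intervals with a fixed seed. Calibration suites (1000
seeded replicates each) verify type-I error 0.05 ± 0.015 and 99% CI
coverage 0.99 ± 0.01; they run with n_perm = 499 and n_boot = 999 per
replicate to stay inside the CPU budget — a scale-down of the defaults,
not of the tolerances.

# What the generator does and does not emulate

Rendered: elliptical sporangia; Lloyd-relaxed discrete Voronoi foam
cross-sections with bright membrane ridges and junction ground truth;
diffraction-level Gaussian PSF blur (σ = 1.5 px ≈ the diffraction spot
at 0.11 µm/px); Gaussian read noise with optional Poisson shot noise;
transient cortical migration pulses; jittered peripheral daughter
layers; band-pass filamentous actin texture advected by an
exponentially decaying radial recoil field with blank ablation frames
and an optional repair phase; separating Gaussian furrow tips; network
dissolution and washout.

Not emulated: out-of-focus light and 3D sectioning, photobleaching,
stage drift, cytoplasmic streaming, cell-to-cell variability in
morphology, and the irregular topology of real mid-stage furrow
networks. Green tests therefore establish that the estimators are
correct and well-calibrated on data satisfying their stated assumptions
— not that those assumptions hold in any particular real data set.

Determinism is a hard contract: identical configurations (including the
seed) produce bit-identical stacks and ground truth, and every
pipeline output directory embeds the config that produced it.

# Numerical and degenerate-input policy

Bilinear interpolation with constant fill 0 outside support is used for
all resampling (unwraps, band scans, warps). Multi-Otsu uses a 256-bin
histogram and exhaustive threshold search. Flat profiles yield zero
peaks (not an error); all-zero frames yield empty nucleus sets; a
constant pre-ablation sum makes the mask fail loudly. Collinear or
< 6-point ellipse fits, zero-length rays, coincident tri-furrow rays,
zero-total tally columns, and PIV windows larger than the frame are
explicit errors. Ties: peak alignment takes the earliest maximum;
`top_fraction` includes speed ties at the quantile threshold.

# Known limitations

* The TIFF codec supports the uncompressed grayscale baseline subset
  only (8/16-bit unsigned, 32-bit float, either endianness). It exists
  because the analysis environment has no R TIFF bindings; it is
  validated against an independent implementation in the test suite.
* The discrete (pixel-grid) Voronoi used by the foam generator
  quantises vertex positions to ~1 px and edge bearings to a few
  degrees; truth tolerances account for this.
* PIV assumes displacements under half a window between consecutive
  (possibly resampled) frames; the recoil generator refuses to render
  scenes that violate this.
* `segment_nuclei` is single-frame; there is no identity linking across
  frames, and crowded cortical rims can merge adjacent nuclei, which
  slightly compresses measured ratio peaks.
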