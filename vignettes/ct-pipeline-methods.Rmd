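---
title: "Models and numerical choices in the ctpipe micro-CT pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in the ctpipe micro-CT pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctpipe)
```

This vignette documents the science and the engineering decisions behind
`ctpipe`: the models each stage implements, the conventions and defaults,
what the synthetic data generator does and does not emulate, and the known
limitations. It states no empirical results beyond what the package's test
suite and `scripts/acceptance.R` themselves compute.

## The processing problem

A parallel-beam (or very slightly cone-beam) micro-CT scan rotates a sample
through 180° while a scintillator-coupled 16-bit camera records
projections; flat fields (beam on, sample out) and dark fields (beam off)
are recorded around the scan. The processing task is to turn these stacks
into a quantitative 32-bit attenuation volume while removing the
instrument signature: beam profile and detector fixed-pattern (flat/dark
correction), defective pixels, detector column miscalibration (ring
artefacts), rotation-axis misalignment, propagation phase contrast fringes
and polychromatic beam hardening.

## Stage 1 — raw correction

**Flat/dark correction** is `(I - D̄) / (F̄ - D̄)` with the per-pixel means
of the reference stacks. Denominators below `eps` (default 10⁻⁶ of the
flat dynamic range) are clamped and counted; the count is reported in the
result attributes and the pipeline provenance.

**Bad pixels.** The repair rule is deliberately parameter-light: a pixel is
flagged when its dark mean or flat mean deviates from the image median by
more than `k` (default 5) times the image MAD, or when its flat response
does not exceed its dark level. Detection uses reference frames only, so it
cannot be biased by sample structure. Flagged pixels are replaced by the
median of their unflagged 3×3 neighbours, growing the window if the whole
neighbourhood is flagged.

**Threshold median filter.** A pixel is replaced by its window median only
when it deviates from that median by more than the threshold; this
preserves smooth structure exactly and makes the filter idempotent, which
the test suite asserts.

**Stage order** is flat/dark → bad pixel → threshold median → trim →
tiling. The position of the threshold median filter relative to flat/dark
correction is not uniquely determined by practice; applying it to
normalised intensities makes a single threshold meaningful across the
field of view, which is why it sits after normalisation here.

**Stitching.** Tile offsets come either from motor positions (dead
reckoning; `mm × 1000 / pixel_size_µm`) or from phase correlation of the
nominal overlap region against the already-assembled tiles, constrained to
a search radius and rounded to integer pixels — the montage problem is
treated as translation-only; rotation/scale registration and exposure
equalisation are out of scope. Overlaps are blended with a separable
linear ramp, which avoids visible seams without inventing an illumination
model; where tiles agree the blend is exact. Coordinates are 0-based,
x right, y down.

## Stage 2 — pre-processing

**TIE-Hom phase retrieval.** The homogeneous-object single-distance filter
is applied in frequency space:

$$H(u) = \frac{1}{1 + \pi \lambda z \gamma |u|^2},$$

with frequencies in cycles per metre on the detector grid, λ = 1.239842
× 10⁻⁹ m · keV / E, z the propagation distance and γ = δ/β. `H(0) = 1`,
so the mean intensity is preserved. Images are padded to the next power of
two per axis before the FFT — edge replication by default, because the
corrected background sits at a constant level near 1 and replication
minimises wrap-around fringing; `reflect` is available. Magnification is
taken as 1 (parallel-like beam), so no M² rescaling appears.

Two conventions deserve explicit mention. First, the package applies the
filter to the *intensity* and defers the `-log` conversion to the
reconstruction stage; the true Paganin thickness output `-(1/μ) ln(·)`
differs only by scaling and logarithm placement, and for reconstruction
purposes the deferred-log route is equivalent while keeping stage 2
linear. Second, `tie_forward()` implements the exact spectral inverse
(division by `H`) as the fringe-synthesis forward model; with
`crop = FALSE` it returns the padded field on which `phase_retrieve()` is
an exact inverse, which is how the round-trip tests reach 10⁻⁶ relative
error on non-power-of-two shapes.

**Beam hardening.** The correction is the second-order polynomial
`f(x) = x + C₂x²`. Physically the linearisation applies to attenuation
line integrals, so `domain = "attenuation"` (with clamping at 0) is the
default; an intensity-domain option exists because production pipelines
sometimes express the correction on intensities. `C₂ = 0` is the identity;
the intended workflow is to increase `C₂` until the centre-to-edge profile
difference of a known-uniform region vanishes, and the test suite verifies
on simulated two-component polychromatic data that the cupping-minimising
`C₂` is strictly positive.

## Stage 3 — reconstruction

**Centre of rotation.** The second projection of a 180°-separated pair is
mirrored about the detector centre column `(n_cols − 1)/2` (0-based); the
horizontal translation of maximum correlation between the two windows is
twice the axis offset. Positive offsets mean the axis sits right of
centre. The default window is the full width and the central 25% of the
height. Three numerical choices matter here and were settled by simulation
during development:

* the correlation spectrum is normalised with exponent 0.5 (generalised
  cross correlation) rather than fully whitened — projection data are
  smooth, and full whitening turns the correlation into a noise-dominated
  delta;
* the peak is refined on a ±1 px grid at 1/20 px steps by direct DFT
  evaluation, which is far more accurate than a 3-point parabola;
* a Hann taper suppresses wrap-around leakage, skipped on axes shorter
  than 8 samples.

Mirror-symmetric samples are a genuine degeneracy for this method — the
mirrored projection then correlates with itself at zero shift — which is
why the correlation window is tunable and why the bundled default phantom
is deliberately asymmetric. The automated search uses a single pair (the
first projection and the one nearest 180° away); averaging several pairs
would reduce noise further but is not implemented. `apply_cor()` shifts
every projection by the negative offset with linear interpolation and edge
padding.

**Ring-artefact correction** operates on the negative-log sinogram, where
detector-gain stripes are additive. Two methods, applied sequentially when
both are enabled — sorting first, because equalising small stripes
stabilises the detection of large ones:

* *stripe sorting*: each column is sorted along the angle axis, the sorted
  array is median-filtered across columns (default width 9), and the
  permutation is inverted. Smooth sinogram content survives nearly
  unchanged; the suite bounds the perturbation of a stripe-free sinogram
  below 1% RMS.
* *large stripes*: columns whose angular mean deviates from a
  running-median-smoothed profile (window `2 × filter_size + 1`, default
  43, so blocks up to ~21 columns remain detectable) by more than
  `snr_threshold` robust sigmas are corrected by subtracting that offset;
  untouched columns are returned bit-identical. The sigma is floored at
  10% of the profile's own robust spread, so a stripe must stand out from
  the smooth structure that survives detrending, not merely from noise —
  without the floor, a noise-free sinogram has near-zero MAD and every
  curvature extremum is falsely flagged.

The "dead stripe" variant and iterative (SIRT/CGLS) reconstruction are out
of scope.

**Filters and back-projection.** Five classical filters are implemented
behind an extensible registry (`register_filter()`): Ram–Lak `|f|` and its
Shepp–Logan, Cosine, Hamming and Hann apodisations, all zero at DC,
optionally cut off above a fraction of Nyquist. Sinogram rows are
zero-padded to at least twice the next power of two, filtered
spectrally, and back-projected with linear detector interpolation on a
grid centred on the rotation axis. The normalisation `π / n_angles` over
180° is fixed by the requirement that a uniform disc of attenuation μ per
pixel reconstructs to μ; non-uniform angle grids get trapezoid-style bin
weights that reduce to `π/n` in the uniform limit. Limited-angle
(tomosynthesis-style) runs simply restrict the angle set; dimensions are
unchanged.

**FDK.** For a finite source-to-axis distance R (in pixels, from
`source_sample_mm`), projections are cosine-weighted
(`R/√(R² + u² + v²)`), row-filtered, and back-projected voxel-wise with
magnification `R/(R − w)` and distance weight `(R/(R − w))²`, where `w` is
the voxel coordinate towards the source and the virtual detector passes
through the axis. At `R = ∞` every weight is 1 and the code path reduces
to stacked per-row FBP — the parallel-limit equivalence asserted at 10⁻³
(and observed at rounding level) in the tests. The deviation of the
geometric weights from 1 is first order in 1/R, which the suite checks via
the halving of the reconstruction deviation when the source distance
doubles.

**Circle mask.** Pixels beyond radius `ratio × width / 2` from the slice
centre are zeroed; the default 0.98 trims 2% of the width.

**Streaming.** Output slices are mutually independent in this
reconstruction (per-row FBP, or voxel-driven FDK), so the streaming path
simply partitions the z-range into slabs sized to the memory budget
(8 bytes per voxel of slab buffer), reconstructs each with the identical
code path and writes it incrementally to HDF5 — making slab/single-pass
bit-equivalence structural rather than approximate. The front-end
(stages 1–2, COR) is recomputed deterministically rather than cached, a
deliberate trade of CPU for memory. Secondary rescaled/binned outputs are
refused in streaming mode since they would need the full volume in memory.

## The acquisition container

The HDF5 dialect mirrors the data-exchange convention:
`/exchange/data`, `/exchange/data_white`, `/exchange/data_dark` (unsigned
16-bit, uncompressed, file shape `(n, rows, cols)`), `/exchange/theta`
(degrees; converted to radians only at computation boundaries), scalar
metadata under `/measurement/*`, and fill masks under `/provenance/*`.
Files are created as a complete pre-sized skeleton before any frame is
written, so acquisition-time writes never resize a dataset and
`validate_skeleton()` can report exactly which slots are missing. Volumes
can be written as HDF5, float32 TIFF stacks (one slice per file,
zero-padded suffixes), NIfTI (spacing stored in mm) or NRRD; sizes are
reported in binary units (2³⁰, 2⁴⁰), the convention under which the
documented 53/461/409 GB and 3 TB figures reproduce.

## The synthetic data generator

`simulate_acquisition()` composes, in physical order: the analytic ellipse
Radon transform (closed-form chords, verified against dense numerical
line integration to 0.1%), optional two-component polychromatic
transmission `Σ wᵢ exp(−sᵢ p)`, optional TIE fringe synthesis, a separable
cosine beam-profile roll-off peaking at 30 000 counts, per-column gain
stripes, Poisson photon noise at a configurable photon budget, dark offset
(default 100 counts) with Gaussian read noise, planted dead/hot pixels,
and final 16-bit quantisation. A fixed seed makes the output bit-identical
across runs, and every planted truth parameter lands in the metadata.

The default phantom is a head-phantom-style nest of seven ellipses with a
low-contrast pair (relative attenuations 0.55 vs 0.45 of the scale) and an
attenuation scale of `4/grid` per pixel, chosen so the maximum line
integral stays near 2 (minimum transmission ≈ 15%) — a realistic
mid-density specimen safely inside the detector range at any raster size.
Its layout is intentionally left-right asymmetric (see the COR discussion).

What the generator does **not** emulate: Fresnel propagation beyond the
TIE filter (no edge diffraction past the validity of the homogeneous
model), scintillator blur/PSF, scatter, detector lag, rotation jitter,
partial-volume effects from a non-extruded third dimension (projections
are constant along the axis except through ellipsoid extensions of the
2-D layout), and speckle/grid wavefront modulation (only the stage
trajectories — grid, serpentine, Fermat spiral with the golden angle
137.5077640500378° — are generated). Passing tests therefore demonstrate
algorithmic correctness under the stated forward model, not robustness to
every effect in real data.

## Problem sizes and defaults used in the checks

The bundled checks run at rasters of 64–256 pixels with the π/2 sampling
rule (403 projections at width 256), 20-scan COR sweeps at width 128, and
64³ volumes for FDK/streaming equivalence — sizes chosen so the whole
suite completes in about a minute on one CPU core while still exercising
every code path at full fidelity. All tolerances asserted by the tests
(5% end-to-end RMSE against the anti-aliased phantom raster, 0.5 px COR,
10⁻⁶ TIE round trip, 5× stripe suppression, bit-exact streaming) are
stated in the test files themselves.

## Known limitations

* Parallel-beam forward model only in the simulator; cone-beam geometry is
  exercised through the FDK weight checks, not through simulated data.
* COR from a single projection pair; homogeneous or mirror-symmetric
  samples need a tuned correlation window or a manual value.
* The registry ships 5 reconstruction filters; others can be added at run
  time but none beyond the classical five are built in.
* NRRD support is a minimal raw-float32 reader/writer, not a full
  implementation of the format zoo.
* The pipeline assumes the acquisition fits in memory; streaming bounds
  only the output volume, not the projection stack.
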